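#' Capture model for the enrichment workflow
#'
#' Parameterizes the probabilistic steps between tagged input DNA and the
#' enriched sequencing library.  A fragment carrying `k > 0` affinity tags
#' binds the beads with probability `b(k) = b_max * (1 - (1 - p_b)^k)` — a
#' saturating independent-site curve that rises with tag count at low CpG
#' density and plateaus at `b_max` — and, if bound, elutes into the enriched
#' fraction with probability `r`.  Untagged fragments bind non-specifically
#' with probability `q_ns` and elute with probability `r_ns`.
#'
#' The default calibration (`tau` 0.95, `p_b` 0.55, `b_max` 0.95, `r` 0.90,
#' `q_ns` 0.056, `r_ns` 0.05, `dup_rate` 0.12) puts single-site specific
#' capture at about 0.95 x 0.55 x 0.95 x 0.90 ~ 0.45 against a non-specific
#' floor of 0.056 x 0.05 = 0.0028, i.e. roughly 160-fold single-site
#' specificity, with under 5% of non-specifically bound material eluting,
#' overall recovery of multi-CpG tagged fragments in the 60%-80% range,
#' and a duplicate fraction of ~12%.
#'
#' @param tau per-site enzymatic tagging probability (near-complete tagging)
#' @param p_b per-tag incremental bead-binding probability
#' @param b_max plateau of the binding curve (must be >= `p_b`)
#' @param q_ns non-specific binding probability of untagged fragments
#' @param r elution (recovery) probability of specifically bound fragments
#' @param r_ns elution probability of non-specifically bound material
#' @param dup_rate duplicate-read fraction of the sequenced library
#' @return an object of class `capture_model`
#' @export
capture_model <- function(tau = 0.95, p_b = 0.55, b_max = 0.95,
                          q_ns = 0.056, r = 0.90, r_ns = 0.05,
                          dup_rate = 0.12) {
  for (nm in c("tau", "p_b", "b_max", "q_ns", "r", "r_ns", "dup_rate")) {
    assert_prob(get(nm), nm)
  }
  if (b_max < p_b) stop_umeseq("b_max must be >= p_b")
  structure(list(tau = tau, p_b = p_b, b_max = b_max, q_ns = q_ns,
                 r = r, r_ns = r_ns, dup_rate = dup_rate),
            class = "capture_model")
}

new_fragment_set <- function(frags, fraction, contigs) {
  stopifnot(fraction %in% c("input", "enriched", "unbound"))
  data.table::setDT(frags)
  structure(frags, class = c("fragment_set", class(frags)),
            fraction = fraction, contigs = contigs)
}

fs_meta <- function(fs) {
  list(fraction = attr(fs, "fraction"), contigs = attr(fs, "contigs"))
}

#' Number of fragments in a fragment set
#' @param fs a `fragment_set`
#' @return integer count
#' @export
n_fragments <- function(fs) nrow(fs)

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("fragment_set (%s): %d fragments on %d contig(s)\n",
              attr(x, "fraction"), nrow(x), nrow(attr(x, "contigs"))))
  invisible(x)
}

#' Combine fragment sets sharing a fraction label
#'
#' Used to pool spike-in fragments with genomic background fragments before
#' tagging and capture.
#'
#' @param ... `fragment_set` objects with the same fraction label
#' @return a pooled `fragment_set`
#' @export
combine_fragments <- function(...) {
  sets <- list(...)
  fr <- unique(vapply(sets, function(s) attr(s, "fraction"), ""))
  if (length(fr) != 1) stop_umeseq("fragment sets have mixed fraction labels")
  contigs <- unique(do.call(rbind, lapply(sets, attr, "contigs")))
  frags <- data.table::rbindlist(lapply(sets, as.data.table_plain))
  new_fragment_set(frags, fraction = fr, contigs = contigs)
}

as.data.table_plain <- function(fs) {
  out <- data.table::as.data.table(fs)
  data.table::setattr(out, "class", c("data.table", "data.frame"))
  out
}

#' Shear a genome into sequencing-ready fragments
#'
#' Draws `n_fragments` fragments with uniform start positions across the
#' genome and truncated-normal lengths (minimum 50 bp, default mean 180 bp
#' emulating sonication).  For each fragment, `n_cpg` counts the catalog
#' CpG dinucleotides wholly inside the fragment and `n_unmodified` draws
#' each site's molecule-level state Bernoulli(1 - beta) under the chosen
#' condition — beta is a population frequency, the fragment is a single
#' molecule.
#'
#' @param genome a `genome_model`
#' @param profile a `methylation_profile` over that genome
#' @param condition condition label in the profile
#' @param n_fragments number of fragments (> 0)
#' @param len_mean,len_sd fragment length distribution in bp (mean >= 50)
#' @param seed integer seed
#' @return a `fragment_set` with fraction `"input"` and origin `"genomic"`
#' @export
fragmentize <- function(genome, profile, condition, n_fragments,
                        len_mean = 180, len_sd = 20, seed = 1L) {
  stopifnot(inherits(genome, "genome_model"),
            inherits(profile, "methylation_profile"))
  if (n_fragments <= 0) stop_umeseq("n_fragments must be > 0")
  if (len_mean < 50) stop_umeseq("len_mean must be >= 50 bp")
  if (is.null(profile$beta[[condition]])) {
    stop_umeseq(sprintf("condition '%s' absent from profile", condition))
  }
  local_seed_eval(derive_seed(seed, paste0("fragmentize/", condition)), {
    contigs <- genome$contigs
    cum <- cumsum(contigs$length)
    gpos <- runif(n_fragments, 0, sum(contigs$length))
    ci <- findInterval(gpos, c(0, cum), rightmost.closed = TRUE)
    start <- floor(gpos - c(0, cum)[ci])
    len <- pmax(50, round(rnorm(n_fragments, len_mean, len_sd)))
    end <- pmin(start + len, contigs$length[ci])
    start <- pmax(0, pmin(start, end - 1))

    frags <- data.table::data.table(
      contig = contigs$name[ci], start = as.integer(start),
      end = as.integer(end), n_cpg = 0L, n_unmodified = 0L,
      n_tagged = NA_integer_, origin = "genomic",
      duplicate_of = NA_integer_)

    # count catalog sites wholly inside each fragment and draw per-molecule
    # methylation states
    beta_tab <- profile$beta
    for (nm in contigs$name) {
      pos <- genome$cpg[[nm]]
      sel <- which(frags$contig == nm)
      if (!length(sel) || !length(pos)) next
      i1 <- findInterval(frags$start[sel] - 0.5, pos) + 1L
      i2 <- findInterval(frags$end[sel] - 2 + 0.5, pos)
      cnt <- pmax(0L, i2 - i1 + 1L)
      frags$n_cpg[sel] <- cnt
      has <- cnt > 0L
      if (!any(has)) next
      site_idx <- sequence(cnt[has], from = i1[has])
      frag_id <- rep(seq_along(sel)[has], cnt[has])
      beta_nm <- beta_tab[[condition]][beta_tab$contig == nm]
      unmod <- rbinom(length(site_idx), 1L, 1 - beta_nm[site_idx])
      sums <- rowsum(unmod, frag_id)
      frags$n_unmodified[sel[as.integer(rownames(sums))]] <-
        as.integer(sums[, 1])
    }
    new_fragment_set(frags, fraction = "input", contigs = contigs)
  })
}

#' Enzymatically tag unmodified CpG sites on input fragments
#'
#' Each unmodified CpG site on each fragment is tagged independently with
#' probability `tau`, so `n_tagged ~ Binomial(n_unmodified, tau)`.
#'
#' @param fs an input-fraction `fragment_set`
#' @param tau per-site tagging probability
#' @param seed integer seed
#' @return the fragment set with `n_tagged` filled in
#' @export
tag_fragments <- function(fs, tau = 0.95, seed = 1L) {
  stopifnot(inherits(fs, "fragment_set"))
  if (attr(fs, "fraction") != "input") {
    stop_umeseq("tag_fragments expects an input-fraction set")
  }
  assert_prob(tau, "tau")
  meta <- fs_meta(fs)
  frags <- as.data.table_plain(fs)
  local_seed_eval(derive_seed(seed, "tag_fragments"), {
    frags$n_tagged <- rbinom(nrow(frags), frags$n_unmodified, tau)
  })
  new_fragment_set(frags, fraction = "input", contigs = meta$contigs)
}

#' Bead capture and elution: split fragments into enriched and unbound
#'
#' A fragment with `k = n_tagged > 0` binds with probability
#' `b_max * (1 - (1 - p_b)^k)` and, if bound, elutes into the enriched
#' fraction with probability `r`.  Untagged fragments bind non-specifically
#' with probability `q_ns` and elute with probability `r_ns`.  Every
#' fragment that does not elute — unbound or bound-but-not-eluted — goes to
#' the unbound fraction, so the two outputs partition the input.
#'
#' @param fs a tagged `fragment_set`
#' @param model a [capture_model()]
#' @param seed integer seed
#' @return list with elements `enriched` and `unbound` (fragment sets)
#' @export
enrich <- function(fs, model = capture_model(), seed = 1L) {
  stopifnot(inherits(fs, "fragment_set"), inherits(model, "capture_model"))
  if (anyNA(fs$n_tagged)) {
    stop_umeseq("fragments carry no tag counts; run tag_fragments first")
  }
  meta <- fs_meta(fs)
  frags <- as.data.table_plain(fs)
  local_seed_eval(derive_seed(seed, "enrich"), {
    k <- frags$n_tagged
    p_bind <- ifelse(k > 0, model$b_max * (1 - (1 - model$p_b)^k),
                     model$q_ns)
    bound <- runif(nrow(frags)) < p_bind
    p_elute <- ifelse(k > 0, model$r, model$r_ns)
    eluted <- bound & (runif(nrow(frags)) < p_elute)
    list(
      enriched = new_fragment_set(frags[eluted], fraction = "enriched",
                                  contigs = meta$contigs),
      unbound = new_fragment_set(frags[!eluted], fraction = "unbound",
                                 contigs = meta$contigs))
  })
}

#' Closed-form capture probability of a fragment
#'
#' Probability that a fragment with `n_unmodified` unmodified CpG sites
#' ends up in the enriched fraction, marginalizing over tagging:
#' `sum_j P(k = j | Binomial(n_unmodified, tau)) * b(j) * r`, with the
#' untagged term `q_ns * r_ns`.  Used for spike-dose expectations and as
#' the independent check on the Monte-Carlo workflow.
#'
#' @param n_unmodified number of unmodified CpG sites (vectorized)
#' @param model a [capture_model()]
#' @return capture probability per element
#' @export
capture_probability <- function(n_unmodified, model = capture_model()) {
  vapply(n_unmodified, function(m) {
    j <- 0:m
    pk <- stats::dbinom(j, m, model$tau)
    pe <- ifelse(j > 0, model$b_max * (1 - (1 - model$p_b)^j) * model$r,
                 model$q_ns * model$r_ns)
    sum(pk * pe)
  }, numeric(1))
}

#' Inject PCR/optical duplicate reads
#'
#' Adds duplicate records (referencing their source row through
#' `duplicate_of`) so that the expected duplicate fraction of the output is
#' `dup_rate`.  [dedup()] removes exactly these records, so
#' `dedup(add_duplicates(fs)) == fs`.
#'
#' @param fs a `fragment_set`
#' @param dup_rate target duplicate fraction in `[0, 1)`
#' @param seed integer seed
#' @return fragment set with appended duplicate records
#' @export
add_duplicates <- function(fs, dup_rate = 0.12, seed = 1L) {
  stopifnot(inherits(fs, "fragment_set"))
  if (dup_rate < 0 || dup_rate >= 1) stop_umeseq("dup_rate must be in [0, 1)")
  meta <- fs_meta(fs)
  frags <- as.data.table_plain(fs)
  n <- nrow(frags)
  if (dup_rate == 0 || n == 0) {
    return(new_fragment_set(frags, meta$fraction, meta$contigs))
  }
  local_seed_eval(derive_seed(seed, "add_duplicates"), {
    n_dup <- rbinom(1, n, dup_rate / (1 - dup_rate))
    if (n_dup > 0) {
      src <- sample(n, n_dup, replace = TRUE)
      dup <- frags[src]
      dup$duplicate_of <- src
      frags <- data.table::rbindlist(list(frags, dup))
    }
    new_fragment_set(frags, meta$fraction, meta$contigs)
  })
}

#' Remove duplicate reads
#'
#' Drops every record whose `duplicate_of` is set; the exact inverse of
#' [add_duplicates()].
#'
#' @param fs a `fragment_set`
#' @return deduplicated fragment set
#' @export
dedup <- function(fs) {
  stopifnot(inherits(fs, "fragment_set"))
  meta <- fs_meta(fs)
  frags <- as.data.table_plain(fs)
  new_fragment_set(frags[is.na(frags$duplicate_of)],
                   meta$fraction, meta$contigs)
}

#' Binding and recovery efficiency from step-level quantities
#'
#' Binding efficiency is the fraction of input material retained on the
#' beads (any loss of solution-phase DNA after incubation is attributed to
#' binding); recovery efficiency is the eluted material as a fraction of
#' what bound.
#'
#' @param n_input input quantity (count or mass)
#' @param n_bound quantity bound to beads
#' @param n_eluted quantity eluted
#' @return list with `binding_efficiency` and `recovery_efficiency`; a zero
#'   denominator yields `NaN` rather than an error
#' @export
binding_recovery_stats <- function(n_input, n_bound, n_eluted) {
  if (!(n_input >= n_bound && n_bound >= n_eluted && n_eluted >= 0)) {
    stop_umeseq("need n_input >= n_bound >= n_eluted >= 0")
  }
  list(binding_efficiency = if (n_input > 0) n_bound / n_input else NaN,
       recovery_efficiency = if (n_bound > 0) n_eluted / n_bound else NaN)
}

#' Fit the per-tag binding probability from binding outcomes
#'
#' Maximum-likelihood estimate of `p_b` in the saturating binding curve
#' `b(k) = b_max * (1 - (1 - p_b)^k)` from observed (tag count, bound)
#' pairs, with `b_max` held at its known value.
#'
#' @param k integer tag counts (> 0)
#' @param bound logical binding outcomes
#' @param b_max known binding plateau
#' @return the MLE of `p_b`
#' @export
fit_binding_pb <- function(k, bound, b_max = 0.95) {
  stopifnot(length(k) == length(bound), all(k > 0))
  nll <- function(p) {
    b <- pmin(pmax(b_max * (1 - (1 - p)^k), 1e-12), 1 - 1e-12)
    -sum(ifelse(bound, log(b), log(1 - b)))
  }
  optimize(nll, c(1e-4, 1 - 1e-4))$minimum
}
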