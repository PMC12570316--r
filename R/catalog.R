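#' Index CpG dinucleotides in nucleotide sequence
#'
#' One site per "CG" occurrence, reported at the 0-based coordinate of the
#' C.  Matching is case-insensitive; `N` runs break matches; characters
#' outside the `ACGTN` alphabet are rejected with their position.
#'
#' @param x named character vector of sequences, a
#'   `Biostrings::DNAStringSet`, or a `genome_model` with materialized
#'   sequence
#' @return data.frame with columns `contig`, `pos` (sorted within contig)
#' @export
index_cpg <- function(x) {
  if (inherits(x, "genome_model")) {
    if (is.null(x$sequence)) {
      stop_umeseq("genome has no materialized sequence")
    }
    x <- x$sequence
  }
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq_", seq_along(x))
    for (i in seq_along(x)) {
      bad <- regexpr("[^ACGTNacgtn]", x[i])
      if (bad > 0) {
        stop_umeseq(sprintf(
          "non-IUPAC character '%s' in sequence '%s' at position %d",
          substr(x[i], bad, bad), names(x)[i], as.integer(bad)))
      }
    }
    x <- Biostrings::DNAStringSet(toupper(x))
  }
  hits <- Biostrings::vmatchPattern("CG", x)
  out <- lapply(seq_along(x), function(i) {
    pos <- Biostrings::start(hits[[i]]) - 1L  # to 0-based
    nm <- names(x)[i] %||% paste0("seq_", i)
    data.frame(contig = rep(nm, length(pos)), pos = pos)
  })
  do.call(rbind, out)
}

#' Classify CpG sites from two bisulfite-style replicate tables
#'
#' A site is called unmethylated when its beta is below `lo` in both
#' replicates, methylated when above `hi` in both, and neither otherwise.
#' Sites with coverage below `min_cov` in either replicate are excluded
#' before classification, and the two tables are intersected on
#' (contig, pos).
#'
#' @param beta_rep1,beta_rep2 data.frames with columns `contig`, `pos`,
#'   `beta` and optionally `coverage`
#' @param lo,hi beta thresholds for the unmethylated/methylated calls
#' @param min_cov minimum coverage required in both replicates (ignored for
#'   tables without a coverage column)
#' @return list with `sites` (data.frame contig, pos, beta1, beta2, label),
#'   `n_excluded_coverage` and `n_excluded_universe`
#' @export
classify_sites <- function(beta_rep1, beta_rep2, lo = 0.05, hi = 0.95,
                           min_cov = 10) {
  t1 <- data.table::as.data.table(beta_rep1)
  t2 <- data.table::as.data.table(beta_rep2)
  for (t in list(t1, t2)) {
    if (!all(c("contig", "pos", "beta") %in% names(t))) {
      stop_umeseq("tables need columns contig, pos, beta")
    }
    if (any(t$beta < 0 | t$beta > 1)) stop_umeseq("beta outside [0, 1]")
  }
  m <- merge(t1, t2, by = c("contig", "pos"), suffixes = c("1", "2"))
  n_universe <- nrow(t1) + nrow(t2) - 2L * nrow(m)
  covered <- rep(TRUE, nrow(m))
  if ("coverage1" %in% names(m)) covered <- covered & m$coverage1 >= min_cov
  if ("coverage2" %in% names(m)) covered <- covered & m$coverage2 >= min_cov
  n_cov <- sum(!covered)
  m <- m[covered]
  label <- rep("neither", nrow(m))
  label[m$beta1 < lo & m$beta2 < lo] <- "unmethylated"
  label[m$beta1 > hi & m$beta2 > hi] <- "methylated"
  list(sites = data.frame(contig = m$contig, pos = m$pos,
                          beta1 = m$beta1, beta2 = m$beta2, label = label),
       n_excluded_coverage = n_cov,
       n_excluded_universe = n_universe)
}

#' Region set constructor
#'
#' A labelled set of sorted, non-overlapping 0-based half-open intervals.
#'
#' @param intervals data.frame with columns `contig`, `start`, `end`
#' @param label set label
#' @return object of class `region_set` (a data.frame)
#' @export
region_set <- function(intervals, label = "regions") {
  stopifnot(all(c("contig", "start", "end") %in% names(intervals)))
  intervals <- as.data.frame(intervals)[, c("contig", "start", "end")]
  intervals <- intervals[order(intervals$contig, intervals$start), ,
                         drop = FALSE]
  if (nrow(intervals) > 1) {
    same <- intervals$contig[-1] == intervals$contig[-nrow(intervals)]
    if (any(same & intervals$start[-1] < intervals$end[-nrow(intervals)])) {
      stop_umeseq("regions within a set must not overlap")
    }
  }
  rownames(intervals) <- NULL
  structure(intervals, class = c("region_set", "data.frame"), label = label)
}

#' Isolated unmethylated CpG sites
#'
#' Selects sites with beta at or below `max_beta` whose nearest catalog CpG
#' neighbour on either side is more than `exclusion_window` bp away
#' (distance measured between C positions; a neighbour at exactly the
#' window distance disqualifies the site).  These single-site probes
#' measure the per-molecule enrichment a lone unmethylated CpG confers.
#'
#' @param sites data.frame of the full CpG catalog with columns `contig`,
#'   `pos` and a beta column named by `condition`
#' @param condition name of the beta column to threshold
#' @param max_beta maximum beta (default 0: strictly unmethylated)
#' @param exclusion_window isolation radius in bp (default 250)
#' @return a `region_set` of 2-bp intervals, one per isolated site
#' @export
isolated_unmethylated_sites <- function(sites, condition,
                                        max_beta = 0,
                                        exclusion_window = 250) {
  sites <- as.data.frame(sites)
  if (is.null(sites[[condition]])) {
    stop_umeseq(sprintf("no beta column '%s'", condition))
  }
  out <- lapply(split(sites, sites$contig), function(s) {
    s <- s[order(s$pos), , drop = FALSE]
    n <- nrow(s)
    d_left <- c(Inf, diff(s$pos))
    d_right <- c(diff(s$pos), Inf)
    keep <- s[[condition]] <= max_beta &
      d_left > exclusion_window & d_right > exclusion_window
    data.frame(contig = s$contig[keep], start = s$pos[keep],
               end = s$pos[keep] + 2)
  })
  region_set(do.call(rbind, out), label = "isolated_unmethylated")
}

#' CpG-free background regions
#'
#' Maximal intervals containing no CpG dinucleotide, of length at least
#' `min_len`.  Between consecutive sites the free interval runs from the
#' end of the left CG (pos + 2) to the start of the right one; contig
#' termini are included by default.
#'
#' @param genome a `genome_model`
#' @param min_len minimum region length in bp (default 1,000)
#' @param include_termini whether contig-terminal CpG-free stretches count
#' @return a `region_set` labelled `"cpg_free"`
#' @export
cpg_free_regions <- function(genome, min_len = 1000,
                             include_termini = TRUE) {
  stopifnot(inherits(genome, "genome_model"))
  out <- lapply(seq_len(nrow(genome$contigs)), function(i) {
    nm <- genome$contigs$name[i]
    L <- genome$contigs$length[i]
    pos <- genome$cpg[[nm]]
    if (!length(pos)) {
      if (!include_termini) {
        return(data.frame(contig = character(0), start = numeric(0),
                          end = numeric(0)))
      }
      return(data.frame(contig = nm, start = 0, end = L))
    }
    starts <- c(0, pos + 2)
    ends <- c(pos, L)
    df <- data.frame(contig = nm, start = starts, end = ends)
    if (!include_termini) df <- df[-c(1, nrow(df)), , drop = FALSE]
    df
  })
  df <- do.call(rbind, out)
  df <- df[df$end - df$start >= min_len, , drop = FALSE]
  region_set(df, label = "cpg_free")
}
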