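#' Parameters for synthetic genome generation
#'
#' Describes the CpG landscape of a synthetic genome: a homogeneous
#' background point process of CpG sites, dense fixed-length CpG islands,
#' and two classes of guaranteed features that the downstream site catalog
#' depends on — isolated CpG sites (no neighbouring CpG within the
#' isolation window on either side) and CpG-free gaps of at least 1 kb.
#' Guaranteed features are carved in deterministically so the generator's
#' post-conditions hold for every seed.
#'
#' @param contig_lengths named integer vector of contig lengths in bp
#'   (each must be at least 2,000 bp)
#' @param background_rate expected background CpG sites per bp; must imply a
#'   mean spacing of at least 2 bp
#' @param n_islands number of CpG islands per genome, or `NULL` to choose
#'   automatically so that island sites make up `island_site_fraction` of
#'   all sites (the lever that sets the genome-wide unmethylated fraction)
#' @param island_length island length in bp
#' @param island_spacing CpG spacing inside islands in bp
#' @param island_site_fraction target fraction of all CpG sites that lie in
#'   islands, used only when `n_islands` is `NULL`
#' @param n_isolated number of guaranteed isolated CpG sites per contig
#' @param isolation_window isolation radius in bp: no other CpG within this
#'   distance on either side of a guaranteed isolated site
#' @param n_gaps number of guaranteed CpG-free gaps per contig
#' @param gap_length length in bp of each guaranteed gap (>= 1,000)
#' @param materialize_sequence if `TRUE`, generate an explicit nucleotide
#'   sequence whose CG dinucleotides occur exactly at the catalog positions
#' @return an object of class `genome_spec`
#' @export
genome_spec <- function(contig_lengths = c(sim_1 = 2e6),
                        background_rate = 1 / 70,
                        n_islands = NULL,
                        island_length = 1000,
                        island_spacing = 10,
                        island_site_fraction = 0.25,
                        n_isolated = 25,
                        isolation_window = 250,
                        n_gaps = 10,
                        gap_length = 2000,
                        materialize_sequence = FALSE) {
  if (is.null(names(contig_lengths)) || any(!nzchar(names(contig_lengths)))) {
    names(contig_lengths) <- paste0("sim_", seq_along(contig_lengths))
  }
  if (any(contig_lengths < 2000)) {
    stop_umeseq("contig lengths below 2,000 bp are rejected")
  }
  if (background_rate < 0 || (background_rate > 0 && 1 / background_rate < 2)) {
    stop_umeseq("background_rate implies expected CpG spacing < 2 bp")
  }
  if (gap_length < 1000) stop_umeseq("gap_length must be >= 1,000 bp")
  structure(list(
    contig_lengths = contig_lengths, background_rate = background_rate,
    n_islands = n_islands, island_length = island_length,
    island_spacing = island_spacing,
    island_site_fraction = island_site_fraction,
    n_isolated = n_isolated, isolation_window = isolation_window,
    n_gaps = n_gaps, gap_length = gap_length,
    materialize_sequence = materialize_sequence
  ), class = "genome_spec")
}

#' Generate a synthetic genome with a structured CpG landscape
#'
#' CpG sites are duplex entities indexed by the 0-based position of the C on
#' the forward strand.  Background sites come from a homogeneous Poisson
#' process, islands are fixed-length runs of densely and regularly spaced
#' sites, and the requested numbers of isolated sites and CpG-free gaps are
#' carved in deterministically (evenly spaced reserved blocks per contig, any
#' conflicting random site removed), so the returned model always contains at
#' least the requested counts of both feature classes.
#'
#' @param spec a [genome_spec()]
#' @param seed integer seed; the same seed reproduces the genome bit for bit
#' @return an object of class `genome_model` with elements
#'   `contigs` (data.frame: name, length), `cpg` (named list of sorted
#'   0-based site positions), `islands`, `isolated`, `gaps` (truth tables
#'   for the planted features) and optionally `sequence` (named character)
#' @export
build_genome <- function(spec = genome_spec(), seed = 1L) {
  stopifnot(inherits(spec, "genome_spec"))
  local_seed_eval(derive_seed(seed, "build_genome"), {
    contigs <- data.frame(name = names(spec$contig_lengths),
                          length = as.numeric(spec$contig_lengths),
                          stringsAsFactors = FALSE)
    cpg <- list(); islands <- list(); isolated <- list(); gaps <- list()
    n_islands_total <- spec$n_islands
    if (is.null(n_islands_total)) {
      grid <- floor(spec$island_length / spec$island_spacing) + 1
      bg_in_island <- spec$island_length * spec$background_rate
      bg_total <- sum(spec$contig_lengths) * spec$background_rate
      f <- spec$island_site_fraction
      # background sites falling inside an island count as island sites:
      # solve f = n*(grid + bg_in) / (bg_total + n*grid) for n
      n_islands_total <- max(0L, round(
        f * bg_total / (grid * (1 - f) + bg_in_island)))
    }
    # apportion islands by contig length
    w <- spec$contig_lengths / sum(spec$contig_lengths)
    n_isl <- floor(n_islands_total * w)
    rem <- n_islands_total - sum(n_isl)
    if (rem > 0) n_isl[seq_len(rem)] <- n_isl[seq_len(rem)] + 1

    for (i in seq_len(nrow(contigs))) {
      L <- contigs$length[i]
      nm <- contigs$name[i]
      res <- carve_blocks(L, spec)
      blocks <- res$blocks     # matrix start,end of reserved intervals
      iso_pos <- res$iso_pos   # carved isolated site positions

      # islands placed by rejection against reserved blocks (+ margin so
      # island sites cannot violate the isolation guarantee)
      isl_starts <- numeric(0)
      margin <- spec$isolation_window + 1
      tries <- 0
      while (length(isl_starts) < n_isl[i] && tries < 50 * max(1, n_isl[i])) {
        tries <- tries + 1
        cand <- floor(runif(1, 0, L - spec$island_length - 2))
        ok <- !overlaps_any(cand - margin, cand + spec$island_length + margin,
                            blocks)
        if (ok && length(isl_starts)) {
          ok <- all(abs(isl_starts - cand) > spec$island_length + 2)
        }
        if (ok) isl_starts <- c(isl_starts, cand)
      }
      isl_starts <- sort(isl_starts)
      island_sites <- unlist(lapply(isl_starts, function(s) {
        seq(s, s + spec$island_length, by = spec$island_spacing)
      }))

      # background: homogeneous point process, thinned out of reserved blocks
      n_bg <- rpois(1, L * spec$background_rate)
      bg <- sort(unique(floor(runif(n_bg, 0, L - 2))))
      if (length(bg) && nrow(blocks)) {
        keep <- !overlaps_any_vec(bg, bg + 2, blocks)
        bg <- bg[keep]
      }

      pos <- sort(unique(c(bg, island_sites, iso_pos)))
      pos <- pos[pos >= 0 & pos <= L - 2]
      # enforce non-overlapping CG dinucleotides (min spacing 2 bp)
      if (length(pos) > 1) {
        keep <- c(TRUE, diff(pos) >= 2)
        while (!all(keep)) {
          pos <- pos[keep]
          keep <- c(TRUE, diff(pos) >= 2)
        }
      }
      cpg[[nm]] <- as.integer(pos)
      islands[[nm]] <- if (length(isl_starts)) {
        data.frame(contig = nm, start = isl_starts,
                   end = isl_starts + spec$island_length + 2)
      }
      isolated[[nm]] <- if (length(iso_pos)) {
        data.frame(contig = nm, pos = as.integer(iso_pos))
      }
      gaps[[nm]] <- if (nrow(res$gap_blocks)) {
        data.frame(contig = nm, start = res$gap_blocks[, 1],
                   end = res$gap_blocks[, 2])
      }
    }
    gm <- structure(list(
      contigs = contigs, cpg = cpg,
      islands = do.call(rbind, islands[!vapply(islands, is.null, TRUE)]),
      isolated = do.call(rbind, isolated[!vapply(isolated, is.null, TRUE)]),
      gaps = do.call(rbind, gaps[!vapply(gaps, is.null, TRUE)]),
      sequence = NULL
    ), class = "genome_model")
    if (isTRUE(spec$materialize_sequence)) {
      gm$sequence <- materialize_sequence(gm)
    }
    gm
  })
}

# Deterministically reserve evenly spaced blocks for guaranteed gaps and
# isolated sites along a contig of length L.  No RNG involved.
carve_blocks <- function(L, spec) {
  iso_w <- 2 * (spec$isolation_window + 1) + 2
  feats <- c(rep("gap", spec$n_gaps), rep("iso", spec$n_isolated))
  m <- length(feats)
  if (m == 0) {
    empty <- matrix(numeric(0), ncol = 2)
    return(list(blocks = empty, gap_blocks = empty, iso_pos = numeric(0)))
  }
  # interleave gap and isolated blocks evenly along the contig
  rank_frac <- c(seq_len(spec$n_gaps) / (spec$n_gaps + 1),
                 seq_len(spec$n_isolated) / (spec$n_isolated + 1))
  feats <- feats[order(rank_frac)]
  # deterministic jitter so feature centers take all window-grid offsets
  # (evenly spaced centers would otherwise share one offset modulo any
  # window width that divides the spacing)
  centers <- floor((seq_len(m) - 0.5) * L / m) + (seq_len(m) * 37L) %% 100L - 50L
  widths <- ifelse(feats == "gap", spec$gap_length, iso_w)
  start <- pmax(0, centers - floor(widths / 2))
  end <- pmin(L, start + widths)
  need <- sum(widths) + m  # feasibility: blocks must fit disjointly
  if (need > L) {
    stop_umeseq("contig too short for the requested isolated sites and gaps")
  }
  if (any(end[-m] > start[-1])) {
    stop_umeseq("carved feature blocks overlap; reduce n_isolated/n_gaps")
  }
  blocks <- cbind(start, end)
  list(blocks = blocks,
       gap_blocks = blocks[feats == "gap", , drop = FALSE],
       iso_pos = floor((start + end) / 2)[feats == "iso"])
}

overlaps_any <- function(s, e, blocks) {
  if (!nrow(blocks)) return(FALSE)
  any(s < blocks[, 2] & e > blocks[, 1])
}

# vectorized: for each interval i, TRUE if it overlaps any block
overlaps_any_vec <- function(s, e, blocks) {
  out <- logical(length(s))
  for (j in seq_len(nrow(blocks))) {
    out <- out | (s < blocks[j, 2] & e > blocks[j, 1])
  }
  out
}

# Random sequence whose CG dinucleotides occur exactly at the catalog sites.
materialize_sequence <- function(gm) {
  seqs <- character(nrow(gm$contigs))
  names(seqs) <- gm$contigs$name
  for (i in seq_len(nrow(gm$contigs))) {
    nm <- gm$contigs$name[i]
    L <- gm$contigs$length[i]
    x <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    # break accidental CG pairs (G -> A never creates a new CG)
    cg <- which(x[-L] == "C" & x[-1] == "G")
    if (length(cg)) x[cg + 1] <- "A"
    p <- gm$cpg[[nm]] + 1  # 1-based
    if (length(p)) {
      x[p] <- "C"
      x[p + 1] <- "G"
    }
    # planting C/G cannot create CG pairs outside the catalog
    seqs[i] <- paste(x, collapse = "")
  }
  seqs
}

#' @export
print.genome_model <- function(x, ...) {
  n_sites <- sum(lengths(x$cpg))
  cat(sprintf(
    "genome_model: %d contig(s), %.3g bp, %d CpG sites (%d islands, %d isolated, %d gaps)\n",
    nrow(x$contigs), sum(x$contigs$length), n_sites,
    if (is.null(x$islands)) 0L else nrow(x$islands),
    if (is.null(x$isolated)) 0L else nrow(x$isolated),
    if (is.null(x$gaps)) 0L else nrow(x$gaps)))
  invisible(x)
}

genome_size <- function(gm) sum(gm$contigs$length)
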