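#' Parameters for synthetic per-CpG methylation profiles
#'
#' The default profile is bimodal: island sites are unmethylated (beta near
#' 0) and background sites methylated (beta near 0.85), which places the
#' genome-wide unmethylated-site fraction in the 20%-30% band typical of a
#' somatic methylome.  On top of the baseline the generator can plant, per
#' condition, cell-type-specific marker blocks (runs of >= 3 adjacent CpGs
#' unmethylated only in that cell type) and tumor-vs-normal differential
#' regions: focal hypermethylation of islands and broad, PMD-like
#' hypomethylated domains where beta drops by a configured amount.
#'
#' @param conditions condition labels receiving a beta column; the first is
#'   the baseline profile others are derived from
#' @param baseline_beta mean beta of methylated background sites
#' @param island_beta beta assigned to island sites (0 = fully unmethylated)
#' @param isolated_beta beta assigned to the genome's guaranteed isolated
#'   sites (0 so they satisfy the isolated-unmethylated site rule)
#' @param stochastic if `TRUE`, betas are drawn from Beta distributions with
#'   the stated means; if `FALSE`, exact constants are used
#' @param target_unmeth_band genome-wide fraction of sites with beta < 0.5
#'   expected of the finished profile (checked with a warning)
#' @param cell_types labels of cell types that receive marker blocks; each
#'   label must be present in `conditions`
#' @param markers_per_type number of marker blocks per cell type
#' @param marker_sites number of adjacent CpG sites per marker block (>= 3)
#' @param gap_shore_width sites within this many bp of a carved CpG-free
#'   gap are fully methylated in every condition, emulating the heavily
#'   methylated CpG-poor territory that kb-scale CpG-free regions sit in;
#'   0 disables
#' @param tumor,normal condition labels forming the differential pair, or
#'   `NULL` for no planted DMRs
#' @param n_hyper number of hypermethylated regions (islands methylated in
#'   the tumor condition)
#' @param hyper_beta beta reached by island sites in the tumor condition
#'   inside hyper regions; near-complete methylation (default 0.98) is
#'   needed to silence capture, because dense islands with residual
#'   unmethylated molecules still bind the beads via the saturating
#'   binding curve
#' @param n_hypo number of hypomethylated domains in the tumor condition
#' @param hypo_effect beta decrease inside hypomethylated domains
#' @param hypo_length_range domain length range in bp (toy-scale partially
#'   methylated domains, 20-50 kb by default)
#' @return an object of class `methylation_spec`
#' @export
methylation_spec <- function(conditions = "normal",
                             baseline_beta = 0.85,
                             island_beta = 0,
                             isolated_beta = 0,
                             stochastic = TRUE,
                             target_unmeth_band = c(0.20, 0.30),
                             gap_shore_width = 300,
                             cell_types = character(0),
                             markers_per_type = 0,
                             marker_sites = 10,
                             tumor = NULL, normal = NULL,
                             n_hyper = 0, hyper_beta = 0.98, n_hypo = 0,
                             hypo_effect = 0.15,
                             hypo_length_range = c(20e3, 50e3)) {
  for (b in c(baseline_beta, island_beta, isolated_beta)) {
    if (b < 0 || b > 1) stop_umeseq("beta values must lie in [0, 1]")
  }
  if (hypo_effect < 0 || hypo_effect > 1) {
    stop_umeseq("hypo_effect must lie in [0, 1]")
  }
  if (marker_sites < 3) stop_umeseq("marker blocks need >= 3 CpG sites")
  if (length(cell_types) && !all(cell_types %in% conditions)) {
    stop_umeseq("every cell type needs a column in 'conditions'")
  }
  if (!is.null(tumor) && !all(c(tumor, normal) %in% conditions)) {
    stop_umeseq("'tumor' and 'normal' must be condition labels")
  }
  structure(list(
    conditions = conditions, baseline_beta = baseline_beta,
    island_beta = island_beta, isolated_beta = isolated_beta,
    stochastic = stochastic, target_unmeth_band = target_unmeth_band,
    gap_shore_width = gap_shore_width, cell_types = cell_types, markers_per_type = markers_per_type,
    marker_sites = marker_sites, tumor = tumor, normal = normal,
    n_hyper = n_hyper, hyper_beta = hyper_beta, n_hypo = n_hypo,
    hypo_effect = hypo_effect,
    hypo_length_range = hypo_length_range
  ), class = "methylation_spec")
}

#' Synthesize a per-CpG methylation profile over a genome
#'
#' Beta here is a population methylation frequency per CpG site and
#' condition; molecule-level methylation states are drawn Bernoulli(beta)
#' later, at fragmentation time.  Planted marker blocks and differential
#' regions are recorded as truth tables for downstream benchmarking.
#'
#' @param genome a `genome_model`
#' @param profile_spec a [methylation_spec()]
#' @param seed integer seed
#' @return an object of class `methylation_profile`: `beta` (data.table with
#'   columns contig, pos and one column per condition), `truth_markers` and
#'   `truth_dmrs` (data.frames contig, start, end, label, effect), and
#'   `conditions`
#' @export
synth_methylation <- function(genome, profile_spec = methylation_spec(),
                              seed = 1L) {
  stopifnot(inherits(genome, "genome_model"),
            inherits(profile_spec, "methylation_spec"))
  ps <- profile_spec
  local_seed_eval(derive_seed(seed, "synth_methylation"), {
    tab <- data.table::rbindlist(lapply(names(genome$cpg), function(nm) {
      data.table::data.table(contig = nm, pos = genome$cpg[[nm]])
    }))
    n <- nrow(tab)
    in_island <- rep(FALSE, n)
    if (!is.null(genome$islands)) {
      in_island <- in_regions(tab, genome$islands)
    }
    is_isolated <- rep(FALSE, n)
    if (!is.null(genome$isolated)) {
      key <- paste(tab$contig, tab$pos)
      is_isolated <- key %in% paste(genome$isolated$contig,
                                    genome$isolated$pos)
    }
    base <- draw_beta(n, ps$baseline_beta, ps$stochastic)
    base[in_island] <- draw_beta(sum(in_island), ps$island_beta,
                                 ps$stochastic)
    base[is_isolated] <- ps$isolated_beta
    for (cond in ps$conditions) tab[[cond]] <- base

    truth_markers <- NULL
    truth_dmrs <- NULL
    used <- logical(NROW(genome$islands))

    # cell-type marker blocks: runs of adjacent background CpGs that are
    # unmethylated only in the owning cell type
    if (length(ps$cell_types) && ps$markers_per_type > 0) {
      mk <- list()
      bg_idx <- which(!in_island & !is_isolated)
      avail <- bg_idx
      for (ct in ps$cell_types) {
        for (j in seq_len(ps$markers_per_type)) {
          blk <- pick_adjacent_run(tab, avail, ps$marker_sites)
          if (is.null(blk)) next
          avail <- setdiff(avail, blk)
          # unmethylated in the owning type, methylated in all others
          for (cond in ps$conditions) {
            tab[[cond]][blk] <- if (cond == ct) {
              draw_beta(length(blk), 0, ps$stochastic)
            } else {
              draw_beta(length(blk), max(ps$baseline_beta, 0.85),
                        ps$stochastic)
            }
          }
          mk[[length(mk) + 1]] <- data.frame(
            contig = tab$contig[blk[1]],
            start = tab$pos[blk[1]],
            end = tab$pos[blk[length(blk)]] + 2,
            label = ct, effect = NA_real_)
        }
      }
      truth_markers <- if (length(mk)) do.call(rbind, mk)
    }

    # tumor-vs-normal differential regions
    if (!is.null(ps$tumor) && (ps$n_hyper > 0 || ps$n_hypo > 0)) {
      dm <- list()
      # hyper: whole islands gain methylation in the tumor condition
      if (ps$n_hyper > 0 && !is.null(genome$islands)) {
        free <- which(!used)
        pick <- free[seq_len(min(ps$n_hyper, length(free)))]
        used[pick] <- TRUE
        for (k in pick) {
          reg <- genome$islands[k, , drop = FALSE]
          idx <- which(in_regions(tab, reg))
          idx <- idx[tab[[ps$normal]][idx] < 0.5]  # only unmethylated sites flip
          if (!length(idx)) next
          tab[[ps$tumor]][idx] <- draw_beta(length(idx), ps$hyper_beta,
                                            ps$stochastic, conc = 150)
          dm[[length(dm) + 1]] <- data.frame(
            contig = reg$contig, start = reg$start, end = reg$end,
            label = "hyper", effect = ps$hyper_beta - ps$island_beta)
        }
      }
      # hypo: broad PMD-like domains lose `hypo_effect` of beta
      if (ps$n_hypo > 0) {
        lens <- floor(runif(ps$n_hypo, ps$hypo_length_range[1],
                            ps$hypo_length_range[2]))
        placed <- if (is.null(truth_markers)) {
          data.frame(contig = character(0), start = numeric(0),
                     end = numeric(0))
        } else truth_markers
        if (!is.null(genome$isolated)) {
          placed <- rbind(placed[, c("contig", "start", "end")],
                          data.frame(contig = genome$isolated$contig,
                                     start = genome$isolated$pos - 251,
                                     end = genome$isolated$pos + 253))
        }
        for (k in seq_len(ps$n_hypo)) {
          reg <- place_interval(genome, lens[k], placed,
                                existing = do.call(
                                  rbind, c(list(NULL), dm)))
          if (is.null(reg)) next
          idx <- which(in_regions(tab, reg))
          for_drop <- idx[tab[[ps$normal]][idx] >= 0.5]  # spare islands
          tab[[ps$tumor]][for_drop] <-
            pmax(0, tab[[ps$tumor]][for_drop] - ps$hypo_effect)
          dm[[length(dm) + 1]] <- data.frame(
            contig = reg$contig, start = reg$start, end = reg$end,
            label = "hypo", effect = -ps$hypo_effect)
        }
      }
      truth_dmrs <- if (length(dm)) do.call(rbind, dm)
    }

    # gap shores: the territory flanking carved CpG-free gaps is fully
    # methylated, so background regions are not shadowed by shoulder
    # coverage from partially methylated flanks
    if (!is.null(genome$gaps) && ps$gap_shore_width > 0) {
      shores <- rbind(
        data.frame(contig = genome$gaps$contig,
                   start = genome$gaps$start - ps$gap_shore_width,
                   end = genome$gaps$start),
        data.frame(contig = genome$gaps$contig,
                   start = genome$gaps$end,
                   end = genome$gaps$end + ps$gap_shore_width))
      shore_idx <- which(in_regions(tab, shores))
      for (cond in ps$conditions) tab[[cond]][shore_idx] <- 1
    }

    prof <- structure(list(
      beta = tab, truth_markers = truth_markers, truth_dmrs = truth_dmrs,
      conditions = ps$conditions
    ), class = "methylation_profile")

    frac <- unmethylated_fraction(prof, ps$conditions[1])
    band <- ps$target_unmeth_band
    if (is.finite(frac) && (frac < band[1] || frac > band[2])) {
      warning(sprintf(
        "unmethylated-site fraction %.3f outside the target band [%.2f, %.2f]",
        frac, band[1], band[2]), call. = FALSE)
    }
    prof
  })
}

#' Genome-wide unmethylated-site fraction of a profile
#'
#' @param profile a `methylation_profile`
#' @param condition condition label
#' @param threshold sites with beta below this count as unmethylated
#' @return fraction of sites with beta < `threshold`
#' @export
unmethylated_fraction <- function(profile, condition, threshold = 0.5) {
  b <- profile$beta[[condition]]
  if (is.null(b)) stop_umeseq(sprintf("unknown condition '%s'", condition))
  mean(b < threshold)
}

#' Mix two methylation profiles, emulating tumor-bearing plasma
#'
#' Cell-free DNA from a cancer patient is modelled as a mixture in which a
#' fraction of molecules derive from the tumor methylome: the mixed beta at
#' each site is `(1 - tumor_fraction) * beta_base + tumor_fraction *
#' beta_tumor`.
#'
#' @param profile a `methylation_profile` containing both conditions
#' @param base condition label of the healthy background profile
#' @param tumor condition label of the tumor profile
#' @param tumor_fraction mixing proportion in `[0, 1]`
#' @param name label of the new mixed condition added to the profile
#' @return the profile with an added condition column
#' @export
mix_profiles <- function(profile, base, tumor, tumor_fraction,
                         name = "plasma") {
  assert_prob(tumor_fraction, "tumor_fraction")
  for (cond in c(base, tumor)) {
    if (is.null(profile$beta[[cond]])) {
      stop_umeseq(sprintf("unknown condition '%s'", cond))
    }
  }
  profile$beta[[name]] <- (1 - tumor_fraction) * profile$beta[[base]] +
    tumor_fraction * profile$beta[[tumor]]
  profile$conditions <- union(profile$conditions, name)
  profile
}

draw_beta <- function(n, mean_beta, stochastic, conc = 30) {
  if (n == 0) return(numeric(0))
  if (!stochastic || mean_beta %in% c(0, 1)) return(rep(mean_beta, n))
  rbeta(n, mean_beta * conc, (1 - mean_beta) * conc)
}

# logical vector: is site (contig,pos) inside any region (0-based half-open,
# requiring the CG dinucleotide to be fully contained)?
in_regions <- function(tab, regions) {
  out <- logical(nrow(tab))
  for (j in seq_len(NROW(regions))) {
    out <- out | (tab$contig == regions$contig[j] &
                    tab$pos >= regions$start[j] &
                    tab$pos + 2 <= regions$end[j])
  }
  out
}

# pick a run of `k` catalog-adjacent sites from the available index pool
pick_adjacent_run <- function(tab, avail, k) {
  if (length(avail) < k) return(NULL)
  for (try in seq_len(200)) {
    i <- sample(length(avail) - k + 1, 1)
    run <- avail[i:(i + k - 1)]
    if (all(diff(run) == 1) &&
        length(unique(tab$contig[run])) == 1) return(run)
  }
  NULL
}

# place an interval of length len avoiding existing truth regions
place_interval <- function(genome, len, placed, existing = NULL) {
  avoid <- placed
  if (!is.null(existing) && NROW(existing)) {
    avoid <- rbind(avoid[, c("contig", "start", "end")],
                   existing[, c("contig", "start", "end")])
  }
  for (try in seq_len(200)) {
    ci <- sample(nrow(genome$contigs), 1,
                 prob = genome$contigs$length)
    L <- genome$contigs$length[ci]
    if (L <= len + 2) next
    s <- floor(runif(1, 0, L - len))
    nm <- genome$contigs$name[ci]
    hit <- NROW(avoid) &&
      any(avoid$contig == nm & s < avoid$end & s + len > avoid$start)
    if (!hit) {
      return(data.frame(contig = nm, start = s, end = s + len))
    }
  }
  NULL
}
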