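#' Marker-region count matrix with library-size normalization and row
#' Z-scores
#'
#' Counts deduplicated fragments per labelled marker region (midpoint
#' containment), normalizes each sample to counts per million, and
#' Z-scores each row with the sample standard deviation.  Constant rows
#' map to all-zero Z-scores and are flagged.
#'
#' @param samples named list of deduplicated `fragment_set`s (each
#'   non-empty)
#' @param markers data.frame with columns `contig`, `start`, `end`,
#'   `label` (cell-type label per marker region)
#' @return object of class `marker_matrix`: list with `counts`,
#'   `normalized` (CPM), `z` (row Z-scores), `labels`, and
#'   `constant_rows` (logical flag vector)
#' @export
marker_matrix <- function(samples, markers) {
  markers <- as.data.frame(markers)
  stopifnot(all(c("contig", "start", "end", "label") %in% names(markers)))
  if (!length(samples)) stop_umeseq("no samples given")
  if (any(vapply(samples, nrow, 0L) == 0)) {
    stop_umeseq("empty sample rejected")
  }
  counts <- matrix(0L, nrow(markers), length(samples),
                   dimnames = list(NULL, names(samples)))
  for (j in seq_along(samples)) {
    fs <- samples[[j]]
    if (any(!is.na(fs$duplicate_of))) {
      stop_umeseq("fragment set still contains duplicates; run dedup first")
    }
    mid <- floor((fs$start + fs$end) / 2)
    for (i in seq_len(nrow(markers))) {
      counts[i, j] <- sum(fs$contig == markers$contig[i] &
                            mid >= markers$start[i] & mid < markers$end[i])
    }
  }
  totals <- vapply(samples, nrow, 0L)
  normalized <- sweep(counts, 2, 1e6 / totals, "*")
  row_sd <- apply(normalized, 1, sd)
  constant <- row_sd == 0 | !is.finite(row_sd)
  z <- (normalized - rowMeans(normalized)) / ifelse(constant, 1, row_sd)
  z[constant, ] <- 0
  structure(list(counts = counts, normalized = normalized, z = z,
                 labels = markers$label, constant_rows = constant),
            class = "marker_matrix")
}

#' Filter tissue DMRs down to those informative in blood
#'
#' Retains DMRs whose case-vs-control cohort-mean signal ratio in
#' cfDNA/blood tracks is at least `fold_min`-fold in either direction
#' (`f >= fold_min` or `f <= 1/fold_min`), and partitions the survivors by
#' the direction of the blood fold change.  The fold is a ratio of
#' cohort-mean region signals (RPGC), computed per DMR.
#'
#' @param dmrs data.frame of called DMRs (`contig`, `start`, `end`, `call`)
#' @param case_tracks,control_tracks lists of RPGC `coverage_track`s with
#'   shared geometry
#' @param fold_min minimum blood fold change (default 1.5)
#' @return list with `hypo` and `hyper` data.frames (DMRs with added
#'   `blood_fold` column, split by blood direction: `hypo` has
#'   `f >= fold_min`, `hyper` has `f <= 1/fold_min`), and `n_excluded`
#'   (zero-control-mean DMRs dropped with a flag)
#' @export
blood_informative_filter <- function(dmrs, case_tracks, control_tracks,
                                     fold_min = 1.5) {
  dmrs <- as.data.frame(dmrs)
  for (t in c(case_tracks, control_tracks)[-1]) {
    check_geometry(case_tracks[[1]], t)
  }
  case_mean <- cohort_region_means(case_tracks, dmrs)
  ctrl_mean <- cohort_region_means(control_tracks, dmrs)
  excluded <- ctrl_mean == 0
  f <- ifelse(excluded, NA_real_, case_mean / ctrl_mean)
  dmrs$blood_fold <- f
  keep_hi <- !excluded & f >= fold_min
  keep_lo <- !excluded & f <= 1 / fold_min
  list(hypo = dmrs[keep_hi, , drop = FALSE],
       hyper = dmrs[keep_lo, , drop = FALSE],
       n_excluded = sum(excluded))
}

cohort_region_means <- function(tracks, regions) {
  per <- vapply(tracks, function(t) region_signal(t, regions)$per_region,
                numeric(nrow(regions)))
  if (is.null(dim(per))) per <- matrix(per, nrow = nrow(regions))
  rowMeans(per)
}

#' Tumor-informed per-sample DMR score
#'
#' The mean region signal of a sample's coverage track over a DMR set —
#' the summary used to compare patient and control plasma at
#' disease-derived regions.  Computed separately for hypo- and
#' hypermethylated DMR sets by the caller.
#'
#' @param track a `coverage_track` (RPGC)
#' @param dmr_set non-empty data.frame/`region_set` of DMR intervals
#' @return scalar score (set-level mean of per-region means)
#' @export
sample_score <- function(track, dmr_set) {
  if (!NROW(dmr_set)) stop_umeseq("dmr_set must be non-empty")
  region_signal(track, dmr_set)$mean
}

#' Exact rank-based cohort separation
#'
#' Exact Mann-Whitney statistic and two-sided p for case versus control
#' scores (mid-ranks under ties), plus the score gap `min(case) -
#' max(control)` — positive iff the cohorts separate completely in the
#' direction of interest.
#'
#' @param case_scores,control_scores numeric vectors (>= 3 each)
#' @return list with `U`, `p`, `gap`
#' @export
cohort_separation <- function(case_scores, control_scores) {
  if (length(case_scores) < 3 || length(control_scores) < 3) {
    stop_umeseq("need >= 3 scores per cohort")
  }
  wt <- suppressWarnings(
    wilcox.test(case_scores, control_scores, exact = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value,
       gap = min(case_scores) - max(control_scores))
}
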