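#' Bin fragments into a fixed-width coverage track
#'
#' Each fragment is counted in the single window containing its midpoint,
#' which keeps window counts additive and partition-safe.  Normalization
#' modes: `raw` (counts), `RPGC` (reads per genomic content — counts scaled
#' by `n_windows / total_count` so the genome-wide mean is 1) and `RPKM`
#' (counts x 1e9 / (window_size x total_count)).
#'
#' @param fs a deduplicated `fragment_set`
#' @param window window width in bp (> 0)
#' @param norm one of `"raw"`, `"RPGC"`, `"RPKM"`
#' @param contigs optional data.frame (name, length) overriding the contig
#'   table carried by the fragment set (e.g. to restrict to genomic contigs)
#' @return an object of class `coverage_track`: `values` (named list of
#'   per-window numeric vectors), `window`, `norm`, `total_fragments`,
#'   `genome_size`, and `empty` flag when normalization was refused because
#'   no fragment fell on the track
#' @export
bin_fragments <- function(fs, window = 100, norm = c("raw", "RPGC", "RPKM"),
                          contigs = NULL) {
  stopifnot(inherits(fs, "fragment_set"))
  norm <- match.arg(norm)
  if (window <= 0) stop_umeseq("window must be > 0")
  if (any(!is.na(fs$duplicate_of))) {
    stop_umeseq("fragment set still contains duplicates; run dedup first")
  }
  contigs <- contigs %||% attr(fs, "contigs")
  n_win <- pmax(1L, as.integer(ceiling(contigs$length / window)))
  values <- vector("list", nrow(contigs))
  names(values) <- contigs$name
  total <- 0
  for (i in seq_len(nrow(contigs))) {
    nm <- contigs$name[i]
    sel <- fs$contig == nm
    mid <- floor((fs$start[sel] + fs$end[sel]) / 2)
    wi <- pmin(mid %/% window, n_win[i] - 1L) + 1L
    values[[i]] <- tabulate(wi, nbins = n_win[i])
    total <- total + sum(values[[i]])
  }
  track <- structure(list(values = values, window = window, norm = "raw",
                          total_fragments = total,
                          genome_size = sum(contigs$length),
                          contigs = contigs, empty = total == 0),
                     class = "coverage_track")
  if (norm == "raw") return(track)
  if (total == 0) {
    track$norm <- norm
    return(track)  # all-zero raw values, flagged empty
  }
  scale <- if (norm == "RPGC") sum(n_win) / total else 1e9 / (window * total)
  track$values <- lapply(track$values, function(v) v * scale)
  track$norm <- norm
  track
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track: %d bp windows, %s, %d fragments, %d contig(s)%s\n",
              x$window, x$norm, x$total_fragments, length(x$values),
              if (isTRUE(x$empty)) " [empty]" else ""))
  invisible(x)
}

track_values <- function(track) unlist(track$values, use.names = FALSE)

check_geometry <- function(a, b) {
  if (a$window != b$window || !identical(lengths(a$values),
                                         lengths(b$values))) {
    stop_umeseq("coverage tracks have mismatched geometry")
  }
}

#' Mean signal over regions
#'
#' Per-region value is the length-weighted mean of the windows the region
#' overlaps; the set-level value is the unweighted mean of the per-region
#' values.
#'
#' @param track a `coverage_track`
#' @param regions a `region_set` (within track bounds)
#' @return list with `per_region` (numeric vector) and `mean` (set-level
#'   mean; `NaN` with `empty = TRUE` when the region set is empty)
#' @export
region_signal <- function(track, regions) {
  stopifnot(inherits(track, "coverage_track"))
  regions <- as.data.frame(regions)
  if (!nrow(regions)) {
    return(list(per_region = numeric(0), mean = NaN, empty = TRUE))
  }
  w <- track$window
  vals <- numeric(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    v <- track$values[[regions$contig[i]]]
    if (is.null(v)) stop_umeseq(sprintf("contig '%s' not on track",
                                        regions$contig[i]))
    s <- regions$start[i]; e <- regions$end[i]
    if (s < 0 || e > length(v) * w || s >= e) {
      stop_umeseq("region outside genome bounds")
    }
    w1 <- s %/% w; w2 <- (e - 1) %/% w
    w2 <- min(w2, length(v) - 1)
    idx <- (w1:w2) + 1L
    win_start <- (w1:w2) * w
    overlap <- pmin(e, win_start + w) - pmax(s, win_start)
    vals[i] <- sum(v[idx] * overlap) / sum(overlap)
  }
  list(per_region = vals, mean = mean(vals), empty = FALSE)
}

#' Enrichment fold of target regions over background regions
#'
#' Ratio of the set-level mean signal over targets to the set-level mean
#' over background (typically CpG-free regions).  Scale-invariant in the
#' track normalization.
#'
#' @param track a `coverage_track`
#' @param targets,background non-empty `region_set`s
#' @return list with `fold`, the two set means, and region counts; a zero
#'   background mean yields `fold = Inf` with the counts reported
#' @export
enrichment_fold <- function(track, targets, background) {
  if (!NROW(targets) || !NROW(background)) {
    stop_umeseq("target and background sets must be non-empty")
  }
  ts <- region_signal(track, targets)
  bs <- region_signal(track, background)
  list(fold = if (bs$mean == 0) Inf else ts$mean / bs$mean,
       target_mean = ts$mean, background_mean = bs$mean,
       n_targets = NROW(targets), n_background = NROW(background))
}

#' Beta-binned log2 signal ratio against an unenriched reference
#'
#' Sites are partitioned into ten beta bins of width 0.1 (left-closed,
#' the last bin closed at 1); per
#' bin, the mean enriched signal at site-containing windows is divided by
#' the mean reference (whole-genome, unenriched) signal at the same
#' windows, on the log2 scale.  A falling curve across bins is the
#' signature of methylation-dependent capture.
#'
#' @param specific,reference `coverage_track`s with identical geometry and
#'   normalization
#' @param sites data.frame with `contig`, `pos` and a beta column
#' @param condition name of the beta column
#' @param bin_width beta bin width (default 0.1)
#' @return data.frame with columns `bin_lo`, `bin_hi`, `n_sites`,
#'   `log2_ratio` (`NA` for bins without sites)
#' @export
beta_bin_log2ratio <- function(specific, reference, sites, condition,
                               bin_width = 0.1) {
  check_geometry(specific, reference)
  if (specific$norm != reference$norm) {
    stop_umeseq("tracks must share a normalization mode")
  }
  sites <- as.data.frame(sites)
  beta <- sites[[condition]]
  if (is.null(beta)) stop_umeseq(sprintf("no beta column '%s'", condition))
  w <- specific$window
  edges <- seq(0, 1, by = bin_width)
  bin <- findInterval(beta, edges, rightmost.closed = TRUE)
  spec_v <- numeric(nrow(sites)); ref_v <- numeric(nrow(sites))
  for (nm in unique(sites$contig)) {
    sel <- sites$contig == nm
    idx <- pmin(sites$pos[sel] %/% w, length(specific$values[[nm]]) - 1L) + 1L
    spec_v[sel] <- specific$values[[nm]][idx]
    ref_v[sel] <- reference$values[[nm]][idx]
  }
  out <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                    n_sites = 0L, log2_ratio = NA_real_)
  for (b in seq_len(nrow(out))) {
    sel <- bin == b
    out$n_sites[b] <- sum(sel)
    if (any(sel)) {
      ms <- mean(spec_v[sel]); mr <- mean(ref_v[sel])
      out$log2_ratio[b] <- if (mr > 0 && ms > 0) log2(ms / mr) else NA_real_
    }
  }
  out
}

#' Library-complexity saturation curve
#'
#' Subsamples the fragment set without replacement at the given fractions
#' (nested, so the curve is non-decreasing by construction) and counts
#' distinct non-empty windows as the saturating quantity.  The depth at
#' which the curve reaches 90% of its full-depth value is found by linear
#' interpolation.
#'
#' @param fs a `fragment_set`
#' @param fractions subsampling fractions in (0, 1]
#' @param window window width in bp (default 100)
#' @param seed integer seed for the subsampling permutation
#' @return list with `curve` (data.frame fraction, n_reads,
#'   distinct_windows) and `depth90` (interpolated read count at 90%
#'   saturation; `NA` when the curve never reaches it before full depth)
#' @export
saturation_curve <- function(fs, fractions = seq(0.1, 1, by = 0.1),
                             window = 100, seed = 1L) {
  stopifnot(inherits(fs, "fragment_set"))
  if (any(fractions <= 0 | fractions > 1)) {
    stop_umeseq("fractions must lie in (0, 1]")
  }
  fractions <- sort(fractions)
  n <- nrow(fs)
  mid <- floor((fs$start + fs$end) / 2)
  key <- paste0(fs$contig, ":", mid %/% window)
  local_seed_eval(derive_seed(seed, "saturation_curve"), {
    perm <- sample.int(n)
    distinct <- vapply(fractions, function(f) {
      length(unique(key[perm[seq_len(floor(f * n))]]))
    }, numeric(1))
    full <- distinct[length(distinct)]
    target <- 0.9 * full
    depth90 <- NA_real_
    j <- which(distinct >= target)[1]
    if (!is.na(j)) {
      if (j == 1) {
        depth90 <- fractions[1] * n * target / max(distinct[1], 1)
      } else {
        f0 <- fractions[j - 1]; f1 <- fractions[j]
        d0 <- distinct[j - 1]; d1 <- distinct[j]
        f90 <- f0 + (target - d0) / (d1 - d0) * (f1 - f0)
        depth90 <- f90 * n
      }
    }
    list(curve = data.frame(fraction = fractions,
                            n_reads = floor(fractions * n),
                            distinct_windows = distinct),
         depth90 = depth90)
  })
}

#' Pairwise Spearman correlation matrix of coverage tracks
#'
#' Rank correlation over all windows of the genome, the standard
#' sample-clustering statistic for enrichment tracks (typically computed on
#' 1,000 bp RPGC tracks).
#'
#' @param tracks list of >= 2 `coverage_track`s with identical geometry
#' @return symmetric correlation matrix with unit diagonal; rows against a
#'   constant track are `NA`
#' @export
spearman_matrix <- function(tracks) {
  if (length(tracks) < 2) stop_umeseq("need at least two tracks")
  for (t in tracks[-1]) check_geometry(tracks[[1]], t)
  m <- vapply(tracks, track_values, numeric(sum(lengths(tracks[[1]]$values))))
  colnames(m) <- names(tracks) %||% paste0("track_", seq_along(tracks))
  const <- apply(m, 2, function(v) stats::var(v) == 0)
  cm <- suppressWarnings(cor(m, method = "spearman"))
  cm[const, ] <- NA; cm[, const] <- NA
  diag(cm) <- ifelse(const, NA, 1)
  cm
}
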