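#' Configuration for segmentation-based DMR calling
#'
#' @param pseudocount per-base pseudocount added to both depth-normalized
#'   coverages before the log2 ratio (> 0)
#' @param lambda segmentation penalty per additional segment, or `NULL` to
#'   use the BIC-like default `2 * sigma^2 * log(n)` with `sigma` the
#'   median-absolute-deviation noise estimate of the log2-FC profile
#' @param alpha adjusted-p significance threshold (default 0.05)
#' @param lfc_min minimum absolute log2 fold change (default 0.58, i.e. a
#'   ~1.5-fold effect floor: 2^0.58 ~ 1.49)
#' @param min_segment_len minimum segment length in bases (default 200,
#'   suppressing single-base segments)
#' @return object of class `dmr_config`
#' @export
dmr_config <- function(pseudocount = 1, lambda = NULL, alpha = 0.05,
                       lfc_min = 0.58, min_segment_len = 200) {
  if (pseudocount <= 0) stop_umeseq("pseudocount must be > 0")
  if (!is.null(lambda) && lambda < 0) stop_umeseq("lambda must be >= 0")
  structure(list(pseudocount = pseudocount, lambda = lambda, alpha = alpha,
                 lfc_min = lfc_min, min_segment_len = min_segment_len),
            class = "dmr_config")
}

#' Per-base log2 fold change between two coverage profiles
#'
#' `y[i] = log2((covA[i] + eps) / (covB[i] + eps))` on library-size-scaled
#' per-condition mean coverages.
#'
#' @param covA,covB equal-length numeric per-base coverage vectors
#' @param eps pseudocount (> 0)
#' @return numeric vector of log2 fold changes
#' @export
per_base_log2fc <- function(covA, covB, eps = 1) {
  if (length(covA) != length(covB)) {
    stop_umeseq("coverage vectors differ in length")
  }
  if (eps <= 0) stop_umeseq("eps must be > 0")
  log2((covA + eps) / (covB + eps))
}

#' Change-point segmentation of a signal by penalized least squares
#'
#' Finds the segment boundaries minimizing the total within-segment sum of
#' squared deviations plus `lambda` per additional segment, by exact
#' pruned optimal partitioning (identical to the full dynamic program);
#' ties are broken toward fewer segments.  `lambda = 0` gives every point
#' its own segment, `lambda = Inf` a single segment.
#'
#' @param y numeric signal (length >= 2)
#' @param lambda penalty (>= 0)
#' @param min_size minimum segment length in points
#' @return sorted 0-based indices of the first point of each segment after
#'   the first (empty when the signal is one segment)
#' @export
find_changepoints <- function(y, lambda, min_size = 1) {
  if (length(y) < 2) stop_umeseq("need at least two points")
  if (lambda < 0) stop_umeseq("lambda must be >= 0")
  if (!is.finite(lambda)) return(integer(0))
  .pelt_sse(as.numeric(y), lambda, as.integer(min_size))
}

#' Default segmentation penalty for a log2-FC profile
#'
#' BIC-like penalty `2 * sigma^2 * corr_len * log(n / corr_len)`.  Per-base
#' coverage profiles are serially correlated over roughly one fragment
#' length, so a run of `corr_len` bases carries about one independent
#' observation; the plain `2 * sigma^2 * log(n)` penalty under-counts that
#' correlation and over-segments.  `sigma` is the median-absolute-deviation
#' noise estimate of differences taken at twice the correlation length.
#'
#' @param y numeric log2-FC profile
#' @param corr_len noise correlation length in points (default 200,
#'   the fragment scale)
#' @return penalty value
#' @export
default_lambda <- function(y, corr_len = 200) {
  lag <- min(2 * corr_len, max(1, length(y) - 1))
  d <- y[-seq_len(lag)] - y[seq_len(length(y) - lag)]
  sigma <- mad(d) / sqrt(2)
  if (sigma == 0) sigma <- sd(y) / sqrt(2)
  if (!is.finite(sigma) || sigma == 0) sigma <- 1e-3
  n_eff <- max(length(y) / corr_len, 2)
  2 * sigma^2 * corr_len * log(n_eff)
}

#' Assign deduplicated fragments to segments by midpoint containment
#'
#' Segments must partition each contig's analyzed territory without
#' overlap; a midpoint sitting exactly on a boundary belongs to the
#' right-hand (containing) half-open segment.
#'
#' @param samples named list of deduplicated `fragment_set`s
#' @param segments data.frame with columns `contig`, `start`, `end`
#' @return integer matrix segments x samples; column sums equal each
#'   sample's in-territory fragment count
#' @export
segment_counts <- function(samples, segments) {
  segments <- as.data.frame(segments)
  o <- order(segments$contig, segments$start)
  so <- segments[o, , drop = FALSE]
  same <- so$contig[-1] == so$contig[-nrow(so)]
  if (any(same & so$start[-1] < so$end[-nrow(so)])) {
    stop_umeseq("overlapping segments rejected")
  }
  counts <- matrix(0L, nrow(segments), length(samples),
                   dimnames = list(NULL, names(samples)))
  for (j in seq_along(samples)) {
    fs <- samples[[j]]
    if (any(!is.na(fs$duplicate_of))) {
      stop_umeseq("fragment set still contains duplicates; run dedup first")
    }
    mid <- floor((fs$start + fs$end) / 2)
    for (nm in unique(so$contig)) {
      seg_sel <- which(so$contig == nm)
      fsel <- fs$contig == nm
      if (!any(fsel)) next
      idx <- findInterval(mid[fsel], so$start[seg_sel])
      inside <- idx >= 1 & mid[fsel] < so$end[seg_sel][pmax(idx, 1)]
      tab <- tabulate(idx[inside], nbins = length(seg_sel))
      counts[o[seg_sel], j] <- counts[o[seg_sel], j] + tab
    }
  }
  counts
}

#' Median-of-ratios size factors
#'
#' Per-sample scaling constants equalizing sequencing depth: each sample's
#' factor is the median across segments of its count divided by the
#' segment's geometric mean, using segments with non-zero counts in every
#' sample.
#'
#' @param counts integer matrix segments x samples
#' @return numeric vector of size factors
#' @export
size_factors <- function(counts) {
  log_geo <- rowMeans(log(counts))
  use <- is.finite(log_geo)
  if (!any(use)) return(rep(1, ncol(counts)))
  apply(counts[use, , drop = FALSE], 2, function(col) {
    exp(median(log(col) - log_geo[use]))
  })
}

#' Negative-binomial Wald test for differential segment coverage
#'
#' A minimal count-based differential pipeline: median-of-ratios size
#' factors; per-segment normalized condition means; log2 fold change
#' `log2((mu_num + 0.5) / (mu_den + 0.5))`; per-segment method-of-moments
#' dispersion `max(0, (s^2 - mu) / mu^2)` shrunk toward a robust trend
#' (the median over segments with informative counts); Wald statistic
#' log2FC / SE with a delta-method standard error and a two-sided normal
#' p value.  The model variance of each group mean is evaluated at the
#' pseudocounted mean, so a zero-count group keeps a variance floor
#' rather than claiming certainty.  Segments with all-zero counts, or
#' with an across-sample mean normalized count below `min_count`
#' (independent filtering: the normal Wald approximation needs moderate
#' counts), get `NA` p values and are excluded from multiple testing.
#'
#' @param counts integer matrix segments x samples
#' @param condition character/factor of per-sample condition labels (>= 2
#'   samples per condition)
#' @param numerator,denominator condition labels forming the fold change
#'   (defaults: second and first factor level)
#' @param shrink_weight prior weight (in pseudo-samples) pulling each
#'   dispersion toward the across-segment trend
#' @param min_count minimum across-sample mean normalized count for a
#'   segment to be tested
#' @return data.frame with columns `log2FC`, `p`, `mu_num`, `mu_den`,
#'   `dispersion`
#' @export
differential_test <- function(counts, condition, numerator = NULL,
                              denominator = NULL, shrink_weight = 4,
                              min_count = 10) {
  counts <- as.matrix(counts)
  condition <- as.factor(condition)
  if (length(condition) != ncol(counts)) {
    stop_umeseq("one condition label per sample column required")
  }
  if (any(table(condition) < 2)) {
    stop_umeseq("need >= 2 samples per condition")
  }
  lv <- levels(condition)
  denominator <- denominator %||% lv[1]
  numerator <- numerator %||% setdiff(lv, denominator)[1]
  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  A <- norm[, condition == numerator, drop = FALSE]
  B <- norm[, condition == denominator, drop = FALSE]
  nA <- ncol(A); nB <- ncol(B)
  muA <- rowMeans(A); muB <- rowMeans(B)
  log2fc <- log2((muA + 0.5) / (muB + 0.5))

  varA <- apply(A, 1, stats::var)
  varB <- apply(B, 1, stats::var)
  s2 <- (varA * (nA - 1) + varB * (nB - 1)) / (nA + nB - 2)
  mu <- (muA * nA + muB * nB) / (nA + nB)
  alpha_hat <- ifelse(mu > 0, pmax(0, (s2 - mu) / mu^2), 0)
  informative <- mu >= 10
  alpha_bar <- if (any(informative)) median(alpha_hat[informative]) else 0
  m <- nA + nB
  alpha <- (m * alpha_hat + shrink_weight * alpha_bar) / (m + shrink_weight)

  vA <- ((muA + 0.5) + alpha * (muA + 0.5)^2) / nA
  vB <- ((muB + 0.5) + alpha * (muB + 0.5)^2) / nB
  se <- sqrt(vA / (muA + 0.5)^2 + vB / (muB + 0.5)^2) / log(2)
  z <- log2fc / se
  p <- 2 * pnorm(-abs(z))
  p[mu == 0 | mu < min_count] <- NA_real_
  data.frame(log2FC = log2fc, p = p, mu_num = muA, mu_den = muB,
             dispersion = alpha)
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' `NA` p values (untestable segments) stay `NA` and do not enter the
#' correction.
#'
#' @param p numeric vector of p values in `[0, 1]`
#' @return adjusted p values
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_umeseq("p values outside [0, 1]")
  p.adjust(p, method = "BH")
}

#' Call differentially methylated regions from tested segments
#'
#' Direction is defined on the enrichment (unmethylated) signal with the
#' tumor-like condition in the numerator: lower signal in tumor
#' (`log2FC < -lfc_min`) means the region gained methylation (`hyper`);
#' higher signal (`log2FC > lfc_min`) means it lost methylation (`hypo`).
#'
#' @param segments data.frame with columns `log2FC` and `padj`
#' @param config a [dmr_config()]
#' @return the data.frame with an added `call` column in
#'   `c("hyper", "hypo", "none")`
#' @export
call_dmrs <- function(segments, config = dmr_config()) {
  call <- rep("none", nrow(segments))
  sig <- !is.na(segments$padj) & segments$padj < config$alpha
  call[sig & segments$log2FC < -config$lfc_min] <- "hyper"
  call[sig & segments$log2FC > config$lfc_min] <- "hypo"
  segments$call <- call
  segments
}

#' End-to-end DMR calling on two replicate groups of fragment sets
#'
#' Builds library-size-scaled per-base mean coverage for each condition,
#' takes the per-base log2 fold change (tumor over normal), segments it by
#' penalized change-point detection per contig, counts each replicate's
#' deduplicated fragments per segment, runs the negative-binomial Wald
#' test, adjusts p values, and applies the significance and effect-size
#' thresholds.
#'
#' The change-point search runs on the per-base profile aggregated into
#' `resolution`-bp means (boundaries are reported at that granularity);
#' exact per-base search is available with `resolution = 1` but scales
#' quadratically with segment length.
#'
#' @param case_samples,control_samples named lists of deduplicated
#'   `fragment_set`s (tumor-like and normal-like replicate groups)
#' @param genome a `genome_model`
#' @param config a [dmr_config()]
#' @param resolution aggregation step in bp for the change-point search
#' @return data.frame of segments: `contig`, `start`, `end`, `log2FC`,
#'   `p`, `padj`, `mu_num`, `mu_den`, `call`
#' @export
call_dmr_pipeline <- function(case_samples, control_samples, genome,
                              config = dmr_config(), resolution = 20) {
  if (is.null(names(case_samples))) {
    names(case_samples) <- paste0("case_", seq_along(case_samples))
  }
  if (is.null(names(control_samples))) {
    names(control_samples) <- paste0("control_", seq_along(control_samples))
  }
  seg_list <- list()
  for (i in seq_len(nrow(genome$contigs))) {
    nm <- genome$contigs$name[i]
    L <- genome$contigs$length[i]
    covA <- mean_scaled_coverage(case_samples, nm, L)
    covB <- mean_scaled_coverage(control_samples, nm, L)
    y <- per_base_log2fc(covA, covB, config$pseudocount)
    if (resolution > 1) {
      nb <- length(y) %/% resolution
      yb <- colMeans(matrix(y[seq_len(nb * resolution)], nrow = resolution))
      lambda <- config$lambda %||%
        default_lambda(yb, corr_len = max(1, 200 %/% resolution))
      min_sz <- max(1, config$min_segment_len %/% resolution)
      cps <- find_changepoints(yb, lambda, min_size = min_sz) * resolution
    } else {
      lambda <- config$lambda %||% default_lambda(y)
      cps <- find_changepoints(y, lambda,
                               min_size = config$min_segment_len)
    }
    starts <- c(0, cps)
    ends <- c(cps, L)
    seg_list[[nm]] <- data.frame(contig = nm, start = starts, end = ends)
  }
  segments <- do.call(rbind, seg_list)
  rownames(segments) <- NULL
  samples <- c(case_samples, control_samples)
  counts <- segment_counts(samples, segments)
  cond <- c(rep("case", length(case_samples)),
            rep("control", length(control_samples)))
  res <- differential_test(counts, cond, numerator = "case",
                           denominator = "control")
  segments <- cbind(segments, res[, c("log2FC", "p", "mu_num", "mu_den")])
  segments$padj <- bh_adjust(segments$p)
  call_dmrs(segments, config)
}

# library-size-scaled (per million fragments) mean per-base coverage of a
# replicate group over one contig
mean_scaled_coverage <- function(samples, contig, L) {
  acc <- numeric(L)
  for (fs in samples) {
    sel <- fs$contig == contig
    cov <- .frag_coverage(as.integer(fs$start[sel]),
                          as.integer(fs$end[sel]), as.integer(L))
    acc <- acc + cov * (1e6 / max(1L, nrow(fs)))
  }
  acc / length(samples)
}
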