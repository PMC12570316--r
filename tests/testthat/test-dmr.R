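test_that("per-base log2 fold change applies the pseudocount formula", {
  expect_equal(per_base_log2fc(3, 1, 1), 1)
  expect_equal(per_base_log2fc(c(2, 5), c(2, 5), 1), c(0, 0))
  expect_equal(per_base_log2fc(0, 0, 1), 0)
  expect_error(per_base_log2fc(1:3, 1:2, 1), "length")
  expect_error(per_base_log2fc(1, 1, 0), "eps")
})

test_that("a clean step yields a single boundary at the step", {
  expect_equal(find_changepoints(c(0, 0, 0, 3, 3, 3), lambda = 1), 3)
})

test_that("penalty limits: infinite gives one segment, zero gives one per point", {
  y <- c(1.3, -0.2, 0.8, 2.1, -1.0)
  expect_equal(length(find_changepoints(rep(2, 10), lambda = 0.5)), 0)
  expect_equal(find_changepoints(y, lambda = Inf), integer(0))
  expect_equal(find_changepoints(y, lambda = 0), 1:4)
  expect_error(find_changepoints(y, lambda = -1), "lambda")
})

test_that("pruned dynamic program equals exhaustive search for n <= 20", {
  withr::with_seed(31, {
    for (rep in 1:25) {
      n <- sample(5:14, 1)
      y <- rnorm(n) + rep(c(0, sample(0:3, 1)), length.out = n)
      lambda <- runif(1, 0.1, 4)
      dp <- find_changepoints(y, lambda)
      ex <- exhaustive_changepoints(y, lambda)
      expect_equal(segmentation_cost(y, dp, lambda), ex$cost,
                   tolerance = 1e-9)
      expect_identical(as.integer(dp), as.integer(ex$boundaries))
    }
    # a larger case, n = 20
    y <- c(rnorm(8), rnorm(7, 3), rnorm(5, -2))
    ex <- exhaustive_changepoints(y, 2)
    dp <- find_changepoints(y, 2)
    expect_identical(as.integer(dp), as.integer(ex$boundaries))
  })
})

test_that("minimum segment length is honoured", {
  y <- c(0, 0, 0, 0, 5, 0, 0, 0, 0, 0)
  cps <- find_changepoints(y, lambda = 1, min_size = 3)
  sizes <- diff(c(0, cps, length(y)))
  expect_true(all(sizes >= 3))
})

test_that("segment counting conserves fragments and uses right-open midpoint rule", {
  fs <- manual_fragments(c(0, 100, 200, 300), c(100, 200, 300, 400),
                         len = 400)
  segs <- data.frame(contig = "c1", start = c(0, 150), end = c(150, 400))
  cm <- segment_counts(list(s = fs), segs)
  expect_equal(colSums(cm), c(s = 4))
  # midpoint exactly on a boundary goes to the right-hand segment
  fs2 <- manual_fragments(100, 200, len = 400)  # midpoint 150
  cm2 <- segment_counts(list(s = fs2), segs)
  expect_equal(cm2[, 1], c(0, 1))
  expect_error(segment_counts(list(s = fs),
                              data.frame(contig = "c1", start = c(0, 100),
                                         end = c(150, 400))), "overlap")
})

test_that("uniform fragments split evenly between equal segments", {
  withr::with_seed(32, {
    n <- 2e4
    s <- floor(runif(n, 0, 9900))
    fs <- manual_fragments(s, s + 100)
    segs <- data.frame(contig = "c1", start = c(0, 5000),
                       end = c(5000, 10000))
    cm <- segment_counts(list(s = fs), segs)
    expect_lt(abs(cm[1, 1] / n - 0.5), 3 * sqrt(0.25 / n))
  })
})

test_that("median-of-ratios size factors match the hand computation", {
  sf <- size_factors(matrix(c(10, 100, 20, 200), ncol = 2))
  expect_equal(sf, c(0.7071068, 1.4142136), tolerance = 1e-6)
})

test_that("the NB Wald test is calibrated on a Poisson null", {
  withr::with_seed(33, {
    counts <- matrix(rpois(2000 * 4, 100), ncol = 4)
    res <- differential_test(counts, c("A", "A", "B", "B"))
    rate <- mean(res$p < 0.05, na.rm = TRUE)
    expect_gte(rate, 0.03)
    expect_lte(rate, 0.07)
  })
})

test_that("a planted 4-fold segment is estimated within 0.3 log2 units", {
  withr::with_seed(34, {
    null <- matrix(rpois(500 * 6, 300), ncol = 6)
    planted <- cbind(matrix(rpois(10 * 3, 800), ncol = 3),
                     matrix(rpois(10 * 3, 200), ncol = 3))
    counts <- rbind(null, planted)
    res <- differential_test(counts, rep(c("T", "N"), each = 3),
                             numerator = "T", denominator = "N")
    lfc <- res$log2FC[501:510]
    expect_true(all(abs(lfc - 2) <= 0.3))
  })
})

test_that("swapping condition labels flips the fold change and the call", {
  withr::with_seed(35, {
    counts <- cbind(matrix(rpois(50 * 3, 400), ncol = 3),
                    matrix(rpois(50 * 3, 100), ncol = 3))
    fwd <- differential_test(counts, rep(c("T", "N"), each = 3),
                             numerator = "T", denominator = "N")
    rev <- differential_test(counts, rep(c("T", "N"), each = 3),
                             numerator = "N", denominator = "T")
    expect_equal(fwd$log2FC, -rev$log2FC, tolerance = 1e-12)
    fwd$padj <- bh_adjust(fwd$p)
    rev$padj <- bh_adjust(rev$p)
    cf <- call_dmrs(fwd)$call
    cr <- call_dmrs(rev)$call
    expect_identical(cf == "hypo", cr == "hyper")
    expect_identical(cf == "hyper", cr == "hypo")
  })
})

test_that("all-zero and weakly covered segments are excluded from testing", {
  counts <- rbind(matrix(rpois(50 * 4, 100), ncol = 4),
                  c(0, 0, 0, 0), c(1, 0, 2, 0))
  res <- differential_test(counts, c("A", "A", "B", "B"))
  expect_true(is.na(res$p[51]))
  expect_true(is.na(res$p[52]))
  expect_true(all(!is.na(res$p[1:50])))
})

test_that("BH adjustment matches the direct step-up formula", {
  p <- c(0.01, 0.04, 0.03, 0.002)
  expect_equal(bh_adjust(p), c(0.02, 0.04, 0.04, 0.008))
  # direct formula on random vectors
  withr::with_seed(36, {
    for (rep in 1:5) {
      pv <- runif(sample(5:40, 1))^2
      n <- length(pv)
      o <- order(pv)
      direct <- numeric(n)
      direct[o] <- rev(cummin(rev(pmin(1, pv[o] * n / seq_len(n)))))
      expect_equal(bh_adjust(pv), direct)
    }
  })
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DMR calls require both significance and the 1.5-fold effect floor", {
  segs <- data.frame(log2FC = c(0.9, 0.3, 2.0, -0.9),
                     padj = c(0.01, 0.01, 0.2, 0.01))
  calls <- call_dmrs(segs)$call
  expect_identical(calls, c("hypo", "none", "none", "hyper"))
  expect_gt(2^0.58, 1.49)
  expect_lt(2^0.58, 1.50)
})

test_that("native fold changes track DESeq2 on a planted dataset", {
  withr::with_seed(37, {
    mu <- exp(runif(200, 3, 6))
    fc <- ifelse(runif(200) < 0.2, sample(c(0.25, 4), 200, replace = TRUE), 1)
    counts <- cbind(matrix(rpois(200 * 3, mu * fc), ncol = 3),
                    matrix(rpois(200 * 3, mu), ncol = 3))
    mine <- differential_test(counts, rep(c("T", "N"), each = 3),
                              numerator = "T", denominator = "N")
    suppressPackageStartupMessages(library(DESeq2))
    dds <- DESeqDataSetFromMatrix(
      countData = counts,
      colData = data.frame(condition = factor(rep(c("T", "N"), each = 3),
                                              levels = c("N", "T"))),
      design = ~condition)
    res <- results(suppressMessages(DESeq(dds, quiet = TRUE)))
    ok <- is.finite(res$log2FoldChange)
    expect_gte(cor(mine$log2FC[ok], res$log2FoldChange[ok]), 0.95)
    # significance calls agree on the strong effects
    strong <- fc != 1
    expect_gte(mean((mine$p < 0.01)[strong] == (res$pvalue < 0.01)[strong],
                    na.rm = TRUE), 0.9)
  })
})
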