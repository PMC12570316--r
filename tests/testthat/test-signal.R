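test_that("RPGC scales window counts to genome-wide mean one", {
  fs2 <- manual_fragments(c(0, 0, 100, 100, 100, 100, 200, 200, 200,
                            200, 200, 200),
                          c(50, 50, 150, 150, 150, 150, 250, 250, 250,
                            250, 250, 250), len = 300)
  raw2 <- bin_fragments(fs2, 100, "raw")
  expect_equal(raw2$values$c1, c(2, 4, 6))
  rpgc <- bin_fragments(fs2, 100, "RPGC")
  expect_equal(rpgc$values$c1, c(0.5, 1.0, 1.5))
  expect_equal(mean(track_values <- unlist(rpgc$values)), 1)
})

test_that("RPGC mean-one invariant holds on simulated samples", {
  w <- small_world()
  tr <- bin_fragments(w$enriched, 100, "RPGC")
  expect_equal(mean(unlist(tr$values)), 1, tolerance = 1e-9)
  tr1k <- bin_fragments(w$enriched, 1000, "RPGC")
  expect_equal(mean(unlist(tr1k$values)), 1, tolerance = 1e-9)
})

test_that("RPKM applies the per-kilobase per-million formula", {
  fs <- manual_fragments(10, 60, len = 1000)
  tr <- bin_fragments(fs, 100, "RPKM")
  expect_equal(tr$values$c1[1], 1e9 / (100 * 1))
})

test_that("empty fragment sets yield a flagged all-zero track", {
  fs <- manual_fragments(integer(0), integer(0))
  tr <- bin_fragments(fs, 100, "RPGC")
  expect_true(tr$empty)
  expect_true(all(unlist(tr$values) == 0))
})

test_that("binning refuses duplicates and bad windows", {
  fs <- manual_fragments(c(0, 10), c(100, 110))
  fs$duplicate_of[2] <- 1L
  expect_error(bin_fragments(fs, 100), "duplicates")
  expect_error(bin_fragments(manual_fragments(0, 100), 0), "window")
})

test_that("region signal is a length-weighted window mean", {
  tr <- manual_track(c(1, 1, 1, 1, 1, 1, 1, 1))
  rs <- region_signal(tr, data.frame(contig = "c1", start = 120,
                                     end = 680))
  expect_equal(rs$per_region, 1)
  tr8 <- manual_track(c(0, 8, 0))
  expect_equal(region_signal(tr8, data.frame(contig = "c1", start = 100,
                                             end = 200))$per_region, 8)
  # region covering two windows equally averages them
  tr26 <- manual_track(c(2, 6))
  expect_equal(region_signal(tr26, data.frame(contig = "c1", start = 50,
                                              end = 150))$per_region, 4)
  # empty set flagged, out-of-bounds rejected
  empty <- region_signal(tr26, data.frame(contig = character(0),
                                          start = numeric(0),
                                          end = numeric(0)))
  expect_true(empty$empty)
  expect_error(region_signal(tr26, data.frame(contig = "c1", start = 100,
                                              end = 500)), "bounds")
})

test_that("region signal agrees with a naive per-base accumulation", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      vals <- rpois(50, 5)
      tr <- manual_track(vals, window = 100)
      s <- sort(sample(0:4900, 2))
      reg <- data.frame(contig = "c1", start = s[1], end = s[2] + 100)
      per_base <- rep(vals, each = 100)
      naive <- mean(per_base[(reg$start + 1):reg$end])
      expect_equal(region_signal(tr, reg)$per_region, naive)
    }
  })
})

test_that("enrichment fold is the ratio of set means and scale-invariant", {
  tr <- manual_track(c(8, 8, 0.05, 0.05))
  targets <- data.frame(contig = "c1", start = 0, end = 200)
  background <- data.frame(contig = "c1", start = 200, end = 400)
  ef <- enrichment_fold(tr, targets, background)
  expect_equal(ef$fold, 160)
  expect_equal(enrichment_fold(tr, targets, targets)$fold, 1)
  tr10 <- manual_track(10 * c(8, 8, 0.05, 0.05))
  expect_equal(enrichment_fold(tr10, targets, background)$fold, 160)
  tr0 <- manual_track(c(1, 1, 0, 0))
  expect_equal(enrichment_fold(tr0, targets, background)$fold, Inf)
  expect_error(enrichment_fold(tr, targets,
                               data.frame(contig = character(0),
                                          start = numeric(0),
                                          end = numeric(0))), "non-empty")
})

test_that("beta-binned ratio is zero on identical tracks and flags empty bins", {
  tr <- manual_track(rpois(100, 20) + 1)
  sites <- data.frame(contig = "c1", pos = c(150, 250, 9050),
                      b = c(0.05, 0.05, 0.95))
  bb <- beta_bin_log2ratio(tr, tr, sites, "b")
  expect_equal(bb$log2_ratio[1], 0)
  expect_equal(bb$log2_ratio[10], 0)
  expect_true(is.na(bb$log2_ratio[5]))
  expect_equal(bb$n_sites[1], 2)
  tr2 <- manual_track(rpois(50, 20) + 1)
  expect_error(beta_bin_log2ratio(tr, tr2, sites, "b"), "geometry")
})

test_that("enriched-vs-input signal falls monotonically with methylation", {
  w <- small_world()
  inp <- dedup(fragmentize(w$genome, w$profile, "normal", 1e5, seed = 33))
  ts <- bin_fragments(w$enriched, 100, "RPGC")
  tw <- bin_fragments(inp, 100, "RPGC")
  bb <- beta_bin_log2ratio(ts, tw, as.data.frame(w$profile$beta), "normal")
  populated <- bb$log2_ratio[bb$n_sites > 50]
  expect_gte(length(populated), 3)
  expect_true(all(diff(populated) < 0))
  expect_gt(populated[1], 0)  # unmethylated bins are enriched
})

test_that("saturation curve is non-decreasing and interpolates the 90% depth", {
  w <- small_world()
  sat <- saturation_curve(w$enriched, seq(0.2, 1, by = 0.2), seed = 5)
  expect_true(all(diff(sat$curve$distinct_windows) >= 0))
  full <- saturation_curve(w$enriched, 1, seed = 5)
  expect_equal(full$curve$distinct_windows,
               sat$curve$distinct_windows[5])
  expect_true(sat$depth90 <= nrow(w$enriched))
  # duplicating every fragment leaves the full-depth distinct count fixed
  dup <- combine_fragments(w$enriched, w$enriched)
  expect_equal(saturation_curve(dup, 1, seed = 5)$curve$distinct_windows,
               full$curve$distinct_windows)
})

test_that("spearman matrix is symmetric with unit diagonal and rank-invariant", {
  t1 <- manual_track(rpois(200, 10))
  t2 <- manual_track(2 * t1$values$c1)   # monotone transform
  cm <- spearman_matrix(list(a = t1, b = t2))
  expect_equal(cm["a", "b"], 1)
  expect_equal(diag(cm), c(a = 1, b = 1))
  expect_equal(cm, t(cm))
  const <- manual_track(rep(3, 200))
  cm2 <- spearman_matrix(list(a = t1, k = const))
  expect_true(is.na(cm2["a", "k"]) && is.na(cm2["k", "k"]))
})

test_that("deeply sequenced technical repeats correlate above 0.9 and cluster by condition", {
  g <- build_genome(genome_spec(contig_lengths = c(a = 2e6)), seed = 2)
  p <- synth_methylation(
    g, methylation_spec(conditions = c("normal", "tumor"),
                        tumor = "tumor", normal = "normal",
                        n_hyper = 8, n_hypo = 8, hypo_effect = 0.3),
    seed = 2)
  reps <- lapply(1:2, function(r) {
    bin_fragments(simulate_sample(g, p, "normal", 2e6, seed = 100 + r),
                  1000, "RPGC")
  })
  tum <- bin_fragments(simulate_sample(g, p, "tumor", 2e6, seed = 103),
                       1000, "RPGC")
  cm <- spearman_matrix(list(n1 = reps[[1]], n2 = reps[[2]], t1 = tum))
  expect_gte(cm["n1", "n2"], 0.9)
  expect_lte(cm["n1", "n2"], 1.0)
  # technical repeats are closer than biologically distinct samples
  expect_gt(cm["n1", "n2"], cm["n1", "t1"])
  expect_gt(cm["n1", "n2"], cm["n2", "t1"])
})
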