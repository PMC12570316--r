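test_that("empty genome spec yields an empty CpG catalog", {
  spec <- genome_spec(contig_lengths = c(a = 10000), background_rate = 0,
                      n_islands = 0, n_isolated = 0, n_gaps = 0)
  g <- build_genome(spec, seed = 1)
  expect_identical(g$cpg$a, integer(0))
})

test_that("requested isolated sites and CpG-free gaps are guaranteed", {
  spec <- genome_spec(contig_lengths = c(a = 2e6), n_isolated = 50,
                      n_gaps = 12)
  g <- build_genome(spec, seed = 7)
  sites <- data.frame(contig = "a", pos = g$cpg$a, beta = 1)
  sites$beta[paste(sites$pos) %in% paste(g$isolated$pos)] <- 0
  iso <- isolated_unmethylated_sites(sites, "beta")
  expect_gte(nrow(iso), 50)
  gaps <- cpg_free_regions(g, min_len = 1000)
  expect_gte(nrow(gaps), 12)
  # every carved gap is found by the region scanner
  for (i in seq_len(nrow(g$gaps))) {
    expect_true(any(gaps$start <= g$gaps$start[i] &
                      gaps$end >= g$gaps$end[i]))
  }
})

test_that("genome generation is deterministic in the seed", {
  spec <- genome_spec(contig_lengths = c(a = 1e5, b = 8e4))
  g1 <- build_genome(spec, seed = 42)
  g2 <- build_genome(spec, seed = 42)
  g3 <- build_genome(spec, seed = 43)
  expect_identical(g1$cpg, g2$cpg)
  expect_false(identical(g1$cpg, g3$cpg))
})

test_that("genome spec rejects degenerate parameters", {
  expect_error(genome_spec(contig_lengths = c(a = 1500)), "2,000")
  expect_error(genome_spec(background_rate = 0.9), "spacing")
  expect_error(genome_spec(gap_length = 500), "1,000")
})

test_that("catalog positions are sorted, in range and non-overlapping", {
  g <- build_genome(genome_spec(contig_lengths = c(a = 3e5, b = 1e5)),
                    seed = 3)
  for (nm in names(g$cpg)) {
    pos <- g$cpg[[nm]]
    L <- g$contigs$length[g$contigs$name == nm]
    expect_true(all(diff(pos) >= 2))
    expect_true(all(pos >= 0 & pos <= L - 2))
  }
})

test_that("materialized sequence has CG exactly at catalog positions", {
  g <- build_genome(genome_spec(contig_lengths = c(a = 20000),
                                n_isolated = 2, n_gaps = 1,
                                gap_length = 1000,
                                materialize_sequence = TRUE), seed = 5)
  found <- index_cpg(g$sequence)
  expect_identical(found$pos[found$contig == "a"], g$cpg$a)
})

test_that("unmethylated fraction lands in the 20-30% band and is monotone in island coverage", {
  g <- build_genome(genome_spec(contig_lengths = c(a = 1e6)), seed = 11)
  p <- synth_methylation(g, methylation_spec(), seed = 11)
  frac <- unmethylated_fraction(p, "normal")
  expect_gte(frac, 0.20)
  expect_lte(frac, 0.30)
  fracs <- vapply(c(0.10, 0.25, 0.40), function(f) {
    gi <- build_genome(genome_spec(contig_lengths = c(a = 1e6),
                                   island_site_fraction = f), seed = 11)
    pi <- suppressWarnings(
      synth_methylation(gi, methylation_spec(), seed = 11))
    unmethylated_fraction(pi, "normal")
  }, numeric(1))
  expect_true(all(diff(fracs) > 0))
})

test_that("deterministic island fraction example: 25% unmethylated islands on a constant baseline", {
  g <- build_genome(genome_spec(contig_lengths = c(a = 1e6),
                                island_site_fraction = 0.25,
                                n_isolated = 0, n_gaps = 0), seed = 2)
  p <- synth_methylation(
    g, methylation_spec(baseline_beta = 0.85, island_beta = 0,
                        stochastic = FALSE, gap_shore_width = 0),
    seed = 2)
  expect_equal(unmethylated_fraction(p, "normal"), 0.25, tolerance = 0.05)
  expect_setequal(unique(p$beta$normal), c(0.85, 0))
})

test_that("zero planted DMRs leave tumor and normal identical; planted hypo lowers beta by the effect", {
  g <- build_genome(genome_spec(contig_lengths = c(a = 1e6)), seed = 4)
  p0 <- synth_methylation(
    g, methylation_spec(conditions = c("normal", "tumor"),
                        tumor = "tumor", normal = "normal"), seed = 4)
  expect_identical(p0$beta$normal, p0$beta$tumor)

  p1 <- synth_methylation(
    g, methylation_spec(conditions = c("normal", "tumor"),
                        tumor = "tumor", normal = "normal",
                        n_hypo = 3, hypo_effect = 0.15,
                        gap_shore_width = 0,
                        hypo_length_range = c(20e3, 30e3)), seed = 4)
  hypo <- p1$truth_dmrs[p1$truth_dmrs$label == "hypo", ]
  expect_gte(nrow(hypo), 1)
  for (i in seq_len(nrow(hypo))) {
    sel <- p1$beta$contig == hypo$contig[i] &
      p1$beta$pos >= hypo$start[i] & p1$beta$pos < hypo$end[i] &
      p1$beta$normal >= 0.5  # methylated background sites carry the drop
    expect_equal(mean(p1$beta$normal[sel]) - mean(p1$beta$tumor[sel]),
                 0.15, tolerance = 0.02)
  }
})

test_that("truth regions lie in bounds and marker blocks span >= 3 CpGs", {
  g <- build_genome(genome_spec(contig_lengths = c(a = 1e6)), seed = 9)
  p <- synth_methylation(
    g, methylation_spec(conditions = c("A", "B"), cell_types = c("A", "B"),
                        markers_per_type = 5, marker_sites = 4), seed = 9)
  mk <- p$truth_markers
  expect_gte(nrow(mk), 8)
  L <- g$contigs$length[1]
  for (i in seq_len(nrow(mk))) {
    expect_true(mk$start[i] >= 0 && mk$end[i] <= L)
    n_sites <- sum(p$beta$pos >= mk$start[i] & p$beta$pos < mk$end[i])
    expect_gte(n_sites, 3)
  }
})

test_that("beta outside [0, 1] is rejected", {
  expect_error(methylation_spec(baseline_beta = 1.2), "\\[0, 1\\]")
  expect_error(methylation_spec(island_beta = -0.1), "\\[0, 1\\]")
})

test_that("spike sets cover the three oligo classes at every dose", {
  sp <- make_spikes(c(100, 500, 1000))
  expect_equal(nrow(sp), 9)
  expect_setequal(unique(sp$label), c("uMe4", "Me4", "CpG0"))
  # dose totals mirror the 5/25/50 pg series, ratio 1:5:10
  tot <- tapply(sp$copies, sp$dose_level, sum)
  expect_equal(as.numeric(tot / tot[1]), c(1, 5, 10))
  z <- sp[sp$label == "CpG0", ]
  expect_true(all(z$n_cpg == 0 & z$n_unmethylated == 0))
  one <- make_spikes(1000)
  expect_equal(nrow(one), 3)
  expect_true(all(one$copies == 1000))
  expect_error(make_spikes(integer(0)))
  expect_error(make_spikes(-5))
})
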