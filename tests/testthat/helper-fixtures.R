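# Shared fixtures, built lazily and cached for the session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# small single-condition genome + profile + one enriched sample
small_world <- function() {
  fixture("small_world", function() {
    g <- build_genome(genome_spec(contig_lengths = c(a = 5e5)), seed = 101)
    p <- synth_methylation(g, methylation_spec(), seed = 101)
    enr <- simulate_sample(g, p, "normal", 1e5, seed = 101)
    list(genome = g, profile = p, enriched = enr)
  })
}

# standard tumor/normal benchmark pair plus its called segments
standard_tn <- function() {
  fixture("standard_tn", function() {
    sim <- simulate_tumor_normal(seed = 1)
    res <- call_dmr_pipeline(sim$case, sim$control, sim$genome)
    c(sim, list(segments = res))
  })
}

# manual fragment set on one 10 kb contig
manual_fragments <- function(starts, ends, contig = "c1", len = 10000,
                             origin = "genomic", fraction = "input") {
  frags <- data.table::data.table(
    contig = contig, start = as.integer(starts), end = as.integer(ends),
    n_cpg = 0L, n_unmodified = 0L, n_tagged = 0L, origin = origin,
    duplicate_of = NA_integer_)
  umeseq:::new_fragment_set(frags, fraction = fraction,
                            contigs = data.frame(name = contig,
                                                 length = len))
}

# manual coverage track from per-window values
manual_track <- function(values, window = 100, contig = "c1",
                         norm = "raw") {
  structure(list(values = setNames(list(values), contig), window = window,
                 norm = norm, total_fragments = sum(values),
                 genome_size = length(values) * window,
                 contigs = data.frame(name = contig,
                                      length = length(values) * window),
                 empty = sum(values) == 0),
            class = "coverage_track")
}

# exhaustive penalized least-squares segmentation over all boundary sets
exhaustive_changepoints <- function(y, lambda) {
  n <- length(y)
  sse <- function(v) sum((v - mean(v))^2)
  best <- Inf
  best_b <- integer(0)
  for (mask in 0:(2^(n - 1) - 1)) {
    b <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    st <- c(0, b)
    en <- c(b, n)
    cost <- sum(vapply(seq_along(st), function(i) {
      sse(y[(st[i] + 1):en[i]])
    }, numeric(1))) + lambda * length(b)
    if (cost < best - 1e-12 ||
        (abs(cost - best) <= 1e-12 && length(b) < length(best_b))) {
      best <- cost
      best_b <- b
    }
  }
  list(cost = best, boundaries = best_b)
}

segmentation_cost <- function(y, boundaries, lambda) {
  sse <- function(v) sum((v - mean(v))^2)
  st <- c(0, boundaries)
  en <- c(boundaries, length(y))
  sum(vapply(seq_along(st), function(i) sse(y[(st[i] + 1):en[i]]),
             numeric(1))) + lambda * length(boundaries)
}

# direction-aware overlap sensitivity/precision for DMR benchmarking
dmr_overlap_stats <- function(called, truth) {
  sens <- mean(vapply(seq_len(nrow(truth)), function(i) {
    any(called$contig == truth$contig[i] & truth$start[i] < called$end &
          truth$end[i] > called$start & called$call == truth$label[i])
  }, logical(1)))
  prec <- if (nrow(called)) {
    mean(vapply(seq_len(nrow(called)), function(i) {
      any(truth$contig == called$contig[i] & called$start[i] < truth$end &
            called$end[i] > truth$start & truth$label == called$call[i])
    }, logical(1)))
  } else NA_real_
  list(sensitivity = sens, precision = prec)
}
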