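#' Simulate one enriched sequencing sample end to end
#'
#' Runs the full per-sample workflow: fragmentation, enzymatic tagging,
#' bead capture and elution, duplicate injection and removal.  Returns the
#' deduplicated enriched fraction (plus, optionally, the unbound fraction
#' and the raw input).
#'
#' @param genome a `genome_model`
#' @param profile a `methylation_profile`
#' @param condition condition label to draw molecule states from
#' @param n_fragments sequencing depth in fragments
#' @param model a [capture_model()]
#' @param seed integer seed (sub-streams are derived internally)
#' @param spikes optional [make_spikes()] set pooled into the input
#' @param keep_all if `TRUE`, also return `unbound` and `input`
#' @return a deduplicated enriched `fragment_set`, or a list when
#'   `keep_all = TRUE`
#' @export
simulate_sample <- function(genome, profile, condition, n_fragments,
                            model = capture_model(), seed = 1L,
                            spikes = NULL, keep_all = FALSE) {
  fs <- fragmentize(genome, profile, condition, n_fragments,
                    seed = derive_seed(seed, "frag"))
  if (!is.null(spikes)) {
    fs <- combine_fragments(fs, spike_fragments(spikes))
  }
  fs <- tag_fragments(fs, model$tau, seed = derive_seed(seed, "tag"))
  parts <- enrich(fs, model, seed = derive_seed(seed, "enrich"))
  enr <- add_duplicates(parts$enriched, model$dup_rate,
                        seed = derive_seed(seed, "dup"))
  enr <- dedup(enr)
  if (!keep_all) return(enr)
  list(enriched = enr, unbound = parts$unbound, input = fs)
}

#' Standard synthetic tumor/normal benchmark pair
#'
#' Builds a two-condition genome and methylation profile with planted
#' hyper- and hypomethylated regions, then simulates replicate enriched
#' samples for both conditions at a fixed per-sample depth.  This is the
#' package's reference dataset for DMR-recovery benchmarking: a 2 Mb
#' genome, 3 + 3 replicates, planted regions of at least 2 kb, and a depth
#' giving roughly 30 sequenced (enriched) fragments per kb per sample.
#'
#' @param seed integer master seed
#' @param genome_length genome size in bp
#' @param n_replicates replicates per condition
#' @param depth input fragments per sample before capture (the default
#'   yields ~30 enriched fragments/kb/sample at the default capture model)
#' @param n_hyper,n_hypo planted region counts
#' @param hypo_effect beta decrease in hypomethylated domains
#' @param model a [capture_model()]
#' @return list with `genome`, `profile`, `case` and `control` (named
#'   lists of deduplicated enriched fragment sets), `truth`
#'   (planted-region table)
#' @export
simulate_tumor_normal <- function(seed = 1L, genome_length = 2e6,
                                  n_replicates = 3, depth = 5e5,
                                  n_hyper = 6, n_hypo = 6,
                                  hypo_effect = 0.3,
                                  model = capture_model()) {
  gspec <- genome_spec(contig_lengths = c(sim_1 = genome_length),
                       n_isolated = 10, n_gaps = 5)
  genome <- build_genome(gspec, seed = derive_seed(seed, "genome"))
  mspec <- methylation_spec(conditions = c("normal", "tumor"),
                            tumor = "tumor", normal = "normal",
                            n_hyper = n_hyper, n_hypo = n_hypo,
                            hypo_effect = hypo_effect,
                            hypo_length_range = c(20e3, 50e3))
  profile <- synth_methylation(genome, mspec,
                               seed = derive_seed(seed, "meth"))
  sim_group <- function(cond) {
    out <- lapply(seq_len(n_replicates), function(r) {
      simulate_sample(genome, profile, cond, depth, model,
                      seed = derive_seed(seed, paste0(cond, "_", r)))
    })
    names(out) <- paste0(cond, "_", seq_len(n_replicates))
    out
  }
  list(genome = genome, profile = profile,
       case = sim_group("tumor"), control = sim_group("normal"),
       truth = profile$truth_dmrs)
}

#' Simulate a tumor-informed cfDNA case/control cohort
#'
#' Patient plasma is a mixture of the healthy profile and the tumor
#' profile at the given tumor fraction; control plasma uses the healthy
#' profile alone.  Plasma depths are reduced relative to tissue samples to
#' emulate low cfDNA inputs.
#'
#' @param genome,profile output of a tumor/normal simulation (profile must
#'   contain both conditions)
#' @param n_case,n_control cohort sizes
#' @param tumor_fraction plasma tumor fraction for cases
#' @param depth fragments per plasma sample
#' @param model a [capture_model()]
#' @param seed integer master seed
#' @return list of named lists `case` and `control` of deduplicated
#'   enriched fragment sets
#' @export
simulate_cfdna_cohort <- function(genome, profile, n_case = 5,
                                  n_control = 5, tumor_fraction = 0.2,
                                  depth = 30000,
                                  model = capture_model(), seed = 1L) {
  profile <- mix_profiles(profile, "normal", "tumor", tumor_fraction,
                          name = ".plasma_case")
  sim <- function(cond, label, n) {
    out <- lapply(seq_len(n), function(r) {
      simulate_sample(genome, profile, cond, depth, model,
                      seed = derive_seed(seed, paste0(label, "_", r)))
    })
    names(out) <- paste0(label, "_", seq_len(n))
    out
  }
  list(case = sim(".plasma_case", "case", n_case),
       control = sim("normal", "control", n_control))
}

#' Simulate the three-class spike-in specificity experiment
#'
#' Pools equal copies of the unmethylated, methylated and CpG-free spike
#' oligos with a genomic background, runs tagging, capture and duplicate
#' handling, and tallies per-class reads in the enriched and unbound
#' fractions.
#'
#' @param copies copies per spike class
#' @param background_fragments genomic background fragments
#' @param model a [capture_model()]
#' @param seed integer master seed
#' @param genome,profile,condition optional background source; a default
#'   500 kb genome with a single-condition profile is built when omitted
#' @return list with `per_class` (data.frame label, enriched, unbound,
#'   total, enriched_fraction), `ratio_uMe_Me` (enriched-read ratio of the
#'   unmethylated over the methylated spike class) and the two fragment
#'   sets
#' @export
simulate_spike_experiment <- function(copies = 10000,
                                      background_fragments = 3e5,
                                      model = capture_model(), seed = 1L,
                                      genome = NULL, profile = NULL,
                                      condition = "normal") {
  if (is.null(genome)) {
    genome <- build_genome(
      genome_spec(contig_lengths = c(bg_1 = 5e5), n_isolated = 5,
                  n_gaps = 3),
      seed = derive_seed(seed, "spike_genome"))
    profile <- synth_methylation(
      genome, methylation_spec(conditions = condition),
      seed = derive_seed(seed, "spike_meth"))
  }
  spikes <- make_spikes(copies)
  bg <- fragmentize(genome, profile, condition, background_fragments,
                    seed = derive_seed(seed, "spike_bg"))
  fs <- combine_fragments(bg, spike_fragments(spikes))
  fs <- tag_fragments(fs, model$tau, seed = derive_seed(seed, "spike_tag"))
  parts <- enrich(fs, model, seed = derive_seed(seed, "spike_enrich"))
  enr <- dedup(add_duplicates(parts$enriched, model$dup_rate,
                              seed = derive_seed(seed, "spike_dup")))
  unb <- dedup(add_duplicates(parts$unbound, model$dup_rate,
                              seed = derive_seed(seed, "spike_dup_u")))
  labs <- c("uMe4", "Me4", "CpG0")
  per_class <- data.frame(
    label = labs,
    enriched = vapply(labs, function(l) sum(enr$origin == l), 0),
    unbound = vapply(labs, function(l) sum(unb$origin == l), 0))
  per_class$total <- per_class$enriched + per_class$unbound
  per_class$enriched_fraction <- per_class$enriched / per_class$total
  list(per_class = per_class,
       ratio_uMe_Me =
         per_class$enriched[1] / max(1, per_class$enriched[2]),
       enriched = enr, unbound = unb)
}
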