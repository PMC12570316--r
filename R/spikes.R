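#' Build the standard three-class spike-in oligo set
#'
#' Three synthetic oligo classes calibrate enrichment specificity: a fully
#' unmethylated oligo with four CpG sites (`uMe4`), a fully methylated oligo
#' with four CpG sites (`Me4`), and a CpG-free oligo (`CpG0`).  Each class
#' is replicated at every requested dose level (copy number), emulating a
#' dose series such as 5/25/50 pg.
#'
#' @param dose_levels positive integer copy numbers, one spike batch per
#'   level
#' @param oligo_length oligo length in bp (default 150; target and
#'   non-target molecules in a typical assay are ~153 and ~142 bp)
#' @return an object of class `spike_set`: data.frame with columns
#'   `label`, `length`, `n_cpg`, `n_unmethylated`, `copies`, `dose_level`
#' @export
make_spikes <- function(dose_levels, oligo_length = 150) {
  if (!length(dose_levels) || any(dose_levels <= 0) ||
      any(dose_levels != floor(dose_levels))) {
    stop_umeseq("dose_levels must be non-empty positive integers")
  }
  classes <- data.frame(
    label = c("uMe4", "Me4", "CpG0"),
    n_cpg = c(4L, 4L, 0L),
    n_unmethylated = c(4L, 0L, 0L))
  out <- do.call(rbind, lapply(seq_along(dose_levels), function(i) {
    data.frame(label = classes$label, length = oligo_length,
               n_cpg = classes$n_cpg,
               n_unmethylated = classes$n_unmethylated,
               copies = as.integer(dose_levels[i]),
               dose_level = i)
  }))
  structure(out, class = c("spike_set", "data.frame"))
}

#' Expand spike-in oligos into input fragments
#'
#' Each oligo copy becomes one fragment on a dedicated decoy contig per
#' class and dose level, so spike reads can be counted separately from
#' genomic reads after enrichment.
#'
#' @param spikes a [make_spikes()] result
#' @return a `fragment_set` with fraction `"input"`; fragment `origin`
#'   carries the spike class label
#' @export
spike_fragments <- function(spikes) {
  stopifnot(inherits(spikes, "spike_set"))
  parts <- lapply(seq_len(nrow(spikes)), function(i) {
    r <- spikes[i, ]
    data.table::data.table(
      contig = sprintf("spike_%s_d%d", r$label, r$dose_level),
      start = 0L, end = as.integer(r$length),
      n_cpg = r$n_cpg, n_unmodified = r$n_unmethylated,
      n_tagged = NA_integer_, origin = r$label,
      duplicate_of = NA_integer_)[rep(1L, r$copies)]
  })
  frags <- data.table::rbindlist(parts)
  contigs <- unique(data.frame(
    name = sprintf("spike_%s_d%d", spikes$label, spikes$dose_level),
    length = spikes$length))
  new_fragment_set(frags, fraction = "input", contigs = contigs)
}
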