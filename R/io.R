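#' Write a genome's sequence as FASTA and its CpG catalog as BED
#'
#' @param genome a `genome_model`
#' @param fasta_path path for the FASTA (requires materialized sequence);
#'   `NULL` to skip
#' @param catalog_path path for the CpG catalog as BED3+1 (contig, pos,
#'   pos + 2, site id); `NULL` to skip
#' @return invisibly, the genome
#' @export
write_genome <- function(genome, fasta_path = NULL, catalog_path = NULL) {
  stopifnot(inherits(genome, "genome_model"))
  if (!is.null(fasta_path)) {
    if (is.null(genome$sequence)) {
      stop_umeseq("genome has no materialized sequence to write")
    }
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(genome$sequence), fasta_path)
  }
  if (!is.null(catalog_path)) {
    tab <- data.table::rbindlist(lapply(names(genome$cpg), function(nm) {
      pos <- genome$cpg[[nm]]
      data.table::data.table(contig = nm, start = pos, end = pos + 2,
                             id = sprintf("%s_cpg_%d", nm,
                                          seq_along(pos)))
    }))
    data.table::fwrite(tab, catalog_path, sep = "\t", col.names = FALSE)
  }
  invisible(genome)
}

#' Read a FASTA file into named sequences
#'
#' @param path FASTA path
#' @return named character vector of sequences
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write/read per-CpG beta tables as TSV
#'
#' Long format with columns `contig`, `pos`, `condition`, `beta`.
#'
#' @param profile a `methylation_profile`
#' @param path TSV path
#' @return invisibly the profile (write) / a data.frame (read)
#' @export
write_beta_tsv <- function(profile, path) {
  tab <- profile$beta
  long <- data.table::rbindlist(lapply(profile$conditions, function(cond) {
    data.table::data.table(contig = tab$contig, pos = tab$pos,
                           condition = cond, beta = tab[[cond]])
  }))
  data.table::fwrite(long, path, sep = "\t")
  invisible(profile)
}

#' @rdname write_beta_tsv
#' @export
read_beta_tsv <- function(path) {
  tab <- data.table::fread(path, sep = "\t")
  need <- c("contig", "pos", "condition", "beta")
  if (!all(need %in% names(tab))) {
    stop_umeseq("beta TSV needs columns contig, pos, condition, beta")
  }
  as.data.frame(tab)
}

#' Write/read fragment sets as BED6+3
#'
#' Columns: contig, start, end, origin, n_tagged, strand ("."), n_cpg,
#' n_unmodified, duplicate flag (0-based half-open coordinates).
#'
#' @param fs a `fragment_set`
#' @param path BED path
#' @param fraction fraction label to restore on read
#' @param contigs contig table (name, length) to restore on read
#' @return invisibly the set (write) / a `fragment_set` (read)
#' @export
write_fragments_bed <- function(fs, path) {
  stopifnot(inherits(fs, "fragment_set"))
  tab <- data.table::data.table(
    contig = fs$contig, start = fs$start, end = fs$end,
    name = fs$origin, score = ifelse(is.na(fs$n_tagged), -1L, fs$n_tagged),
    strand = ".", n_cpg = fs$n_cpg, n_unmodified = fs$n_unmodified,
    duplicate_of = ifelse(is.na(fs$duplicate_of), 0L, fs$duplicate_of))
  data.table::fwrite(tab, path, sep = "\t", col.names = FALSE)
  invisible(fs)
}

#' @rdname write_fragments_bed
#' @export
read_fragments_bed <- function(path, fraction = "input", contigs = NULL) {
  tab <- data.table::fread(path, sep = "\t", header = FALSE,
                           col.names = c("contig", "start", "end", "name",
                                         "score", "strand", "n_cpg",
                                         "n_unmodified", "duplicate_of"))
  bad <- which(!is.finite(tab$start) | !is.finite(tab$end) |
                 tab$start < 0 | tab$start >= tab$end)
  if (length(bad)) {
    stop_umeseq(sprintf("malformed BED interval at line %d", bad[1]))
  }
  frags <- data.table::data.table(
    contig = tab$contig, start = as.integer(tab$start),
    end = as.integer(tab$end), n_cpg = as.integer(tab$n_cpg),
    n_unmodified = as.integer(tab$n_unmodified),
    n_tagged = ifelse(tab$score < 0, NA_integer_,
                      as.integer(tab$score)),
    origin = tab$name,
    duplicate_of = ifelse(tab$duplicate_of == 0, NA_integer_,
                          as.integer(tab$duplicate_of)))
  if (is.null(contigs)) {
    contigs <- data.frame(name = unique(frags$contig),
                          length = NA_real_)
  }
  new_fragment_set(frags, fraction = fraction, contigs = contigs)
}

#' Write/read region sets as BED
#'
#' BED3 plus an optional name column carrying the per-region label.
#'
#' @param regions a `region_set` or data.frame with contig/start/end and
#'   optionally label
#' @param path BED path
#' @return invisibly the set (write) / a data.frame (read)
#' @export
write_regions_bed <- function(regions, path) {
  df <- as.data.frame(regions)
  label <- df$label %||% rep(attr(regions, "label") %||% ".", nrow(df))
  tab <- data.table::data.table(contig = df$contig, start = df$start,
                                end = df$end, name = label,
                                score = 0L, strand = ".")
  data.table::fwrite(tab, path, sep = "\t", col.names = FALSE)
  invisible(regions)
}

#' @rdname write_regions_bed
#' @export
read_regions_bed <- function(path) {
  tab <- data.table::fread(path, sep = "\t", header = FALSE)
  if (ncol(tab) < 3) stop_umeseq("BED needs at least 3 columns")
  names(tab)[1:3] <- c("contig", "start", "end")
  bad <- which(tab$start < 0 | tab$start >= tab$end)
  if (length(bad)) {
    stop_umeseq(sprintf("malformed BED interval at line %d", bad[1]))
  }
  out <- data.frame(contig = tab$contig, start = tab$start, end = tab$end)
  if (ncol(tab) >= 4) out$label <- tab[[4]]
  out
}

#' Write/read coverage tracks as bedGraph
#'
#' Fixed-step windows; records are emitted sorted by contig then start,
#' and unsorted input is rejected on read with the first offending line.
#'
#' @param track a `coverage_track`
#' @param path bedGraph path
#' @return invisibly the track (write) / list with `values`, `window`
#'   (read)
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  w <- track$window
  tab <- data.table::rbindlist(lapply(names(track$values), function(nm) {
    v <- track$values[[nm]]
    L <- track$contigs$length[track$contigs$name == nm]
    starts <- (seq_along(v) - 1) * w
    data.table::data.table(contig = nm, start = starts,
                           end = pmin(starts + w, L),
                           value = signif(v, 6))
  }))
  data.table::fwrite(tab, path, sep = "\t", col.names = FALSE)
  invisible(track)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path) {
  tab <- data.table::fread(path, sep = "\t", header = FALSE,
                           col.names = c("contig", "start", "end", "value"))
  ord_ok <- c(TRUE, tab$contig[-1] != tab$contig[-nrow(tab)] |
                tab$start[-1] > tab$start[-nrow(tab)])
  if (!all(ord_ok)) {
    stop_umeseq(sprintf("unsorted bedGraph record at line %d",
                        which(!ord_ok)[1]))
  }
  values <- lapply(split(tab, tab$contig), function(s) s$value)
  window <- if (nrow(tab) > 1) tab$end[1] - tab$start[1] else NA_real_
  list(values = values, window = window)
}
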