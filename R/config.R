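#' Assemble a reproducible run configuration
#'
#' A run is fully determined by its configuration plus one master seed;
#' every stage derives named sub-streams from that seed via
#' [derive_seed()], so adding a stage never perturbs earlier stages'
#' draws.
#'
#' @param seed master integer seed
#' @param genome a [genome_spec()] (stored as a plain list)
#' @param methylation a [methylation_spec()]
#' @param capture a [capture_model()]
#' @param depths named list/vector of per-sample fragment depths
#' @param dmr a [dmr_config()]
#' @return object of class `run_config`
#' @export
run_config <- function(seed = 1L, genome = genome_spec(),
                       methylation = methylation_spec(),
                       capture = capture_model(),
                       depths = c(sample_1 = 1e5),
                       dmr = dmr_config()) {
  structure(list(seed = as.integer(seed), genome = unclass(genome),
                 methylation = unclass(methylation),
                 capture = unclass(capture),
                 depths = as.list(depths), dmr = unclass(dmr)),
            class = "run_config")
}

#' Write/read a run configuration as YAML
#'
#' On read, unknown keys are rejected rather than silently dropped, so a
#' misspelled parameter can never fall back to a default.
#'
#' @param config a [run_config()]
#' @param path YAML path
#' @return invisibly the config (write) / a `run_config` (read)
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(config)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  template <- unclass(run_config())
  check_keys <- function(x, ref, prefix = "") {
    extra <- setdiff(names(x), names(ref))
    if (length(extra)) {
      stop_umeseq(sprintf("unknown config key '%s%s'", prefix, extra[1]))
    }
    for (nm in names(x)) {
      if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])) &&
          nm != "depths" && is.list(x[[nm]])) {
        check_keys(x[[nm]], ref[[nm]], paste0(prefix, nm, "/"))
      }
    }
  }
  check_keys(raw, template)
  cfg <- template
  for (nm in names(raw)) {
    if (is.list(template[[nm]]) && nm != "depths") {
      for (k in names(raw[[nm]])) cfg[[nm]][[k]] <- raw[[nm]][[k]]
    } else {
      cfg[[nm]] <- raw[[nm]]
    }
  }
  # restore contig-length names that YAML may flatten
  if (!is.null(cfg$genome$contig_lengths)) {
    cl <- unlist(cfg$genome$contig_lengths)
    cfg$genome$contig_lengths <- cl
  }
  cfg$genome <- do.call(genome_spec, cfg$genome)
  cfg$methylation <- do.call(methylation_spec, cfg$methylation)
  cfg$capture <- do.call(capture_model, cfg$capture)
  cfg$dmr <- do.call(dmr_config, cfg$dmr)
  run_config(seed = cfg$seed, genome = cfg$genome,
             methylation = cfg$methylation, capture = cfg$capture,
             depths = cfg$depths, dmr = cfg$dmr)
}
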