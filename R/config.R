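# Run configuration: every tunable of the three pipelines, serialized
# into each output directory so runs are reproducible from their own
# artifacts.

#' Default run configuration
#'
#' Defaults equal the stated analysis values where stated: e-value cutoff
#' 1e-5, minimum hit span 300 nt, intact floor 270 codons, 10,000
#' coalescent/permutation replicates, FDR alpha 0.05. The remaining knobs
#' (merge distance, extension window, gap definition, hydropathy window
#' and threshold) are documented package choices.
#'
#' @param ... overrides, e.g. `default_config(coalescent_reps = 2000)`
#' @return named list of class `v1r_config`
#' @export
default_config <- function(...) {
  cfg <- list(
    evalue_cutoff = 1e-5,
    min_hit_nt = 300L,
    merge_nt = 50L,
    window_nt = 3000L,
    min_codons = 270L,
    gap_min_n = 10L,
    tm_window = 19L,
    tm_threshold = 1.6,
    coalescent_reps = 10000L,
    permutation_reps = 10000L,
    fdr_alpha = 0.05,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  structure(utils::modifyList(cfg, over), class = "v1r_config")
}

#' Write / read a configuration as YAML
#' @param cfg `v1r_config`
#' @param path file path
#' @return `read_config` returns a `v1r_config`; `write_config` returns
#'   `path` invisibly
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(default_config, vals)
}
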