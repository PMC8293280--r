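# Reproducibility plumbing for the analysis drivers: every artifact written
# by an analysis script is traceable to one manifest.

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(config, tf, version = 2)
  unname(tools::md5sum(tf))
}

#' Write a run manifest
#'
#' Records the command label, a hash of the configuration, seeds, package
#' version, input/output paths and a timestamp as JSON next to the
#' artifacts a driver script produces.
#'
#' @param path Output JSON path.
#' @param command Label of the analysis step.
#' @param config List of configuration values (hashed and embedded).
#' @param seeds Named list/vector of seeds used.
#' @param inputs,outputs Character vectors of paths.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, command, config = list(), seeds = list(),
                           inputs = character(0), outputs = character(0)) {
  manifest <- list(
    command = command,
    config_hash = config_hash(config),
    config = config,
    seeds = seeds,
    package_version = as.character(utils::packageVersion("kv4pace")),
    r_version = R.version.string,
    inputs = inputs, outputs = outputs,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
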