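#' Write a reproducibility manifest for an analysis run
#'
#' Records the command/step name, a hash of the configuration object, the
#' seed, the package version and a timestamp, so that any artifact directory
#' can be reproduced from its manifest alone.
#'
#' @param out_dir output directory (created if needed)
#' @param command name of the analysis step
#' @param config the configuration object used (hashed after serialization)
#' @param seed integer seed used for the run
#' @return the manifest as a list, invisibly; written to
#'   `file.path(out_dir, "manifest.yaml")`
#' @export
write_run_manifest <- function(out_dir, command, config = NULL, seed = NA) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_txt <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  manifest <- list(
    command = command,
    config_hash = sprintf("%08x", sum(utf8ToInt(cfg_txt) *
                                        (seq_along(utf8ToInt(cfg_txt)) %% 257 + 1)) %% .Machine$integer.max),
    seed = as.integer(seed),
    package_version = as.character(utils::packageVersion("thiodyn")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
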