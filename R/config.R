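# Run configuration (YAML) and provenance: every artifact directory gets a
# log carrying the seed, the package and parameter-set versions, and a hash
# of the configuration that produced it, so deterministic stages re-run
# bit-identically from a persisted config.

#' Read a run configuration
#'
#' @param path YAML file with a `stages` list, optional per-stage parameter
#'   blocks, and a global `seed`
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  class(cfg) <- "run_config"
  cfg
}

#' Write a run configuration
#' @param cfg a list / `run_config`
#' @param path output YAML file
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Hash of a configuration object
#'
#' MD5 of the canonical (sorted-name, YAML-serialized) configuration;
#' identical configs hash identically across sessions.
#'
#' @param cfg a list
#' @return Hex digest string.
#' @export
config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  if (!is.null(names(cfg))) cfg <- cfg[order(names(cfg))]
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}

#' Write a provenance log
#'
#' @param dir output directory
#' @param seed RNG seed of the run
#' @param cfg the configuration that produced the artifacts
#' @param extra named character vector of additional fields
#' @return Path of the log file, invisibly.
#' @export
write_provenance <- function(dir, seed, cfg = list(), extra = character()) {
  path <- file.path(dir, "provenance.log")
  lines <- c(
    paste0("timestamp: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paste0("package: ctdphase ",
           as.character(utils::packageVersion("ctdphase"))),
    paste0("params_version: ", default_params()$version),
    paste0("seed: ", seed),
    paste0("config_hash: ", config_hash(cfg)))
  if (length(extra)) lines <- c(lines, paste0(names(extra), ": ", extra))
  writeLines(lines, path)
  invisible(path)
}
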