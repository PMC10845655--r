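#' Read / write a simulation config as a YAML key/value file
#'
#' The config file is a flat YAML mapping whose keys are the arguments of
#' [sim_config()] (unknown keys are rejected by name); an optional `optical`
#' sub-mapping carries [optical_model()] arguments. See
#' `system.file("extdata", "study-config.yaml", package = "dppghb")` for a
#' complete documented example.
#'
#' @param path File path.
#' @return `read_sim_config()` returns a list with elements `config`
#'   (a `sim_config`) and `optical` (an `optical_model`).
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such config file: '%s'.", path))
  doc <- yaml::read_yaml(path)
  opt_args <- doc$optical %||% list()
  doc$optical <- NULL
  known <- names(formals(sim_config))
  bad <- setdiff(names(doc), known)
  if (length(bad) > 0) {
    abort(sprintf("Unknown config key(s): %s.",
                  paste0("`", bad, "`", collapse = ", ")))
  }
  bad_opt <- setdiff(names(opt_args), names(formals(optical_model)))
  if (length(bad_opt) > 0) {
    abort(sprintf("Unknown optical key(s): %s.",
                  paste0("`", bad_opt, "`", collapse = ", ")))
  }
  list(
    config = do.call(sim_config, doc),
    optical = do.call(optical_model, opt_args)
  )
}

#' @rdname read_sim_config
#' @param config A [sim_config()].
#' @param optical An [optical_model()], or `NULL` to omit.
#' @export
write_sim_config <- function(config, path, optical = NULL) {
  stopifnot(inherits(config, "sim_config"))
  doc <- unclass(config)
  doc$seed <- doc$seed %||% NULL
  if (!is.null(optical)) {
    stopifnot(inherits(optical, "optical_model"))
    doc$optical <- unclass(optical)
  }
  # full double precision so exact-inverse optical calibrations survive I/O
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}
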