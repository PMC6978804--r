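#' Default model configuration
#'
#' Reads the packaged parameter file (skeleton, muscles, motor control,
#' contact, integration settings) and returns it as a nested list.  All
#' fields carry explicit unit suffixes in the file and are converted to
#' SI by the constructors that consume them.
#'
#' @return nested list of configuration blocks
#' @export
default_config <- function() {
  cfg <- .ratgait_cache$default_config
  if (is.null(cfg)) {
    path <- system.file("extdata", "default_params.yaml", package = "ratgait")
    cfg <- yaml::read_yaml(path)
    .ratgait_cache$default_config <- cfg
  }
  cfg
}

.ratgait_cache <- new.env(parent = emptyenv())

#' Load a configuration file layered over the defaults
#'
#' User files need only state the fields they change; everything else is
#' taken from [default_config()].
#'
#' @param path path to a YAML file, or `NULL` for pure defaults
#' @return nested configuration list
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- modifyList(cfg, user)
  }
  cfg
}

#' Write a fully resolved configuration
#'
#' @param cfg configuration list
#' @param path output path (YAML)
#' @return `path`, invisibly
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
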