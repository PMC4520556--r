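#' Run configuration files
#'
#' Experiment runs are described by a YAML file with the blocks
#' `acquisition` (arguments of [acquisition_config()]), `scene` (a `kind`
#' plus the matching scene constructor's arguments), `cohort` (arguments of
#' [cohort_params()]), `protocol` (`name` plus [run_protocol()] arguments),
#' `experiment` (for the experiment drivers), `seed` and `output`. Unknown
#' keys anywhere in the file are rejected before anything runs.
#'
#' @param path Path to a YAML configuration.
#' @return A validated named list of class `ldf_run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg, source = path)
}

#' @rdname read_run_config
#' @param config A named list with the same structure as the YAML file.
#' @param source Label used in error messages.
#' @export
validate_run_config <- function(config, source = "config") {
  check_keys <- function(x, allowed, where) {
    extra <- setdiff(names(x), allowed)
    if (length(extra)) {
      stop(source, ": unknown key(s) in ", where, ": ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  check_keys(config,
             c("acquisition", "scene", "cohort", "protocol", "experiment",
               "seed", "output"),
             "top level")
  if (!is.null(config$acquisition)) {
    check_keys(config$acquisition, names(formals(acquisition_config)),
               "acquisition")
  }
  if (!is.null(config$scene)) {
    kind <- config$scene$kind
    if (is.null(kind) || !kind %in% c("wheel", "capillary", "artery", "onh")) {
      stop(source, ": scene.kind must be one of wheel/capillary/artery/onh",
           call. = FALSE)
    }
    ctor <- scene_constructor(kind)
    check_keys(config$scene, c("kind", setdiff(names(formals(ctor)), "cfg")),
               paste0("scene (", kind, ")"))
  }
  if (!is.null(config$cohort)) {
    check_keys(config$cohort, names(formals(cohort_params)), "cohort")
  }
  if (!is.null(config$seed) &&
      (!is.numeric(config$seed) || config$seed != round(config$seed))) {
    stop(source, ": seed must be an integer", call. = FALSE)
  }
  structure(config, class = "ldf_run_config")
}

scene_constructor <- function(kind) {
  switch(kind,
         wheel = scene_wheel, capillary = scene_capillary,
         artery = scene_artery, onh = scene_onh,
         stop("unknown scene kind: ", kind, call. = FALSE))
}

#' Build package objects from a run configuration
#'
#' @param config An `ldf_run_config` (or list passing
#'   [validate_run_config()]).
#' @return `config_acquisition()` an [acquisition_config()];
#'   `config_scene()` an [ldf_scene].
#' @export
config_acquisition <- function(config) {
  do.call(acquisition_config, config$acquisition %||% list())
}

#' @rdname config_acquisition
#' @export
config_scene <- function(config) {
  stopifnot(!is.null(config$scene))
  cfg <- config_acquisition(config)
  args <- config$scene
  kind <- args$kind
  args$kind <- NULL
  args$cfg <- cfg
  do.call(scene_constructor(kind), args)
}
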