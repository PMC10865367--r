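# Plugin registry: fusion algorithms are looked up by name, so user-supplied
# methods are dispatched exactly like the built-ins.

.registry <- new.env(parent = emptyenv())

#' Register a fusion algorithm
#'
#' Makes a new algorithm available to [fuse()] and the command-line `fuse`
#' command under the given name. The function receives the
#' [segmentation_set] and the resolved [fusion_config] (plugin parameters
#' arrive in `config$extra`, already validated against `params_schema`), and
#' must return a `contour_line`.
#'
#' @param name Algorithm identifier; must not collide with a registered name.
#' @param fn Function `(set, config) -> contour_line`.
#' @param params_schema Optional declarative parameter description: a named
#'   list of `list(type = "integer"|"numeric"|"character"|"logical",
#'   default = ...)` entries, used to parse and validate parameters from a
#'   config file.
#' @return Invisibly, `name`.
#' @export
register_algorithm <- function(name, fn, params_schema = list()) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    sf_abort("algorithm name must be a non-empty string", "segfuse_registration_error")
  }
  if (exists(name, envir = .registry, inherits = FALSE)) {
    sf_abort(sprintf("algorithm '%s' is already registered", name),
             "segfuse_registration_error")
  }
  if (!is.function(fn)) {
    sf_abort("fn must be a function(set, config)", "segfuse_registration_error")
  }
  assign(name, list(fn = fn, params_schema = params_schema), envir = .registry)
  invisible(name)
}

registry_get <- function(name) {
  if (exists(name, envir = .registry, inherits = FALSE)) {
    get(name, envir = .registry, inherits = FALSE)
  } else {
    NULL
  }
}

#' List registered fusion algorithms
#'
#' @return Character vector of algorithm names (built-ins first, then
#'   plugins in registration order).
#' @export
list_algorithms <- function() {
  builtins <- c("largest", "smallest", "avg_smallest_largest",
                "avg_target_largest", "avg_target_smallest", "avg_target_input",
                "middle", "staple")
  extra <- setdiff(ls(.registry), builtins)
  c(builtins[builtins %in% ls(.registry)], extra)
}

validate_params <- function(schema, values, algorithm) {
  out <- list()
  for (nm in names(schema)) {
    sp <- schema[[nm]]
    v <- if (nm %in% names(values)) values[[nm]] else sp$default
    if (is.null(v)) {
      sf_abort(sprintf("algorithm '%s': parameter '%s' is required", algorithm, nm),
               "segfuse_validation_error")
    }
    ok <- switch(sp$type,
      integer = is.numeric(v) && all(v == round(v)),
      numeric = is.numeric(v),
      character = is.character(v),
      logical = is.logical(v),
      sf_abort(sprintf("algorithm '%s': unknown schema type '%s' for '%s'",
                       algorithm, sp$type, nm), "segfuse_validation_error")
    )
    if (!ok) {
      sf_abort(sprintf("algorithm '%s': parameter '%s' must be %s (got %s)",
                       algorithm, nm, sp$type, class(v)[1]),
               "segfuse_validation_error")
    }
    if (sp$type == "integer") v <- as.integer(v)
    out[[nm]] <- v
  }
  unknown <- setdiff(names(values), names(schema))
  if (length(unknown)) {
    sf_abort(sprintf("algorithm '%s': unknown parameter(s) %s", algorithm,
                     paste(sprintf("'%s'", unknown), collapse = ", ")),
             "segfuse_validation_error")
  }
  out
}

register_builtins <- function() {
  for (nm in ls(.registry)) rm(list = nm, envir = .registry)
  assign("largest", list(fn = fuse_largest_impl, params_schema = list()), envir = .registry)
  assign("smallest", list(fn = fuse_smallest_impl, params_schema = list()), envir = .registry)
  assign("avg_smallest_largest",
         list(fn = fuse_avg_smallest_largest_impl, params_schema = list()), envir = .registry)
  assign("avg_target_largest",
         list(fn = function(set, config) fuse_avg_target_impl(set, config, "largest"),
              params_schema = list()), envir = .registry)
  assign("avg_target_smallest",
         list(fn = function(set, config) fuse_avg_target_impl(set, config, "smallest"),
              params_schema = list()), envir = .registry)
  assign("avg_target_input",
         list(fn = function(set, config) fuse_avg_target_impl(set, config, "input"),
              params_schema = list()), envir = .registry)
  assign("middle", list(fn = fuse_middle_impl, params_schema = list()), envir = .registry)
  assign("staple", list(fn = fuse_staple_impl, params_schema = list()), envir = .registry)
}

.onLoad <- function(libname, pkgname) {
  register_builtins()
}
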