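#' Load a run configuration file
#'
#' Reads a YAML file with the namespaces \code{normalization.*},
#' \code{scoring.*} and \code{simulate.*} and returns the corresponding
#' parameter objects, using package defaults for anything unset. Unknown
#' keys are an error (a silently ignored typo would change nothing and look
#' like it did).
#'
#' @param path Path to a YAML file, or NULL for all-defaults.
#' @return A list with elements \code{normalization}
#'   (\code{\link{normalization_config}}), \code{scoring}
#'   (\code{\link{scoring_params}}) and \code{simulate}
#'   (\code{\link{simulation_config}}).
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read config files",
           call. = FALSE)
    }
    y <- yaml::read_yaml(path)
    if (is.null(y)) list() else y
  }
  known <- c("normalization", "scoring", "simulate")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0L) {
    stop("unknown config section(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  build <- function(fn, args, section) {
    ok <- names(formals(fn))
    bad <- setdiff(names(args), ok)
    if (length(bad) > 0L) {
      stop("unknown key(s) in config section '", section, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    do.call(fn, args)
  }
  list(
    normalization = build(normalization_config,
                          raw$normalization %||% list(), "normalization"),
    scoring = build(scoring_params, raw$scoring %||% list(), "scoring"),
    simulate = build(simulation_config, raw$simulate %||% list(), "simulate")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
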