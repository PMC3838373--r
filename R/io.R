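#' Write a configuration to a YAML file
#'
#' Serialises a [leg_config()] as human-readable nested key-value text.
#' Slow-fibre activation rates are never written: they are derived from the
#' fast rates by the fixed divisor on loading.
#'
#' @param cfg A `leg_config`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_config <- function(cfg, path) {
  cfg <- validate_config(cfg)
  x <- unclass(cfg)
  x$commands <- as.list(x$commands)
  # write named vectors as maps so the file reads muscle-by-muscle
  yamlify <- function(v) {
    if (is.list(v) && !is.data.frame(v)) lapply(v, yamlify)
    else if (is.atomic(v) && !is.null(names(v))) as.list(v)
    else v
  }
  writeLines(yaml::as.yaml(yamlify(x), precision = 15), path)
  invisible(path)
}

#' Load and validate a configuration file
#'
#' Reads a YAML configuration, merges it over the packaged defaults
#' (an empty file yields the full default configuration), rejects unknown
#' keys with the path to the offending field, and validates the result.
#'
#' @param path A YAML file written by [write_config()] /
#'   [export_defaults()], or any partial override of the same structure.
#' @return A validated `leg_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) return(leg_config())
  base <- unclass(leg_config())
  merged <- .merge_checked(base, raw, "")
  merged$commands <- .as_commands(merged$commands)
  cfg <- structure(merged, class = "leg_config")
  validate_config(cfg)
  cfg
}

.as_commands <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.null(x) || length(x) == 0 || length(x$time) == 0)
    return(data.frame(time = numeric(0), command = character(0),
                      alpha_s = numeric(0), stringsAsFactors = FALSE))
  data.frame(time = as.numeric(x$time),
             command = as.character(x$command),
             alpha_s = if (is.null(x$alpha_s)) NA_real_ else
               vapply(x$alpha_s, function(v)
                 if (is.null(v) || is.na(v)) NA_real_ else as.numeric(v),
                 numeric(1)),
             stringsAsFactors = FALSE)
}

.merge_checked <- function(base, over, where) {
  for (nm in names(over)) {
    path <- if (nzchar(where)) paste0(where, "/", nm) else nm
    if (!nm %in% names(base))
      stop("unknown configuration key: ", path, call. = FALSE)
    if (identical(nm, "commands")) {
      base[[nm]] <- over[[nm]]
    } else if (is.list(base[[nm]]) && !is.data.frame(base[[nm]])) {
      base[[nm]] <- .merge_checked(base[[nm]], over[[nm]], path)
    } else {
      v <- over[[nm]]
      if (is.list(v)) v <- unlist(v)
      if (!is.null(names(base[[nm]])) && length(v) == length(base[[nm]]))
        names(v) <- names(base[[nm]])
      base[[nm]] <- v
    }
  }
  base
}

#' Export the packaged default parameter set
#'
#' Writes the full default configuration - including the published fast
#' activation rate constants and slow residual spring constants - to a
#' YAML file that round-trips bit-exactly through [load_config()].
#'
#' @param path Output file.
#' @return The path, invisibly.
#' @export
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' export_defaults(f)
#' identical(unclass(load_config(f)), unclass(leg_config()))
export_defaults <- function(path) {
  write_config(leg_config(), path)
}
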