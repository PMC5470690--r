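# Flat key = value configuration files (INI/TOML-like, no sections).
# Resolution order everywhere: package defaults < config file < explicit
# flags. The resolved configuration is echoed into every report.

config_defaults <- function() {
  pal <- he_palette()
  wp <- weighting_params()
  list(
    red = pal$refs["red", ], pink = pal$refs["pink", ], blue = pal$refs["blue", ],
    b0 = pal$b0, s0 = pal$s0,
    f0 = wp$f0, gamma = wp$gamma,
    window_start = 8L, min_segment = 2L,
    seed = 1L, verbosity = 1L
  )
}

parse_config_value <- function(raw) {
  raw <- trimws(raw)
  raw <- sub("^['\"]", "", sub("['\"]$", "", raw))
  parts <- trimws(strsplit(raw, ",", fixed = TRUE)[[1]])
  num <- suppressWarnings(as.numeric(parts))
  if (!anyNA(num)) num else raw
}

#' Read a flat key = value configuration file
#'
#' Lines are `key = value`; `#` or `;` start a comment; RGB triples are
#' comma-separated (`red = 150, 30, 40`). Unknown keys are rejected.
#'
#' @param path configuration file path.
#' @return named list of parsed values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("config file '%s' does not exist", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("[#;].*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop_validation(sprintf("malformed config line: '%s'", ln))
    key <- trimws(sub("=.*$", "", ln))
    val <- sub("^[^=]*=", "", ln)
    if (!key %in% names(config_defaults()))
      stop_validation(sprintf("unknown config key '%s'", key))
    out[[key]] <- parse_config_value(val)
  }
  out
}

#' Resolve a run configuration
#'
#' @param config_file optional path to a [read_config()] file.
#' @param ... explicit overrides (highest precedence), using the same keys
#'   as the config file.
#' @return named list of class `run_config` containing every parameter,
#'   plus constructed `palette` and `weighting` objects.
#' @export
run_config <- function(config_file = NULL, ...) {
  cfg <- config_defaults()
  if (!is.null(config_file)) {
    file_cfg <- read_config(config_file)
    cfg[names(file_cfg)] <- file_cfg
  }
  overrides <- list(...)
  overrides <- overrides[!vapply(overrides, is.null, logical(1))]
  bad <- setdiff(names(overrides), names(cfg))
  if (length(bad))
    stop_validation(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  cfg[names(overrides)] <- overrides
  cfg$palette <- he_palette(red = cfg$red, pink = cfg$pink, blue = cfg$blue,
                            b0 = cfg$b0, s0 = cfg$s0)
  cfg$weighting <- weighting_params(f0 = cfg$f0, gamma = cfg$gamma)
  cfg$window_start <- as.integer(cfg$window_start)
  cfg$min_segment <- as.integer(cfg$min_segment)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

# serializable echo of the resolved configuration (provenance)
config_echo <- function(cfg) {
  list(red = as.numeric(cfg$red), pink = as.numeric(cfg$pink),
       blue = as.numeric(cfg$blue), b0 = cfg$b0, s0 = cfg$s0,
       f0 = cfg$f0, gamma = cfg$gamma,
       window_start = cfg$window_start, min_segment = cfg$min_segment,
       seed = cfg$seed)
}
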