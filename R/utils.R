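# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x == as.integer(x) && x >= 0

is_prob <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x <= 1)

#' Read a flat key-value configuration file
#'
#' Parses a minimal TOML-style file of `key = value` lines (comments starting
#' with `#` and blank lines ignored). Values are returned as numerics where
#' they parse as numbers, otherwise as strings. Dotted keys such as
#' `prevalence.c_mental_health` are kept verbatim; callers split them.
#'
#' @param path Path to the configuration file.
#' @return Named list of values.
#' @export
read_flat_config <- function(path) {
  assert_that(file.exists(path), sprintf("config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop(sprintf("config line is not 'key = value': %s", ln), call. = FALSE)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    val <- gsub('^"|"$', "", val)
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
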