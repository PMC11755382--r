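## small internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a classed dotdecode error
#'
#' All user-facing errors in the package carry a condition class so callers
#' (and tests) can discriminate failure modes without parsing messages.
#'
#' @param class condition class, e.g. "dot_invalid_parameter"
#' @param msg error message
#' @keywords internal
#' @noRd
dot_stop <- function(class, msg) {
  stop(errorCondition(msg, class = c(class, "dotdecode_error")))
}

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state, so
#' seeded generators do not perturb the global random stream.
#'
#' @param seed integer seed or NULL (use the current stream)
#' @param code expression to evaluate
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

## round-half-up at d decimals (printed tables round 3.125 -> 3.13)
round_half_up <- function(x, d = 0) {
  p <- 10^d
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a fraction as a percentage string
#'
#' Rounds half-up to 1 decimal place, or 2 decimals for values below 10%,
#' matching the rendering convention of the package's summary tables
#' (25.0, 12.5, 6.25, 3.13).
#'
#' @param frac fraction in \[0, 1\]
#' @return character vector of percentages (no "%" sign)
#' @export
#' @examples
#' format_pct(c(0.25, 0.125, 0.0625, 0.03125))
format_pct <- function(frac) {
  pct <- 100 * frac
  d <- ifelse(pct < 10, 2L, 1L)
  mapply(function(v, dd) formatC(round_half_up(v, dd), format = "f", digits = dd),
         pct, d, USE.NAMES = FALSE)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)
}

is_number <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)
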