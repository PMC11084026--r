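#' @keywords internal
"_PACKAGE"

# Polynomial design in normalised time u = t / t_scale. Raw (not orthogonal)
# powers so coefficients stay interpretable as percent-change at u^k.
traj_basis <- function(t_hours, degree, t_scale = 96) {
  u <- t_hours / t_scale
  outer(u, 0:degree, `^`)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

# log(sum(exp(x))) by row, guarded against -Inf rows
logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Event percentage rounded to integer percent
#'
#' The convention used in the run report's outcome frequency table:
#' `round(100 * events / n)` as an integer.
#'
#' @param events event count(s).
#' @param n denominator.
#' @return integer vector of percentages.
#' @export
percent_rounded <- function(events, n) as.integer(round(100 * events / n))

# cubic (or lower-degree) coefficients through equally spaced control values
# over u in [0, 1]; used by the generator presets
poly_through_controls <- function(values) {
  k <- length(values)
  u <- seq(0, 1, length.out = k)
  solve(outer(u, 0:(k - 1), `^`), values)
}
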