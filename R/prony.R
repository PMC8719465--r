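#' Prony-series relaxation terms
#'
#' A Prony series defines the dimensionless reduced relaxation function
#' \deqn{g_R(t) = 1 - \sum_i g_i (1 - e^{-t/\tau_i}),}
#' with \eqn{g_R(0) = 1} and long-term fraction
#' \eqn{g_R(\infty) = 1 - \sum_i g_i > 0}. Material tables often report a
#' decay constant \eqn{\beta_i = 1/\tau_i} in 1/s instead of the relaxation
#' time; supply either.
#'
#' @param g relaxation fractions \eqn{g_i}, each in `[0, 1)` with
#'   `sum(g) < 1`. May be empty (`numeric(0)`) for a purely elastic model.
#' @param tau relaxation times \eqn{\tau_i} in seconds (positive). Exactly
#'   one of `tau`, `decay` must be given (unless `g` is empty).
#' @param decay decay constants \eqn{\beta_i = 1/\tau_i} in 1/s.
#' @return An object of class `prony_series` storing `g` and `tau`.
#' @examples
#' pr <- prony_series(g = 0.99, decay = 0.276) # tau = 1/0.276 s
#' reduced_relaxation(c(0, pr$tau, 100), pr)
#' @export
prony_series <- function(g = numeric(0), tau = NULL, decay = NULL) {
  if (!is.numeric(g) || anyNA(g))
    stop("`g` must be numeric", call. = FALSE)
  if (length(g) == 0L)
    return(structure(list(g = numeric(0), tau = numeric(0)),
                     class = "prony_series"))
  if (is.null(tau) == is.null(decay))
    stop("supply exactly one of `tau` or `decay`", call. = FALSE)
  if (is.null(tau)) {
    if (any(decay <= 0)) stop("decay constants must be > 0", call. = FALSE)
    tau <- 1 / decay
  }
  if (length(tau) != length(g))
    stop("`g` and `tau`/`decay` must have equal length", call. = FALSE)
  if (any(g < 0) || sum(g) >= 1)
    stop("need g_i >= 0 and sum(g) < 1 (positive long-term modulus)",
         call. = FALSE)
  if (any(tau <= 0)) stop("relaxation times must be > 0", call. = FALSE)
  structure(list(g = as.numeric(g), tau = as.numeric(tau)),
            class = "prony_series")
}

#' @export
print.prony_series <- function(x, ...) {
  if (length(x$g) == 0L) {
    cat("Prony series: empty (purely elastic)\n")
  } else {
    cat(sprintf("Prony series (%d term%s):\n", length(x$g),
                if (length(x$g) > 1L) "s" else ""))
    for (i in seq_along(x$g))
      cat(sprintf("  g_%d = %g, tau_%d = %g s (decay %g 1/s)\n",
                  i, x$g[i], i, x$tau[i], 1 / x$tau[i]))
    cat(sprintf("  long-term fraction: %g\n", 1 - sum(x$g)))
  }
  invisible(x)
}

#' Reduced relaxation function
#'
#' Evaluates \eqn{g_R(t) = 1 - \sum_i g_i(1 - e^{-t/\tau_i})}.
#'
#' @param t time(s) in seconds, `>= 0`; vectorized.
#' @param prony a [prony_series()] object.
#' @return Dimensionless relaxation fraction(s) in `(0, 1]`.
#' @export
reduced_relaxation <- function(t, prony) {
  stopifnot(inherits(prony, "prony_series"))
  if (!is.numeric(t) || anyNA(t) || any(t < 0))
    stop("`t` must be numeric and >= 0", call. = FALSE)
  out <- rep(1, length(t))
  for (i in seq_along(prony$g))
    out <- out - prony$g[i] * (1 - exp(-t / prony$tau[i]))
  out
}
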