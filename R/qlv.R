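#' Quasi-linear viscoelastic stress by recursive exponential integration
#'
#' Evaluates the QLV hereditary integral
#' \deqn{\sigma(t) = \int_0^t g_R(t - s)\,\frac{d\sigma^e}{ds}\,ds}
#' where \eqn{\sigma^e} is the instantaneous Ogden stress of the active
#' mode and \eqn{g_R} the Prony reduced relaxation function. Splitting the
#' kernel as \eqn{g_R(u) = (1 - \sum_i g_i) + \sum_i g_i e^{-u/\tau_i}}
#' gives \eqn{\sigma(t) = (1 - \sum_i g_i)\,\sigma^e(t) + \sum_i h_i(t)}
#' with one exponential internal variable per Prony term,
#' \eqn{h_i(t) = g_i \int_0^t e^{-(t-s)/\tau_i} \dot\sigma^e\,ds}. On a
#' uniform time grid each internal variable is updated by the standard
#' recurrence
#' \deqn{h_i^{n+1} = e^{-\Delta t/\tau_i} h_i^n +
#'   g_i \frac{\tau_i}{\Delta t}(1 - e^{-\Delta t/\tau_i})
#'   (\sigma^e_{n+1} - \sigma^e_n),}
#' which integrates the convolution exactly for an elastic stress that is
#' piecewise linear in time. With an empty Prony series the output equals
#' the instantaneous Ogden curve exactly.
#'
#' @param history a [loading_history()] on a uniform time grid.
#' @param ogden an [ogden_parameters()] object.
#' @param prony a [prony_series()] object (may be empty).
#' @param measure stress measure for uniaxial tension, `"cauchy"` or
#'   `"nominal"`; ignored in shear (Cauchy \eqn{\sigma_{12}}).
#' @return A [stress_strain_curve()] indexed by the history's strain grid.
#' @export
qlv_stress_recursive <- function(history, ogden, prony = prony_series(),
                                 measure = c("cauchy", "nominal")) {
  stopifnot(inherits(history, "loading_history"),
            inherits(ogden, "ogden_parameters"),
            inherits(prony, "prony_series"))
  measure <- match.arg(measure)
  dt <- diff(history$time)
  if (any(dt <= 0))
    stop("reversed or degenerate time grid", call. = FALSE)
  if (max(abs(dt - dt[1])) > 1e-9 * dt[1])
    stop("qlv_stress_recursive requires a uniform time grid", call. = FALSE)
  sig_e <- .instantaneous_stress(history$strain, history$mode, ogden, measure)
  stress <- sig_e
  if (length(prony$g) > 0L) {
    h_sum <- numeric(length(sig_e) - 1L)
    dsig <- diff(sig_e)
    for (i in seq_along(prony$g)) {
      e_i <- exp(-dt[1] / prony$tau[i])
      c_i <- prony$g[i] * (prony$tau[i] / dt[1]) * (1 - e_i)
      h_sum <- h_sum +
        as.numeric(stats::filter(c_i * dsig, e_i, method = "recursive"))
    }
    stress <- (1 - sum(prony$g)) * sig_e + c(0, h_sum)
  }
  stress_strain_curve(history$mode, history$nominal_rate,
                      history$strain, stress)
}

#' Quasi-linear viscoelastic stress by trapezoidal quadrature
#'
#' Brute-force evaluation of the same hereditary integral as
#' [qlv_stress_recursive()], as a Riemann-Stieltjes trapezoid sum on a time
#' grid refined `refinement`-fold. It is an independent oracle for the
#' recursive integrator: the two converge to each other as the step size
#' shrinks. Cost is quadratic in the grid size; intended for testing and
#' validation, not production use.
#'
#' @inheritParams qlv_stress_recursive
#' @param refinement integer `>= 1`; each time step is split into this many
#'   sub-steps before integrating.
#' @return A [stress_strain_curve()] on the original (coarse) strain grid.
#' @export
qlv_stress_quadrature <- function(history, ogden, prony = prony_series(),
                                  refinement = 4,
                                  measure = c("cauchy", "nominal")) {
  stopifnot(inherits(history, "loading_history"),
            inherits(ogden, "ogden_parameters"),
            inherits(prony, "prony_series"))
  measure <- match.arg(measure)
  refinement <- as.integer(refinement)
  if (refinement < 1L) stop("`refinement` must be >= 1", call. = FALSE)
  dt <- diff(history$time)
  if (any(dt <= 0))
    stop("reversed or degenerate time grid", call. = FALSE)
  n <- length(history$time)
  # refine each interval uniformly; coarse nodes stay on the fine grid
  tf <- unlist(lapply(seq_len(n - 1L), function(k)
    seq(history$time[k], history$time[k + 1L],
        length.out = refinement + 1L)[-(refinement + 1L)]))
  tf <- c(tf, history$time[n])
  sf <- stats::approx(history$time, history$strain, xout = tf)$y
  sig_e <- .instantaneous_stress(sf, history$mode, ogden, measure)
  if (length(prony$g) == 0L) {
    stress <- sig_e[seq(1L, length(tf), by = refinement)]
  } else {
    dsig <- diff(sig_e)
    stress <- numeric(n)
    for (j in 2:n) {
      jf <- (j - 1L) * refinement + 1L
      gr <- reduced_relaxation(tf[jf] - tf[seq_len(jf)], prony)
      stress[j] <- sum(dsig[seq_len(jf - 1L)] *
                         (gr[-jf] + gr[-1L][seq_len(jf - 1L)]) / 2)
    }
  }
  stress_strain_curve(history$mode, history$nominal_rate,
                      history$strain, stress)
}

# instantaneous elastic stress for the active mode (strain vector in)
.instantaneous_stress <- function(strain, mode, ogden, measure = "cauchy") {
  if (mode == "simple_shear")
    instantaneous_shear_stress(strain, ogden)
  else
    instantaneous_uniaxial_stress(strain, ogden, measure)
}

#' Model stress-strain curve at one strain rate
#'
#' Convenience wrapper: builds a constant-rate ramp and runs the recursive
#' QLV forward model for a material, returning the curve indexed by strain.
#'
#' @param material a [material_model()] with Ogden terms (Prony optional).
#' @param mode deformation mode.
#' @param rate strain rate in 1/s.
#' @param max_strain final strain of the ramp (\eqn{\gamma_{max}} or
#'   \eqn{\lambda_{max}}).
#' @param n_steps forward-integration steps (default 1000).
#' @param measure uniaxial stress measure, `"cauchy"` or `"nominal"`.
#' @return A [stress_strain_curve()].
#' @export
rate_response_curve <- function(material, mode, rate, max_strain,
                                n_steps = 1000,
                                measure = c("cauchy", "nominal")) {
  stopifnot(inherits(material, "material_model"))
  if (is.null(material$ogden))
    stop(sprintf("material '%s' has no Ogden terms", material$name),
         call. = FALSE)
  measure <- match.arg(measure)
  prony <- if (is.null(material$prony)) prony_series() else material$prony
  h <- ramp_history(rate, max_strain, n_steps, mode)
  qlv_stress_recursive(h, material$ogden, prony, measure)
}
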