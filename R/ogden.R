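#' Ogden hyperelastic parameters
#'
#' Container for an N-term incompressible Ogden model in principal
#' stretches. The strain-energy convention used throughout this package is
#' \deqn{W = \sum_i \frac{2\mu_i}{\alpha_i^2}
#'   (\lambda_1^{\alpha_i} + \lambda_2^{\alpha_i} + \lambda_3^{\alpha_i} - 3),}
#' under which the small-strain shear modulus is \eqn{\sum_i \mu_i}. This is
#' the convention used by the major explicit FE solver families, and it is
#' the reason material tables can label the \eqn{\mu} column "shear modulus".
#'
#' @param mu numeric vector of shear-modulus-like coefficients \eqn{\mu_i}
#'   in kPa; all strictly positive.
#' @param alpha numeric vector of dimensionless exponents \eqn{\alpha_i};
#'   each must satisfy \eqn{|\alpha_i| \ge 0.1} (the energy is singular at
#'   \eqn{\alpha = 0}).
#' @return An object of class `ogden_parameters`.
#' @examples
#' og <- ogden_parameters(mu = 1.81, alpha = 10.1) # cerebrum-like
#' small_strain_shear_modulus(og)
#' @export
ogden_parameters <- function(mu, alpha) {
  if (length(mu) < 1L || length(mu) != length(alpha))
    stop("`mu` and `alpha` must be non-empty vectors of equal length",
         call. = FALSE)
  if (!is.numeric(mu) || !is.numeric(alpha) || anyNA(mu) || anyNA(alpha))
    stop("Ogden parameters must be finite numerics", call. = FALSE)
  if (any(mu <= 0))
    stop("every mu_i must be > 0", call. = FALSE)
  if (any(abs(alpha) < 0.1))
    stop("every |alpha_i| must be >= 0.1 (energy singular at alpha = 0)",
         call. = FALSE)
  structure(list(mu = as.numeric(mu), alpha = as.numeric(alpha)),
            class = "ogden_parameters")
}

#' @export
print.ogden_parameters <- function(x, ...) {
  cat(sprintf("Ogden parameters (%d term%s):\n", length(x$mu),
              if (length(x$mu) > 1L) "s" else ""))
  for (i in seq_along(x$mu))
    cat(sprintf("  mu_%d = %g kPa, alpha_%d = %g\n", i, x$mu[i], i, x$alpha[i]))
  cat(sprintf("  small-strain shear modulus: %g kPa\n", sum(x$mu)))
  invisible(x)
}

#' Principal stretches of an incompressible deformation
#'
#' @param lambda1,lambda2,lambda3 principal stretches; all positive and
#'   satisfying \eqn{\lambda_1 \lambda_2 \lambda_3 = 1} within `1e-12`.
#' @return An object of class `principal_stretches`.
#' @export
principal_stretches <- function(lambda1, lambda2, lambda3) {
  l <- c(lambda1, lambda2, lambda3)
  if (any(!is.finite(l)) || any(l <= 0))
    stop("principal stretches must be positive and finite", call. = FALSE)
  if (abs(prod(l) - 1) > 1e-12)
    stop("incompressibility violated: lambda1*lambda2*lambda3 != 1",
         call. = FALSE)
  structure(list(lambda = l), class = "principal_stretches")
}

#' Simple-shear kinematics
#'
#' Maps engineering shear strain \eqn{\gamma} (plate displacement divided by
#' sample thickness) to the principal stretches of simple shear,
#' \eqn{(\lambda, 1/\lambda, 1)} with \eqn{\lambda - 1/\lambda = \gamma},
#' i.e. \eqn{\lambda = \gamma/2 + \sqrt{1 + \gamma^2/4}}.
#'
#' @param gamma engineering shear strain, `gamma >= 0` (scalar).
#' @return A `principal_stretches` object.
#' @export
shear_kinematics <- function(gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma))
    stop("`gamma` must be a finite scalar", call. = FALSE)
  if (gamma < 0)
    stop("`gamma` must be >= 0", call. = FALSE)
  lam <- gamma / 2 + sqrt(1 + gamma^2 / 4)
  principal_stretches(lam, 1 / lam, 1)
}

#' Ogden strain-energy density
#'
#' Evaluates the Ogden energy density at a given incompressible stretch
#' state, in kPa (energy per unit reference volume).
#'
#' @param stretches a [principal_stretches()] object.
#' @param ogden an [ogden_parameters()] object.
#' @return Energy density in kPa; zero iff all stretches equal 1.
#' @export
strain_energy <- function(stretches, ogden) {
  stopifnot(inherits(stretches, "principal_stretches"),
            inherits(ogden, "ogden_parameters"))
  l <- stretches$lambda
  sum(2 * ogden$mu / ogden$alpha^2 *
        (l[1]^ogden$alpha + l[2]^ogden$alpha + l[3]^ogden$alpha - 3))
}

#' Instantaneous Cauchy shear stress of an Ogden solid in simple shear
#'
#' For simple shear with stretches \eqn{(\lambda, 1/\lambda, 1)} the Cauchy
#' shear stress is
#' \deqn{\sigma_{12}(\gamma) = \sum_i \frac{2\mu_i}{\alpha_i}
#'   \frac{\lambda^{\alpha_i} - \lambda^{-\alpha_i}}{\lambda + \lambda^{-1}}.}
#' With a single term and \eqn{\alpha = 2} this reduces exactly to the
#' neo-Hookean \eqn{\sigma_{12} = \mu\gamma}. This stress component equals
#' the shear traction on the loading plates for this kinematics.
#'
#' @param gamma engineering shear strain(s), `>= 0`; vectorized.
#' @param ogden an [ogden_parameters()] object.
#' @return Cauchy shear stress in kPa, same length as `gamma`.
#' @export
instantaneous_shear_stress <- function(gamma, ogden) {
  stopifnot(inherits(ogden, "ogden_parameters"))
  if (!is.numeric(gamma) || anyNA(gamma) || any(gamma < 0))
    stop("`gamma` must be numeric and >= 0", call. = FALSE)
  lam <- gamma / 2 + sqrt(1 + gamma^2 / 4)
  out <- numeric(length(gamma))
  for (i in seq_along(ogden$mu)) {
    a <- ogden$alpha[i]
    out <- out + (2 * ogden$mu[i] / a) * (lam^a - lam^(-a)) / (lam + 1 / lam)
  }
  out
}

#' Instantaneous axial stress of an Ogden solid in uniaxial tension
#'
#' Incompressible uniaxial extension has stretches
#' \eqn{(\lambda, \lambda^{-1/2}, \lambda^{-1/2})}; with the lateral faces
#' traction-free the hydrostatic pressure is eliminated and
#' \deqn{\sigma_{11} = \sum_i \frac{2\mu_i}{\alpha_i}
#'   (\lambda^{\alpha_i} - \lambda^{-\alpha_i/2}),}
#' the Cauchy (true) stress. The nominal (engineering) stress is
#' \eqn{P_{11} = \sigma_{11}/\lambda}.
#'
#' @param lambda axial stretch(es), `>= 1` (compression is out of scope);
#'   vectorized.
#' @param ogden an [ogden_parameters()] object.
#' @param measure `"cauchy"` (default) or `"nominal"`.
#' @return Axial stress in kPa, same length as `lambda`.
#' @export
instantaneous_uniaxial_stress <- function(lambda, ogden,
                                          measure = c("cauchy", "nominal")) {
  stopifnot(inherits(ogden, "ogden_parameters"))
  measure <- match.arg(measure)
  if (!is.numeric(lambda) || anyNA(lambda) || any(lambda < 1))
    stop("`lambda` must be numeric and >= 1 (tension only)", call. = FALSE)
  out <- numeric(length(lambda))
  for (i in seq_along(ogden$mu)) {
    a <- ogden$alpha[i]
    out <- out + (2 * ogden$mu[i] / a) * (lambda^a - lambda^(-a / 2))
  }
  if (measure == "nominal") out <- out / lambda
  out
}

#' Small-strain shear modulus of an Ogden model
#'
#' Under the energy convention used here the initial shear modulus is simply
#' \eqn{\sum_i \mu_i}; it equals the limit of \eqn{\sigma_{12}/\gamma} as
#' \eqn{\gamma \to 0}.
#'
#' @param ogden an [ogden_parameters()] object.
#' @return Shear modulus in kPa.
#' @export
small_strain_shear_modulus <- function(ogden) {
  stopifnot(inherits(ogden, "ogden_parameters"))
  sum(ogden$mu)
}
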