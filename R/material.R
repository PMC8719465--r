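#' A named tissue material model
#'
#' One material as it would appear in a solver material table: density,
#' bulk modulus (carried as metadata — homogeneous shear and uniaxial test
#' stresses of an incompressible material do not depend on it), an Ogden
#' deviatoric backbone, an optional Prony series, and optional
#' linear-elastic metadata for non-fitted stiff components (e.g. bone).
#'
#' @param name material name.
#' @param density mass density in kg/m^3 (positive).
#' @param bulk_modulus bulk modulus in GPa (positive), metadata only.
#' @param ogden an [ogden_parameters()] object, or `NULL` for purely
#'   linear-elastic metadata materials.
#' @param prony a [prony_series()] object or `NULL` (elastic).
#' @param elastic_modulus optional linear elastic modulus in GPa.
#' @param poisson_ratio optional Poisson's ratio in `(-1, 0.5)`.
#' @param provenance free-text provenance note.
#' @return An object of class `material_model`.
#' @export
material_model <- function(name, density, bulk_modulus = NULL, ogden = NULL,
                           prony = NULL, elastic_modulus = NULL,
                           poisson_ratio = NULL, provenance = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("`name` must be a non-empty string", call. = FALSE)
  if (!is.numeric(density) || density <= 0)
    stop("`density` must be > 0 (kg/m^3)", call. = FALSE)
  if (!is.null(bulk_modulus) && bulk_modulus <= 0)
    stop("`bulk_modulus` must be > 0 (GPa)", call. = FALSE)
  if (!is.null(ogden)) stopifnot(inherits(ogden, "ogden_parameters"))
  if (!is.null(prony)) {
    stopifnot(inherits(prony, "prony_series"))
    if (is.null(ogden))
      stop("a Prony series requires an Ogden backbone", call. = FALSE)
  }
  if (!is.null(poisson_ratio) &&
      (poisson_ratio <= -1 || poisson_ratio >= 0.5))
    stop("`poisson_ratio` must lie in (-1, 0.5)", call. = FALSE)
  structure(list(name = name, density = as.numeric(density),
                 bulk_modulus = bulk_modulus, ogden = ogden, prony = prony,
                 elastic_modulus = elastic_modulus,
                 poisson_ratio = poisson_ratio, provenance = provenance),
            class = "material_model")
}

#' @export
print.material_model <- function(x, ...) {
  cat(sprintf("Material model '%s': density %g kg/m^3", x$name, x$density))
  if (!is.null(x$bulk_modulus))
    cat(sprintf(", bulk modulus %g GPa", x$bulk_modulus))
  cat("\n")
  if (!is.null(x$elastic_modulus))
    cat(sprintf("  linear elastic: E = %g GPa, nu = %g\n",
                x$elastic_modulus, x$poisson_ratio))
  if (!is.null(x$ogden)) print(x$ogden)
  if (!is.null(x$prony)) print(x$prony)
  invisible(x)
}

#' Reference tissue material presets
#'
#' The six calibrated Göttingen-minipig head materials used throughout the
#' package's examples and tests: three brain regions (cerebrum, cerebellum,
#' brainstem; one-term Ogden + one-term Prony, characterized in simple
#' shear), the middle-cerebral-artery vasculature (one-term Ogden +
#' one-term Prony, characterized in uniaxial tension), the dura (one-term
#' Ogden, purely hyperelastic), and the skull (compressible linear-elastic
#' metadata only; it is never fit).
#'
#' @return Named list of [material_model()] objects.
#' @examples
#' preset_materials()$cerebrum
#' @export
preset_materials <- function() {
  soft <- function(name, mu, alpha, g = NULL, decay = NULL) {
    material_model(
      name, density = 1040, bulk_modulus = 2.19,
      ogden = ogden_parameters(mu, alpha),
      prony = if (is.null(g)) NULL else prony_series(g = g, decay = decay),
      provenance = "calibrated minipig head-model material table")
  }
  list(
    cerebrum    = soft("cerebrum",    1.81,  10.1, 0.99, 0.276),
    cerebellum  = soft("cerebellum",  1.46,   8.0, 0.92, 0.562),
    brainstem   = soft("brainstem",   2.25,  11.2, 0.99, 0.455),
    vasculature = soft("vasculature", 700.40, 12.6, 0.90, 0.077),
    dura        = soft("dura",        450.00, 16.5),
    skull       = material_model(
      "skull", density = 1200, elastic_modulus = 2.00, poisson_ratio = 0.22,
      provenance = "compressible linear-elastic metadata; not fit")
  )
}

#' Replicate-experiment design
#'
#' Describes one multi-rate test campaign: the deformation mode, the strain
#' rates, the number of replicates per rate, the maximum strain of the ramp
#' and the number of strain-grid points retained per curve.
#'
#' @param mode deformation mode.
#' @param rates strain rates in 1/s (positive, distinct).
#' @param n replicates per rate (`>= 1`).
#' @param max_strain final strain of each ramp.
#' @param n_points points on the shared strain grid per curve (default 101).
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(mode, rates, n, max_strain, n_points = 101) {
  .check_mode(mode)
  if (!is.numeric(rates) || length(rates) < 1L || any(rates <= 0))
    stop("`rates` must be positive strain rates (1/s)", call. = FALSE)
  if (anyDuplicated(rates))
    stop("`rates` must be distinct", call. = FALSE)
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (max_strain <= .strain_origin(mode))
    stop("`max_strain` must exceed the undeformed strain", call. = FALSE)
  if (n_points < 2) stop("`n_points` must be >= 2", call. = FALSE)
  structure(list(mode = mode, rates = as.numeric(rates), n = as.integer(n),
                 max_strain = as.numeric(max_strain),
                 n_points = as.integer(n_points)),
            class = "experiment_design")
}

#' Reference experiment designs
#'
#' The two test campaigns the synthetic generator emulates:
#' \describe{
#'   \item{`brain_shear`}{simple shear at 0.01, 150 and 300 1/s, n = 6
#'     replicates per rate, \eqn{\gamma_{max} = 8/7 \approx 1.14} (an 8 mm
#'     plate displacement on a 7 mm thick sample).}
#'   \item{`vessel_tension`}{uniaxial tension at the same three rates,
#'     n = 12 replicates per rate, \eqn{\lambda_{max} = 1.3}.}
#' }
#'
#' @return Named list of [experiment_design()] objects.
#' @export
preset_designs <- function() {
  list(
    brain_shear = experiment_design("simple_shear",
                                    rates = c(0.01, 150, 300), n = 6,
                                    max_strain = 8 / 7),
    vessel_tension = experiment_design("uniaxial_tension",
                                       rates = c(0.01, 150, 300), n = 12,
                                       max_strain = 1.3)
  )
}
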