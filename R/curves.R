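#' Deformation modes
#'
#' The two homogeneous test modes supported by the package. The strain
#' variable is mode-dependent: `"simple_shear"` curves carry engineering
#' shear strain \eqn{\gamma \ge 0} (plate displacement / sample thickness);
#' `"uniaxial_tension"` curves carry the axial stretch \eqn{\lambda \ge 1}
#' (current length / reference length).
#'
#' @name deformation_modes
#' @keywords internal
NULL

.modes <- c("simple_shear", "uniaxial_tension")

.check_mode <- function(mode) {
  if (!is.character(mode) || length(mode) != 1L || !(mode %in% .modes))
    stop("`mode` must be one of: ", paste(.modes, collapse = ", "),
         call. = FALSE)
  mode
}

.strain_origin <- function(mode) if (mode == "simple_shear") 0 else 1

#' A single stress-strain curve
#'
#' The basic data container: one test (or model) curve in one deformation
#' mode at one nominal strain rate. A curve may be a raw replicate (then
#' `replicate` identifies it) or a replicate summary (then `sem` and `n`
#' are present and `stress` holds the pointwise mean).
#'
#' @param mode `"simple_shear"` or `"uniaxial_tension"`.
#' @param rate nominal strain rate in 1/s (positive).
#' @param strain strain grid: \eqn{\gamma} (shear) or \eqn{\lambda}
#'   (tension), non-decreasing.
#' @param stress stress values in kPa (mean stress for summaries).
#' @param replicate optional replicate identifier.
#' @param sem optional pointwise standard error of the mean (kPa, `>= 0`).
#' @param n optional number of replicates behind a summary (`>= 1`). A
#'   summary with `n = 1` must carry `sem = NULL` (unknown), never zeros.
#' @param curve_id optional curve identifier used by the file writers.
#' @return An object of class `stress_strain_curve`.
#' @export
stress_strain_curve <- function(mode, rate, strain, stress, replicate = NULL,
                                sem = NULL, n = NULL, curve_id = NULL) {
  .check_mode(mode)
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("`rate` must be a positive scalar (1/s)", call. = FALSE)
  if (length(strain) != length(stress))
    stop("`strain` and `stress` must have equal length", call. = FALSE)
  if (anyNA(strain) || anyNA(stress))
    stop("strain/stress must not contain NA", call. = FALSE)
  if (is.unsorted(strain))
    stop("`strain` must be non-decreasing", call. = FALSE)
  if (!is.null(sem)) {
    if (length(sem) != length(strain) || any(sem < 0))
      stop("`sem` must match the grid length and be >= 0", call. = FALSE)
    if (is.null(n) || n < 2)
      stop("a summary with `sem` needs `n` >= 2; with n = 1 the SEM is ",
           "unknown and must be omitted", call. = FALSE)
  }
  if (!is.null(n) && (length(n) != 1L || n < 1))
    stop("`n` must be a scalar >= 1", call. = FALSE)
  structure(list(mode = mode, rate = as.numeric(rate),
                 strain = as.numeric(strain), stress = as.numeric(stress),
                 replicate = replicate, sem = if (is.null(sem)) NULL
                 else as.numeric(sem),
                 n = if (is.null(n)) NULL else as.integer(n),
                 curve_id = curve_id),
            class = "stress_strain_curve")
}

#' @export
print.stress_strain_curve <- function(x, ...) {
  kind <- if (!is.null(x$sem)) sprintf("summary (n = %d)", x$n)
  else if (!is.null(x$replicate)) sprintf("replicate %s", x$replicate)
  else "model/raw"
  cat(sprintf("Stress-strain curve [%s], %s, rate %g 1/s, %d points\n",
              x$mode, kind, x$rate, length(x$strain)))
  cat(sprintf("  strain range [%g, %g], peak |stress| %g kPa\n",
              min(x$strain), max(x$strain), max(abs(x$stress))))
  invisible(x)
}

#' Constant-rate loading history
#'
#' A time/strain grid describing one test. For ramps the strain is affine
#' in time with slope equal to the nominal rate.
#'
#' @param mode deformation mode (see [stress_strain_curve()]).
#' @param time strictly increasing time grid in s, starting at 0.
#' @param strain strain value per time point; starts at 0 (shear
#'   \eqn{\gamma}) or 1 (tension \eqn{\lambda}).
#' @param nominal_rate declared constant strain rate in 1/s.
#' @return An object of class `loading_history`.
#' @export
loading_history <- function(mode, time, strain, nominal_rate) {
  .check_mode(mode)
  if (length(time) < 2L || length(time) != length(strain))
    stop("`time` and `strain` must be equal-length vectors (>= 2 points)",
         call. = FALSE)
  if (time[1] != 0 || any(diff(time) <= 0))
    stop("`time` must start at 0 and be strictly increasing", call. = FALSE)
  if (abs(strain[1] - .strain_origin(mode)) > 1e-12)
    stop(sprintf("strain must start at %g for mode %s",
                 .strain_origin(mode), mode), call. = FALSE)
  if (!is.numeric(nominal_rate) || nominal_rate <= 0)
    stop("`nominal_rate` must be > 0", call. = FALSE)
  structure(list(mode = mode, time = as.numeric(time),
                 strain = as.numeric(strain),
                 nominal_rate = as.numeric(nominal_rate)),
            class = "loading_history")
}

#' Constant-strain-rate ramp history
#'
#' Builds a uniform time grid over `[0, excursion/rate]` with strain affine
#' in time: from 0 to `max_strain` for shear, from 1 to `max_strain` for
#' tension (excursion `max_strain - 1`).
#'
#' @param rate constant strain rate in 1/s (positive).
#' @param max_strain final strain: \eqn{\gamma_{max} > 0} (shear) or
#'   \eqn{\lambda_{max} > 1} (tension).
#' @param n_steps number of time steps (`>= 1`; the grid has
#'   `n_steps + 1` points).
#' @param mode deformation mode.
#' @return A [loading_history()] object.
#' @examples
#' h <- ramp_history(rate = 0.01, max_strain = 1, n_steps = 4,
#'                   mode = "simple_shear")
#' h$time # 0, 25, 50, 75, 100 s
#' @export
ramp_history <- function(rate, max_strain, n_steps = 1000,
                         mode = "simple_shear") {
  .check_mode(mode)
  if (!is.numeric(rate) || rate <= 0) stop("`rate` must be > 0", call. = FALSE)
  if (n_steps < 1) stop("`n_steps` must be >= 1", call. = FALSE)
  origin <- .strain_origin(mode)
  excursion <- max_strain - origin
  if (excursion <= 0)
    stop(sprintf("`max_strain` must exceed %g for mode %s", origin, mode),
         call. = FALSE)
  duration <- excursion / rate
  time <- seq(0, duration, length.out = n_steps + 1L)
  loading_history(mode, time, origin + rate * time, rate)
}
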