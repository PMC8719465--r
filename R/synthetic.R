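#' Replicate noise model
#'
#' Gaussian observation noise for synthetic replicates: at every grid point
#' the stress is drawn as `truth + Normal(0, sd)` with
#' `sd = a * |truth| + b`, i.e. a multiplicative fraction plus an additive
#' floor. The defaults (5% multiplicative, floor at 1% of the per-curve
#' peak stress) are chosen to resemble the scale of standard-error bars
#' seen on averaged soft-tissue test curves.
#'
#' @param a multiplicative noise fraction (`>= 0`), default 0.05.
#' @param b additive noise floor in kPa (`>= 0`), or `NULL` (default) for
#'   1% of the peak |true stress| of each curve, resolved at generation.
#' @param seed integer RNG seed, default 0.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(a = 0.05, b = NULL, seed = 0) {
  if (!is.numeric(a) || a < 0) stop("`a` must be >= 0", call. = FALSE)
  if (!is.null(b) && (!is.numeric(b) || b < 0))
    stop("`b` must be >= 0 or NULL (auto)", call. = FALSE)
  structure(list(a = as.numeric(a), b = b, seed = as.integer(seed)),
            class = "noise_model")
}

# run code with a private RNG stream; global .Random.seed is restored
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate synthetic replicate stress-strain data
#'
#' For every rate in the design, the true curve is computed with the
#' recursive QLV forward model (internally integrated on a fine uniform
#' grid, then subsampled onto the design's shared strain grid) and `n`
#' independent noisy replicates are drawn from the noise model. The
#' generating truth is stored alongside the replicates so parameter
#' recovery can be tested.
#'
#' @param material a [material_model()] with Ogden terms.
#' @param design an [experiment_design()].
#' @param noise a [noise_model()]; `noise_model(a = 0)` with `b = 0` gives
#'   replicates identical to the truth.
#' @param n_steps internal forward-integration steps (default 1000).
#' @param measure uniaxial stress measure.
#' @return An object of class `replicate_set`: a list with elements
#'   `mode`, `rates`, `curves` (per-rate list of replicate
#'   [stress_strain_curve()]s), `truth` (per-rate true curve), `material`,
#'   `design`, `noise`.
#' @export
generate_replicates <- function(material, design, noise = noise_model(),
                                n_steps = 1000,
                                measure = c("cauchy", "nominal")) {
  stopifnot(inherits(material, "material_model"),
            inherits(design, "experiment_design"),
            inherits(noise, "noise_model"))
  measure <- match.arg(measure)
  if (is.null(material$ogden))
    stop(sprintf("material '%s' has no Ogden terms", material$name),
         call. = FALSE)
  # integrate on a fine grid that contains the design grid as a subset
  per <- max(1L, ceiling(n_steps / (design$n_points - 1L)))
  steps <- per * (design$n_points - 1L)
  keep <- seq(1L, steps + 1L, by = per)
  out <- .with_seed(noise$seed, {
    lapply(design$rates, function(rate) {
      full <- rate_response_curve(material, design$mode, rate,
                                  design$max_strain, n_steps = steps,
                                  measure = measure)
      truth <- stress_strain_curve(design$mode, rate, full$strain[keep],
                                   full$stress[keep],
                                   curve_id = sprintf("%s_r%g",
                                                      material$name, rate))
      b <- if (is.null(noise$b)) 0.01 * max(abs(truth$stress)) else noise$b
      sd <- noise$a * abs(truth$stress) + b
      reps <- lapply(seq_len(design$n), function(k) {
        stress_strain_curve(design$mode, rate, truth$strain,
                            truth$stress + stats::rnorm(length(sd), 0, sd),
                            replicate = k, curve_id = truth$curve_id)
      })
      list(truth = truth, replicates = reps)
    })
  })
  structure(list(mode = design$mode, rates = design$rates,
                 curves = lapply(out, `[[`, "replicates"),
                 truth = lapply(out, `[[`, "truth"),
                 material = material, design = design, noise = noise),
            class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  cat(sprintf("Replicate set [%s]: %d rate%s (%s 1/s), n = %d per rate\n",
              x$mode, length(x$rates), if (length(x$rates) > 1L) "s" else "",
              paste(x$rates, collapse = ", "), x$design$n))
  if (!is.null(x$material))
    cat(sprintf("  generated from material '%s'\n", x$material$name))
  invisible(x)
}

#' Summarize replicates into mean/SEM curves
#'
#' Pointwise mean and standard error of the mean (sd/sqrt(n)) per rate,
#' the summary convention used when averaged test curves are reported with
#' SEM bars. With a single replicate the SEM is unknown and omitted rather
#' than reported as zero.
#'
#' @param reps a [replicate_set()] from [generate_replicates()] or
#'   [read_curves()].
#' @return List of summary [stress_strain_curve()]s, one per rate.
#' @export
summarize_replicates <- function(reps) {
  stopifnot(inherits(reps, "replicate_set"))
  if (length(reps$curves) == 0L || any(lengths(reps$curves) == 0L))
    stop("empty replicate set", call. = FALSE)
  lapply(seq_along(reps$rates), function(j) {
    group <- reps$curves[[j]]
    strain <- group[[1]]$strain
    for (cv in group)
      if (length(cv$strain) != length(strain) ||
          max(abs(cv$strain - strain)) > 1e-10)
        stop("replicates within a rate must share one strain grid",
             call. = FALSE)
    mat <- vapply(group, `[[`, numeric(length(strain)), "stress")
    n <- length(group)
    if (n == 1L)
      return(stress_strain_curve(reps$mode, reps$rates[j], strain,
                                 as.numeric(mat), n = 1L,
                                 curve_id = group[[1]]$curve_id))
    stress_strain_curve(reps$mode, reps$rates[j], strain, rowMeans(mat),
                        sem = apply(mat, 1, stats::sd) / sqrt(n), n = n,
                        curve_id = group[[1]]$curve_id)
  })
}
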