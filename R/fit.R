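#' Calibration configuration
#'
#' Controls the simultaneous multi-rate least-squares fit: model order,
#' box bounds, residual weighting, multi-start policy and optimizer
#' tolerances. Parameters are packed in the order
#' `c(mu_1..mu_m, alpha_1..alpha_m, g_1..g_p, beta_1..beta_p)` where
#' `beta_i = 1/tau_i` are Prony decay constants in 1/s; `n_prony = 0`
#' requests a purely hyperelastic fit.
#'
#' @param n_ogden number of Ogden terms (default 1).
#' @param n_prony number of Prony terms (default 1; 0 = elastic-only).
#' @param mu_bounds bounds on each mu_i in kPa, default `c(1e-4, 1e6)`.
#' @param alpha_max upper bound on |alpha_i|, default 50 (lower bound 0.1).
#' @param positive_alpha restrict alpha to positive values (default `TRUE`;
#'   set `FALSE` for signed-exponent multi-term fits).
#' @param g_max upper bound on each g_i, default 0.999.
#' @param beta_bounds bounds on each decay constant in 1/s, default
#'   `c(1e-4, 1e4)`.
#' @param weighting `"peak"` (default): each curve's residuals are scaled
#'   by 1/max|mean stress| so stiff high-rate curves do not dominate;
#'   `"inv_sem"`: pointwise 1/SEM weights (requires summaries with SEM).
#' @param n_starts multi-start count (default 16), `>= 1`.
#' @param seed integer seed for the multi-start draws (default 0).
#' @param ftol,ptol Levenberg-Marquardt convergence tolerances.
#' @param maxiter maximum optimizer iterations per start.
#' @param n_steps forward-model integration steps per curve (default 1000).
#' @param measure uniaxial stress measure used by the forward model.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(n_ogden = 1, n_prony = 1,
                       mu_bounds = c(1e-4, 1e6), alpha_max = 50,
                       positive_alpha = TRUE, g_max = 0.999,
                       beta_bounds = c(1e-4, 1e4),
                       weighting = c("peak", "inv_sem"),
                       n_starts = 16, seed = 0,
                       ftol = 1e-12, ptol = 1e-12, maxiter = 200,
                       n_steps = 1000,
                       measure = c("cauchy", "nominal")) {
  weighting <- match.arg(weighting)
  measure <- match.arg(measure)
  if (n_ogden < 1) stop("`n_ogden` must be >= 1", call. = FALSE)
  if (n_prony < 0) stop("`n_prony` must be >= 0", call. = FALSE)
  if (n_starts < 1) stop("`n_starts` must be >= 1", call. = FALSE)
  stopifnot(mu_bounds[1] > 0, mu_bounds[2] > mu_bounds[1],
            alpha_max > 0.1, g_max > 0, g_max < 1,
            beta_bounds[1] > 0, beta_bounds[2] > beta_bounds[1],
            ftol > 0, ptol > 0, maxiter >= 1, n_steps >= 2)
  structure(list(n_ogden = as.integer(n_ogden),
                 n_prony = as.integer(n_prony),
                 mu_bounds = mu_bounds, alpha_max = alpha_max,
                 positive_alpha = isTRUE(positive_alpha), g_max = g_max,
                 beta_bounds = beta_bounds, weighting = weighting,
                 n_starts = as.integer(n_starts), seed = as.integer(seed),
                 ftol = ftol, ptol = ptol, maxiter = as.integer(maxiter),
                 n_steps = as.integer(n_steps), measure = measure),
            class = "fit_config")
}

# ---- parameter packing -----------------------------------------------------

.theta_split <- function(theta, config) {
  m <- config$n_ogden; p <- config$n_prony
  if (length(theta) != 2 * m + 2 * p)
    stop("parameter vector has wrong length", call. = FALSE)
  list(mu = theta[seq_len(m)], alpha = theta[m + seq_len(m)],
       g = if (p) theta[2 * m + seq_len(p)] else numeric(0),
       beta = if (p) theta[2 * m + p + seq_len(p)] else numeric(0))
}

.theta_model <- function(theta, config) {
  sp <- .theta_split(theta, config)
  list(ogden = ogden_parameters(sp$mu, sp$alpha),
       prony = if (config$n_prony) prony_series(sp$g, decay = sp$beta)
       else prony_series())
}

# internal optimizer scale: log(mu), alpha, g, log(beta)
.to_internal <- function(theta, config) {
  sp <- .theta_split(theta, config)
  c(log(sp$mu), sp$alpha, sp$g, log(sp$beta))
}

.from_internal <- function(eta, config) {
  m <- config$n_ogden; p <- config$n_prony
  c(exp(eta[seq_len(m)]), eta[m + seq_len(m)],
    if (p) eta[2 * m + seq_len(p)] else numeric(0),
    if (p) exp(eta[2 * m + p + seq_len(p)]) else numeric(0))
}

.internal_bounds <- function(config) {
  m <- config$n_ogden; p <- config$n_prony
  a_lo <- if (config$positive_alpha) 0.1 else -config$alpha_max
  lower <- c(rep(log(config$mu_bounds[1]), m), rep(a_lo, m),
             rep(0, p), rep(log(config$beta_bounds[1]), p))
  upper <- c(rep(log(config$mu_bounds[2]), m), rep(config$alpha_max, m),
             rep(config$g_max, p), rep(log(config$beta_bounds[2]), p))
  list(lower = lower, upper = upper)
}

# ---- residuals -------------------------------------------------------------

# precompute per-curve ramp histories, weights and data vectors
.fit_problem <- function(datasets, config) {
  stopifnot(length(datasets) >= 1L)
  prob <- lapply(seq_along(datasets), function(j) {
    cv <- datasets[[j]]
    stopifnot(inherits(cv, "stress_strain_curve"))
    id <- if (!is.null(cv$curve_id)) cv$curve_id else sprintf("curve %d", j)
    origin <- .strain_origin(cv$mode)
    if (min(cv$strain) < origin - 1e-12)
      stop(sprintf("curve '%s': strain below the undeformed state", id),
           call. = FALSE)
    if (max(cv$strain) <= origin)
      stop(sprintf("curve '%s': no strain excursion to simulate", id),
           call. = FALSE)
    hist <- ramp_history(cv$rate, max(cv$strain), config$n_steps, cv$mode)
    peak <- max(abs(cv$stress))
    if (peak == 0)
      stop(sprintf("curve '%s': all-zero stress cannot be peak-normalized",
                   id), call. = FALSE)
    w <- if (config$weighting == "peak") {
      rep(1 / peak, length(cv$strain))
    } else {
      if (is.null(cv$sem))
        stop(sprintf("curve '%s': inv_sem weighting needs SEM", id),
             call. = FALSE)
      1 / pmax(cv$sem, 1e-6 * peak)
    }
    list(curve = cv, history = hist, w = w, id = id)
  })
  prob
}

.residuals_from_problem <- function(theta, problem, config) {
  model <- .theta_model(theta, config)
  unlist(lapply(problem, function(pb) {
    sim <- qlv_stress_recursive(pb$history, model$ogden, model$prony,
                                config$measure)
    fit <- stats::approx(sim$strain, sim$stress, xout = pb$curve$strain)$y
    pb$w * (fit - pb$curve$stress)
  }))
}

#' Weighted residual vector of the multi-rate QLV fit
#'
#' One weighted residual per data point:
#' `w * (model stress - mean data stress)`, with the model evaluated by the
#' recursive QLV integrator on a constant-rate ramp covering each curve's
#' strain range and interpolated linearly onto the data strain grid.
#'
#' @param theta packed parameter vector on the natural scale,
#'   `c(mu..., alpha..., g..., beta...)` (see [fit_config()]).
#' @param datasets list of summary [stress_strain_curve()]s (the fit
#'   targets are mean curves).
#' @param config a [fit_config()].
#' @return Numeric vector of weighted residuals (concatenated over curves).
#' @export
residual_vector <- function(theta, datasets, config = fit_config()) {
  stopifnot(inherits(config, "fit_config"))
  .residuals_from_problem(theta, .fit_problem(datasets, config), config)
}

#' Coefficient of determination between a model and a data curve
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} with \eqn{SS_{tot}} taken about the
#' data-curve mean stress. Curves must share one strain grid.
#'
#' @param model_curve,data_curve [stress_strain_curve()]s on a common
#'   strain grid, or plain numeric stress vectors of equal length.
#' @return \eqn{R^2 \le 1}; 1 for identical curves.
#' @export
r_squared <- function(model_curve, data_curve) {
  ms <- if (inherits(model_curve, "stress_strain_curve"))
    model_curve$stress else as.numeric(model_curve)
  ds <- if (inherits(data_curve, "stress_strain_curve"))
    data_curve$stress else as.numeric(data_curve)
  if (inherits(model_curve, "stress_strain_curve") &&
      inherits(data_curve, "stress_strain_curve") &&
      (length(model_curve$strain) != length(data_curve$strain) ||
       max(abs(model_curve$strain - data_curve$strain)) > 1e-10))
    stop("curves must share one strain grid", call. = FALSE)
  if (length(ms) != length(ds))
    stop("curves must have equal length", call. = FALSE)
  ss_tot <- sum((ds - mean(ds))^2)
  if (ss_tot == 0)
    stop("R^2 undefined for a constant data curve", call. = FALSE)
  1 - sum((ds - ms)^2) / ss_tot
}

# ---- the simultaneous multi-rate fit ---------------------------------------

#' Simultaneous multi-rate Ogden/Prony calibration
#'
#' Estimates Ogden and Prony parameters by bounded Levenberg-Marquardt
#' least squares on the weighted residuals of [residual_vector()], fitting
#' all rate curves simultaneously. The optimizer works internally on
#' `log(mu)` and `log(beta)` for conditioning. Multi-start: `n_starts`
#' initial points drawn log-uniformly in mu and beta and uniformly in
#' alpha and g within the bounds, deterministically from the config seed;
#' the best converged start wins, ties broken by lowest start index.
#'
#' @param datasets list of summary [stress_strain_curve()]s, or a
#'   [generate_replicates()] `replicate_set` (summarized automatically).
#' @param config a [fit_config()].
#' @return An object of class `fit_result` with elements `ogden`, `prony`,
#'   `r_squared` (per curve), `pooled_r_squared`, `rss` (weighted),
#'   `converged`, `n_starts`, `best_start`, `warnings`, `starts`
#'   (per-start diagnostics), `config`.
#' @examples
#' \donttest{
#' mat <- preset_materials()$cerebrum
#' reps <- generate_replicates(mat, preset_designs()$brain_shear,
#'                             noise_model(a = 0, b = 0))
#' fit <- fit_multirate(reps, fit_config(n_starts = 4))
#' fit$ogden
#' }
#' @export
fit_multirate <- function(datasets, config = fit_config()) {
  stopifnot(inherits(config, "fit_config"))
  if (inherits(datasets, "replicate_set"))
    datasets <- summarize_replicates(datasets)
  if (inherits(datasets, "stress_strain_curve")) datasets <- list(datasets)
  warns <- character(0)
  n_rates <- length(unique(vapply(datasets, `[[`, numeric(1), "rate")))
  if (config$n_prony > 0 && n_rates < 2) {
    warns <- c(warns, paste("Prony terms requested but curves span fewer",
                            "than 2 distinct rates; relaxation is weakly",
                            "identifiable"))
    warning(warns[length(warns)], call. = FALSE)
  }
  problem <- .fit_problem(datasets, config)
  bounds <- .internal_bounds(config)
  starts <- .draw_starts(config)
  fn <- function(eta) .residuals_from_problem(.from_internal(eta, config),
                                              problem, config)
  results <- vector("list", config$n_starts)
  for (s in seq_len(config$n_starts)) {
    eta0 <- pmin(pmax(.to_internal(starts[[s]], config), bounds$lower),
                 bounds$upper)
    res <- tryCatch(
      minpack.lm::nls.lm(par = eta0, lower = bounds$lower,
                         upper = bounds$upper, fn = fn,
                         control = minpack.lm::nls.lm.control(
                           ftol = config$ftol, ptol = config$ptol,
                           maxiter = config$maxiter,
                           maxfev = 100 * config$maxiter)),
      error = function(e) e)
    if (inherits(res, "error")) {
      results[[s]] <- list(ok = FALSE, message = conditionMessage(res))
    } else {
      results[[s]] <- list(ok = res$info %in% 1:4, info = res$info,
                           message = res$message,
                           rss = sum(res$fvec^2),
                           theta = .from_internal(res$par, config))
    }
  }
  ok <- vapply(results, `[[`, logical(1), "ok")
  if (!any(ok)) {
    diag <- paste(sprintf("start %d: %s", seq_along(results),
                          vapply(results, `[[`, character(1), "message")),
                  collapse = "; ")
    stop("no optimizer start converged; per-start diagnostics: ", diag,
         call. = FALSE)
  }
  rss <- vapply(results, function(r) if (isTRUE(r$ok)) r$rss else Inf,
                numeric(1))
  best <- which.min(rss) # which.min returns the first (lowest-index) min
  theta <- results[[best]]$theta
  model <- .theta_model(theta, config)
  r2 <- vapply(problem, function(pb) {
    sim <- qlv_stress_recursive(pb$history, model$ogden, model$prony,
                                config$measure)
    fit <- stats::approx(sim$strain, sim$stress, xout = pb$curve$strain)$y
    r_squared(fit, pb$curve$stress)
  }, numeric(1))
  names(r2) <- vapply(problem, `[[`, character(1), "id")
  all_fit <- unlist(lapply(problem, function(pb) {
    sim <- qlv_stress_recursive(pb$history, model$ogden, model$prony,
                                config$measure)
    stats::approx(sim$strain, sim$stress, xout = pb$curve$strain)$y
  }))
  all_dat <- unlist(lapply(problem, function(pb) pb$curve$stress))
  structure(list(ogden = model$ogden, prony = model$prony,
                 theta = theta, r_squared = r2,
                 pooled_r_squared = r_squared(all_fit, all_dat),
                 rss = rss[best], converged = TRUE,
                 n_starts = config$n_starts, best_start = best,
                 warnings = warns, starts = results, config = config),
            class = "fit_result")
}

.draw_starts <- function(config) {
  .with_seed(config$seed, {
    lapply(seq_len(config$n_starts), function(s) {
      m <- config$n_ogden; p <- config$n_prony
      mu <- exp(stats::runif(m, log(config$mu_bounds[1]),
                             log(config$mu_bounds[2])))
      alpha <- if (config$positive_alpha)
        stats::runif(m, 0.1, config$alpha_max)
      else stats::runif(m, -config$alpha_max, config$alpha_max)
      g <- if (p) stats::runif(p, 0, config$g_max) else numeric(0)
      beta <- if (p) exp(stats::runif(p, log(config$beta_bounds[1]),
                                      log(config$beta_bounds[2])))
      else numeric(0)
      c(mu, alpha, g, beta)
    })
  })
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Multi-rate QLV fit: best of %d start(s) = start %d, ",
              x$n_starts, x$best_start))
  cat(sprintf("weighted RSS %.4g\n", x$rss))
  print(x$ogden)
  print(x$prony)
  cat("Per-curve R^2:\n")
  for (nm in names(x$r_squared))
    cat(sprintf("  %s: %.5f\n", nm, x$r_squared[[nm]]))
  cat(sprintf("Pooled R^2: %.5f\n", x$pooled_r_squared))
  invisible(x)
}

#' Bootstrap parameter uncertainty
#'
#' Nonparametric bootstrap over replicates: within each rate the replicate
#' curves are resampled with replacement, re-summarized and refit;
#' percentile intervals are computed over the bootstrap parameter draws.
#' Deterministic given `seed`.
#'
#' @param replicates a `replicate_set` with `>= 2` replicates per rate.
#' @param config a [fit_config()].
#' @param n_boot number of bootstrap refits (`>= 2`).
#' @param seed integer RNG seed for the resampling.
#' @param level interval coverage level (default 0.95).
#' @return A data frame with one row per packed parameter: `parameter`,
#'   `estimate` (full-data fit), `lower`, `upper`; the bootstrap draws are
#'   attached as attribute `"draws"`.
#' @export
bootstrap_uncertainty <- function(replicates, config = fit_config(),
                                  n_boot = 50, seed = 0, level = 0.95) {
  stopifnot(inherits(replicates, "replicate_set"))
  if (n_boot < 2) stop("`n_boot` must be >= 2", call. = FALSE)
  if (any(lengths(replicates$curves) < 2L))
    stop("need >= 2 replicates per rate to bootstrap", call. = FALSE)
  full <- fit_multirate(summarize_replicates(replicates), config)
  draws <- .with_seed(seed, {
    idx <- lapply(seq_len(n_boot), function(b)
      lapply(replicates$curves, function(group)
        sample.int(length(group), replace = TRUE)))
    t(vapply(seq_len(n_boot), function(b) {
      boot <- replicates
      boot$curves <- lapply(seq_along(boot$curves), function(j) {
        group <- replicates$curves[[j]][idx[[b]][[j]]]
        for (k in seq_along(group)) group[[k]]$replicate <- k
        group
      })
      fit_multirate(summarize_replicates(boot), config)$theta
    }, numeric(2 * config$n_ogden + 2 * config$n_prony)))
  })
  nm <- .theta_names(config)
  colnames(draws) <- nm
  a <- (1 - level) / 2
  out <- data.frame(parameter = nm, estimate = full$theta,
                    lower = apply(draws, 2, stats::quantile, probs = a),
                    upper = apply(draws, 2, stats::quantile, probs = 1 - a),
                    row.names = NULL)
  attr(out, "draws") <- draws
  out
}

.theta_names <- function(config) {
  m <- config$n_ogden; p <- config$n_prony
  c(sprintf("mu_%d", seq_len(m)), sprintf("alpha_%d", seq_len(m)),
    if (p) sprintf("g_%d", seq_len(p)),
    if (p) sprintf("beta_%d", seq_len(p)))
}
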