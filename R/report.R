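#' Material-table style parameter report
#'
#' Builds a delimited parameter table with one row per material or fit:
#' name, density, elastic constants, bulk modulus, Ogden terms, Prony
#' fractions and decay constants (`= 1/tau`, the convention of solver
#' material tables), and — for fitted rows — the per-curve minimum and
#' pooled R^2. Units follow the mixed convention of such tables: density
#' kg/m^3, moduli of stiff elastic components in GPa, Ogden `mu` in kPa,
#' decay constants in 1/s.
#'
#' @param x a named list whose elements are [material_model()]s and/or
#'   `fit_result`s (names label fit rows); an empty list yields a
#'   header-only table.
#' @param path optional output path; when given, the table is written as
#'   tab-delimited text (deterministic formatting, 9 significant digits).
#' @return A `data.frame`, invisibly when `path` is given.
#' @examples
#' report_parameter_table(preset_materials())
#' @export
report_parameter_table <- function(x, path = NULL) {
  if (inherits(x, "material_model") || inherits(x, "fit_result"))
    x <- list(x)
  stopifnot(is.list(x))
  n_og <- max(1L, vapply(x, function(e) {
    if (inherits(e, "fit_result")) length(e$ogden$mu)
    else if (!is.null(e$ogden)) length(e$ogden$mu) else 0L
  }, integer(1)))
  n_pr <- max(1L, vapply(x, function(e) {
    if (inherits(e, "fit_result")) length(e$prony$g)
    else if (!is.null(e$prony)) length(e$prony$g) else 0L
  }, integer(1)))
  pad <- function(v, n) c(v, rep(NA_real_, n - length(v)))
  rows <- lapply(seq_along(x), function(i) {
    e <- x[[i]]
    nm <- names(x)[i]
    if (inherits(e, "fit_result")) {
      og <- e$ogden; pr <- e$prony
      base <- data.frame(name = if (!is.null(nm) && nzchar(nm)) nm
                         else sprintf("fit_%d", i),
                         density_kg_m3 = NA_real_,
                         elastic_modulus_gpa = NA_real_,
                         poissons_ratio = NA_real_,
                         bulk_modulus_gpa = NA_real_)
      r2_min <- min(e$r_squared); r2_pool <- e$pooled_r_squared
    } else {
      stopifnot(inherits(e, "material_model"))
      og <- e$ogden; pr <- e$prony
      base <- data.frame(name = e$name, density_kg_m3 = e$density,
                         elastic_modulus_gpa = e$elastic_modulus %||%
                           NA_real_,
                         poissons_ratio = e$poisson_ratio %||% NA_real_,
                         bulk_modulus_gpa = e$bulk_modulus %||% NA_real_)
      r2_min <- r2_pool <- NA_real_
    }
    mu <- pad(if (is.null(og)) numeric(0) else og$mu, n_og)
    al <- pad(if (is.null(og)) numeric(0) else og$alpha, n_og)
    g <- pad(if (is.null(pr)) numeric(0) else pr$g, n_pr)
    dec <- pad(if (is.null(pr)) numeric(0) else 1 / pr$tau, n_pr)
    extra <- as.data.frame(as.list(c(
      stats::setNames(mu, sprintf("mu_%d_kpa", seq_len(n_og))),
      stats::setNames(al, sprintf("alpha_%d", seq_len(n_og))),
      stats::setNames(g, sprintf("g_%d", seq_len(n_pr))),
      stats::setNames(dec, sprintf("decay_%d_per_s", seq_len(n_pr))))))
    cbind(base, extra, data.frame(r_squared_min = r2_min,
                                  pooled_r_squared = r2_pool))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = 10)),
                    c("name", "density_kg_m3", "elastic_modulus_gpa",
                      "poissons_ratio", "bulk_modulus_gpa", "mu_1_kpa",
                      "alpha_1", "g_1", "decay_1_per_s", "r_squared_min"))
  if (!is.null(path)) {
    txt <- out
    for (cl in names(txt))
      if (is.numeric(txt[[cl]])) txt[[cl]] <- .fmt_num(txt[[cl]])
    utils::write.table(txt, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}
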