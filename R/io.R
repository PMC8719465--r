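#' Curve file dialects
#'
#' Two tab-delimited UTF-8 text formats with mandatory header row and `.`
#' decimal separator:
#' \describe{
#'   \item{`long`}{one row per observation:
#'     `curve_id, replicate_id, mode, rate_per_s, strain, stress_kpa`.}
#'   \item{`summary`}{one row per mean-curve point:
#'     `curve_id, mode, rate_per_s, strain, stress_mean_kpa,
#'     stress_sem_kpa, n` (`stress_sem_kpa` empty/NA when n = 1).}
#' }
#' Strain semantics follow the mode: engineering shear strain for
#' `simple_shear`, stretch for `uniaxial_tension`. Writers emit rows in a
#' deterministic order (curve_id, replicate_id, strain ascending) with
#' numbers at 9 significant digits, so rewrites of identical inputs are
#' byte-identical.
#'
#' @name curve_dialects
#' @keywords internal
NULL

.long_cols <- c("curve_id", "replicate_id", "mode", "rate_per_s",
                "strain", "stress_kpa")
.summary_cols <- c("curve_id", "mode", "rate_per_s", "strain",
                   "stress_mean_kpa", "stress_sem_kpa", "n")

.fmt_num <- function(x) {
  out <- formatC(x, digits = 9, format = "g")
  out[is.na(x)] <- ""
  trimws(out)
}

#' Write stress-strain curves to a delimited text file
#'
#' @param curves a `replicate_set` (dialect `"long"`) or a list of summary
#'   [stress_strain_curve()]s (dialect `"summary"`); an empty list writes a
#'   header-only summary file.
#' @param path output file path.
#' @param dialect `"long"` or `"summary"` (see [curve_dialects]).
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path, dialect = c("long", "summary")) {
  dialect <- match.arg(dialect)
  if (dialect == "long") {
    stopifnot(inherits(curves, "replicate_set"))
    rows <- do.call(rbind, unlist(lapply(seq_along(curves$rates),
                                         function(j) {
      lapply(curves$curves[[j]], function(cv) {
        data.frame(curve_id = cv$curve_id %||%
                     sprintf("%s_r%g", curves$mode, cv$rate),
                   replicate_id = cv$replicate,
                   mode = cv$mode, rate_per_s = cv$rate,
                   strain = cv$strain, stress_kpa = cv$stress,
                   stringsAsFactors = FALSE)
      })
    }), recursive = FALSE))
    rows <- rows[order(rows$curve_id, rows$replicate_id, rows$strain), ]
    body <- sprintf("%s\t%s\t%s\t%s\t%s\t%s", rows$curve_id,
                    rows$replicate_id, rows$mode, .fmt_num(rows$rate_per_s),
                    .fmt_num(rows$strain), .fmt_num(rows$stress_kpa))
    lines <- c(paste(.long_cols, collapse = "\t"), body)
  } else {
    if (inherits(curves, "stress_strain_curve")) curves <- list(curves)
    stopifnot(is.list(curves))
    rows <- do.call(rbind, lapply(curves, function(cv) {
      stopifnot(inherits(cv, "stress_strain_curve"))
      data.frame(curve_id = cv$curve_id %||%
                   sprintf("%s_r%g", cv$mode, cv$rate),
                 mode = cv$mode, rate_per_s = cv$rate, strain = cv$strain,
                 stress_mean_kpa = cv$stress,
                 stress_sem_kpa = if (is.null(cv$sem)) NA_real_ else cv$sem,
                 n = if (is.null(cv$n)) 1L else cv$n,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(rows)) {
      lines <- paste(.summary_cols, collapse = "\t")
    } else {
      rows <- rows[order(rows$curve_id, rows$strain), ]
      body <- sprintf("%s\t%s\t%s\t%s\t%s\t%s\t%d", rows$curve_id,
                      rows$mode, .fmt_num(rows$rate_per_s),
                      .fmt_num(rows$strain), .fmt_num(rows$stress_mean_kpa),
                      .fmt_num(rows$stress_sem_kpa), rows$n)
      lines <- c(paste(.summary_cols, collapse = "\t"), body)
    }
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.read_table <- function(path, cols, dialect) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s dialect: missing column(s): %s", dialect,
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (nrow(df) == 0L)
    stop("file contains a header but no data rows: ", path, call. = FALSE)
  df
}

.parse_numeric_col <- function(df, col, allow_na = FALSE) {
  x <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(is.na(x) & (!allow_na | nzchar(trimws(df[[col]]))))
  if (length(bad))
    stop(sprintf("column '%s': non-numeric value(s) at data line(s) %s",
                 col, paste(utils::head(bad + 1L, 5), collapse = ", ")),
         call. = FALSE)
  x
}

#' Read stress-strain curves from a delimited text file
#'
#' Validates the header against the dialect and each row's content;
#' malformed rows are reported with their line numbers (header = line 1).
#'
#' @param path input file path.
#' @param dialect `"long"` or `"summary"` (see [curve_dialects]).
#' @return For `"long"`: a `replicate_set` (without generating truth).
#'   For `"summary"`: a list of summary [stress_strain_curve()]s.
#' @export
read_curves <- function(path, dialect = c("long", "summary")) {
  dialect <- match.arg(dialect)
  if (dialect == "long") {
    df <- .read_table(path, .long_cols, "long")
    df$rate_per_s <- .parse_numeric_col(df, "rate_per_s")
    df$strain <- .parse_numeric_col(df, "strain")
    df$stress_kpa <- .parse_numeric_col(df, "stress_kpa")
    .validate_rows(df)
    mode <- unique(df$mode)
    if (length(mode) != 1L)
      stop("long files must contain a single deformation mode; found: ",
           paste(mode, collapse = ", "), call. = FALSE)
    rates <- sort(unique(df$rate_per_s))
    curves <- lapply(rates, function(r) {
      sub <- df[df$rate_per_s == r, ]
      reps <- split(sub, list(sub$curve_id, sub$replicate_id), drop = TRUE)
      lapply(seq_along(reps), function(k) {
        rk <- reps[[k]][order(reps[[k]]$strain), ]
        if (anyDuplicated(rk$strain))
          stop(sprintf("replicate '%s/%s': non-monotone (duplicated) strain",
                       rk$curve_id[1], rk$replicate_id[1]), call. = FALSE)
        stress_strain_curve(mode, r, rk$strain, rk$stress_kpa,
                            replicate = rk$replicate_id[1],
                            curve_id = rk$curve_id[1])
      })
    })
    n <- unique(lengths(curves))
    design <- experiment_design(mode, rates, max(lengths(curves)),
                                max(df$strain),
                                n_points = length(curves[[1]][[1]]$strain))
    structure(list(mode = mode, rates = rates, curves = curves,
                   truth = NULL, material = NULL, design = design,
                   noise = NULL),
              class = "replicate_set")
  } else {
    df <- .read_table(path, .summary_cols, "summary")
    df$rate_per_s <- .parse_numeric_col(df, "rate_per_s")
    df$strain <- .parse_numeric_col(df, "strain")
    df$stress_mean_kpa <- .parse_numeric_col(df, "stress_mean_kpa")
    df$stress_sem_kpa <- .parse_numeric_col(df, "stress_sem_kpa",
                                            allow_na = TRUE)
    df$n <- .parse_numeric_col(df, "n")
    names(df)[names(df) == "stress_mean_kpa"] <- "stress_kpa"
    .validate_rows(df)
    groups <- split(df, df$curve_id)
    lapply(groups, function(g) {
      g <- g[order(g$strain), ]
      n <- unique(g$n)
      if (length(n) != 1L)
        stop(sprintf("curve '%s': inconsistent n", g$curve_id[1]),
             call. = FALSE)
      has_sem <- !all(is.na(g$stress_sem_kpa))
      stress_strain_curve(g$mode[1], g$rate_per_s[1], g$strain, g$stress_kpa,
                          sem = if (has_sem) g$stress_sem_kpa else NULL,
                          n = n, curve_id = g$curve_id[1])
    })
  }
}

.validate_rows <- function(df) {
  bad_mode <- which(!(df$mode %in% .modes))
  if (length(bad_mode))
    stop("invalid mode at data line(s) ",
         paste(utils::head(bad_mode + 1L, 5), collapse = ", "),
         call. = FALSE)
  bad_rate <- which(df$rate_per_s <= 0)
  if (length(bad_rate))
    stop("non-positive rate at data line(s) ",
         paste(utils::head(bad_rate + 1L, 5), collapse = ", "),
         call. = FALSE)
  invisible(df)
}
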