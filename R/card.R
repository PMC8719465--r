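#' Export a material as a generic FE material card
#'
#' Renders one material as a solver-style keyword text block. The dialect
#' is a documented generic one (not claimed byte-compatible with any
#' commercial solver): hyperelastic lines carry
#' `(mu_i [Pa], alpha_i, 0)` — the trailing 0 is the incompressibility
#' placeholder — and viscoelastic lines carry `(g_i, 0, tau_i [s])`.
#' Curve-level quantities in this package are in kPa; cards are SI (Pa),
#' and the conversion is recorded in the card comments. Materials without
#' Ogden terms but with linear-elastic metadata export as an `*ELASTIC`
#' card instead. Numeric fields are written at 6 significant digits and
#' round-trip exactly through [parse_material_card()].
#'
#' @param material a [material_model()].
#' @param dialect only `"generic_fe"` is defined.
#' @return A single character string (the card text).
#' @examples
#' cat(export_material_card(preset_materials()$cerebrum))
#' @export
export_material_card <- function(material, dialect = "generic_fe") {
  stopifnot(inherits(material, "material_model"))
  if (!identical(dialect, "generic_fe"))
    stop("unknown card dialect: ", dialect, call. = FALSE)
  f <- function(x) trimws(formatC(x, digits = 6, format = "g"))
  lines <- c(
    "** generic FE material card",
    paste0("** ogden convention: W = sum_i 2*mu_i/alpha_i^2 ",
           "(l1^a_i + l2^a_i + l3^a_i - 3)"),
    "** units: SI (kg/m^3, Pa, s); curve-level kPa converted to Pa",
    sprintf("*MATERIAL, NAME=%s", material$name),
    "*DENSITY",
    f(material$density))
  if (!is.null(material$bulk_modulus))
    lines <- c(lines, sprintf("** bulk_modulus_pa: %s",
                              f(material$bulk_modulus * 1e9)))
  if (!is.null(material$ogden)) {
    og <- material$ogden
    lines <- c(lines,
               sprintf("*HYPERELASTIC, OGDEN, N=%d", length(og$mu)),
               sprintf("%s, %s, 0", f(og$mu * 1e3), f(og$alpha)))
    if (!is.null(material$prony) && length(material$prony$g) > 0L) {
      pr <- material$prony
      lines <- c(lines, "*VISCOELASTIC, PRONY",
                 sprintf("%s, 0, %s", f(pr$g), f(pr$tau)))
    }
  } else if (!is.null(material$elastic_modulus)) {
    lines <- c(lines, "*ELASTIC",
               sprintf("%s, %s", f(material$elastic_modulus * 1e9),
                       f(material$poisson_ratio)))
  } else {
    stop(sprintf("material '%s' has neither Ogden terms nor elastic metadata",
                 material$name), call. = FALSE)
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Parse a generic FE material card
#'
#' Inverse of [export_material_card()]: reads the keyword block back into a
#' [material_model()]. `parse_material_card(export_material_card(x))`
#' reproduces every numeric field of `x` at the card's 6-significant-digit
#' precision.
#'
#' @param text card text (single string or character vector of lines).
#' @param dialect only `"generic_fe"`.
#' @return A [material_model()].
#' @export
parse_material_card <- function(text, dialect = "generic_fe") {
  if (!identical(dialect, "generic_fe"))
    stop("unknown card dialect: ", dialect, call. = FALSE)
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  bulk <- NULL
  bm <- grep("^\\*\\* bulk_modulus_pa:", lines, value = TRUE)
  if (length(bm))
    bulk <- as.numeric(sub("^\\*\\* bulk_modulus_pa:\\s*", "", bm[1])) / 1e9
  lines <- lines[!startsWith(lines, "**")]
  kw <- grep("^\\*", lines)
  get_block <- function(pattern) {
    i <- grep(pattern, lines[kw])
    if (!length(i)) return(NULL)
    from <- kw[i[1]] + 1L
    to <- if (any(kw > kw[i[1]])) min(kw[kw > kw[i[1]]]) - 1L
    else length(lines)
    lines[seq(from, to)]
  }
  mat_line <- grep("^\\*MATERIAL", lines, value = TRUE)
  if (!length(mat_line)) stop("not a material card: no *MATERIAL line",
                              call. = FALSE)
  name <- sub("^\\*MATERIAL,\\s*NAME=", "", mat_line[1])
  nums <- function(block) lapply(strsplit(block, ","), as.numeric)
  dens <- nums(get_block("^\\*DENSITY"))[[1]][1]
  hyper <- get_block("^\\*HYPERELASTIC")
  visco <- get_block("^\\*VISCOELASTIC")
  elast <- get_block("^\\*ELASTIC")
  og <- pr <- NULL; e_mod <- nu <- NULL
  if (!is.null(hyper)) {
    rows <- do.call(rbind, nums(hyper))
    og <- ogden_parameters(rows[, 1] / 1e3, rows[, 2])
    if (!is.null(visco)) {
      rows <- do.call(rbind, nums(visco))
      pr <- prony_series(rows[, 1], tau = rows[, 3])
    }
  } else if (!is.null(elast)) {
    row <- nums(elast)[[1]]
    e_mod <- row[1] / 1e9; nu <- row[2]
  }
  material_model(name, dens, bulk_modulus = bulk, ogden = og, prony = pr,
                 elastic_modulus = e_mod, poisson_ratio = nu)
}
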