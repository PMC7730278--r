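# alamarBlue (resazurin) molar extinction coefficients, L/(mol cm):
# oxidized and reduced forms at the two read wavelengths.
EXT_OX_570 <- 80586
EXT_OX_600 <- 117216
EXT_RED_570 <- 155677
EXT_RED_600 <- 14652

# Effective dye concentration x path length (mol/L * cm) and the fraction of
# dye reduced by an untreated (100% viable) control well after incubation.
DYE_CONC_PATH <- 1e-5
CONTROL_REDUCTION <- 0.6

#' Four-parameter logistic viability curve
#'
#' Percent viability as a function of drug concentration with asymptotes
#' fixed at 100 (no drug) and 0 (full kill): `100 / (1 + (conc/ic50)^hill)`.
#' By construction the curve passes through 50% at `ic50`.
#'
#' @param conc Concentration vector (same unit as `ic50`).
#' @param ic50 Midpoint concentration.
#' @param hill Hill slope (> 0).
#' @return Percent viability in (0, 100).
#' @export
#' @examples
#' viability_logistic(c(0, 4.62, 1e6), 4.62, 1)
viability_logistic <- function(conc, ic50, hill = 1) {
  100 / (1 + (conc / ic50)^hill)
}

#' Simulate a 96-well cytotoxicity plate
#'
#' Emulates the alamarBlue assay layout: columns 1 and 12 are cell-free
#' blanks, columns 2 and 11 drug-free growth controls, and columns 3-10
#' carry the line's 8-point concentration series, each concentration in 4
#' wells (rows A-D; rows E-H of the seeded columns stay cell-free). True
#' viability follows the 4-parameter logistic through the configured IC50;
#' additive Gaussian noise (`cfg$plate_noise_sd`, truncated to \[-5, 120\])
#' acts on the viability scale, and well absorbances at 570/600 nm are
#' produced from the oxidised/reduced dye mixture so that the two-wavelength
#' percent-reduction calculation recovers the underlying viability.
#'
#' @param cfg A [sim_config()].
#' @param cell_line,drug Identify the true curve; unknown combinations are a
#'   configuration error.
#' @param plate_id Integer replicate plate number (distinct noise stream).
#' @return An object of class `ablue_plate`: list with 8x12 matrices `a570`
#'   and `a600`, a `layout` data frame (`row`, `col`, `role`, `conc`), and
#'   fields `cell_line`, `drug`, `unit`, `plate_id`.
#' @seealso [percent_viability()] to convert a plate into a viability curve.
#' @export
#' @examples
#' cfg <- sim_config(seed = 7)
#' p <- simulate_plate(cfg, "A2780", "PTX")
#' round(p$a570[1:2, 1:4], 3)
simulate_plate <- function(cfg, cell_line, drug, plate_id = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  tr <- cfg_ic50(cfg, cell_line, drug)
  set.seed(derive_seed(cfg$seed,
                       paste("plate", cell_line, drug, plate_id)))

  rows <- LETTERS[1:8]
  layout <- expand.grid(row = rows, col = 1:12, stringsAsFactors = FALSE)
  layout$role <- "blank"
  seeded <- layout$row %in% rows[1:4] & layout$col %in% 2:11
  layout$role[seeded & layout$col %in% c(2, 11)] <- "control"
  layout$role[seeded & layout$col %in% 3:10] <- "treated"
  layout$conc <- NA_real_
  layout$conc[layout$role == "treated"] <- tr$grid[layout$col[
    layout$role == "treated"] - 2L]

  true_v <- rep(NA_real_, nrow(layout))
  true_v[layout$role == "control"] <- 100
  tw <- layout$role == "treated"
  true_v[tw] <- viability_logistic(layout$conc[tw], tr$ic50, cfg$hill_slope)
  noisy <- true_v
  has_cells <- !is.na(true_v)
  if (cfg$plate_noise_sd > 0) {
    noisy[has_cells] <- true_v[has_cells] +
      rnorm(sum(has_cells), sd = cfg$plate_noise_sd)
    noisy[has_cells] <- pmin(pmax(noisy[has_cells], -5), 120)
  }

  # fraction of dye reduced: blanks 0, cell wells proportional to viability
  frac <- ifelse(has_cells, CONTROL_REDUCTION * noisy / 100, 0)
  a570 <- DYE_CONC_PATH * ((1 - frac) * EXT_OX_570 + frac * EXT_RED_570)
  a600 <- DYE_CONC_PATH * ((1 - frac) * EXT_OX_600 + frac * EXT_RED_600)

  shape <- function(v) matrix(v, nrow = 8, ncol = 12,
                              dimnames = list(rows, 1:12))
  structure(list(a570 = shape(a570), a600 = shape(a600), layout = layout,
                 cell_line = cell_line, drug = drug, unit = tr$unit,
                 plate_id = as.integer(plate_id)),
            class = "ablue_plate")
}

#' @export
print.ablue_plate <- function(x, ...) {
  cat("alamarBlue plate:", x$cell_line, "/", x$drug, "(plate", x$plate_id,
      ")\n")
  concs <- sort(unique(x$layout$conc[!is.na(x$layout$conc)]))
  cat("  concentrations (", x$unit, "): ",
      paste(signif(concs, 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}
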