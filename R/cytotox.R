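#' Construct a viability curve
#'
#' Per cell line and drug: an ordered set of (concentration, mean %
#' viability, SD, n) summary points, the basic container of the
#' cytotoxicity analysis.
#'
#' @param cell_line,drug Identifiers.
#' @param conc Strictly increasing positive concentrations.
#' @param mean_viab Mean percent viability per concentration.
#' @param sd,n Optional per-point SD and well count (n >= 1).
#' @param unit Concentration unit, one of `"nM"`, `"uM"`, `"M"`.
#' @return A `viability_curve`: data frame (`conc`, `mean_viab`, `sd`, `n`)
#'   with attributes `cell_line`, `drug`, `unit`.
#' @export
#' @examples
#' viability_curve("A2780", "PTX", c(1, 3), c(60, 40), unit = "nM")
viability_curve <- function(cell_line, drug, conc, mean_viab, sd = NA_real_,
                            n = 1L, unit = c("nM", "uM", "M")) {
  unit <- match.arg(unit)
  if (anyDuplicated(conc))
    stop("duplicate concentrations in viability curve", call. = FALSE)
  o <- order(conc)
  conc <- conc[o]
  mean_viab <- mean_viab[o]
  sd <- rep_len(sd, length(conc))[o]
  n <- rep_len(n, length(conc))[o]
  if (any(conc <= 0)) stop("concentrations must be positive", call. = FALSE)
  if (any(n < 1)) stop("each point needs n >= 1 wells", call. = FALSE)
  structure(data.frame(conc = conc, mean_viab = mean_viab, sd = sd, n = n),
            cell_line = cell_line, drug = drug, unit = unit,
            class = c("viability_curve", "data.frame"))
}

#' Percent viability from plate absorbances
#'
#' Converts raw two-wavelength alamarBlue absorbances into a viability
#' curve. Percent dye reduction per well follows the standard
#' two-wavelength formula
#' `(eox600*A570 - eox570*A600) / (ered570*A600' - ered600*A570') * 100`,
#' where primed absorbances come from the cell-free blank wells (negative
#' control) and the extinction coefficients are the published values for
#' oxidised (80586 at 570 nm, 117216 at 600 nm) and reduced (155677, 14652)
#' dye. Percent viability is then `100 * reduction_treated /
#' mean(reduction_control)`, with drug-free control wells defining 100%.
#'
#' @param plate An `ablue_plate` (from [simulate_plate()] or
#'   [read_plate()]).
#' @return A [viability_curve()] with one point per distinct concentration
#'   (mean, SD and well count over that concentration's wells).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, plate_noise_sd = 0)
#' percent_viability(simulate_plate(cfg, "A2780", "PTX"))
percent_viability <- function(plate) {
  stopifnot(inherits(plate, "ablue_plate"))
  lay <- plate$layout
  a570 <- as.vector(plate$a570)
  a600 <- as.vector(plate$a600)

  blank <- lay$role == "blank"
  ctrl <- lay$role == "control"
  trt <- lay$role == "treated"
  if (!any(blank) || !any(ctrl) || !any(trt))
    stop("plate must contain blank, control and treated wells",
         call. = FALSE)

  denom <- mean(EXT_RED_570 * a600[blank] - EXT_RED_600 * a570[blank])
  reduction <- (EXT_OX_600 * a570 - EXT_OX_570 * a600) / denom * 100
  ctrl_red <- mean(reduction[ctrl])
  blank_red <- mean(reduction[blank])
  if (!is.finite(ctrl_red) || ctrl_red <= blank_red)
    stop("degenerate plate: control signal does not exceed blank signal",
         call. = FALSE)

  viab <- reduction / ctrl_red * 100
  concs <- sort(unique(lay$conc[trt]))
  pts <- t(vapply(concs, function(cc) {
    v <- viab[trt & lay$conc == cc]
    c(mean(v), sd(v), length(v))
  }, numeric(3)))
  viability_curve(plate$cell_line, plate$drug, conc = concs,
                  mean_viab = pts[, 1], sd = pts[, 2], n = pts[, 3],
                  unit = plate$unit)
}

#' Concentrations at selected viability levels
#'
#' For each requested viability level, scans the curve's segments from the
#' lowest concentration and linearly interpolates the first bracketing
#' segment: `x = x1 + (x2 - x1) * (y - y1) / (y2 - y1)`. If a level equals
#' an observed mean viability, that observed concentration is returned
#' exactly. A level bracketed by more than one segment triggers a
#' multi-crossing warning (the first crossing is used). Levels outside the
#' observed range yield `NA` unless `extrapolate = TRUE`, which extends the
#' terminal segment.
#'
#' @param curve A [viability_curve()] with >= 2 points.
#' @param levels Viability levels (%), default the standard 90 down to 20.
#' @param extrapolate Permit extension of the first/last segment.
#' @return A `viability_grid`: data frame (`level`, `conc`) with the curve's
#'   identity attributes.
#' @export
#' @examples
#' cv <- viability_curve("A2780", "PTX", c(1, 3), c(60, 40), unit = "nM")
#' viability_grid(cv, levels = 50) # 2 nM
viability_grid <- function(curve, levels = seq(90, 20, by = -10),
                           extrapolate = FALSE) {
  stopifnot(inherits(curve, "viability_curve"))
  if (nrow(curve) < 2)
    stop("viability curve needs at least 2 points", call. = FALSE)
  x <- curve$conc
  y <- curve$mean_viab

  conc_at <- vapply(levels, function(lev) {
    hits <- which((y[-length(y)] - lev) * (y[-1] - lev) <= 0)
    if (length(hits) == 0) {
      if (!extrapolate) return(NA_real_)
      # extend the terminal segment nearer to the requested level
      i <- if (abs(y[1] - lev) <= abs(y[length(y)] - lev)) 1L
           else length(y) - 1L
      hits <- i
    } else if (length(hits) > 1) {
      # distinct crossings: sign changes of (y - level), zeros dropped
      s <- sign(y - lev)
      s <- s[s != 0]
      if (sum(diff(s) != 0) > 1)
        warning("level ", lev, "% crossed more than once; using the first ",
                "crossing", call. = FALSE)
    }
    i <- hits[1]
    if (y[i] == lev) return(x[i])
    if (y[i + 1] == y[i]) return(x[i])
    x[i] + (x[i + 1] - x[i]) * (lev - y[i]) / (y[i + 1] - y[i])
  }, numeric(1))

  structure(data.frame(level = levels, conc = conc_at),
            cell_line = attr(curve, "cell_line"), drug = attr(curve, "drug"),
            unit = attr(curve, "unit"),
            class = c("viability_grid", "data.frame"))
}

#' Interpolated IC50 of a viability curve
#'
#' The 50% entry of [viability_grid()]: the drug concentration at which the
#' piecewise-linear viability curve crosses 50%. Errors if 50% is never
#' bracketed (unless `extrapolate = TRUE`).
#'
#' @inheritParams viability_grid
#' @return A single concentration, with the curve's `unit` attribute.
#' @export
#' @examples
#' ic50(viability_curve("A2780", "PTX", c(1, 3), c(60, 40), unit = "nM"))
ic50 <- function(curve, extrapolate = FALSE) {
  g <- viability_grid(curve, levels = 50, extrapolate = extrapolate)
  if (is.na(g$conc))
    stop("50% viability is never bracketed by the curve ",
         "(use extrapolate = TRUE to extend the terminal segment)",
         call. = FALSE)
  structure(g$conc, unit = attr(curve, "unit"))
}

#' pIC50: negative log10 molar IC50
#'
#' @param ic50 Positive concentration (scalar or vector).
#' @param unit Concentration unit of `ic50`; taken from its `unit` attribute
#'   when present.
#' @return `-log10` of the molar concentration.
#' @export
#' @examples
#' pic50(1, "uM")    # 6
#' pic50(4.62, "nM") # 8.3354
pic50 <- function(ic50, unit = attr(ic50, "unit")) {
  if (is.null(unit)) stop("concentration unit is required", call. = FALSE)
  unit <- match.arg(unit, c("nM", "uM", "M"))
  if (any(!is.finite(ic50)) || any(ic50 <= 0))
    stop("IC50 must be positive and finite", call. = FALSE)
  molar <- unname(ic50) * switch(unit, nM = 1e-9, uM = 1e-6, M = 1)
  -log10(molar)
}

#' Resistance and sensitivity indices
#'
#' `resistance_index()` is the ratio subline IC50 / reference IC50 for the
#' selecting drug (values > 1 mean acquired resistance);
#' `sensitivity_index()` is reference IC50 / subline IC50 for the bystander
#' drug (values > 1 mean collateral sensitisation). Both inputs must share
#' one unit. Reported values are conventionally rounded to 2 decimals, half
#' away from zero; pass `digits` to apply that here.
#'
#' @param ic50_sub,ic50_ref Positive IC50s of the subline and the reference
#'   (parental) line, same unit.
#' @param digits Optional rounding digits (half away from zero).
#' @return The index as a plain number.
#' @export
#' @examples
#' resistance_index(77.54, 4.62, digits = 2) # 16.78
#' sensitivity_index(0.65, 4.58, digits = 2) # 7.05
resistance_index <- function(ic50_sub, ic50_ref, digits = NULL) {
  check_same_unit(ic50_sub, ic50_ref)
  stopifnot(ic50_sub > 0, ic50_ref > 0)
  out <- unname(ic50_sub) / unname(ic50_ref)
  if (!is.null(digits)) out <- round_away(out, digits)
  out
}

#' @rdname resistance_index
#' @export
sensitivity_index <- function(ic50_sub, ic50_ref, digits = NULL) {
  check_same_unit(ic50_sub, ic50_ref)
  stopifnot(ic50_sub > 0, ic50_ref > 0)
  out <- unname(ic50_ref) / unname(ic50_sub)
  if (!is.null(digits)) out <- round_away(out, digits)
  out
}

check_same_unit <- function(a, b) {
  ua <- attr(a, "unit"); ub <- attr(b, "unit")
  if (!is.null(ua) && !is.null(ub) && ua != ub)
    stop("IC50 unit mismatch: '", ua, "' vs '", ub, "'", call. = FALSE)
  invisible(NULL)
}

#' Resistance/sensitivity profile of a cell-line series
#'
#' Summarises a named vector of IC50s against a reference line: IC50, pIC50
#' and the index (RI = subline/reference for the selecting drug; SI =
#' reference/subline for the bystander drug). The reference's own index is
#' 1 by construction.
#'
#' @param ic50s Named positive IC50s, in series order.
#' @param reference Name of the reference (parental) line; must be present.
#' @param drug Drug label carried into the output.
#' @param unit Concentration unit of `ic50s`.
#' @param kind `"RI"` (resistance, selecting drug) or `"SI"` (sensitivity,
#'   bystander drug).
#' @param digits Rounding (half away from zero) applied to the index column;
#'   `NULL` for unrounded.
#' @return A `resistance_profile`: data frame with columns `cell_line`,
#'   `drug`, `ic50`, `pic50`, `index`, `index_kind`.
#' @export
#' @examples
#' ptx <- c(A2780 = 4.62, `A/16PTX` = 77.54)
#' resistance_profile(ptx, "A2780", "PTX", "nM", kind = "RI")
resistance_profile <- function(ic50s, reference, drug, unit,
                               kind = c("RI", "SI"), digits = 2) {
  kind <- match.arg(kind)
  if (is.null(names(ic50s)) || !reference %in% names(ic50s))
    stop("'ic50s' must be named and include the reference line",
         call. = FALSE)
  if (any(ic50s <= 0)) stop("IC50 values must be positive", call. = FALSE)
  ref <- ic50s[[reference]]
  idx <- if (kind == "RI") unname(ic50s) / ref else ref / unname(ic50s)
  if (!is.null(digits)) idx <- round_away(idx, digits)
  structure(data.frame(cell_line = names(ic50s), drug = drug,
                       ic50 = unname(ic50s),
                       pic50 = pic50(unname(ic50s), unit),
                       index = idx, index_kind = kind,
                       stringsAsFactors = FALSE),
            reference = reference, unit = unit,
            class = c("resistance_profile", "data.frame"))
}

#' Fold change between consecutive lines of the series
#'
#' One row per consecutive (parent, child) pair of the derivation series.
#' For the selecting drug (`kind = "RI"`) the fold is child IC50 / parent
#' IC50; for the bystander drug (`kind = "SI"`) it is parent IC50 / child
#' IC50. The product of the unrounded folds telescopes exactly to the
#' end-to-end index of the last line versus the first.
#'
#' @param ic50s Named positive IC50s in derivation order (>= 2).
#' @param kind `"RI"` or `"SI"`.
#' @param digits Rounding for the reported `fold` column.
#' @return Data frame (`parent`, `child`, `fold_unrounded`, `fold`) with an
#'   `end_to_end` attribute holding the unrounded overall index.
#' @export
#' @examples
#' fold_change_consecutive(c(A2780 = 4.62, `A/4PTX` = 11.47,
#'                           `A/8PTX` = 18.71), kind = "RI")
fold_change_consecutive <- function(ic50s, kind = c("RI", "SI"), digits = 2) {
  kind <- match.arg(kind)
  if (length(ic50s) < 2)
    stop("need at least 2 profiles to form consecutive pairs", call. = FALSE)
  if (any(ic50s <= 0)) stop("IC50 values must be positive", call. = FALSE)
  if (is.null(names(ic50s))) names(ic50s) <- seq_along(ic50s)
  k <- length(ic50s)
  parent <- ic50s[-k]
  child <- ic50s[-1]
  fold <- if (kind == "RI") unname(child) / unname(parent)
          else unname(parent) / unname(child)
  structure(data.frame(parent = names(parent), child = names(child),
                       fold_unrounded = fold,
                       fold = round_away(fold, digits),
                       stringsAsFactors = FALSE),
            kind = kind, end_to_end = prod(fold),
            class = c("fold_change_table", "data.frame"))
}
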