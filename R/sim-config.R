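#' Reference IC50 table for the A2780 paclitaxel-selection series
#'
#' Measured 120-h IC50 values for the parental A2780 ovarian cancer line and
#' six sublines selected by stepwise paclitaxel (PTX) escalation, for both
#' the selecting drug (PTX, nM) and the bystander drug cisplatin (CDDP, uM).
#' These values define the default true dose-response curves of the plate
#' simulator.
#'
#' @return A data frame with columns `cell_line`, `drug`, `ic50`, `unit`.
#' @export
#' @examples
#' default_ic50_table()
default_ic50_table <- function() {
  lines <- c("A2780", "A/4PTX", "A/8PTX", "A/16PTX", "A/32PTX", "A/64PTX",
             "A/128PTX")
  rbind(
    data.frame(cell_line = lines, drug = "PTX",
               ic50 = c(4.62, 11.47, 18.71, 77.54, 148.47, 173.86, 272.47),
               unit = "nM", stringsAsFactors = FALSE),
    data.frame(cell_line = lines, drug = "CDDP",
               ic50 = c(4.58, 4.27, 2.12, 0.65, 0.44, 0.40, 0.83),
               unit = "uM", stringsAsFactors = FALSE)
  )
}

#' Trend-pattern class labels
#'
#' The five kinetic classes used throughout the package, plus `"null"` for
#' genes simulated without any planted effect.
#' @return Character vector of class names.
#' @export
trend_classes <- function() {
  c("consistently_up", "rising", "variable", "descending",
    "consistently_down")
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generators: the cell-line
#' series, true dose-response curves for the plate simulator, and the
#' negative-binomial count model with planted five-pattern trend structure.
#' Defaults emulate the study conditions of the modelled series: 7 lines x 2
#' replicates, a 4-parameter-logistic viability curve through each line's
#' measured IC50, and per-line 8-point concentration grids.
#'
#' @param seed Integer seed; all generators derive their RNG streams from it.
#' @param n_lines Number of cell lines (parent first), default 7.
#' @param n_reps RNA-seq replicates per line (>= 2), default 2.
#' @param n_genes Number of simulated genes.
#' @param pattern_props Named fractions over
#'   `c(trend_classes(), "null")` summing to 1; proportions of genes planted
#'   with each expression pattern across the ordered contrasts.
#' @param effect_log2fc Planted absolute log2 fold change at full effect.
#' @param dispersion Negative-binomial dispersion (1/size).
#' @param lib_size_mean Mean library size (reads per sample).
#' @param true_ic50 Data frame (`cell_line`, `drug`, `ic50`, `unit`) of true
#'   IC50s for the plate simulator; default [default_ic50_table()].
#' @param hill_slope Hill slope of the 4-parameter logistic viability curve.
#' @param plate_noise_sd SD of additive Gaussian well noise, in % viability
#'   units; noise is truncated to \[-5, 120\].
#' @param conc_grid Optional named list (`"line|drug"`) of 8 strictly
#'   increasing concentrations; default is a geometric grid spanning
#'   IC50/10 to 10*IC50 for each line/drug, mirroring per-line serial
#'   dilutions chosen to bracket the whole 90-20% viability range.
#' @param line_names Optional cell-line names (length `n_lines`).
#' @return An object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 500)
#' cfg$pattern_props
sim_config <- function(seed = 1L,
                       n_lines = 7L,
                       n_reps = 2L,
                       n_genes = 11588L,
                       pattern_props = c(consistently_up = 0.06,
                                         rising = 0.09,
                                         variable = 0.04,
                                         descending = 0.05,
                                         consistently_down = 0.06,
                                         null = 0.70),
                       effect_log2fc = 3,
                       dispersion = 0.05,
                       lib_size_mean = 2e7,
                       true_ic50 = default_ic50_table(),
                       hill_slope = 1,
                       plate_noise_sd = 3,
                       conc_grid = NULL,
                       line_names = NULL) {
  if (length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite integer", call. = FALSE)
  if (n_lines < 3L)
    stop("'n_lines' must be >= 3 (one parent plus >= 2 sublines)",
         call. = FALSE)
  if (n_reps < 2L)
    stop("'n_reps' must be >= 2", call. = FALSE)
  wanted <- c(trend_classes(), "null")
  if (!setequal(names(pattern_props), wanted))
    stop("'pattern_props' must be named exactly: ",
         paste(wanted, collapse = ", "), call. = FALSE)
  pattern_props <- pattern_props[wanted]
  if (any(pattern_props < 0) || abs(sum(pattern_props) - 1) > 1e-9)
    stop("'pattern_props' must be nonnegative and sum to 1 (+/- 1e-9)",
         call. = FALSE)
  if (effect_log2fc <= 0) stop("'effect_log2fc' must be > 0", call. = FALSE)
  if (dispersion <= 0) stop("'dispersion' must be > 0", call. = FALSE)
  if (lib_size_mean <= 0) stop("'lib_size_mean' must be > 0", call. = FALSE)
  if (hill_slope <= 0) stop("'hill_slope' must be > 0", call. = FALSE)
  if (plate_noise_sd < 0) stop("'plate_noise_sd' must be >= 0", call. = FALSE)
  stopifnot(is.data.frame(true_ic50),
            all(c("cell_line", "drug", "ic50", "unit") %in%
                  colnames(true_ic50)))
  if (any(true_ic50$ic50 <= 0))
    stop("all true IC50 values must be positive", call. = FALSE)

  if (is.null(line_names)) {
    defaults <- unique(default_ic50_table()$cell_line)
    line_names <- if (n_lines <= length(defaults)) defaults[seq_len(n_lines)]
                  else c("A2780", paste0("L", seq_len(n_lines - 1L)))
  }
  if (length(line_names) != n_lines)
    stop("'line_names' must have length n_lines", call. = FALSE)

  if (is.null(conc_grid)) {
    conc_grid <- lapply(seq_len(nrow(true_ic50)), function(i)
      true_ic50$ic50[i] * 10^seq(-1, 1, length.out = 8))
    names(conc_grid) <- paste(true_ic50$cell_line, true_ic50$drug, sep = "|")
  }
  for (g in conc_grid) {
    if (length(g) != 8L || any(g <= 0) || any(diff(g) <= 0))
      stop("each concentration grid must hold 8 strictly increasing ",
           "positive concentrations", call. = FALSE)
  }

  structure(list(seed = as.integer(seed), n_lines = as.integer(n_lines),
                 n_reps = as.integer(n_reps), n_genes = as.integer(n_genes),
                 pattern_props = pattern_props,
                 effect_log2fc = effect_log2fc, dispersion = dispersion,
                 lib_size_mean = lib_size_mean, true_ic50 = true_ic50,
                 hill_slope = hill_slope, plate_noise_sd = plate_noise_sd,
                 conc_grid = conc_grid, line_names = line_names),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration (seed ", x$seed, ")\n", sep = "")
  cat("  lines:", paste(x$line_names, collapse = ", "), "\n")
  cat("  counts:", x$n_genes, "genes x", x$n_lines * x$n_reps, "samples;",
      "effect |log2FC| =", x$effect_log2fc, "; dispersion =", x$dispersion,
      "\n")
  cat("  pattern proportions:",
      paste(names(x$pattern_props), signif(x$pattern_props, 3),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# Look up a true IC50 (and its unit/grid); unknown line/drug is a
# configuration error.
cfg_ic50 <- function(cfg, cell_line, drug) {
  i <- which(cfg$true_ic50$cell_line == cell_line & cfg$true_ic50$drug == drug)
  if (length(i) != 1L)
    stop("no true IC50 configured for line '", cell_line, "' and drug '",
         drug, "'", call. = FALSE)
  key <- paste(cell_line, drug, sep = "|")
  grid <- cfg$conc_grid[[key]]
  if (is.null(grid))
    stop("no concentration grid configured for '", key, "'", call. = FALSE)
  list(ic50 = cfg$true_ic50$ic50[i], unit = cfg$true_ic50$unit[i],
       grid = grid)
}
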