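#' Mixed-model comparison of two dose-response relationships
#'
#' Models well-level percent viability of two cell lines as a linear
#' function of drug concentration, `viability = a_i + b_i * conc`, with
#' line-specific fixed intercepts and slopes and a random slope deviation
#' for every line-by-plate unit (replicate plates are the grouping
#' factor). The quantity of interest is the slope difference `b_2 - b_1`,
#' the line-by-concentration interaction.
#'
#' Inference on the slope difference is stratum-exact by default
#' (`df_method = "stratum"`): because the slope contrast lies entirely in
#' the between-plate stratum of the (balanced) assay design, the pooled
#' two-sample t-test on the per-plate least-squares slopes — with
#' `plates - 2` denominator degrees of freedom — is exactly calibrated
#' under the model, whereas Wald z and Satterthwaite approximations are
#' liberal with the two or three replicate plates typical of
#' cytotoxicity assays. `"satterthwaite"` (via the fitted mixed model) and
#' `"wald"` are available for unbalanced data.
#'
#' @param data Data frame with columns `cell_line` (exactly two levels),
#'   `plate` (replicate plate id within line), `conc` (numeric, raw
#'   concentration scale) and `viability` (%).
#' @param df_method `"stratum"` (default), `"satterthwaite"` or `"wald"`.
#' @param log_conc Model viability against `log10(conc)` instead of the
#'   raw concentration scale (requires strictly positive concentrations);
#'   off by default.
#' @param conf_level Confidence level of the slope-difference interval.
#' @return An `lmm_comparison`: list with `slope_diff`, `se`, `df`, `p`,
#'   `ci`, per-line `slopes` and `intercepts` (mixed-model fixed effects),
#'   a `singular` flag (variance component at the boundary), and the
#'   fitted `model`.
#' @seealso [simulate_dose_response()] for generating calibration data,
#'   [compare_ttest_pic50()] for the single-point alternative.
#' @export
#' @examples
#' d <- simulate_dose_response(seed = 1, slope = c(-0.5, -0.8))
#' compare_lmm(d)$p
compare_lmm <- function(data, df_method = c("stratum", "satterthwaite",
                                            "wald"),
                        log_conc = FALSE, conf_level = 0.95) {
  df_method <- match.arg(df_method)
  need <- c("cell_line", "plate", "conc", "viability")
  if (!all(need %in% colnames(data)))
    stop("'data' must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (log_conc) {
    if (any(data$conc <= 0))
      stop("log_conc requires strictly positive concentrations",
           call. = FALSE)
    data$conc <- log10(data$conc)
  }
  data$cell_line <- factor(data$cell_line)
  if (nlevels(data$cell_line) != 2)
    stop("exactly two cell lines are compared at a time", call. = FALSE)
  n_conc <- tapply(data$conc, data$cell_line,
                   function(z) length(unique(z)))
  if (any(n_conc < 2))
    stop("each cell line needs at least 2 distinct concentrations",
         call. = FALSE)
  data$unit <- interaction(data$cell_line, data$plate, drop = TRUE)

  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(viability ~ cell_line * conc + (0 + conc | unit),
                   data = data,
                   control = lme4::lmerControl(calc.derivs = FALSE,
                                               check.conv.singular =
                                                 "ignore"))))
  singular <- lme4::isSingular(fit)
  if (singular)
    warning("variance component at the boundary; slope comparison flagged",
            call. = FALSE)

  lv <- levels(data$cell_line)
  co <- summary(fit)$coefficients
  irow <- grep(":conc$", rownames(co))
  fx <- lme4::fixef(fit)
  slopes <- c(fx[["conc"]], fx[["conc"]] + co[irow, "Estimate"])
  intercepts <- c(fx[["(Intercept)"]],
                  fx[["(Intercept)"]] + fx[[paste0("cell_line", lv[2])]])
  names(slopes) <- names(intercepts) <- lv

  n_plates <- tapply(data$plate, data$cell_line,
                     function(z) length(unique(z)))
  if (df_method == "stratum" && any(n_plates < 2)) {
    warning("fewer than 2 plates per line; falling back to Satterthwaite",
            call. = FALSE)
    df_method <- "satterthwaite"
  }

  if (df_method == "stratum") {
    unit_slope <- vapply(split(data, data$unit), function(d)
      unname(coef(lm(viability ~ conc, data = d))["conc"]), numeric(1))
    unit_line <- vapply(split(data$cell_line, data$unit), function(z)
      as.character(z[1]), character(1))
    b1 <- unit_slope[unit_line == lv[1]]
    b2 <- unit_slope[unit_line == lv[2]]
    m1 <- length(b1); m2 <- length(b2)
    est <- mean(b2) - mean(b1)
    dfree <- m1 + m2 - 2
    sp2 <- (sum((b1 - mean(b1))^2) + sum((b2 - mean(b2))^2)) / dfree
    if (sp2 == 0) {
      se <- 0
      p <- if (est == 0) 1 else 0
    } else {
      se <- sqrt(sp2 * (1 / m1 + 1 / m2))
      p <- 2 * pt(-abs(est / se), df = dfree)
    }
  } else {
    est <- co[irow, "Estimate"]
    se <- co[irow, "Std. Error"]
    if (df_method == "satterthwaite") {
      dfree <- co[irow, "df"]
      p <- co[irow, "Pr(>|t|)"]
    } else {
      dfree <- Inf
      p <- 2 * pnorm(-abs(est / se))
    }
  }
  crit <- qt(1 - (1 - conf_level) / 2, df = dfree)

  structure(list(slope_diff = unname(est), se = unname(se),
                 df = unname(dfree), p = unname(p),
                 ci = unname(c(est - crit * se, est + crit * se)),
                 slopes = slopes, intercepts = intercepts,
                 singular = singular, df_method = df_method, model = fit),
            class = "lmm_comparison")
}

#' @export
print.lmm_comparison <- function(x, ...) {
  cat("Dose-response slope comparison (random-slope mixed model)\n")
  cat(sprintf("  slope difference %.4g (95%% CI %.4g to %.4g), p = %.3g%s\n",
              x$slope_diff, x$ci[1], x$ci[2], x$p,
              if (x$singular) " [flagged: singular fit]" else ""))
  invisible(x)
}

#' Pooled t-test on replicate pIC50 values
#'
#' Unpaired two-sided Student t-test (pooled variance, not Welch)
#' comparing mean pIC50 between two lines. pIC50 values are approximately
#' normal where raw IC50s are log-normal, so the t-test operates on them.
#' When both groups have zero variance, p is 1 for equal means and 0
#' otherwise, by convention.
#'
#' @param pic50_a,pic50_b Numeric replicate pIC50 vectors (>= 2 each).
#' @param conf_level Confidence level for the mean-difference interval.
#' @return A `pic50_ttest`: list with `mean_a`, `mean_b`, `diff`, `t`,
#'   `df`, `p`, `ci`.
#' @export
#' @examples
#' compare_ttest_pic50(c(8.0, 8.1, 8.2), c(9.0, 9.1, 9.2))$p
compare_ttest_pic50 <- function(pic50_a, pic50_b, conf_level = 0.95) {
  if (length(pic50_a) < 2 || length(pic50_b) < 2)
    stop("need at least 2 replicate pIC50 values per line", call. = FALSE)
  na <- length(pic50_a); nb <- length(pic50_b)
  ma <- mean(pic50_a); mb <- mean(pic50_b)
  dfree <- na + nb - 2
  sp2 <- (sum((pic50_a - ma)^2) + sum((pic50_b - mb)^2)) / dfree
  d <- ma - mb
  if (sp2 == 0) {
    p <- if (d == 0) 1 else 0
    tt <- if (d == 0) 0 else sign(d) * Inf
    ci <- c(d, d)
  } else {
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    tt <- d / se
    p <- 2 * pt(-abs(tt), df = dfree)
    crit <- qt(1 - (1 - conf_level) / 2, df = dfree)
    ci <- c(d - crit * se, d + crit * se)
  }
  structure(list(mean_a = ma, mean_b = mb, diff = d, t = tt, df = dfree,
                 p = p, ci = ci),
            class = "pic50_ttest")
}

#' @export
print.pic50_ttest <- function(x, ...) {
  cat(sprintf(
    "pIC50 t-test (pooled): diff %.4g, t = %.3g (df %d), p = %.3g\n",
    x$diff, x$t, x$df, x$p))
  invisible(x)
}

#' Simulate well-level linear dose-response data
#'
#' Generates the well-level viability table consumed by [compare_lmm()],
#' under the same linear model the comparison fits: per-line intercept and
#' slope, a Gaussian random slope deviation per replicate plate, and
#' Gaussian residual noise. Used for the calibration (type-I error, power)
#' studies of the two curve-comparison tests.
#'
#' @param seed Integer seed.
#' @param lines Two line labels.
#' @param slope Length-2 true slopes (viability % per concentration unit).
#' @param intercept Length-2 (or scalar) true intercepts.
#' @param conc Concentration design points (shared by both lines).
#' @param n_plates Replicate plates per line.
#' @param wells_per_conc Wells per concentration per plate.
#' @param plate_slope_sd SD of the per-plate slope deviation.
#' @param resid_sd Residual SD (% viability).
#' @return Data frame with columns `cell_line`, `plate`, `conc`,
#'   `viability`.
#' @export
#' @examples
#' head(simulate_dose_response(seed = 1))
simulate_dose_response <- function(seed = 1L, lines = c("A", "B"),
                                   slope = c(-0.5, -0.5),
                                   intercept = 100,
                                   conc = seq(0, 140, by = 20),
                                   n_plates = 3L, wells_per_conc = 4L,
                                   plate_slope_sd = 0.05, resid_sd = 5) {
  set.seed(derive_seed(seed, "dose-response"))
  intercept <- rep_len(intercept, 2L)
  out <- expand.grid(well = seq_len(wells_per_conc), conc = conc,
                     plate = seq_len(n_plates), line_i = 1:2)
  b_plate <- rnorm(2L * n_plates, sd = plate_slope_sd)
  unit <- (out$line_i - 1L) * n_plates + out$plate
  out$viability <- intercept[out$line_i] +
    (slope[out$line_i] + b_plate[unit]) * out$conc +
    rnorm(nrow(out), sd = resid_sd)
  data.frame(cell_line = lines[out$line_i], plate = out$plate,
             conc = out$conc, viability = out$viability,
             stringsAsFactors = FALSE)
}
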