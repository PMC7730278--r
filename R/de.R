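#' Remove genes with very low expression
#'
#' Keeps genes with more than `threshold` normalised reads in at least
#' `min_samples` samples, where "normalised reads" are counts-per-million
#' (count / library size x 1e6) and library sizes are the column sums. The
#' filter is applied once, globally across all samples, so every contrast
#' is tested on the same gene universe.
#'
#' @param cm A [count_matrix()] with >= 2 samples.
#' @param threshold CPM threshold (strictly greater than), default 5.
#' @param min_samples Minimum number of samples above the threshold.
#' @return The filtered [count_matrix()].
#' @export
filter_low_expression <- function(cm, threshold = 5, min_samples = 2) {
  stopifnot(inherits(cm, "count_matrix"))
  if (ncol(cm$counts) < 2)
    stop("need at least 2 samples", call. = FALSE)
  lib <- colSums(cm$counts)
  if (any(lib == 0)) stop("zero library size", call. = FALSE)
  cpm <- sweep(cm$counts, 2, lib, "/") * 1e6
  keep <- rowSums(cpm > threshold) >= min_samples
  if (!any(keep))
    stop("no genes survive the low-expression filter", call. = FALSE)
  count_matrix(cm$counts[keep, , drop = FALSE], cm$samples)
}

#' Log2 counts-per-million transformation
#'
#' `log2((count + 0.5) / (libsize + 1) * 1e6)` per cell, with a half-count
#' offset keeping zeros finite. With `norm_method = "tmm"` (default) the
#' library size is the effective one — column sum times its trimmed-mean
#' (TMM) scaling factor — so that fold changes are centred on the
#' non-changing majority of genes and are robust to composition shifts
#' when many genes move in one direction; `"total"` uses the raw column
#' sums.
#'
#' @param cm A (typically filtered) [count_matrix()].
#' @param norm_method `"tmm"` (trimmed-mean scaling via
#'   [edgeR::calcNormFactors()]) or `"total"` (plain column sums).
#' @return A `log_expression`: list with `log2cpm` (genes x samples
#'   matrix), `lib_sizes` (effective sizes used), `norm_factors`, and the
#'   `samples` metadata.
#' @export
normalize_log <- function(cm, norm_method = c("tmm", "total")) {
  stopifnot(inherits(cm, "count_matrix"))
  norm_method <- match.arg(norm_method)
  lib <- colSums(cm$counts)
  if (any(lib == 0)) stop("zero library size", call. = FALSE)
  nf <- if (norm_method == "tmm")
    edgeR::calcNormFactors(cm$counts, lib.size = lib, method = "TMM")
  else rep(1, ncol(cm$counts))
  eff <- lib * nf
  log2cpm <- log2(sweep(cm$counts + 0.5, 2, eff + 1, "/") * 1e6)
  structure(list(log2cpm = log2cpm, lib_sizes = eff, norm_factors = nf,
                 samples = cm$samples),
            class = "log_expression")
}

#' Moderated two-group differential expression for one contrast
#'
#' Per gene: log2 fold change is the mean log2-CPM difference
#' (`line_b` minus `line_a`); the residual variance (pooled within-group)
#' is shrunk toward a common prior by the empirical-Bayes moderated-t
#' construction — the prior degrees of freedom `d0` and prior variance
#' `s0^2` are estimated by the method of moments on the log residual
#' variances (an inverse-chi-square prior), the posterior variance is
#' `(d0*s0^2 + d*s^2)/(d0 + d)`, and two-sided p-values use a t
#' distribution with `d + d0` degrees of freedom. Observation-level
#' precision weights (a mean-variance trend) are deliberately not used.
#'
#' @param le A [normalize_log()] result.
#' @param line_a,line_b Cell-line labels; the contrast is `line_b` vs
#'   `line_a` (positive log2FC means higher in `line_b`). Each needs >= 2
#'   replicates.
#' @param prior_df Override the estimated prior degrees of freedom: `0`
#'   gives the ordinary two-sample t-test, `Inf` (with `prior_var`) a
#'   pooled-variance z-test. Default `NULL` estimates it from the data.
#' @param prior_var Override the prior variance (required with
#'   `prior_df = Inf`).
#' @return A `de_comparison` data frame: `gene`, `log2fc`, `stat`, `p`,
#'   `q` (Benjamini-Hochberg), with attributes `contrast`, `prior_df`,
#'   `prior_var`, `residual_df`.
#' @export
fit_de <- function(le, line_a, line_b, prior_df = NULL, prior_var = NULL) {
  stopifnot(inherits(le, "log_expression"))
  cl <- as.character(le$samples$cell_line)
  ia <- which(cl == line_a)
  ib <- which(cl == line_b)
  if (length(ia) < 2 || length(ib) < 2)
    stop("each line of the contrast needs >= 2 replicates", call. = FALSE)
  xa <- le$log2cpm[, ia, drop = FALSE]
  xb <- le$log2cpm[, ib, drop = FALSE]
  na <- length(ia); nb <- length(ib)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  dfres <- na + nb - 2
  s2 <- (rowSums((xa - ma)^2) + rowSums((xb - mb)^2)) / dfres

  if (is.null(prior_df)) {
    eb <- fit_variance_prior(s2, dfres)
    prior_df <- eb$df_prior
    prior_var <- eb$var_prior
  } else if (prior_df > 0 && is.null(prior_var)) {
    if (is.infinite(prior_df))
      stop("'prior_var' is required when prior_df = Inf", call. = FALSE)
    prior_var <- fit_variance_prior(s2, dfres)$var_prior
  }

  s2_post <- if (prior_df == 0) s2
             else if (is.infinite(prior_df)) rep(prior_var, length(s2))
             else (prior_df * prior_var + dfres * s2) / (prior_df + dfres)
  log2fc <- mb - ma
  stat <- log2fc / sqrt(s2_post * (1 / na + 1 / nb))
  p <- 2 * pt(-abs(stat), df = dfres + prior_df)
  bad <- !is.finite(stat)
  if (any(bad)) {
    warning(sum(bad), " gene(s) with degenerate variance excluded from ",
            "testing (p set to NA)", call. = FALSE)
    p[bad] <- NA_real_
  }
  q <- adjust_fdr(p)
  structure(data.frame(gene = rownames(le$log2cpm), log2fc = log2fc,
                       stat = stat, p = p, q = q,
                       row.names = NULL, stringsAsFactors = FALSE),
            contrast = c(line_a, line_b), prior_df = prior_df,
            prior_var = prior_var, residual_df = dfres,
            class = c("de_comparison", "data.frame"))
}

# Method-of-moments fit of the scaled inverse-chi-square variance prior:
# moments of log(s^2) around the digamma/trigamma expansion. Returns
# df_prior (possibly Inf) and var_prior.
fit_variance_prior <- function(s2, dfres) {
  s2 <- s2[is.finite(s2)]
  if (length(s2) < 2) return(list(df_prior = 0, var_prior = mean(s2)))
  m <- median(s2)
  if (m == 0) m <- 1
  x <- pmax(s2, 1e-5 * m)   # offset exact zeros away from log(0)
  e <- log(x) - digamma(dfres / 2) + log(dfres / 2)
  evar <- var(e) - trigamma(dfres / 2)
  if (is.finite(evar) && evar > 0) {
    df_prior <- 2 * trigamma_inverse(evar)
    var_prior <- exp(mean(e) + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    df_prior <- Inf
    var_prior <- mean(x)
  }
  list(df_prior = df_prior, var_prior = var_prior)
}

#' Fit all subline-vs-reference contrasts of an ordered series
#'
#' Convenience wrapper running [fit_de()] of every non-reference line
#' against the reference, in the series order of the `cell_line` factor.
#'
#' @param le A [normalize_log()] result.
#' @param reference Reference (parental) line label.
#' @param ... Passed to [fit_de()].
#' @return Named list of `de_comparison` objects (one per subline).
#' @export
fit_de_series <- function(le, reference, ...) {
  stopifnot(inherits(le, "log_expression"))
  lv <- levels(le$samples$cell_line)
  if (!reference %in% lv)
    stop("reference line '", reference, "' not present", call. = FALSE)
  sublines <- setdiff(lv, reference)
  out <- lapply(sublines, function(s) fit_de(le, reference, s, ...))
  names(out) <- sublines
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values ("q-values"), clipped to 1. `NA` p-values
#' propagate with a warning. A conservative Storey-style variant
#' (`method = "storey"`) rescales by a pi0 estimate at lambda = 0.5.
#'
#' @param p P-values in \[0, 1\] (NA allowed).
#' @param method `"BH"` (default) or `"storey"`.
#' @return Adjusted q-values, same length and order as `p`.
#' @export
#' @examples
#' adjust_fdr(c(0.01, 0.02, 0.03))
adjust_fdr <- function(p, method = c("BH", "storey")) {
  method <- match.arg(method)
  if (any(is.na(p)))
    warning("NA p-values propagated to NA q-values", call. = FALSE)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  q <- p.adjust(p, method = "BH")
  if (method == "storey") {
    pi0 <- min(1, mean(p > 0.5, na.rm = TRUE) / 0.5)
    q <- pmin(q * pi0, 1)
  }
  q
}

#' Call differentially expressed genes for one contrast
#'
#' Genes with `q < q_threshold` (and, optionally, `|log2fc| >
#' fc_threshold`), split by fold-change sign.
#'
#' @param de A `de_comparison` from [fit_de()].
#' @param q_threshold FDR threshold in (0, 1).
#' @param fc_threshold Optional absolute log2FC threshold (strictly
#'   greater than).
#' @return A `deg_set`: list with `up` and `down` gene-id vectors, `genes`
#'   (their union), the thresholds and the contrast.
#' @export
call_degs <- function(de, q_threshold = 0.05, fc_threshold = NULL) {
  stopifnot(inherits(de, "de_comparison"))
  if (q_threshold <= 0 || q_threshold >= 1)
    stop("'q_threshold' must lie strictly inside (0, 1)", call. = FALSE)
  sel <- !is.na(de$q) & de$q < q_threshold
  if (!is.null(fc_threshold)) sel <- sel & abs(de$log2fc) > fc_threshold
  structure(list(up = de$gene[sel & de$log2fc > 0],
                 down = de$gene[sel & de$log2fc < 0],
                 genes = de$gene[sel],
                 q_threshold = q_threshold, fc_threshold = fc_threshold,
                 contrast = attr(de, "contrast")),
            class = "deg_set")
}

#' @export
print.deg_set <- function(x, ...) {
  cat("DEG set [", paste(x$contrast, collapse = " vs "), "]: ",
      length(x$genes), " genes (", length(x$up), " up, ", length(x$down),
      " down) at q < ", x$q_threshold,
      if (!is.null(x$fc_threshold))
        paste0(", |log2FC| > ", x$fc_threshold) else "", "\n", sep = "")
  invisible(x)
}

#' Spearman correlation of DEG counts with resistance-index differences
#'
#' Rank correlation between per-pair DEG totals and the corresponding
#' absolute differences in resistance (or sensitivity) index, quantifying
#' "the larger the resistance change, the larger the transcriptome change".
#'
#' @param deg_counts Per-pair DEG totals (>= 4 pairs).
#' @param deltas Per-pair absolute index differences, same length.
#' @return List with `rho` and `p`.
#' @export
correlate_deg_counts <- function(deg_counts, deltas) {
  if (length(deg_counts) != length(deltas))
    stop("'deg_counts' and 'deltas' must have equal length", call. = FALSE)
  if (length(deg_counts) < 4)
    stop("need at least 4 pairs", call. = FALSE)
  if (length(unique(deg_counts)) == 1 || length(unique(deltas)) == 1)
    stop("correlation undefined for a constant vector", call. = FALSE)
  ct <- suppressWarnings(
    cor.test(deg_counts, deltas, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
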