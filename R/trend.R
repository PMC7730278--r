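#' Classify one gene's expression kinetics across the ordered contrasts
#'
#' Reduces a log2 fold-change trajectory over the ordered subline-vs-parent
#' contrasts to a sign pattern and one of five kinetic classes:
#'
#' * `consistently_up`: positive in every contrast;
#' * `consistently_down`: negative in every contrast;
#' * `rising`: exactly one sign switch, from negative to positive;
#' * `descending`: exactly one switch, from positive to negative;
#' * `variable`: two or more switches.
#'
#' Fold changes with `|log2fc| < epsilon` count as sign 0 and inherit the
#' previous nonzero sign (leading zeros inherit the first nonzero sign), so
#' noise-level wobbles do not break an otherwise consistent run. An
#' all-zero trajectory is labelled `variable` with `zero_pattern = TRUE`.
#' Classification uses fold-change signs only, not per-contrast
#' significance.
#'
#' @param log2fc Numeric vector of log2 fold changes over >= 2 ordered
#'   contrasts, no NA.
#' @param epsilon Dead zone below which a fold change counts as 0.
#' @return A `trend_assignment`: list with `sign_pattern` (string over
#'   `+`/`-`/`0`), `klass`, `switch_index` (position of the first contrast
#'   after the switch; `NA` unless rising/descending), `zero_pattern`.
#' @export
#' @examples
#' classify_trend(c(-3, -3, 3, 3, 3, 3)) # rising, switch at contrast 3
classify_trend <- function(log2fc, epsilon = 0.1) {
  if (length(log2fc) < 2 || any(!is.finite(log2fc)))
    stop("'log2fc' must hold >= 2 finite values", call. = FALSE)
  s <- ifelse(abs(log2fc) < epsilon, 0, sign(log2fc))
  pattern <- paste(c("-", "0", "+")[s + 2], collapse = "")

  nz <- s[s != 0]
  if (length(nz) == 0)
    return(structure(list(sign_pattern = pattern, klass = "variable",
                          switch_index = NA_integer_, zero_pattern = TRUE),
                     class = "trend_assignment"))

  # zeros inherit the previous nonzero sign; leading zeros the first one
  eff <- s
  eff[eff == 0] <- NA
  first_nz <- which(!is.na(eff))[1]
  if (first_nz > 1) eff[seq_len(first_nz - 1)] <- eff[first_nz]
  for (i in seq_along(eff)) if (is.na(eff[i])) eff[i] <- eff[i - 1]

  r <- rle(eff)
  n_switch <- length(r$values) - 1L
  if (n_switch == 0) {
    klass <- if (r$values[1] > 0) "consistently_up" else "consistently_down"
    sw <- NA_integer_
  } else if (n_switch == 1) {
    klass <- if (r$values[1] < 0) "rising" else "descending"
    sw <- r$lengths[1] + 1L
  } else {
    klass <- "variable"
    sw <- NA_integer_
  }
  structure(list(sign_pattern = pattern, klass = klass,
                 switch_index = sw, zero_pattern = FALSE),
            class = "trend_assignment")
}

#' @export
print.trend_assignment <- function(x, ...) {
  cat("trend: ", x$klass, " [", x$sign_pattern, "]",
      if (!is.na(x$switch_index)) paste0(", switch at contrast ",
                                         x$switch_index) else "",
      "\n", sep = "")
  invisible(x)
}

#' Classify many genes at once
#'
#' Row-wise [classify_trend()] over a genes x contrasts log2FC matrix.
#'
#' @param fc_matrix Numeric matrix, genes in rows (rownames = gene ids),
#'   ordered contrasts in columns.
#' @inheritParams classify_trend
#' @return Data frame: `gene`, `sign_pattern`, `class`, `switch_index`,
#'   `zero_pattern`.
#' @export
classify_trends <- function(fc_matrix, epsilon = 0.1) {
  fc_matrix <- as.matrix(fc_matrix)
  res <- lapply(seq_len(nrow(fc_matrix)), function(i)
    classify_trend(fc_matrix[i, ], epsilon = epsilon))
  data.frame(gene = rownames(fc_matrix) %||%
               as.character(seq_len(nrow(fc_matrix))),
             sign_pattern = vapply(res, `[[`, "", "sign_pattern"),
             class = vapply(res, `[[`, "", "klass"),
             switch_index = vapply(res, `[[`, 1L, "switch_index"),
             zero_pattern = vapply(res, `[[`, TRUE, "zero_pattern"),
             stringsAsFactors = FALSE)
}

#' Select the scaffold gene set of the series
#'
#' Scaffold genes satisfy `q < q_threshold` and `|log2FC| > fc_threshold`
#' in *every* contrast of the ordered series — the genes whose expression
#' is strongly and significantly changed at each stage of resistance
#' development. Each member is annotated with its kinetic class and a
#' direction summary (`up` for consistently up, `down` for consistently
#' down, `nonconsistent` otherwise). Being a conjunction, the selection is
#' invariant to contrast order.
#'
#' @param de_list Named list of `de_comparison` objects (one per ordered
#'   contrast) over one common gene universe.
#' @param q_threshold,fc_threshold The per-contrast thresholds (defaults
#'   0.001 and 2).
#' @param epsilon Dead zone for [classify_trend()].
#' @return A `scaffold_set` data frame: `gene`, `class`, `switch_index`,
#'   `direction`, plus one `fc_*` column per contrast; attributes
#'   `contrasts`, `q_threshold`, `fc_threshold`.
#' @export
select_scaffold <- function(de_list, q_threshold = 0.001, fc_threshold = 2,
                            epsilon = 0.1) {
  if (length(de_list) == 0) stop("empty contrast list", call. = FALSE)
  genes <- de_list[[1]]$gene
  for (de in de_list)
    if (!identical(sort(de$gene), sort(genes)))
      stop("all contrasts must share one gene universe", call. = FALSE)
  labels <- names(de_list) %||% as.character(seq_along(de_list))

  fc <- sapply(de_list, function(de) de$log2fc[match(genes, de$gene)])
  qq <- sapply(de_list, function(de) de$q[match(genes, de$gene)])
  keep <- rowSums(!is.na(qq) & qq < q_threshold &
                    abs(fc) > fc_threshold) == length(de_list)

  fc_keep <- fc[keep, , drop = FALSE]
  rownames(fc_keep) <- genes[keep]
  ann <- classify_trends(fc_keep, epsilon = epsilon)
  direction <- c(consistently_up = "up", consistently_down = "down")[
    ann$class]
  direction[is.na(direction)] <- "nonconsistent"

  out <- data.frame(gene = genes[keep], class = ann$class,
                    switch_index = ann$switch_index, direction = direction,
                    stringsAsFactors = FALSE, row.names = NULL)
  fc_cols <- as.data.frame(fc_keep, row.names = NULL)
  names(fc_cols) <- paste0("fc_", gsub("[^A-Za-z0-9]", "", labels))
  structure(cbind(out, fc_cols),
            contrasts = labels, q_threshold = q_threshold,
            fc_threshold = fc_threshold,
            class = c("scaffold_set", "data.frame"))
}

#' Shared-DEG matrix over contrast pairs
#'
#' For every pair of contrasts, counts the DEGs they share: the upper
#' triangle holds shared *upregulated* counts, the lower triangle shared
#' *downregulated* counts (diagonal `NA`). If an early/late partition of
#' the contrasts is supplied, per-direction totals are aggregated for
#' "comparisons with the early sublines" (at least one early member) and
#' "comparisons within the late sublines" (both late).
#'
#' @param deg_sets Named list (>= 2) of `deg_set` objects from
#'   [call_degs()], names = contrast labels.
#' @param early,late Optional disjoint label vectors partitioning the
#'   contrast labels; unknown labels are an error.
#' @return List with `shared` (k x k integer matrix) and, when a partition
#'   is given, `totals` (data frame: `group`, `direction`, `shared`).
#' @export
shared_deg_matrix <- function(deg_sets, early = NULL, late = NULL) {
  k <- length(deg_sets)
  if (k < 2) stop("need at least 2 contrasts", call. = FALSE)
  labels <- names(deg_sets) %||% as.character(seq_len(k))
  m <- matrix(NA_integer_, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    m[i, j] <- length(intersect(deg_sets[[i]]$up, deg_sets[[j]]$up))
    m[j, i] <- length(intersect(deg_sets[[i]]$down, deg_sets[[j]]$down))
  }
  out <- list(shared = m)

  if (!is.null(early) || !is.null(late)) {
    part <- c(early, late)
    if (any(!part %in% labels) || any(!labels %in% part) ||
        anyDuplicated(part))
      stop("early/late labels must partition the contrast labels exactly",
           call. = FALSE)
    is_late <- labels %in% late
    tot <- expand.grid(group = c("early", "late"),
                       direction = c("up", "down"),
                       stringsAsFactors = FALSE)
    tot$shared <- 0L
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      grp <- if (is_late[i] && is_late[j]) "late" else "early"
      tot$shared[tot$group == grp & tot$direction == "up"] <-
        tot$shared[tot$group == grp & tot$direction == "up"] + m[i, j]
      tot$shared[tot$group == grp & tot$direction == "down"] <-
        tot$shared[tot$group == grp & tot$direction == "down"] + m[j, i]
    }
    out$totals <- tot
  }
  out
}

#' Principal component embedding of samples
#'
#' Centred (unscaled) PCA of the samples via singular value decomposition,
#' optionally restricted to a gene list (e.g. the most significant DEGs).
#' Genes are centred; no unit-variance scaling is applied.
#'
#' @param mat Numeric matrix, genes x samples (>= 3 samples).
#' @param genes Optional gene ids selecting rows.
#' @return A `pca_embedding`: list with `coordinates` (samples x
#'   components), `explained` (variance fractions, nonincreasing) and
#'   `rotation`.
#' @export
embed_pca <- function(mat, genes = NULL) {
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(mat))
    if (length(missing))
      stop("genes not present in the matrix: ",
           paste(head(missing, 3), collapse = ", "), call. = FALSE)
    mat <- mat[genes, , drop = FALSE]
  }
  if (ncol(mat) < 3) stop("need at least 3 samples", call. = FALSE)
  pr <- prcomp(t(mat), center = TRUE, scale. = FALSE)
  expl <- pr$sdev^2 / sum(pr$sdev^2)
  rank <- sum(pr$sdev > pr$sdev[1] * 1e-12)
  # centering always removes one dimension; warn only beyond that
  if (rank < min(ncol(mat) - 1L, nrow(mat)))
    warning("rank-deficient input: only ", rank,
            " informative components", call. = FALSE)
  structure(list(coordinates = pr$x, explained = expl,
                 rotation = pr$rotation),
            class = "pca_embedding")
}

#' @export
print.pca_embedding <- function(x, ...) {
  cat("PCA embedding:", nrow(x$coordinates), "samples;",
      "PC1-PC3 explain",
      paste0(round(100 * x$explained[seq_len(min(3, length(x$explained)))],
                   2), "%", collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.pca_embedding <- function(x, components = c(1, 2), ...) {
  co <- x$coordinates[, components, drop = FALSE]
  plot(co, xlab = sprintf("PC%d (%.1f%%)", components[1],
                          100 * x$explained[components[1]]),
       ylab = sprintf("PC%d (%.1f%%)", components[2],
                      100 * x$explained[components[2]]), ...)
  text(co, labels = rownames(co), pos = 3, cex = 0.7)
  invisible(x)
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of samples on Euclidean distance (default)
#' with average linkage (default), as used for heat-map sample ordering.
#'
#' @param mat Numeric matrix, genes x samples (>= 2 samples).
#' @param linkage Agglomeration method for [hclust()].
#' @param dist_method Distance for [dist()].
#' @return A `sample_clustering`: list with the `hclust` object and
#'   `leaves`, the left-to-right leaf order.
#' @seealso [write_dendrogram()] for Newick export.
#' @export
cluster_samples <- function(mat, linkage = "average",
                            dist_method = "euclidean") {
  if (ncol(mat) < 2) stop("need at least 2 samples", call. = FALSE)
  d <- dist(t(mat), method = dist_method)
  if (any(is.na(d))) stop("NaN/NA distances between samples", call. = FALSE)
  hc <- hclust(d, method = linkage)
  structure(list(hclust = hc, leaves = hc$labels[hc$order],
                 linkage = linkage, dist_method = dist_method),
            class = "sample_clustering")
}

#' @export
print.sample_clustering <- function(x, ...) {
  cat("sample clustering (", x$dist_method, " / ", x$linkage, "): ",
      paste(x$leaves, collapse = ", "), "\n", sep = "")
  invisible(x)
}
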