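#' Gene-by-sample count matrix with sample metadata
#'
#' Container for RNA-seq counts over the ordered cell-line series. Genes
#' index rows; samples index columns and carry a `cell_line` factor (levels
#' in series order) and a replicate id.
#'
#' @param counts Nonnegative integer matrix, genes x samples, with unique
#'   rownames (gene ids) and colnames matching `samples$sample`.
#' @param samples Data frame with columns `sample`, `cell_line`,
#'   `replicate`; every cell line needs >= 2 replicates.
#' @return A `count_matrix`: list with elements `counts` and `samples`.
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0 || ncol(counts) == 0)
    stop("empty count matrix", call. = FALSE)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("counts need unique gene ids as rownames", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers", call. = FALSE)
  need <- c("sample", "cell_line", "replicate")
  if (!all(need %in% colnames(samples)))
    stop("'samples' must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!identical(colnames(counts), as.character(samples$sample)))
    stop("colnames(counts) must match samples$sample in order",
         call. = FALSE)
  if (!is.factor(samples$cell_line))
    samples$cell_line <- factor(samples$cell_line,
                                levels = unique(samples$cell_line))
  if (any(table(samples$cell_line) < 2))
    stop("every cell line needs >= 2 replicates", call. = FALSE)
  structure(list(counts = counts, samples = samples),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples (", nlevels(x$samples$cell_line), "cell lines )\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Simulate an ordered-series count matrix with planted trend structure
#'
#' Draws negative-binomial counts for `cfg$n_lines` cell lines x
#' `cfg$n_reps` replicates. Each gene gets a pattern class with
#' probabilities `cfg$pattern_props`; its true log2 fold change in each of
#' the `n_lines - 1` subline-vs-parent contrasts is `+/- effect_log2fc`
#' following the class:
#'
#' * `consistently_up` / `consistently_down`: same sign in every contrast;
#' * `rising`: negative early, switching once to positive at a switch
#'   contrast drawn uniformly from positions 2..(k-1);
#' * `descending`: the mirror image;
#' * `variable`: a random sign sequence with >= 2 sign switches;
#' * `null`: zero effect everywhere.
#'
#' Counts are `NB(mean = library-size-scaled expression, size =
#' 1/dispersion)`. Output is bit-reproducible given the configuration.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_counts`: `cm` (a [count_matrix()]), `truth`
#'   (data frame: `gene`, `class`, `switch_index`, plus one `fc_*` column of
#'   true log2FC per contrast), and `contrasts` (subline names in order).
#' @export
#' @examples
#' sim <- simulate_counts(sim_config(seed = 1, n_genes = 200))
#' table(sim$truth$class)
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  k <- cfg$n_lines - 1L
  props <- cfg$pattern_props
  if (props[["variable"]] > 0 && k < 3L)
    stop("variable patterns (>= 2 sign switches) need at least 3 contrasts",
         call. = FALSE)
  set.seed(derive_seed(cfg$seed, "counts"))

  n <- cfg$n_genes
  classes <- sample(names(props), n, replace = TRUE, prob = props)
  fc <- matrix(0, nrow = n, ncol = k)
  switch_index <- rep(NA_integer_, n)
  eff <- cfg$effect_log2fc
  switch_range <- if (k >= 3L) 2:(k - 1L) else 2L

  for (g in seq_len(n)) {
    cls <- classes[g]
    if (cls == "null") next
    if (cls == "consistently_up") {
      fc[g, ] <- eff
    } else if (cls == "consistently_down") {
      fc[g, ] <- -eff
    } else if (cls %in% c("rising", "descending")) {
      s <- if (length(switch_range) > 1) sample(switch_range, 1)
           else switch_range
      signs <- ifelse(seq_len(k) < s, -1, 1)
      if (cls == "descending") signs <- -signs
      fc[g, ] <- eff * signs
      switch_index[g] <- s
    } else { # variable: redraw until at least two sign switches
      repeat {
        signs <- sample(c(-1, 1), k, replace = TRUE)
        if (sum(diff(signs) != 0) >= 2) break
      }
      fc[g, ] <- eff * signs
    }
  }

  genes <- sprintf("G%05d", seq_len(n))
  lines <- cfg$line_names
  sublines <- lines[-1]
  n_samp <- cfg$n_lines * cfg$n_reps
  line_of <- rep(lines, each = cfg$n_reps)
  rep_of <- rep(seq_len(cfg$n_reps), times = cfg$n_lines)
  sample_id <- paste0(gsub("[^A-Za-z0-9]", "", line_of), "_r", rep_of)

  base_log2cpm <- pmin(pmax(rnorm(n, mean = 5, sd = 2), 1), 12)
  lib_sizes <- round(cfg$lib_size_mean * runif(n_samp, 0.85, 1.15))

  fc_full <- cbind(0, fc)              # column per line, parent first
  counts <- matrix(0L, nrow = n, ncol = n_samp,
                   dimnames = list(genes, sample_id))
  for (j in seq_len(n_samp)) {
    li <- match(line_of[j], lines)
    mu <- 2^(base_log2cpm + fc_full[, li]) / 1e6 * lib_sizes[j]
    counts[, j] <- rnbinom(n, size = 1 / cfg$dispersion, mu = mu)
  }

  samples <- data.frame(sample = sample_id,
                        cell_line = factor(line_of, levels = lines),
                        replicate = rep_of, stringsAsFactors = FALSE)
  truth <- data.frame(gene = genes, class = classes,
                      switch_index = switch_index,
                      stringsAsFactors = FALSE)
  fc_cols <- as.data.frame(fc)
  names(fc_cols) <- paste0("fc_", gsub("[^A-Za-z0-9]", "", sublines))
  truth <- cbind(truth, fc_cols)

  structure(list(cm = count_matrix(counts, samples), truth = truth,
                 contrasts = sublines),
            class = "sim_counts")
}
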