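test_that("low-expression filter keeps genes with CPM > 5 in >= 2 samples", {
  cm <- toy_count_matrix(seed = 2, n_genes = 20, lambda = 100)
  cm$counts[1, ] <- 0L                       # all zero -> removed
  lib <- colSums(cm$counts)
  # boundary gene: CPM just above 5 in exactly two samples, 0 elsewhere
  cm$counts[2, ] <- c(as.integer(ceiling(5 * lib[1:2] / 1e6)) + 1L, 0L, 0L)
  cm2 <- count_matrix(cm$counts, cm$samples)
  kept <- rownames(filter_low_expression(cm2)$counts)
  expect_false("g001" %in% kept)
  expect_true("g002" %in% kept)

  # brute-force recount oracle on a 500-gene toy matrix
  cm <- toy_count_matrix(seed = 3, n_genes = 500, lambda = 3)
  lib <- colSums(cm$counts)
  oracle <- vapply(seq_len(500), function(g)
    sum(cm$counts[g, ] / lib * 1e6 > 5) >= 2, logical(1))
  expect_identical(rownames(filter_low_expression(cm)$counts),
                   rownames(cm$counts)[oracle])
})

test_that("log-CPM transformation is monotone and column-scale invariant", {
  # monotone in counts within a column
  cml <- toy_count_matrix(seed = 5, n_genes = 30)
  lg <- normalize_log(cml, norm_method = "total")$log2cpm
  o <- order(cml$counts[, 1])
  expect_true(all(diff(lg[o, 1]) >= 0))
  # scaling a column cancels (up to the +0.5/+1 offsets) for counts >= 100
  big <- toy_count_matrix(seed = 6, n_genes = 40, lambda = 500)
  doubled <- big$counts; doubled[, 1] <- doubled[, 1] * 2L
  for (method in c("total", "tmm")) {
    l1 <- normalize_log(big, norm_method = method)$log2cpm
    l2 <- normalize_log(count_matrix(doubled, big$samples),
                        norm_method = method)$log2cpm
    expect_lt(max(abs(l1[, 1] - l2[, 1])), 0.01)
  }
})

test_that("the zero-count closed form equals -1 at library size 1e6 - 1", {
  counts <- matrix(1L, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  counts[1, ] <- 0L
  counts[2, ] <- as.integer(1e6 - 1)
  samples <- data.frame(sample = c("s1", "s2"),
                        cell_line = factor(c("P", "P")), replicate = 1:2)
  le <- normalize_log(count_matrix(counts, samples), norm_method = "total")
  expect_equal(unname(le$log2cpm[1, ]), c(-1, -1))
})

test_that("moderated t collapses to its classical limits", {
  set.seed(41)
  n <- 200
  counts <- matrix(rpois(n * 4, 400), nrow = n,
                   dimnames = list(sprintf("g%03d", 1:n),
                                   c("P_r1", "P_r2", "S_r1", "S_r2")))
  samples <- data.frame(sample = colnames(counts),
                        cell_line = factor(rep(c("P", "S"), each = 2),
                                           levels = c("P", "S")),
                        replicate = rep(1:2, 2))
  le <- normalize_log(count_matrix(counts, samples))

  # prior df -> 0: ordinary two-sample t on log-expression
  de0 <- fit_de(le, "P", "S", prior_df = 0)
  pt_oracle <- vapply(seq_len(n), function(g)
    pooled_t_oracle(le$log2cpm[g, 1:2], le$log2cpm[g, 3:4])$p, numeric(1))
  expect_lt(max(abs(de0$p - pt_oracle)), 1e-8)

  # prior df -> Inf: z-test with the supplied pooled variance
  v0 <- 0.02
  deInf <- fit_de(le, "P", "S", prior_df = Inf, prior_var = v0)
  z_oracle <- 2 * pnorm(-abs((rowMeans(le$log2cpm[, 3:4]) -
                                rowMeans(le$log2cpm[, 1:2])) / sqrt(v0)))
  expect_lt(max(abs(deInf$p - z_oracle)), 1e-10)
})

test_that("moderated statistics agree with the reference empirical-Bayes fit", {
  set.seed(43)
  n <- 300
  mu <- exp(rnorm(n, 5, 1))
  counts <- matrix(rnbinom(n * 4, size = 20, mu = mu), nrow = n,
                   dimnames = list(sprintf("g%03d", 1:n),
                                   c("P_r1", "P_r2", "S_r1", "S_r2")))
  counts[counts == 0] <- 1L
  samples <- data.frame(sample = colnames(counts),
                        cell_line = factor(rep(c("P", "S"), each = 2),
                                           levels = c("P", "S")),
                        replicate = rep(1:2, 2))
  le <- normalize_log(count_matrix(counts, samples))
  de <- fit_de(le, "P", "S")

  design <- cbind(1, rep(c(0, 1), each = 2))
  fit <- limma::eBayes(limma::lmFit(le$log2cpm, design), trend = FALSE,
                       robust = FALSE)
  expect_equal(attr(de, "prior_df"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(de, "prior_var"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(de$stat, unname(fit$t[, 2]), tolerance = 1e-8)
  # p-values agree up to the reference capping its total df at the pooled
  # residual df (we keep the exact augmented df)
  expect_equal(de$p, unname(fit$p.value[, 2]), tolerance = 2e-3)
})

test_that("contrast antisymmetry holds and identical groups give null results", {
  cm <- toy_count_matrix(seed = 10, n_genes = 80)
  le <- normalize_log(cm)
  ab <- fit_de(le, "P", "S")
  ba <- fit_de(le, "S", "P")
  expect_equal(ab$log2fc, -ba$log2fc, tolerance = 1e-12)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)

  # a gene identical across all samples: log2FC 0, p 1
  counts <- cm$counts
  counts[1, ] <- 500L
  le2 <- normalize_log(count_matrix(counts, cm$samples))
  # equalise library sizes so the shared gene is exactly constant
  de <- fit_de(normalize_log(count_matrix(
    rbind(counts, libfix = as.integer(max(colSums(counts)) -
                                        colSums(counts) + 10L)),
    cm$samples), norm_method = "total"), "P", "S")
  expect_equal(de$log2fc[de$gene == "g001"], 0, tolerance = 1e-12)
  expect_equal(de$p[de$gene == "g001"], 1, tolerance = 1e-9)
})

test_that("BH adjustment matches hand computation and the exhaustive oracle", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  expect_warning(q <- adjust_fdr(c(0.5, NA)), "NA")
  expect_true(is.na(q[2]))
  expect_error(adjust_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(17)
  p6 <- c(0.011, 0.22, 0.013, 0.94, 0.077, 0.62)
  for (perm in all_perms(6)) {
    p <- p6[unlist(perm)]
    expect_equal(adjust_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
  # property: q >= p, and q is monotone along sorted p
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    q <- adjust_fdr(p)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("DEG calling applies both thresholds and splits by direction", {
  de <- structure(data.frame(gene = letters[1:5],
                             log2fc = c(3, -3, 1, -0.5, 2.5),
                             stat = 0, p = c(0.001, 0.002, 0.003, 0.5, 0.01),
                             q = c(0.01, 0.01, 0.02, 0.9, 0.04)),
                  contrast = c("P", "S"),
                  class = c("de_comparison", "data.frame"))
  ds <- call_degs(de, q_threshold = 0.05)
  expect_setequal(ds$up, c("a", "c", "e"))
  expect_setequal(ds$down, "b")
  expect_equal(length(intersect(ds$up, ds$down)), 0)
  ds2 <- call_degs(de, q_threshold = 0.05, fc_threshold = 2)
  expect_setequal(ds2$genes, c("a", "b", "e"))
  de$q <- rep(1, 5)
  expect_equal(length(call_degs(de, 0.05)$genes), 0)
  expect_error(call_degs(de, q_threshold = 1.5), "strictly inside")
})

test_that("Spearman correlation of DEG counts matches rank-then-Pearson", {
  expect_equal(correlate_deg_counts(1:6, c(2, 4, 9, 11, 30, 31))$rho, 1)
  expect_equal(correlate_deg_counts(1:6, c(31, 30, 11, 9, 4, 2))$rho, -1)
  set.seed(23)
  x <- sample(1000, 21); y <- rnorm(21)
  res <- correlate_deg_counts(x, y)
  expect_equal(res$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
  expect_error(correlate_deg_counts(rep(2, 6), 1:6), "constant")
  expect_error(correlate_deg_counts(1:3, 1:3), "at least 4")
})
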