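test_that("sign trajectories map to the five kinetic classes", {
  expect_equal(classify_trend(rep(3, 6))$klass, "consistently_up")
  expect_equal(classify_trend(rep(-3, 6))$klass, "consistently_down")
  r <- classify_trend(c(-3, -3, 3, 3, 3, 3))
  expect_equal(r$klass, "rising")
  expect_equal(r$switch_index, 3)
  d <- classify_trend(c(2, 2, 2, -2, -2, -2))
  expect_equal(d$klass, "descending")
  expect_equal(d$switch_index, 4)
  expect_equal(classify_trend(c(3, -3, 3, -3, 3, -3))$klass, "variable")

  # dead-zone handling: small values inherit the neighbouring sign
  expect_equal(classify_trend(c(2, 0.05, 2))$klass, "consistently_up")
  expect_equal(classify_trend(c(0.01, -2, -2))$klass, "consistently_down")
  expect_equal(classify_trend(c(-2, 0.04, 2))$klass, "rising")
  z <- classify_trend(c(0.01, -0.02, 0.03))
  expect_equal(z$klass, "variable")
  expect_true(z$zero_pattern)
  expect_equal(classify_trend(c(-1, 0.05, 1, 0.05, -1))$klass, "variable")
  expect_error(classify_trend(3), ">= 2")
  expect_error(classify_trend(c(1, NA)), "finite")
})

test_that("the five classes partition any gene list", {
  set.seed(61)
  for (i in 1:10) {
    fc <- matrix(rnorm(100 * 6, sd = 2), nrow = 100)
    rownames(fc) <- sprintf("g%03d", 1:100)
    ann <- classify_trends(fc)
    expect_true(all(ann$class %in% trend_classes()))
    expect_equal(sum(table(factor(ann$class, levels = trend_classes()))),
                 100)
  }
})

test_that("scaffold selection is the per-contrast conjunction", {
  set.seed(62)
  n <- 1000; k <- 6
  genes <- sprintf("g%04d", 1:n)
  de_list <- lapply(1:k, function(j) {
    structure(data.frame(gene = genes, log2fc = rnorm(n, sd = 2),
                         stat = 0, p = runif(n),
                         q = runif(n)^0.5),
              class = c("de_comparison", "data.frame"))
  })
  names(de_list) <- paste0("C", 1:k)
  sc <- select_scaffold(de_list, q_threshold = 0.4, fc_threshold = 1)

  # brute-force conjunction oracle
  oracle <- vapply(seq_len(n), function(i)
    all(vapply(de_list, function(de)
      de$q[i] < 0.4 && abs(de$log2fc[i]) > 1, logical(1))), logical(1))
  expect_setequal(sc$gene, genes[oracle])
  expect_true(all(c("class", "direction", "switch_index") %in% names(sc)))
  expect_equal(sum(sc$direction %in% c("up", "down", "nonconsistent")),
               nrow(sc))

  # invariance to contrast order
  sc_rev <- select_scaffold(rev(de_list), q_threshold = 0.4,
                            fc_threshold = 1)
  expect_setequal(sc_rev$gene, sc$gene)

  # a gene failing the fold bound in a single contrast is excluded
  de_list2 <- de_list
  strong <- genes[oracle][1]
  de_list2[[3]]$log2fc[de_list2[[3]]$gene == strong] <- 0.5
  expect_false(strong %in% select_scaffold(de_list2, 0.4, 1)$gene)

  expect_error(select_scaffold(list()), "empty")
  de_bad <- de_list
  de_bad[[2]] <- de_bad[[2]][-1, ]
  expect_error(select_scaffold(de_bad, 0.4, 1), "gene universe")
})

test_that("shared-DEG matrices count pairwise intersections by direction", {
  mk <- function(up, down) structure(list(up = up, down = down,
                                          genes = c(up, down),
                                          q_threshold = 0.05,
                                          fc_threshold = NULL,
                                          contrast = c("P", "x")),
                                     class = "deg_set")
  disjoint <- list(a = mk(c("u1"), c("d1")), b = mk(c("u2"), c("d2")))
  m <- shared_deg_matrix(disjoint)$shared
  expect_equal(m["a", "b"], 0L)
  expect_equal(m["b", "a"], 0L)
  same <- list(a = mk(c("u1", "u2"), c("d1")),
               b = mk(c("u1", "u2"), c("d1")))
  m <- shared_deg_matrix(same)$shared
  expect_equal(m["a", "b"], 2L)
  expect_equal(m["b", "a"], 1L)

  # random sets against a brute-force intersection recount
  set.seed(63)
  pool <- sprintf("g%03d", 1:60)
  sets <- lapply(1:5, function(i) mk(sample(pool, 20), sample(pool, 15)))
  names(sets) <- paste0("C", 1:5)
  res <- shared_deg_matrix(sets, early = c("C1", "C2"),
                           late = c("C3", "C4", "C5"))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(res$shared[i, j],
                 length(intersect(sets[[i]]$up, sets[[j]]$up)))
    expect_equal(res$shared[j, i],
                 length(intersect(sets[[i]]$down, sets[[j]]$down)))
    expect_lte(res$shared[i, j], min(length(sets[[i]]$up),
                                     length(sets[[j]]$up)))
  }
  # partition totals recount
  late_pairs <- combn(3:5, 2)
  tot_late_up <- sum(vapply(seq_len(ncol(late_pairs)), function(c2)
    res$shared[late_pairs[1, c2], late_pairs[2, c2]], integer(1)))
  expect_equal(res$totals$shared[res$totals$group == "late" &
                                   res$totals$direction == "up"],
               tot_late_up)
  all_up <- sum(res$shared[upper.tri(res$shared)])
  expect_equal(sum(res$totals$shared[res$totals$direction == "up"]), all_up)

  expect_error(shared_deg_matrix(sets, early = "C1", late = c("C3", "C9")),
               "partition")
  expect_error(shared_deg_matrix(sets[1]), "at least 2")
})

test_that("PCA embedding is a faithful centred SVD", {
  set.seed(64)
  mat <- matrix(rnorm(50 * 6), nrow = 50,
                dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:6)))
  emb <- embed_pca(mat)
  expect_true(all(diff(emb$explained) <= 1e-12))
  expect_equal(sum(emb$explained), 1, tolerance = 1e-9)
  # full reconstruction of the centred matrix
  centred <- t(mat) - colMeans(t(mat))[col(t(mat))]
  recon <- emb$coordinates %*% t(emb$rotation)
  expect_equal(recon, centred, tolerance = 1e-9,
               ignore_attr = TRUE)
  # duplicated samples land on identical coordinates
  mat2 <- cbind(mat, dup = mat[, 3])
  emb2 <- suppressWarnings(embed_pca(mat2))
  expect_equal(unname(emb2$coordinates["dup", ]),
               unname(emb2$coordinates["s3", ]), tolerance = 1e-9)
  expect_error(embed_pca(mat[, 1:2]), "3 samples")
  expect_error(embed_pca(mat, genes = c("g01", "nope")), "not present")
})

test_that("replicates of one line are mutual nearest neighbours in PCA", {
  ok <- 0L; total <- 0L
  for (s in 1:5) {
    cfg <- sim_config(seed = 100 + s, n_genes = 600, lib_size_mean = 2e6)
    sim <- simulate_counts(cfg)
    le <- normalize_log(filter_low_expression(sim$cm))
    emb <- embed_pca(le$log2cpm)
    co <- emb$coordinates
    d <- as.matrix(dist(co))
    diag(d) <- Inf
    for (ln in levels(sim$cm$samples$cell_line)) {
      ids <- sim$cm$samples$sample[sim$cm$samples$cell_line == ln]
      total <- total + 1L
      if (names(which.min(d[ids[1], ]))[1] == ids[2] &&
          names(which.min(d[ids[2], ]))[1] == ids[1])
        ok <- ok + 1L
    }
  }
  expect_gte(ok / total, 0.95)
})

test_that("average-linkage clustering matches a naive agglomeration oracle", {
  set.seed(65)
  mat <- matrix(rnorm(20 * 10), nrow = 20,
                dimnames = list(NULL, paste0("s", 1:10)))
  cs <- cluster_samples(mat)
  expect_equal(sort(cs$hclust$height), upgma_oracle(dist(t(mat))),
               tolerance = 1e-9)
  # identical samples merge at height zero, distant point joins last
  mat2 <- cbind(a = c(1, 0, 0), b = c(1, 0, 0), c = c(1.5, 0, 0),
                far = c(90, 5, 5))
  cs2 <- cluster_samples(mat2)
  expect_equal(min(cs2$hclust$height), 0)
  expect_equal(cs2$hclust$merge[1, ], c(-1, -2))
  expect_true("far" %in% cs2$leaves[c(1, 4)])
  expect_equal(max(cs2$hclust$height),
               tail(cs2$hclust$height, 1))
  expect_error(cluster_samples(mat[, 1, drop = FALSE]), "2 samples")
})
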