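# Independent oracles used across the suite. Each is a deliberately naive
# computation, kept free of the package's own code paths.

# Benjamini-Hochberg straight from the definition: q_i is the smallest
# step-up bound n * t / #{p <= t} over candidate thresholds t >= p_i.
bh_oracle <- function(p) {
  n <- length(p)
  vapply(p, function(pi) {
    cand <- p[p >= pi]
    min(1, min(vapply(cand, function(t) n * t / sum(p <= t), numeric(1))))
  }, numeric(1))
}

# All permutations of seq_len(n), as a list (n! small in tests).
all_perms <- function(n) {
  rec <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in rec(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  rec(seq_len(n))
}

# Hypergeometric upper-tail p by exhaustive enumeration of all queries of
# size n from a universe of size N with K marked elements: the fraction of
# subsets sharing >= k elements with the marked set.
hyper_enum_oracle <- function(N, K, n, k) {
  marked <- seq_len(K)
  subsets <- combn(N, n)
  hits <- colSums(matrix(subsets %in% marked, nrow = n))
  mean(hits >= k)
}

# Naive O(n^3) UPGMA agglomeration returning sorted merge heights.
upgma_oracle <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  active <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(active)) for (j in seq_along(active)) {
      if (i >= j) next
      h <- mean(d[active[[i]], active[[j]]])
      if (h < best_h) { best_h <- h; best <- c(i, j) }
    }
    heights <- c(heights, best_h)
    merged <- c(active[[best[1]]], active[[best[2]]])
    active <- c(active[-best], list(merged))
  }
  sort(heights)
}

# Dense numeric inversion of the 4-parameter logistic restricted to a
# concentration grid: the linear interpolation of (grid, logistic) sampled
# on a very fine grid, solved for a target viability level.
logistic_grid_inverse <- function(grid, ic50, hill, level, n_dense = 2e5) {
  xs <- seq(min(grid), max(grid), length.out = n_dense)
  ys <- approx(grid, 100 / (1 + (grid / ic50)^hill), xout = xs)$y
  i <- which.min(abs(ys - level))
  xs[i]
}

# Ordinary pooled two-sample t-test written out by hand.
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = tt, df = na + nb - 2, p = 2 * pt(-abs(tt), df = na + nb - 2))
}

# Small random count_matrix fixture over two lines.
toy_count_matrix <- function(seed = 1, n_genes = 50, lines = c("P", "S"),
                             reps = 2, lambda = 200) {
  set.seed(seed)
  n_samp <- length(lines) * reps
  counts <- matrix(rpois(n_genes * n_samp, lambda), nrow = n_genes,
                   dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                   paste0(rep(lines, each = reps), "_r",
                                          rep(seq_len(reps), length(lines)))))
  samples <- data.frame(sample = colnames(counts),
                        cell_line = factor(rep(lines, each = reps),
                                           levels = lines),
                        replicate = rep(seq_len(reps), length(lines)))
  count_matrix(counts, samples)
}

# Hand-built alamarBlue plate with a given fraction of dye reduced per
# role (blank wells always 0).
manual_plate <- function(frac_control, frac_treated, concs = c(1, 2, 4, 8)) {
  rows <- LETTERS[1:8]
  layout <- expand.grid(row = rows, col = 1:12, stringsAsFactors = FALSE)
  layout$role <- "blank"
  seeded <- layout$row %in% rows[1:4] & layout$col %in% 2:11
  layout$role[seeded & layout$col %in% c(2, 11)] <- "control"
  layout$role[seeded & layout$col %in% 3:10] <- "treated"
  layout$conc <- NA_real_
  trt <- layout$role == "treated"
  layout$conc[trt] <- concs[(layout$col[trt] - 3L) %% length(concs) + 1L]
  frac <- numeric(nrow(layout))
  frac[layout$role == "control"] <- frac_control
  if (length(frac_treated) == 1) {
    frac[layout$role == "treated"] <- frac_treated
  } else {
    frac[layout$role == "treated"] <-
      frac_treated[match(layout$conc[layout$role == "treated"], concs)]
  }
  a570 <- 1e-5 * ((1 - frac) * 80586 + frac * 155677)
  a600 <- 1e-5 * ((1 - frac) * 117216 + frac * 14652)
  shape <- function(v) matrix(v, 8, 12, dimnames = list(rows, 1:12))
  structure(list(a570 = shape(a570), a600 = shape(a600), layout = layout,
                 cell_line = "X", drug = "PTX", unit = "nM", plate_id = 1L),
            class = "ablue_plate")
}
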