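#' Simulate a scored edge list with planted hubs
#'
#' Generates a protein-protein interaction edge list over `genes` in which
#' `n_hubs` randomly chosen genes are hubs: each hub is connected to
#' exactly `hub_degree` partners, while extra background edges among
#' non-hubs are added sparsely with every non-hub's total degree capped at
#' `hub_degree - 1`. Hub recovery by [find_hubs()] at `min_degree =
#' hub_degree` is therefore exact by construction. Scores are uniform on
#' \[0.15, 0.99\].
#'
#' @param cfg A [sim_config()] (source of the RNG stream).
#' @param genes Nonempty character vector of gene ids.
#' @param n_hubs Number of planted hubs (<= `length(genes)`).
#' @param hub_degree Degree given to each hub (default 9; needs
#'   `length(genes) > hub_degree`).
#' @param background_density Expected fraction of non-hub pairs connected
#'   by background edges.
#' @return List with `edges` (data frame `gene_a`, `gene_b`, `score`) and
#'   `hubs` (planted hub ids).
#' @export
#' @examples
#' cfg <- sim_config(seed = 3)
#' net <- simulate_network(cfg, sprintf("G%02d", 1:30), n_hubs = 2)
#' net$hubs
simulate_network <- function(cfg, genes, n_hubs, hub_degree = 9,
                             background_density = 0.02) {
  stopifnot(inherits(cfg, "sim_config"))
  genes <- as.character(genes)
  if (length(genes) == 0) stop("empty gene list", call. = FALSE)
  if (n_hubs > length(genes))
    stop("'n_hubs' cannot exceed the number of genes", call. = FALSE)
  if (n_hubs > 0 && length(genes) <= hub_degree)
    stop("need more than 'hub_degree' genes to plant hubs", call. = FALSE)
  set.seed(derive_seed(cfg$seed, paste("network", length(genes), n_hubs)))

  hubs <- if (n_hubs > 0) sort(sample(genes, n_hubs)) else character()
  nonhubs <- setdiff(genes, hubs)
  deg <- setNames(integer(length(genes)), genes)
  ea <- character(); eb <- character()

  add_edge <- function(a, b) {
    ea <<- c(ea, a); eb <<- c(eb, b)
    deg[a] <<- deg[a] + 1L; deg[b] <<- deg[b] + 1L
  }

  for (h in hubs) {
    # prefer non-hub partners whose capped degree leaves room
    partners <- setdiff(genes, h)
    free <- partners[!(partners %in% nonhubs) |
                       deg[partners] < hub_degree - 1L]
    pick <- sample(free, hub_degree)
    for (p in pick) add_edge(h, p)
  }

  if (length(nonhubs) >= 2) {
    pairs <- combn(sort(nonhubs), 2)
    chosen <- runif(ncol(pairs)) < background_density
    for (i in which(chosen)) {
      a <- pairs[1, i]; b <- pairs[2, i]
      already <- any((ea == a & eb == b) | (ea == b & eb == a))
      if (!already && deg[a] < hub_degree - 1L && deg[b] < hub_degree - 1L)
        add_edge(a, b)
    }
  }

  edges <- data.frame(gene_a = ea, gene_b = eb,
                      score = round(runif(length(ea), 0.15, 0.99), 3),
                      stringsAsFactors = FALSE)
  list(edges = edges, hubs = hubs)
}
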