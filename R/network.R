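#' Build the direction-annotated scaffold interaction network
#'
#' Induces the subgraph of a scored protein-protein interaction edge list
#' on the scaffold genes, keeping edges with combined score >=
#' `min_score`. Self-loops are removed and duplicate undirected edges
#' collapse to their maximum score. Edges touching a gene outside the
#' scaffold are dropped (with a warning summarising how many). Node
#' direction comes from the scaffold trend summary: consistently
#' upregulated genes are `up`, consistently downregulated `down`,
#' everything else `nonconsistent`.
#'
#' @param scaffold A `scaffold_set` from [select_scaffold()], or a
#'   character vector of gene ids (then `directions` may supply a named
#'   direction vector).
#' @param edges Data frame with columns `gene_a`, `gene_b`, `score`
#'   (scores in \[0, 1\]).
#' @param min_score Minimum combined score, default 0.4 (the common
#'   medium-confidence convention).
#' @param directions Optional named direction vector when `scaffold` is a
#'   plain gene vector.
#' @return A `ppi_network`: list with `graph` (igraph), `nodes` (data
#'   frame: `gene`, `direction`, `degree`) and the retained `edges`.
#' @export
build_network <- function(scaffold, edges, min_score = 0.4,
                          directions = NULL) {
  if (inherits(scaffold, "scaffold_set")) {
    genes <- scaffold$gene
    directions <- setNames(scaffold$direction, scaffold$gene)
  } else {
    genes <- as.character(scaffold)
    if (is.null(directions))
      directions <- setNames(rep("nonconsistent", length(genes)), genes)
  }
  if (length(genes) == 0) {
    edges_kept <- data.frame(gene_a = character(), gene_b = character(),
                             score = numeric())
    g <- igraph::make_empty_graph(0, directed = FALSE)
    nodes <- data.frame(gene = character(), direction = character(),
                        degree = integer())
    return(structure(list(graph = g, nodes = nodes, edges = edges_kept,
                          min_score = min_score), class = "ppi_network"))
  }
  need <- c("gene_a", "gene_b", "score")
  if (!all(need %in% colnames(edges)))
    stop("'edges' must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(edges$score < 0 | edges$score > 1))
    stop("edge scores must lie in [0, 1]", call. = FALSE)

  e <- edges[edges$gene_a != edges$gene_b, , drop = FALSE]
  e <- e[e$score >= min_score, , drop = FALSE]
  inside <- e$gene_a %in% genes & e$gene_b %in% genes
  if (any(!inside))
    warning(sum(!inside), " edge(s) referencing genes outside the ",
            "scaffold dropped", call. = FALSE)
  e <- e[inside, , drop = FALSE]
  if (nrow(e)) {
    key <- paste(pmin(e$gene_a, e$gene_b), pmax(e$gene_a, e$gene_b))
    e <- do.call(rbind, lapply(split(e, key), function(d)
      d[which.max(d$score), , drop = FALSE]))
    rownames(e) <- NULL
  }

  g <- igraph::graph_from_data_frame(
    e[, c("gene_a", "gene_b", "score")], directed = FALSE,
    vertices = data.frame(name = genes))
  deg <- igraph::degree(g)
  nodes <- data.frame(gene = genes,
                      direction = unname(directions[genes]),
                      degree = as.integer(deg[genes]),
                      stringsAsFactors = FALSE)
  structure(list(graph = g, nodes = nodes, edges = e,
                 min_score = min_score),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("PPI network:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges (score >=", x$min_score, ")\n")
  if (nrow(x$nodes))
    print(table(x$nodes$direction))
  invisible(x)
}

#' Detect hub nodes of a PPI network
#'
#' Hubs are nodes whose degree reaches `min_degree` (default 7, matching
#' the convention that scaffold hubs carry on the order of 7-11
#' interaction partners), sorted by decreasing degree, ties broken by gene
#' id.
#'
#' @param net A `ppi_network` from [build_network()].
#' @param min_degree Minimum degree, default 7.
#' @return Character vector of hub gene ids (possibly empty).
#' @export
find_hubs <- function(net, min_degree = 7) {
  stopifnot(inherits(net, "ppi_network"))
  hubs <- net$nodes[net$nodes$degree >= min_degree, , drop = FALSE]
  hubs <- hubs[order(-hubs$degree, hubs$gene), , drop = FALSE]
  hubs$gene
}

#' Hypergeometric gene-set over-representation
#'
#' For each annotation term, the one-sided upper-tail hypergeometric
#' p-value of the overlap between the query and the term's genes, both
#' restricted to the universe; Benjamini-Hochberg q-values across the
#' tested terms. Terms with no genes in the universe are skipped. Terms
#' with `q < 0.05` are conventionally reported as enriched.
#'
#' @param query Gene set of interest; must be a subset of `universe`.
#' @param universe Background gene set (e.g. all expressed genes).
#' @param annotation Named list of term gene vectors (e.g. from
#'   [read_gmt()]).
#' @return Data frame sorted by p: `term`, `k` (overlap), `K` (term size
#'   in universe), `n` (query size), `N` (universe size), `p`, `q`.
#' @export
#' @examples
#' enrich_sets(c("a", "b"), letters[1:10], list(T1 = c("a", "b", "c")))
enrich_sets <- function(query, universe, annotation) {
  query <- unique(query)
  universe <- unique(universe)
  if (!all(query %in% universe))
    stop("'query' must be a subset of 'universe'", call. = FALSE)
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(annotation), function(term) {
    tg <- intersect(unique(annotation[[term]]), universe)
    K <- length(tg)
    if (K == 0) return(NULL)
    k <- length(intersect(query, tg))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      q = numeric()))
  out$q <- adjust_fdr(out$p)
  out[order(out$p, out$term), , drop = FALSE]
}
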