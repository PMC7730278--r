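#' Read and write cytotoxicity plates
#'
#' A plate is stored as three CSV files under a common prefix:
#' `<prefix>_a570.csv` and `<prefix>_a600.csv` (8 rows A-H x 12 columns of
#' absorbances) plus `<prefix>_layout.csv` (well roles and concentrations,
#' with the plate's identity in its leading columns).
#'
#' @param plate An `ablue_plate`.
#' @param prefix File path prefix (directories must exist).
#' @return `write_plate()` the prefix, invisibly; `read_plate()` an
#'   `ablue_plate`.
#' @export
write_plate <- function(plate, prefix) {
  stopifnot(inherits(plate, "ablue_plate"))
  write.csv(plate$a570, paste0(prefix, "_a570.csv"))
  write.csv(plate$a600, paste0(prefix, "_a600.csv"))
  lay <- plate$layout
  lay$cell_line <- plate$cell_line
  lay$drug <- plate$drug
  lay$unit <- plate$unit
  lay$plate_id <- plate$plate_id
  write.csv(lay, paste0(prefix, "_layout.csv"), row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_plate
#' @export
read_plate <- function(prefix) {
  rd <- function(suffix) {
    m <- as.matrix(read.csv(paste0(prefix, suffix), row.names = 1,
                            check.names = FALSE))
    dimnames(m) <- list(LETTERS[1:8], 1:12)
    m
  }
  lay <- read.csv(paste0(prefix, "_layout.csv"), stringsAsFactors = FALSE)
  structure(list(a570 = rd("_a570.csv"), a600 = rd("_a600.csv"),
                 layout = lay[c("row", "col", "role", "conc")],
                 cell_line = lay$cell_line[1], drug = lay$drug[1],
                 unit = lay$unit[1], plate_id = lay$plate_id[1]),
            class = "ablue_plate")
}

#' Read and write count matrices
#'
#' Counts are a TSV with gene ids in the first column (`gene`) and one
#' column per sample; sample metadata live in a companion TSV with columns
#' `sample`, `cell_line`, `replicate` (cell-line order in the metadata
#' file defines the series order).
#'
#' @param cm A [count_matrix()].
#' @param counts_file,samples_file File paths.
#' @export
write_counts <- function(cm, counts_file, samples_file) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(gene = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, counts_file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cm$samples, samples_file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(counts_file)
}

#' @rdname write_counts
#' @export
read_counts <- function(counts_file, samples_file) {
  df <- read.delim(counts_file, check.names = FALSE,
                   stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  storage.mode(counts) <- "integer"
  samples <- read.delim(samples_file, stringsAsFactors = FALSE)
  samples$cell_line <- factor(samples$cell_line,
                              levels = unique(samples$cell_line))
  count_matrix(counts, samples)
}

#' Read and write scored edge lists
#'
#' Three-column TSV: `gene_a`, `gene_b`, `score` (combined interaction
#' score in \[0, 1\]).
#'
#' @param edges Data frame with the three columns.
#' @param path File path.
#' @export
write_edge_list <- function(edges, path) {
  write.table(edges[c("gene_a", "gene_b", "score")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Read and write GMT gene-set annotations
#'
#' The tab-separated GMT convention: one term per line — term id,
#' description, then member genes. Reading delegates to
#' [fgsea::gmtPathways()].
#'
#' @param sets Named list of gene-id vectors.
#' @param path File path.
#' @param descriptions Optional term descriptions (recycled `"NA"`).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("NA", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write a DEG set as a gene list with a JSON sidecar
#'
#' The gene ids go to `<path>` one per line; `<path>.json` records the
#' contrast, thresholds and up/down counts.
#'
#' @param ds A `deg_set` from [call_degs()].
#' @param path Output path for the gene list.
#' @export
write_deg_set <- function(ds, path) {
  stopifnot(inherits(ds, "deg_set"))
  writeLines(ds$genes, path)
  meta <- list(contrast = ds$contrast, q_threshold = ds$q_threshold,
               fc_threshold = ds$fc_threshold,
               n_up = length(ds$up), n_down = length(ds$down),
               n_total = length(ds$genes))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Export a sample dendrogram as Newick
#'
#' @param cs A `sample_clustering` from [cluster_samples()].
#' @param path Output file.
#' @export
write_dendrogram <- function(cs, path) {
  stopifnot(inherits(cs, "sample_clustering"))
  ape::write.tree(ape::as.phylo(cs$hclust), file = path)
  invisible(path)
}

#' Export a PPI network as GraphML plus a node table
#'
#' Writes `<prefix>.graphml` (igraph GraphML with score edge attributes
#' and direction node attributes) and `<prefix>_nodes.tsv` (`gene`,
#' `direction`, `degree`, `is_hub`).
#'
#' @param net A `ppi_network`.
#' @param prefix Output path prefix.
#' @param min_degree Hub threshold recorded in the node table.
#' @export
write_network <- function(net, prefix, min_degree = 7) {
  stopifnot(inherits(net, "ppi_network"))
  g <- net$graph
  igraph::V(g)$direction <- net$nodes$direction[
    match(igraph::V(g)$name, net$nodes$gene)]
  igraph::write_graph(g, paste0(prefix, ".graphml"), format = "graphml")
  nodes <- net$nodes
  nodes$is_hub <- nodes$degree >= min_degree
  write.table(nodes, paste0(prefix, "_nodes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
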