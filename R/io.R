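# Readers and writers for the exchange formats of the pipeline.
# Dialect: tab-separated UTF-8 with a header row for all tables; GTF for
# annotation (1-based closed on disk, 0-based half-open in memory);
# GraphML for networks.

#' Read a count matrix from TSV
#'
#' Expects a header row with `feature_id`, `feature_class` and then one
#' column per sample.  Group labels come from a companion two-column
#' samples TSV (`sample_id`, `group`) or from a named vector.
#'
#' @param path Path to the counts TSV.
#' @param samples Either a path to a samples TSV or a named character
#'   vector mapping sample id to `control`/`treatment`.
#' @return A [count_matrix].
#' @export
read_counts <- function(path, samples) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L)
    stop("counts TSV needs feature_id, feature_class and >=1 sample column")
  if (!identical(names(df)[1:2], c("feature_id", "feature_class")))
    stop("counts TSV must start with columns feature_id, feature_class")
  cnt <- df[, -(1:2), drop = FALSE]
  for (j in seq_along(cnt)) {
    v <- cnt[[j]]
    if (!is.numeric(v) || any(is.na(v)) || any(v != round(v)) || any(v < 0))
      stop("counts column '", names(cnt)[j],
           "' contains a negative, missing or non-integer value")
  }
  m <- as.matrix(cnt)
  rownames(m) <- df$feature_id
  if (is.character(samples) && length(samples) == 1L && is.null(names(samples)))
    samples <- read_samples(samples)
  grp <- samples[colnames(m)]
  if (any(is.na(grp)))
    stop("samples table is missing group labels for: ",
         paste(colnames(m)[is.na(grp)], collapse = ", "))
  count_matrix(m, df$feature_class, grp)
}

#' Read a samples table (sample_id, group) from TSV
#'
#' @param path Path to a two-column TSV with header `sample_id`, `group`.
#' @return Named character vector sample id -> group.
#' @export
read_samples <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("samples TSV must have columns sample_id and group")
  stats::setNames(as.character(df$group), df$sample_id)
}

#' Write a count matrix (and optionally its samples table) to TSV
#'
#' @param cm A [count_matrix].
#' @param path Output counts TSV path.
#' @param samples_path Optional output path for the samples TSV.
#' @return Invisibly, `path`.
#' @export
write_counts <- function(cm, path, samples_path = NULL) {
  df <- data.frame(feature_id = feature_ids(cm),
                   feature_class = unname(cm$feature_class),
                   cm$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(samples_path)) {
    sdf <- data.frame(sample_id = sample_ids(cm),
                      group = as.character(cm$group))
    utils::write.table(sdf, samples_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a miRNA-target interaction table from TSV
#'
#' Two columns (`mirna`, `target`), one predicted interaction per row.
#' Duplicate rows are collapsed (set semantics).  If no universe file is
#' given, the universe is the set of distinct miRNA ids observed.
#'
#' @param path Path to the interaction TSV.
#' @param universe_path Optional path to a text file listing the full
#'   miRNA universe, one id per line.
#' @return An [interaction_map].
#' @export
read_interactions <- function(path, universe_path = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("mirna", "target") %in% names(df)))
    stop("interaction TSV must have columns mirna and target")
  if (nrow(df) == 0L)
    stop("interaction table is empty")
  targets_of <- split(df$target, df$mirna)
  universe <- NULL
  if (!is.null(universe_path)) {
    universe <- readLines(universe_path)
    universe <- universe[nzchar(universe)]
  }
  interaction_map(targets_of, universe)
}

#' Write an interaction map to TSV (one row per miRNA-target pair)
#'
#' @param map An [interaction_map].
#' @param path Output TSV path.
#' @param universe_path Optional path for the universe list (one id per
#'   line); written when the universe is larger than the observed miRNAs.
#' @return Invisibly, `path`.
#' @export
write_interactions <- function(map, path, universe_path = NULL) {
  df <- data.frame(
    mirna = rep(names(map$targets_of), lengths(map$targets_of)),
    target = unlist(map$targets_of, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(universe_path))
    writeLines(map$universe, universe_path)
  invisible(path)
}

#' Read a category-to-gene map (GO/KEGG style) from TSV
#'
#' @param path TSV with columns `category`, `gene`.
#' @return Named list: category id -> character vector of gene ids.
#' @export
read_categories <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("category", "gene") %in% names(df)))
    stop("category TSV must have columns category and gene")
  if (nrow(df) == 0L) stop("category table is empty")
  lapply(split(df$gene, df$category), function(g) sort(unique(g)))
}

#' Read gene lengths from TSV
#'
#' @param path TSV with columns `gene`, `length` (nt, positive).
#' @return Named numeric vector gene -> length.
#' @export
read_gene_lengths <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("gene", "length") %in% names(df)))
    stop("length TSV must have columns gene and length")
  if (any(df$length <= 0)) stop("gene lengths must be positive")
  stats::setNames(as.numeric(df$length), df$gene)
}

#' Write a ceRNA pair network as edge-list TSV and GraphML
#'
#' Emits (a) an edge-list TSV with columns `node_a`, `node_b`, `K`, `n`,
#' `c`, `N`, `pvalue`, `fdr`, `component_id` and (b) a GraphML file with a
#' node attribute `class` and the same edge attributes, readable by any
#' standard graph library.
#'
#' @param pairs Data frame of ceRNA pairs as produced by [build_pairs()]
#'   (columns `target_a`, `target_b`, `K`, `n`, `c`, `N`, `pvalue`,
#'   `fdr`).  May be empty.
#' @param node_classes Named character vector: node id -> feature class.
#' @param edges_path Output path for the edge-list TSV.
#' @param graphml_path Output path for the GraphML file.
#' @return Invisibly, a list with the two paths.
#' @export
write_network <- function(pairs, node_classes, edges_path, graphml_path) {
  g <- pairs_to_graph(pairs, node_classes)
  comp <- if (igraph::vcount(g) > 0) igraph::components(g)$membership else integer(0)
  edf <- data.frame(node_a = character(0), node_b = character(0),
                    K = integer(0), n = integer(0), c = integer(0),
                    N = integer(0), pvalue = numeric(0), fdr = numeric(0),
                    component_id = integer(0))
  if (nrow(pairs) > 0L) {
    edf <- data.frame(node_a = pairs$target_a, node_b = pairs$target_b,
                      K = pairs$K, n = pairs$n, c = pairs$c, N = pairs$N,
                      pvalue = pairs$pvalue, fdr = pairs$fdr,
                      component_id = unname(comp[pairs$target_a]))
  }
  utils::write.table(edf, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (igraph::vcount(g) > 0)
    igraph::V(g)$component_id <- unname(comp[igraph::V(g)$name])
  igraph::write_graph(g, graphml_path, format = "graphml")
  invisible(list(edges = edges_path, graphml = graphml_path))
}

#' Build an igraph graph from a ceRNA pair table
#'
#' @param pairs Data frame with `target_a`, `target_b` and edge attribute
#'   columns (`K`, `n`, `c`, `N`, `pvalue`, `fdr` when present).
#' @param node_classes Named character vector node id -> class; nodes not
#'   named in it get class `"unknown"`.
#' @return An undirected `igraph` graph with node attribute `class`.
#' @export
pairs_to_graph <- function(pairs, node_classes = character(0)) {
  if (nrow(pairs) == 0L) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(g)
  }
  attr_cols <- intersect(c("K", "n", "c", "N", "pvalue", "fdr"), names(pairs))
  edf <- data.frame(from = pairs$target_a, to = pairs$target_b,
                    pairs[, attr_cols, drop = FALSE])
  nodes <- sort(unique(c(pairs$target_a, pairs$target_b)))
  cls <- unname(node_classes[nodes])
  cls[is.na(cls)] <- "unknown"
  vdf <- data.frame(name = nodes, class = cls)
  igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
}

#' Read transcript models from a GTF file
#'
#' Keeps rows of type `exon`; converts coordinates from the GTF 1-based
#' closed convention to the package's 0-based half-open convention.
#'
#' @param path Path to a GTF file with `transcript_id` and `gene_id`
#'   attributes.
#' @return A [transcript_models] table.
#' @export
read_transcripts_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) stop("no exon records in GTF ", path)
  transcript_models(data.frame(
    transcript_id = gr$transcript_id,
    gene_id = gr$gene_id,
    seqnames = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)))
}

#' Write transcript models to a GTF file
#'
#' @param tx A [transcript_models] table (0-based half-open internally;
#'   written as 1-based closed GTF).
#' @param path Output GTF path.
#' @return Invisibly, `path`.
#' @export
write_transcripts_gtf <- function(tx, path) {
  gr <- .tx_exon_granges(tx)
  gr$type <- "exon"
  gr$source <- "cernachill"
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Write a differential-expression result table to TSV
#'
#' @param de Data frame from [run_de()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_de <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
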