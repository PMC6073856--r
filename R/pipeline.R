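# One-call driver that chains the stages on simulated data and writes
# every artefact as TSV/GraphML.  Used by the command-line wrapper and by
# the end-to-end determinism checks: with a fixed seed, two runs produce
# byte-identical outputs.

#' Run the full pipeline on simulated data and write all outputs
#'
#' Simulates a count matrix (mRNA/lncRNA/circRNA/miRNA), a miRNA-target
#' interaction map with planted ceRNA modules, a toy annotation, gene
#' lengths and a category map; then runs differential expression, lncRNA
#' classification, ceRNA pair testing with network extraction, and
#' central plus Wallenius enrichment; and writes counts, samples, DE
#' table, classes, pairs, network (edge TSV + GraphML), enrichment tables
#' and the pathway network into `out_dir`.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed driving every simulation.
#' @param n_features Named feature counts for [simulate_counts()].
#' @param n_per_group Samples per group.
#' @param min_mirnas,max_fdr ceRNA filter rules.
#' @param top_k Components to flag in the ceRNA network.
#' @return Invisibly, a list with the in-memory results of each stage and
#'   the paths written.
#' @export
run_pipeline <- function(out_dir, seed = 1L,
                         n_features = c(mRNA = 600, lncRNA = 200,
                                        circRNA = 60, miRNA = 80),
                         n_per_group = 3,
                         min_mirnas = 5, max_fdr = 0.05, top_k = 3) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)

  # --- simulate ---
  sim <- simulate_counts(n_features = n_features, n_per_group = n_per_group,
                         seed = seed)
  ann <- simulate_annotation(seed = seed + 1L)
  write_counts(sim$counts, pth("counts.tsv"), pth("samples.tsv"))
  write_transcripts_gtf(ann$reference, pth("reference.gtf"))
  write_transcripts_gtf(ann$novel, pth("novel.gtf"))

  # --- differential expression ---
  de <- run_de(sim$counts)
  write_de(de, pth("de.tsv"))

  # --- lncRNA classification ---
  classes <- classify_transcripts(ann$novel, ann$reference)
  utils::write.table(classes, pth("lnc_classes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # --- ceRNA network over DE mRNA/lncRNA/circRNA ---
  # the interaction map is simulated over the DE candidate set itself,
  # with planted ceRNA modules among those candidates
  de_hit <- de[de$status %in% c("up", "down") &
                 de$feature_class != "miRNA", ]
  modules <- list(list(size = 6, shared = 10),
                  list(size = 5, shared = 10),
                  list(size = 4, shared = 10))
  if (nrow(de_hit) < 20L)
    stop("too few DE candidates to build a ceRNA network (", nrow(de_hit), ")")
  int <- simulate_interactions(
    n_mirna = 200, background_degree = 6, planted_modules = modules,
    target_ids = stats::setNames(de_hit$feature_class, de_hit$feature_id),
    seed = seed + 2L)
  pairs <- build_pairs(names(int$classes), int$map, classes = int$classes)
  pairs <- filter_pairs(pairs, min_mirnas = min_mirnas, max_fdr = max_fdr)
  utils::write.table(pairs, pth("cerna_pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  net <- extract_networks(pairs, int$classes, top_k = top_k)
  write_network(net$edges[, setdiff(names(net$edges), "component_id")],
                int$classes, pth("cerna_edges.tsv"), pth("cerna_network.graphml"))
  utils::write.table(net$nodes, pth("cerna_nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # --- enrichment over the mRNA universe ---
  universe <- feature_ids(sim$counts)[sim$counts$feature_class == "mRNA"]
  de_mrna <- intersect(de_hit$feature_id, universe)
  set.seed(seed + 3L)
  lengths <- stats::setNames(
    round(stats::rlnorm(length(universe), meanlog = log(1500), sdlog = 0.6)),
    universe)
  cats <- simulate_categories(universe, n_categories = 30, seed = seed + 4L)
  enr_c <- central_enrich(de_mrna, cats, universe)
  w <- fit_pwf(lengths, universe %in% de_mrna)
  enr_w <- wallenius_enrich(de_mrna, cats, universe, w)
  utils::write.table(enr_c, pth("enrich_central.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(enr_w, pth("enrich_wallenius.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pn <- pathway_network(enr_w, cats, de_mrna)
  utils::write.table(pn$edges, pth("pathway_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  igraph::write_graph(pn$graph, pth("pathway_network.graphml"),
                      format = "graphml")

  invisible(list(de = de, classes = classes, pairs = pairs, network = net,
                 enrich_central = enr_c, enrich_wallenius = enr_w,
                 pathway = pn, out_dir = out_dir))
}
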