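# Competing-endogenous-RNA (ceRNA) pair inference.  Two transcripts that
# share an unexpectedly large number of targeting miRNAs are candidate
# ceRNAs: for each unordered pair the upper-tail hypergeometric
# probability of sharing at least c of N miRNAs is computed, given that
# one partner is targeted by K miRNAs and the other by n.  P-values are
# BH-adjusted across all tested pairs, pairs are filtered on miRNA degree
# and FDR, and the surviving edges are reported as connected components.

#' Shared-miRNA counts for a pair of targets
#'
#' @param a,b Target feature ids (must differ).
#' @param map An [interaction_map].
#' @return Named integer vector `c(K, n, c, N)`: the number of miRNAs
#'   targeting `a`, the number targeting `b`, the number shared, and the
#'   universe size.
#' @export
shared_counts <- function(a, b, map) {
  stopifnot(inherits(map, "interaction_map"))
  if (identical(a, b)) stop("shared_counts: the two targets must differ")
  mir_a <- names(map$targets_of)[vapply(map$targets_of, function(t) a %in% t, TRUE)]
  mir_b <- names(map$targets_of)[vapply(map$targets_of, function(t) b %in% t, TRUE)]
  c(K = length(mir_a), n = length(mir_b),
    c = length(intersect(mir_a, mir_b)), N = length(map$universe))
}

#' Upper-tail hypergeometric p-value for a ceRNA pair
#'
#' Probability that two targets, regulated by K and n of N miRNAs
#' respectively, share at least c miRNAs under random assignment:
#' P = sum over i from c to min(K, n) of
#' choose(K, i) choose(N - K, n - i) / choose(N, n).
#' Evaluated in log space (log-gamma binomials with log-sum-exp), so
#' universes of hundreds of miRNAs do not overflow.  Vectorised over its
#' arguments.
#'
#' @param N Universe size (>= 1).
#' @param K,n miRNA degrees of the two targets (0 <= K, n <= N).
#' @param c Shared count (0 <= c <= min(K, n)).
#' @return P-value(s) in `[0, 1]`.
#' @export
cerna_pvalue <- function(N, K, n, c) {
  args <- cbind(N = N, K = K, n = n, c = c)   # recycles
  N <- args[, "N"]; K <- args[, "K"]; n <- args[, "n"]; c <- args[, "c"]
  if (any(N < 1) || any(K < 0) || any(n < 0) || any(c < 0))
    stop("cerna_pvalue: counts must be non-negative and N >= 1")
  if (any(K > N) || any(n > N))
    stop("cerna_pvalue: K and n cannot exceed N")
  if (any(c > pmin(K, n)))
    stop("cerna_pvalue: c cannot exceed min(K, n)")
  vapply(seq_along(N), function(j) {
    i <- seq.int(c[j], min(K[j], n[j]))
    lt <- lchoose(K[j], i) + lchoose(N[j] - K[j], n[j] - i) -
      lchoose(N[j], n[j])
    m <- max(lt)
    min(1, exp(m + log(sum(exp(lt - m)))))
  }, numeric(1))
}

# logical incidence matrix: candidate targets x universe miRNAs
.target_incidence <- function(candidates, map) {
  mir_ids <- names(map$targets_of)
  inc <- matrix(FALSE, nrow = length(candidates), ncol = length(mir_ids),
                dimnames = list(candidates, mir_ids))
  for (j in seq_along(mir_ids)) {
    hit <- map$targets_of[[j]]
    inc[candidates %in% hit, j] <- TRUE
  }
  inc
}

#' Enumerate and test all candidate ceRNA pairs
#'
#' All unordered pairs of candidates that share at least `min_shared`
#' miRNAs are tested with [cerna_pvalue()]; pairs sharing none have p = 1
#' by construction and are excluded before BH adjustment, so the BH
#' family is the set of tested pairs (m = number of rows returned).
#' Output order is deterministic (lexicographic on the pair ids, with
#' `target_a < target_b`).
#'
#' @param candidates Character vector of candidate feature ids (>= 2), or
#'   a named character vector of classes keyed by feature id.
#' @param map An [interaction_map].
#' @param min_shared Minimum shared-miRNA count for a pair to be tested
#'   (default 1).
#' @param classes Optional named vector feature id -> class (overrides
#'   names of `candidates`).
#' @param pair_types Optional character vector of allowed unordered class
#'   combinations, each written `"classA-classB"` (e.g.
#'   `c("lncRNA-mRNA", "circRNA-mRNA")`); default tests every
#'   combination.
#' @return Data frame of tested pairs: `target_a`, `target_b`, `class_a`,
#'   `class_b`, `K`, `n`, `c`, `N`, `pvalue`, `fdr`.
#' @export
build_pairs <- function(candidates, map, min_shared = 1, classes = NULL,
                        pair_types = NULL) {
  stopifnot(inherits(map, "interaction_map"))
  if (is.null(classes) && !is.null(names(candidates)))
    classes <- candidates
  ids <- if (!is.null(names(candidates))) names(candidates) else candidates
  ids <- sort(unique(as.character(ids)))
  empty <- data.frame(target_a = character(0), target_b = character(0),
                      class_a = character(0), class_b = character(0),
                      K = integer(0), n = integer(0), c = integer(0),
                      N = integer(0), pvalue = numeric(0), fdr = numeric(0))
  if (length(ids) < 2L) {
    warning("fewer than 2 candidates; no ceRNA pairs to test")
    return(empty)
  }
  inc <- .target_incidence(ids, map)
  deg <- rowSums(inc)
  cshared <- tcrossprod(inc * 1)              # shared miRNA counts
  Nuni <- length(map$universe)
  ut <- which(upper.tri(cshared) & cshared >= min_shared, arr.ind = TRUE)
  if (nrow(ut) == 0L) return(empty)
  pairs <- data.frame(
    target_a = ids[ut[, 1]], target_b = ids[ut[, 2]],
    K = as.integer(deg[ut[, 1]]), n = as.integer(deg[ut[, 2]]),
    c = as.integer(cshared[ut]), N = Nuni)
  cls <- function(x) {
    if (is.null(classes)) return(rep("unknown", length(x)))
    out <- unname(classes[x])
    out[is.na(out)] <- "unknown"
    out
  }
  pairs$class_a <- cls(pairs$target_a)
  pairs$class_b <- cls(pairs$target_b)
  if (!is.null(pair_types)) {
    norm <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "-")
    keep <- norm(pairs$class_a, pairs$class_b) %in%
      vapply(strsplit(pair_types, "-"), function(p) norm(p[1], p[2]), "")
    pairs <- pairs[keep, , drop = FALSE]
    if (nrow(pairs) == 0L) return(empty)
  }
  pairs <- pairs[order(pairs$target_a, pairs$target_b), , drop = FALSE]
  pairs$pvalue <- cerna_pvalue(pairs$N, pairs$K, pairs$n, pairs$c)
  pairs$fdr <- bh_adjust(pairs$pvalue)
  rownames(pairs) <- NULL
  pairs[, c("target_a", "target_b", "class_a", "class_b",
            "K", "n", "c", "N", "pvalue", "fdr")]
}

#' Apply the ceRNA filter rules
#'
#' A pair passes when both endpoints are targeted by at least
#' `min_mirnas` miRNAs (`min(K, n) >= min_mirnas`; set
#' `symmetric = FALSE` for the literal one-sided rule on the candidate
#' partner only) and its FDR is strictly below `max_fdr`.
#'
#' @param pairs Data frame from [build_pairs()].
#' @param min_mirnas Minimum miRNA degree (default 5).
#' @param max_fdr FDR cutoff, strict inequality (default 0.05).
#' @param symmetric Apply the degree rule to both endpoints (default
#'   `TRUE`).
#' @return `pairs` with a logical `passes_filters` column.
#' @export
filter_pairs <- function(pairs, min_mirnas = 5, max_fdr = 0.05,
                         symmetric = TRUE) {
  if (nrow(pairs) == 0L) {
    pairs$passes_filters <- logical(0)
    return(pairs)
  }
  deg_ok <- if (symmetric) pmin(pairs$K, pairs$n) >= min_mirnas else
    pairs$n >= min_mirnas
  pairs$passes_filters <- deg_ok & pairs$fdr < max_fdr
  pairs
}

#' Extract ceRNA networks as ranked connected components
#'
#' Builds the undirected graph of passing pairs and reports its connected
#' components, ranked by node count (ties broken by edge count, then by
#' lexicographically smallest node id).  All components are reported; the
#' `top_k` largest are flagged.
#'
#' @param pairs Data frame from [filter_pairs()]; only rows with
#'   `passes_filters` contribute edges (all rows are used when the column
#'   is absent).
#' @param node_classes Named character vector node id -> class.
#' @param top_k Number of top components to flag (default 3).
#' @return A list with `nodes` (data frame `node`, `class`,
#'   `component_id`, `in_top`), `edges` (the passing pairs with
#'   `component_id`), `components` (data frame `component_id`,
#'   `n_nodes`, `n_edges`), and `graph` (the igraph object).
#' @export
extract_networks <- function(pairs, node_classes = character(0), top_k = 3) {
  if ("passes_filters" %in% names(pairs))
    pairs <- pairs[pairs$passes_filters, , drop = FALSE]
  g <- pairs_to_graph(pairs, node_classes)
  if (igraph::vcount(g) == 0L) {
    return(list(nodes = data.frame(node = character(0), class = character(0),
                                   component_id = integer(0), in_top = logical(0)),
                edges = cbind(pairs, component_id = integer(0)),
                components = data.frame(component_id = integer(0),
                                        n_nodes = integer(0), n_edges = integer(0)),
                graph = g))
  }
  memb <- igraph::components(g)$membership
  names_v <- igraph::V(g)$name
  # rank components: node count desc, edge count desc, smallest node id
  comp_nodes <- split(names_v, memb)
  n_nodes <- lengths(comp_nodes)
  edge_memb <- memb[pairs$target_a]
  n_edges <- vapply(names(comp_nodes), function(k)
    sum(edge_memb == as.integer(k)), 0L)
  min_node <- vapply(comp_nodes, min, "")
  ord <- order(-n_nodes, -n_edges, min_node)
  rank_of <- stats::setNames(seq_along(ord), names(comp_nodes)[ord])
  comp_id <- unname(rank_of[as.character(memb)])
  names(comp_id) <- names_v
  cls <- unname(node_classes[names_v])
  cls[is.na(cls)] <- "unknown"
  nodes <- data.frame(node = names_v, class = cls,
                      component_id = comp_id,
                      in_top = comp_id <= top_k)
  nodes <- nodes[order(nodes$component_id, nodes$node), ]
  rownames(nodes) <- NULL
  edges <- pairs
  edges$component_id <- unname(comp_id[pairs$target_a])
  comps <- data.frame(component_id = seq_along(ord),
                      n_nodes = as.integer(n_nodes[ord]),
                      n_edges = as.integer(n_edges[ord]))
  igraph::V(g)$component_id <- unname(comp_id)
  list(nodes = nodes, edges = edges, components = comps, graph = g)
}
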