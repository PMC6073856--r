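# Category (GO/KEGG-style) enrichment of differentially expressed gene
# sets.  Two variants: the central hypergeometric test, and a
# length-bias-corrected test using the Wallenius non-central
# hypergeometric distribution, where the odds of sampling a gene scale
# with an isotonic fit of P(DE | transcript length).  Also builds the
# pathway-sharing network of significant categories.

#' Central hypergeometric category enrichment
#'
#' For each category, the upper-tail hypergeometric probability of
#' observing at least k DE genes in the category, given K_cat category
#' genes in a universe of N_u genes of which n_de are DE.  Categories are
#' trimmed to the universe; BH adjustment is across the tested
#' categories.
#'
#' @param de_set Character vector of DE gene ids (subset of `universe`).
#' @param categories Named list category id -> gene ids.
#' @param universe Character vector of all testable gene ids.
#' @return Data frame: `category_id`, `k`, `K_cat`, `n_de`, `N_u`,
#'   `odds` (1 for the central test), `pvalue`, `padj`, `method`.
#' @export
central_enrich <- function(de_set, categories, universe) {
  .check_enrich_inputs(de_set, categories, universe)
  n_de <- length(unique(de_set))
  N_u <- length(unique(universe))
  res <- lapply(names(categories), function(id) {
    cat_genes <- intersect(categories[[id]], universe)
    k <- length(intersect(cat_genes, de_set))
    data.frame(category_id = id, k = k, K_cat = length(cat_genes),
               n_de = n_de, N_u = N_u, odds = 1,
               pvalue = cerna_pvalue(N_u, length(cat_genes), n_de, k))
  })
  out <- do.call(rbind, res)
  out$padj <- bh_adjust(out$pvalue)
  out$method <- "central"
  out <- out[order(out$category_id), ]
  rownames(out) <- NULL
  out
}

.check_enrich_inputs <- function(de_set, categories, universe) {
  if (length(universe) == 0L) stop("gene universe is empty")
  if (length(categories) == 0L) stop("no categories supplied")
  extra <- setdiff(de_set, universe)
  if (length(extra))
    stop("DE genes outside the universe: ",
         paste(utils::head(extra, 5), collapse = ", "))
}

#' Isotonic probability-weighting function for length bias
#'
#' Fits a monotone non-decreasing estimate of P(DE | length) by isotonic
#' regression of the DE indicator on transcript length, then rescales the
#' fitted values to mean 1 over the universe.  These weights feed the
#' Wallenius test: longer transcripts that are more likely to be called
#' DE for length alone receive proportionally larger sampling odds, which
#' the non-central test then discounts.
#'
#' @param lengths Positive numeric vector of gene/transcript lengths,
#'   named by gene id.
#' @param de_flags Logical vector (same length/order) marking DE genes.
#' @return Named numeric weight vector with mean 1 (a constant 1 with a
#'   warning when all lengths are equal).
#' @export
fit_pwf <- function(lengths, de_flags) {
  if (any(lengths <= 0)) stop("lengths must be positive")
  if (length(lengths) != length(de_flags))
    stop("lengths and de_flags must have equal length")
  de_flags <- as.logical(de_flags)
  if (!any(de_flags) || all(de_flags))
    stop("need at least one DE and one non-DE gene to fit the weight function")
  ids <- names(lengths)
  if (length(unique(lengths)) == 1L) {
    warning("all lengths equal; using constant weight 1")
    return(stats::setNames(rep(1, length(lengths)), ids))
  }
  ord <- order(lengths)
  iso <- stats::isoreg(lengths[ord], as.numeric(de_flags)[ord])
  w <- numeric(length(lengths))
  w[ord] <- iso$yf
  w <- pmax(w, 1e-6)          # avoid zero sampling odds at the short end
  w <- w / mean(w)
  stats::setNames(w, ids)
}

# Wallenius non-central hypergeometric point mass.  m1 "white" items
# with odds w against m2 "black" items, n draws without replacement, x
# white successes.  The textbook integral representation
#   P(X = x) = C(m1,x) C(m2,n-x) * Int_0^1 (1-t^(w/D))^x (1-t^(1/D))^(n-x) dt
# with D = w (m1 - x) + (m2 - (n - x)) concentrates all of its mass in an
# exponentially narrow neighbourhood of t = 0 when D is large, which
# defeats quadrature on [0, 1] directly.  Substituting t = s^D gives the
# equivalent beta-kernel form
#   P(X = x) = C(m1,x) C(m2,n-x) * D * Int_0^1 s^(D-1) (1-s^w)^x (1-s)^(n-x) ds
# whose integrand is smooth and unimodal; it is evaluated in log space
# (peak value factored out) with adaptive quadrature, abs tol 1e-10 per
# rescaled mass term.  At w = 1 the integral is an exact beta function
# and the expression reduces to the central hypergeometric pmf.
.dwallenius <- function(x, m1, m2, n, w, abs_tol = 1e-10) {
  if (x < max(0, n - m2) || x > min(m1, n)) return(0)
  D <- w * (m1 - x) + (m2 - (n - x))
  if (D <= 0) return(1)       # whole urn drawn: the outcome is certain
  logg <- function(s) {
    out <- (D - 1) * log(s)
    if (x > 0) out <- out + x * log1p(-s^w)
    if (n - x > 0) out <- out + (n - x) * log1p(-s)
    out[s <= 0 | s >= 1] <- -Inf
    out
  }
  opt <- stats::optimize(logg, c(1e-12, 1 - 1e-12), maximum = TRUE)
  gmax <- opt$objective
  if (!is.finite(gmax)) return(0)
  int <- stats::integrate(function(s) exp(logg(s) - gmax), 0, 1,
                          abs.tol = abs_tol, rel.tol = 1e-10,
                          subdivisions = 200L, stop.on.error = FALSE)
  if (!(int$message %in% c("OK", "roundoff error was detected")))
    stop("Wallenius quadrature did not converge: ", int$message,
         " (abs.error = ", format(int$abs.error), ")")
  exp(lchoose(m1, x) + lchoose(m2, n - x) + log(D) + gmax + log(int$value))
}

#' Upper-tail Wallenius non-central hypergeometric probability
#'
#' P(X >= k) when n items are drawn without replacement from m1 items
#' with sampling odds `odds` and m2 items with odds 1 (biased urn).
#' At `odds = 1` this reduces to the central hypergeometric tail.
#'
#' @param k Threshold count.
#' @param m1 Number of odds-weighted ("category") items.
#' @param m2 Number of remaining items.
#' @param n Number of draws.
#' @param odds Positive odds ratio.
#' @return P(X >= k) in `[0, 1]`.
#' @export
wallenius_tail <- function(k, m1, m2, n, odds) {
  if (odds <= 0) stop("odds must be positive")
  if (n > m1 + m2) stop("cannot draw more items than the urn holds")
  hi <- min(m1, n)
  if (k > hi) return(0)
  lo <- max(k, max(0, n - m2))
  if (lo > hi) return(0)
  p <- sum(vapply(lo:hi, .dwallenius, numeric(1),
                  m1 = m1, m2 = m2, n = n, w = odds))
  min(1, max(0, p))
}

#' Wallenius (length-bias-corrected) category enrichment
#'
#' Per category, the odds parameter is the mean probability weight inside
#' the category divided by the mean weight outside (the standard
#' two-weight-class reduction of the full per-gene-weight distribution),
#' and the p-value is the upper-tail Wallenius probability of at least k
#' DE genes in n_de draws.  BH adjustment across categories.
#'
#' @inheritParams central_enrich
#' @param weights Named weight vector over the universe from
#'   [fit_pwf()].
#' @return Data frame as in [central_enrich()] with `method =
#'   "wallenius"` and the per-category `odds`.
#' @export
wallenius_enrich <- function(de_set, categories, universe, weights) {
  .check_enrich_inputs(de_set, categories, universe)
  missing_w <- setdiff(universe, names(weights))
  if (length(missing_w))
    stop("weights missing for ", length(missing_w), " universe gene(s)")
  n_de <- length(unique(de_set))
  N_u <- length(unique(universe))
  res <- lapply(names(categories), function(id) {
    cat_genes <- intersect(categories[[id]], universe)
    out_genes <- setdiff(universe, cat_genes)
    k <- length(intersect(cat_genes, de_set))
    odds <- if (length(cat_genes) == 0L || length(out_genes) == 0L) 1 else
      mean(weights[cat_genes]) / mean(weights[out_genes])
    data.frame(category_id = id, k = k, K_cat = length(cat_genes),
               n_de = n_de, N_u = N_u, odds = odds,
               pvalue = wallenius_tail(k, length(cat_genes),
                                       length(out_genes), n_de, odds))
  })
  out <- do.call(rbind, res)
  out$padj <- bh_adjust(out$pvalue)
  out$method <- "wallenius"
  out <- out[order(out$category_id), ]
  rownames(out) <- NULL
  out
}

#' Pathway-sharing network of significant categories
#'
#' Nodes are the categories significant at `padj_cutoff` (optionally only
#' the `top_n` most significant); an undirected edge joins two categories
#' weighted by the number of significant (DE) genes they share, and edges
#' with weight below `min_shared` are dropped.
#'
#' @param results Enrichment results from [central_enrich()] or
#'   [wallenius_enrich()].
#' @param categories Named list category id -> gene ids.
#' @param de_set Character vector of DE gene ids.
#' @param padj_cutoff Significance cutoff for nodes (default 0.05).
#' @param min_shared Minimum shared-gene count for an edge (default 1).
#' @param top_n Optional cap on the number of most-significant categories
#'   used as nodes.
#' @return A list with `nodes` (data frame `category_id`, `padj`,
#'   `n_de_genes`), `edges` (data frame `category_a`, `category_b`,
#'   `shared`) and `graph` (igraph object with edge attribute `shared`).
#' @export
pathway_network <- function(results, categories, de_set,
                            padj_cutoff = 0.05, min_shared = 1,
                            top_n = NULL) {
  sig <- results[results$padj < padj_cutoff, , drop = FALSE]
  sig <- sig[order(sig$pvalue, sig$category_id), , drop = FALSE]
  if (!is.null(top_n)) sig <- utils::head(sig, top_n)
  ids <- sort(sig$category_id)
  de_in <- lapply(stats::setNames(ids, ids),
                  function(id) intersect(categories[[id]], de_set))
  nodes <- data.frame(category_id = ids,
                      padj = sig$padj[match(ids, sig$category_id)],
                      n_de_genes = lengths(de_in)[ids])
  rownames(nodes) <- NULL
  edges <- data.frame(category_a = character(0), category_b = character(0),
                      shared = integer(0))
  if (length(ids) >= 2L) {
    cmb <- utils::combn(ids, 2L)
    shared <- vapply(seq_len(ncol(cmb)), function(j)
      length(intersect(de_in[[cmb[1L, j]]], de_in[[cmb[2L, j]]])), 0L)
    keep <- shared >= min_shared
    edges <- data.frame(category_a = cmb[1L, keep],
                        category_b = cmb[2L, keep],
                        shared = shared[keep])
  }
  g <- if (nrow(nodes) > 0L) {
    igraph::graph_from_data_frame(
      if (nrow(edges)) data.frame(from = edges$category_a,
                                  to = edges$category_b,
                                  shared = edges$shared) else
        data.frame(from = character(0), to = character(0),
                   shared = integer(0)),
      directed = FALSE, vertices = data.frame(name = nodes$category_id))
  } else igraph::make_empty_graph(0, directed = FALSE)
  list(nodes = nodes, edges = edges, graph = g)
}
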