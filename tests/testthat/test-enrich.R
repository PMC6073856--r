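test_that("central enrichment handles degenerate and exact cases", {
  universe <- paste0("g", 1:20)
  de <- paste0("g", 1:5)
  # category identical to the DE set with universe = DE set: forced
  # overlap, p = 1
  res <- central_enrich(de, list(c1 = de), de)
  expect_equal(res$pvalue, 1, tolerance = 1e-12)
  # the 1126/15504 small case: K_cat = 5, n_de = 5, k = 3 in N_u = 20
  cats <- list(c1 = c("g1", "g2", "g3", "g18", "g19"))
  res <- central_enrich(de, cats, universe)
  expect_identical(res$k, 3L)
  expect_equal(res$pvalue, 1126 / 15504, tolerance = 1e-12)
  # disjoint category: k = 0 gives p = 1
  res0 <- central_enrich(de, list(c1 = paste0("g", 11:14)), universe)
  expect_equal(res0$pvalue, 1, tolerance = 1e-12)
  # genes outside the universe are trimmed before counting
  res_t <- central_enrich(de, list(c1 = c("g1", "not_a_gene")), universe)
  expect_identical(res_t$K_cat, 1L)
  expect_error(central_enrich(de, cats, character(0)), "empty")
  expect_error(central_enrich("zzz", cats, universe), "outside")
})

test_that("the isotonic weight function is monotone with mean one", {
  set.seed(51)
  n <- 400
  lens <- sort(runif(n, 200, 5000))
  # DE probability increasing in length
  de <- runif(n) < (0.05 + 0.4 * (lens - 200) / 4800)
  w <- fit_pwf(setNames(lens, paste0("g", 1:n)), de)
  expect_true(all(diff(w[order(lens)]) >= -1e-12))
  expect_equal(mean(w), 1, tolerance = 1e-9)
  # no length effect: bulk of the weights near 1, and the induced odds
  # for an arbitrary half-split category stay near 1
  de0 <- runif(n) < 0.2
  w0 <- fit_pwf(setNames(lens, paste0("g", 1:n)), de0)
  expect_lt(diff(quantile(w0, c(0.1, 0.9))), 0.8)
  half <- sample(names(w0), n / 2)
  odds <- mean(w0[half]) / mean(w0[setdiff(names(w0), half)])
  expect_lt(abs(odds - 1), 0.25)
  expect_equal(mean(w0), 1, tolerance = 1e-9)
  # constant lengths fall back to weight 1 with a warning
  expect_warning(wc <- fit_pwf(setNames(rep(100, 4), paste0("g", 1:4)),
                               c(TRUE, FALSE, TRUE, FALSE)), "constant|equal")
  expect_identical(unname(wc), rep(1, 4))
  expect_error(fit_pwf(c(a = -1, b = 2), c(TRUE, FALSE)), "positive")
  expect_error(fit_pwf(c(a = 1, b = 2), c(TRUE, TRUE)), "non-DE")
})

test_that("Wallenius at odds one reduces to the central hypergeometric", {
  set.seed(52)
  for (r in 1:40) {
    N_u <- sample(10:50, 1)
    K_cat <- sample(1:N_u, 1)
    n_de <- sample(1:N_u, 1)
    k <- sample(0:min(K_cat, n_de), 1)
    if (n_de - k > N_u - K_cat) k <- max(0, n_de - (N_u - K_cat))
    expect_equal(wallenius_tail(k, K_cat, N_u - K_cat, n_de, 1),
                 cerna_pvalue(N_u, K_cat, n_de, k), tolerance = 1e-6)
  }
})

test_that("Wallenius point masses sum to one and split into clean tails", {
  grid <- expand.grid(m1 = c(3, 8), m2 = c(5, 22), n = c(4, 10),
                      w = c(0.3, 1, 2, 5))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    if (g$n > g$m1 + g$m2) next
    lo <- max(0, g$n - g$m2)
    hi <- min(g$m1, g$n)
    masses <- vapply(lo:hi, cernachill:::.dwallenius, numeric(1),
                     m1 = g$m1, m2 = g$m2, n = g$n, w = g$w)
    expect_equal(sum(masses), 1, tolerance = 1e-9)
    for (k in lo:hi) {
      upper <- wallenius_tail(k, g$m1, g$m2, g$n, g$w)
      expect_equal(upper, sum(masses[(k - lo + 1):length(masses)]),
                   tolerance = 1e-9)
    }
  }
})

test_that("the Wallenius tail matches a biased-urn Monte-Carlo oracle", {
  set.seed(53)
  draws <- rwallenius_urn(1e5, m1 = 8, m2 = 22, n = 10, w = 2)
  for (k in 3:6) {
    mc <- mean(draws >= k)
    se <- sqrt(mc * (1 - mc) / 1e5)
    expect_lt(abs(wallenius_tail(k, 8, 22, 10, 2) - mc), 3 * se + 1e-12)
  }
})

test_that("extreme odds saturate the tail at its logical limits", {
  # huge odds with k = min(K_cat, n_de): the category is drawn first, p -> 1
  expect_equal(wallenius_tail(5, 5, 20, 10, 1e6), 1, tolerance = 1e-3)
  # k above the support is impossible
  expect_identical(wallenius_tail(6, 5, 20, 10, 2), 0)
})

test_that("wallenius_enrich agrees with central_enrich when weights are flat", {
  universe <- paste0("g", 1:30)
  de <- paste0("g", 1:8)
  cats <- simulate_categories(universe, n_categories = 8,
                              size_range = c(4, 12), seed = 54)
  w <- setNames(rep(1, 30), universe)
  rc <- central_enrich(de, cats, universe)
  rw <- wallenius_enrich(de, cats, universe, w)
  expect_equal(rw$pvalue, rc$pvalue, tolerance = 1e-6)
  expect_equal(rw$odds, rep(1, 8))
  expect_identical(rw$method, rep("wallenius", 8))
  # results invariant to category input order
  rw2 <- wallenius_enrich(de, rev(cats), universe, w)
  expect_equal(rw2, rw)
})

test_that("the pathway network shares significant genes across categories", {
  res <- data.frame(category_id = c("p1", "p2", "p3"),
                    k = c(4, 4, 2), K_cat = 8, n_de = 10, N_u = 100,
                    odds = 1, pvalue = c(1e-5, 2e-5, 1e-4),
                    padj = c(3e-5, 3e-5, 1e-4), method = "central")
  cats <- list(p1 = c("a", "b", "c", "d"), p2 = c("b", "c", "d", "e"),
               p3 = c("x", "y"))
  de <- c("a", "b", "c", "d", "e", "x", "y")
  pn <- pathway_network(res, cats, de)
  expect_identical(nrow(pn$nodes), 3L)
  # p1 and p2 share 3 DE genes
  e12 <- pn$edges[pn$edges$category_a == "p1" & pn$edges$category_b == "p2", ]
  expect_identical(e12$shared, 3L)
  # p3 shares nothing: isolated node in the graph
  expect_identical(igraph::degree(pn$graph)[["p3"]], 0)
  # raising min_shared drops the weight-3 edge
  pn4 <- pathway_network(res, cats, de, min_shared = 4)
  expect_identical(nrow(pn4$edges), 0L)
  # cutoff excludes non-significant nodes
  pn_cut <- pathway_network(res, cats, de, padj_cutoff = 5e-5)
  expect_setequal(pn_cut$nodes$category_id, c("p1", "p2"))
})
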