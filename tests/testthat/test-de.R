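test_that("median-of-ratios size factors behave as defined", {
  # identical columns -> all factors 1
  m <- matrix(c(10L, 30L, 10L, 30L), 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_equal(unname(estimate_size_factors(m)), c(1, 1))
  # hand-computed example
  cm <- toy_cm()  # counts [[10,20],[30,60]]
  sf <- estimate_size_factors(cm)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-3)
  # scale equivariance: doubling one column doubles its factor relative
  # to the others (the row geometric means absorb a common sqrt(2))
  m2 <- cm$counts
  m2[, 2] <- m2[, 2] * 2L
  sf2 <- estimate_size_factors(m2)
  expect_equal(unname(sf2[2] / sf2[1]), unname(2 * sf[2] / sf[1]),
               tolerance = 1e-12)
  # no all-positive feature -> error
  m3 <- matrix(c(0L, 1L, 2L, 0L), 2,
               dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(estimate_size_factors(m3), "all-positive")
})

test_that("size factors agree with an independent implementation", {
  sim <- simulate_counts(n_features = c(mRNA = 300), n_per_group = 3,
                         seed = 21)
  ours <- estimate_size_factors(sim$counts)
  ref <- DESeq2::estimateSizeFactorsForMatrix(sim$counts$counts)
  # DESeq2 takes the median of log ratios (a geometric median for even
  # feature counts), so agreement is close but not exact
  expect_equal(unname(ours), unname(ref), tolerance = 1e-3)
})

test_that("dispersion estimation recovers the simulated dispersion", {
  sim <- simulate_counts(n_features = c(mRNA = 600), n_per_group = 50,
                         mu = 100, frac_de = 0, dispersion = 0.1, seed = 22)
  sf <- estimate_size_factors(sim$counts)
  disp <- estimate_dispersion(sim$counts, sf, moderate = FALSE)
  expect_gt(median(disp, na.rm = TRUE), 0.05)
  expect_lt(median(disp, na.rm = TRUE), 0.2)
})

test_that("Poisson-like counts give floor-level dispersions", {
  sim <- simulate_counts(n_features = c(mRNA = 400), n_per_group = 20,
                         mu = 500, frac_de = 0, dispersion = 1e-8,
                         size_factor_range = c(1, 1), seed = 23)
  sf <- estimate_size_factors(sim$counts)
  disp <- estimate_dispersion(sim$counts, sf, moderate = FALSE)
  # variance/mean near 1 => (var - mean)/mean^2 near 0; half the features
  # land exactly on the floor
  expect_lt(median(disp, na.rm = TRUE), 0.005)
})

test_that("all-zero features are flagged untestable and untested", {
  m <- rbind(g1 = c(5L, 6L, 4L, 7L), g2 = c(0L, 0L, 0L, 0L),
             g3 = c(9L, 11L, 30L, 35L))
  colnames(m) <- c("c1", "c2", "t1", "t2")
  cm <- count_matrix(m, "mRNA", rep(c("control", "treatment"), each = 2))
  sf <- rep(1, 4)
  disp <- estimate_dispersion(cm, sf)
  expect_true(is.na(disp["g2"]))
  res <- nb_test(cm, sf, disp)
  expect_identical(res$status[res$feature_id == "g2"], "untested")
  expect_true(is.na(res$pvalue[res$feature_id == "g2"]))
})

test_that("dispersion estimation refuses single-replicate groups", {
  m <- matrix(c(5L, 6L, 4L, 7L), 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  cm <- count_matrix(m, "mRNA", c("control", "treatment"))
  expect_error(estimate_dispersion(cm, c(1, 1)), ">= 2 samples")
})

test_that("the Wald test is symmetric and null-centred", {
  # identical group totals, equal size factors -> zero fold-change, p ~ 1
  m <- cbind(c1 = c(10L, 40L), c2 = c(20L, 35L),
             t1 = c(20L, 35L), t2 = c(10L, 40L))
  rownames(m) <- c("g1", "g2")
  cm <- count_matrix(m, "mRNA", rep(c("control", "treatment"), each = 2))
  res <- nb_test(cm, rep(1, 4), c(g1 = 0.1, g2 = 0.1))
  expect_true(all(abs(res$log2fc) < 1e-6))
  expect_true(all(res$pvalue > 0.5))
})

test_that("relabelling groups flips fold-changes and keeps p-values", {
  sim <- simulate_counts(n_features = c(mRNA = 200), n_per_group = 3,
                         frac_de = 0.2, seed = 24)
  cm <- sim$counts
  flipped <- count_matrix(cm$counts, cm$feature_class,
                          ifelse(cm$group == "control", "treatment", "control"))
  sf <- estimate_size_factors(cm)
  d1 <- estimate_dispersion(cm, sf)
  d2 <- estimate_dispersion(flipped, sf)
  r1 <- nb_test(cm, sf, d1)
  r2 <- nb_test(flipped, sf, d2)
  ok <- !is.na(r1$pvalue)
  expect_equal(r1$log2fc[ok], -r2$log2fc[ok], tolerance = 1e-9)
  expect_equal(r1$pvalue[ok], r2$pvalue[ok], tolerance = 1e-9)
})

test_that("planted fold-changes are estimated accurately", {
  sim <- simulate_counts(n_features = c(mRNA = 2000), n_per_group = 3,
                         mu = 100, mean_log2fc = 2, frac_de = 0.1,
                         dispersion = 0.1, seed = 25)
  res <- run_de(sim$counts)
  planted <- sim$truth$de_features
  est <- res$log2fc[match(planted$feature_id, res$feature_id)]
  expect_gt(median(abs(est)), 1.6)
  expect_lt(median(abs(est)), 2.4)
  expect_gt(cor(est, planted$log2fc), 0.9)
})

test_that("BH adjustment matches hand-computed step-up examples", {
  expect_equal(bh_adjust(0.05), 0.05)                      # m = 1 identity
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bh_adjust(c(0.01, 1.0)), c(0.02, 1.0))
  expect_error(bh_adjust(c(0.1, NaN)), "NA")
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_identical(bh_adjust(numeric(0)), numeric(0))
})

test_that("BH adjustment equals the brute-force definition on random vectors", {
  set.seed(31)
  for (r in 1:100) {
    p <- runif(sample(1:200, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_brute(p), tolerance = 1e-12)
  }
})

test_that("class-specific significance rules are applied literally", {
  res <- data.frame(
    feature_id = paste0("f", 1:5),
    feature_class = c("mRNA", "mRNA", "miRNA", "lncRNA", "circRNA"),
    log2fc = c(1.5, 0.5, 0.2, -3, 2),
    padj = c(0.005, 0.005, 0.03, 0.05, 0.011),
    status = "not_de")
  out <- call_de(res)
  expect_identical(out$status,
                   c("up",      # padj < 0.01 and |lfc| > 1
                     "not_de",  # |lfc| <= 1 despite small padj
                     "up",      # miRNA: padj < 0.05 alone, sign picks up
                     "not_de",  # lncRNA at padj boundary 0.05 >= 0.01
                     "not_de")) # circRNA padj 0.011 >= 0.01
  expect_error(call_de(transform(res, feature_class = "tRNA")), "class")
})

test_that("null false-positive rate at the DE thresholds stays nominal", {
  sim <- simulate_counts(n_features = c(mRNA = 2000), n_per_group = 3,
                         frac_de = 0, dispersion = 0.1, seed = 26)
  res <- run_de(sim$counts)
  frac <- mean(res$status %in% c("up", "down"))
  mc_se <- sqrt(0.01 * 0.99 / 2000)
  expect_lte(frac, 0.01 + 3 * mc_se)
})
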