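# Negative-binomial differential expression for two-group count data:
# median-of-ratios normalisation, method-of-moments dispersion with
# trend-based moderation, a Wald test on the log mean ratio, BH FDR, and
# the class-specific significance rules (padj < 0.01 and |log2FC| > 1 for
# mRNA/lncRNA/circRNA; padj < 0.05 for miRNA).

#' Median-of-ratios size factors
#'
#' For each sample j, the factor is the median over features i (restricted
#' to features with an all-positive row, i.e. a positive geometric mean)
#' of counts\[i, j\] / geometric_mean(counts\[i, \]).
#'
#' @param cm A [count_matrix] or a non-negative count matrix.
#' @return Named positive numeric vector, one factor per sample.
#' @export
estimate_size_factors <- function(cm) {
  m <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  log_gm <- rowMeans(log(m))
  ok <- is.finite(log_gm)
  if (!any(ok))
    stop("cannot estimate size factors: no feature has all-positive counts")
  sf <- apply(m[ok, , drop = FALSE], 2, function(col)
    stats::median(exp(log(col) - log_gm[ok])))
  if (any(!is.finite(sf)) || any(sf <= 0))
    stop("size factor estimation failed (non-positive factor)")
  sf
}

#' Per-feature NB dispersion with optional trend moderation
#'
#' Raw estimates are method-of-moments on size-factor-normalised counts,
#' pooled within groups: alpha_i = max(floor, (var_i - mean_i) / mean_i^2)
#' with the within-group pooled variance and the mean of squared group
#' means in the denominator.  With few replicates these estimates are very
#' noisy (about n - 2 degrees of freedom each), so by default they are
#' shrunk towards a mean-dispersion trend fitted across all features
#' (a gamma GLM of the form a0 + a1 / mean, falling back to the median
#' when the fit is degenerate), with a prior weight of `prior_df` pseudo
#' degrees of freedom.  The moderated values carry a `t_df` attribute
#' (residual df + prior df) that [nb_test()] uses as the reference
#' degrees of freedom for the Wald statistic.
#'
#' @param cm A [count_matrix].
#' @param size_factors Positive per-sample factors from
#'   [estimate_size_factors()].
#' @param floor Lower bound for the dispersion (default 1e-8).
#' @param moderate Shrink towards the fitted trend (default `TRUE`).
#' @param prior_df Prior degrees of freedom of the trend (default 40).
#' @return Named numeric vector of dispersions, `NA` for untestable
#'   (all-zero) features, with attributes `raw`, `trend`, `df` and
#'   `t_df`.
#' @export
estimate_dispersion <- function(cm, size_factors, floor = 1e-8,
                                moderate = TRUE, prior_df = 40) {
  stopifnot(inherits(cm, "count_matrix"))
  if (any(size_factors <= 0)) stop("size factors must be positive")
  grp <- cm$group
  n_c <- sum(grp == "control"); n_t <- sum(grp == "treatment")
  if (n_c < 2L || n_t < 2L)
    stop("dispersion estimation needs >= 2 samples per group; ",
         "with a single replicate no within-group pooling is possible")
  q <- sweep(cm$counts, 2, size_factors, "/")
  qc <- q[, grp == "control", drop = FALSE]
  qt <- q[, grp == "treatment", drop = FALSE]
  m_c <- rowMeans(qc); m_t <- rowMeans(qt)
  v_c <- apply(qc, 1, stats::var); v_t <- apply(qt, 1, stats::var)
  v <- ((n_c - 1) * v_c + (n_t - 1) * v_t) / (n_c + n_t - 2)
  mbar <- (m_c + m_t) / 2
  msq <- (m_c^2 + m_t^2) / 2
  raw <- pmax(floor, (v - mbar) / msq)
  untestable <- rowMeans(q) == 0
  raw[untestable] <- NA_real_

  out <- raw
  trend <- rep(NA_real_, length(raw))
  d <- n_c + n_t - 2L
  if (moderate) {
    base_mean <- rowMeans(q)
    ok <- !untestable & is.finite(raw)
    trend_fit <- tryCatch({
      dfit <- data.frame(a = raw[ok], m = base_mean[ok])
      co <- suppressWarnings(
        stats::coef(stats::glm(a ~ I(1 / m), data = dfit,
                               family = stats::Gamma(link = "identity"),
                               start = c(stats::median(dfit$a), 1))))
      if (any(!is.finite(co))) stop("degenerate trend fit")
      pmax(floor, co[1] + co[2] / base_mean)
    }, error = function(e) rep(stats::median(raw[ok]), length(raw)))
    trend <- trend_fit
    out[ok] <- (d * raw[ok] + prior_df * trend[ok]) / (d + prior_df)
  }
  names(out) <- feature_ids(cm)
  attr(out, "raw") <- raw
  attr(out, "trend") <- trend
  attr(out, "df") <- d
  attr(out, "t_df") <- if (moderate) d + prior_df else Inf
  out
}

#' Wald test of the group effect in a log-link NB mean model
#'
#' Group means are estimated as sum(counts) / sum(size factors) within
#' each group; the log2 fold-change uses a pseudo-mean of `pseudo_mean`
#' normalised counts on both sides to avoid infinite ratios on zero
#' groups.  The Wald statistic divides the log ratio by a delta-method
#' standard error built from the NB variance (mu + alpha mu^2) with the
#' supplied dispersions plugged in, and is referred to a t distribution
#' with the `t_df` attribute of `dispersions` (normal when absent or
#' infinite) for the two-sided p-value.
#'
#' @param cm A [count_matrix].
#' @param size_factors Per-sample factors.
#' @param dispersions Per-feature dispersions from
#'   [estimate_dispersion()] (or any positive vector; `NA` marks
#'   untestable features).
#' @param pseudo_mean Pseudo-mean added to both group means (normalised
#'   scale) for the fold-change; default 0.5.
#' @return Data frame with columns `feature_id`, `feature_class`,
#'   `base_mean`, `log2fc`, `stat`, `pvalue`, `status` (`untested` for
#'   features without a test, `not_de` otherwise; final calls are made by
#'   [call_de()]).
#' @export
nb_test <- function(cm, size_factors, dispersions, pseudo_mean = 0.5) {
  stopifnot(inherits(cm, "count_matrix"))
  grp <- cm$group
  if (nlevels(droplevels(grp)) != 2L)
    stop("both groups must be present")
  t_df <- attr(dispersions, "t_df")
  if (is.null(t_df)) t_df <- Inf
  ic <- grp == "control"; it <- grp == "treatment"
  sc <- size_factors[ic]; st <- size_factors[it]
  mu_c <- rowSums(cm$counts[, ic, drop = FALSE]) / sum(sc)
  mu_t <- rowSums(cm$counts[, it, drop = FALSE]) / sum(st)
  alpha <- as.numeric(dispersions)
  var_c <- (mu_c * sum(sc) + alpha * mu_c^2 * sum(sc^2)) / sum(sc)^2
  var_t <- (mu_t * sum(st) + alpha * mu_t^2 * sum(st^2)) / sum(st)^2
  eps <- pseudo_mean
  beta <- log(mu_t + eps) - log(mu_c + eps)
  se <- sqrt(var_t / (mu_t + eps)^2 + var_c / (mu_c + eps)^2)
  stat <- beta / se
  pvalue <- if (is.finite(t_df)) 2 * stats::pt(-abs(stat), df = t_df) else
    2 * stats::pnorm(-abs(stat))
  base_mean <- rowMeans(sweep(cm$counts, 2, size_factors, "/"))
  untested <- is.na(alpha) | base_mean == 0
  pvalue[untested] <- NA_real_
  stat[untested] <- NA_real_
  data.frame(feature_id = feature_ids(cm),
             feature_class = unname(cm$feature_class),
             base_mean = unname(base_mean),
             log2fc = unname(beta / log(2)),
             stat = unname(stat),
             pvalue = unname(pvalue),
             status = ifelse(untested, "untested", "not_de"),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param pvalues Numeric vector in `[0, 1]`; `NA`/`NaN` values are
#'   rejected (filter untestable features before adjusting).
#' @return Adjusted p-values: monotone in rank and clipped to
#'   `[p, 1]`.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(is.na(pvalues)))
    stop("bh_adjust: p-values contain NA/NaN")
  if (any(pvalues < 0 | pvalues > 1))
    stop("bh_adjust: p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Apply the class-specific differential-expression calls
#'
#' mRNA, lncRNA and circRNA features are called up/down when
#' `padj < padj_cutoff` and `|log2fc| > lfc_cutoff` (defaults 0.01 and 1);
#' miRNAs are called on the adjusted p-value alone
#' (`padj < mirna_padj_cutoff`, default 0.05), with the sign of the
#' fold-change picking the direction.  Untested features stay untested.
#'
#' @param results Data frame with `feature_class`, `log2fc`, `padj` and
#'   `status` columns.
#' @param padj_cutoff,lfc_cutoff Thresholds for mRNA/lncRNA/circRNA.
#' @param mirna_padj_cutoff Threshold for miRNA.
#' @return `results` with `status` set to one of up, down, not_de,
#'   untested.
#' @export
call_de <- function(results, padj_cutoff = 0.01, lfc_cutoff = 1,
                    mirna_padj_cutoff = 0.05) {
  bad <- setdiff(unique(results$feature_class), FEATURE_CLASSES)
  if (length(bad))
    stop("unknown feature class: ", paste(bad, collapse = ", "))
  st <- results$status
  testable <- st != "untested" & !is.na(results$padj)
  is_mir <- results$feature_class == "miRNA"
  sig <- testable &
    ((!is_mir & results$padj < padj_cutoff & abs(results$log2fc) > lfc_cutoff) |
       (is_mir & results$padj < mirna_padj_cutoff))
  st[testable] <- "not_de"
  st[sig] <- ifelse(results$log2fc[sig] > 0, "up", "down")
  results$status <- st
  results
}

#' Full differential-expression pipeline for one count matrix
#'
#' Runs normalisation, dispersion estimation, the NB Wald test, BH
#' adjustment and the class-specific calls.  Adjustment is done within
#' each feature class (each RNA type is its own testing family, as when
#' the types are analysed as separate datasets), over the features that
#' could be tested; all-zero features are excluded before adjustment,
#' which reduces the family size m.
#'
#' @param cm A [count_matrix].
#' @inheritParams call_de
#' @param ... Passed to [estimate_dispersion()].
#' @return Data frame with columns `feature_id`, `feature_class`,
#'   `base_mean`, `log2fc`, `stat`, `pvalue`, `padj`, `status`.
#' @export
run_de <- function(cm, padj_cutoff = 0.01, lfc_cutoff = 1,
                   mirna_padj_cutoff = 0.05, ...) {
  sf <- estimate_size_factors(cm)
  disp <- estimate_dispersion(cm, sf, ...)
  res <- nb_test(cm, sf, disp)
  res$padj <- NA_real_
  tested <- res$status != "untested"
  for (cl in unique(res$feature_class)) {
    sel <- tested & res$feature_class == cl
    res$padj[sel] <- bh_adjust(res$pvalue[sel])
  }
  call_de(res, padj_cutoff = padj_cutoff, lfc_cutoff = lfc_cutoff,
          mirna_padj_cutoff = mirna_padj_cutoff)
}
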