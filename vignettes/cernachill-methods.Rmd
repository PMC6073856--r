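---
title: "Models and methods behind cernachill"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cernachill}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernachill)
```

`cernachill` analyses two-group (control vs. treatment) RNA-seq count
data for four transcript classes — mRNA, lncRNA, circRNA and miRNA — and
infers competing-endogenous-RNA (ceRNA) relationships from a
miRNA→target interaction table. This vignette explains the statistical
models, the defaults and their rationale, the numerical choices, and the
limits of what the bundled simulations demonstrate.

## Differential expression

Counts for feature $i$ in sample $j$ are modelled as negative binomial,
$K_{ij} \sim \mathrm{NB}(\mu_{ij}, \alpha_i)$ with
$\mathrm{Var} = \mu + \alpha\mu^2$ and
$\mu_{ij} = s_j\,q_{ig(j)}$, where $s_j$ is a sample size factor and
$q_{ig}$ the group mean.

**Size factors** are median-of-ratios: $s_j = \mathrm{median}_i\,
K_{ij}/(\prod_{j'} K_{ij'})^{1/m}$ over features with an all-positive
row. This is the standard normalisation for library depth plus mild
composition bias; it fails (by design, with an error) if no feature is
observed in every sample.

**Dispersions** start from the per-feature method-of-moments estimator on
normalised counts, pooled within groups:
$\hat\alpha_i = \max(\text{floor}, (\hat v_i - \bar m_i)/\overline{m^2_i})$
with floor $10^{-8}$. With the default 3 samples per group each estimate
has roughly $n-2 = 4$ degrees of freedom and is far too noisy to plug
into a Wald test directly (dispersion underestimates inflate the
statistic). The estimates are therefore shrunk toward a mean–dispersion
trend $\alpha(\mu) = a_0 + a_1/\mu$ fitted across all features by a gamma
GLM (falling back to the median when the fit degenerates), with a prior
weight of `prior_df = 40` pseudo degrees of freedom:
$\tilde\alpha_i = (d\,\hat\alpha_i + d_0\,\alpha(\bar\mu_i))/(d + d_0)$.
This is the same borrow-strength idea used by the established
empirical-Bayes DE packages, reduced to its simplest moment-based form.
Raw estimates remain available via `moderate = FALSE`.

**Testing.** The group effect $\beta_i = \log(\mu_{iT}/\mu_{iC})$ is
estimated from the size-factor-weighted group means with a pseudo-mean of
0.5 normalised counts on both sides (so zero-count groups give finite
fold-changes), and divided by a delta-method standard error built from
the NB variance with $\tilde\alpha_i$ plugged in. Because the dispersion
is estimated, the statistic is referred to a $t$ distribution with
$d + d_0$ degrees of freedom rather than a normal — the moderated-$t$
device. Under the null simulation (2000 features, $\mu = 100$,
$\alpha = 0.1$, 3 vs 3) this combination gives an empirical
$P(p \le 0.05)$ of about 0.05 (the acceptance suite checks it against
the binomial 99% interval), where a normal reference with raw
method-of-moments dispersions gives about 0.11.

**Calls.** P-values are BH-adjusted within each feature class (each RNA
type is treated as its own testing family, as when the types are
analysed as separate datasets); all-zero features are excluded before
adjustment. mRNA/lncRNA/circRNA are called up or down when
$p_{adj} < 0.01$ and $|\log_2 FC| > 1$; miRNAs when $p_{adj} < 0.05$
with no fold-change gate. Both thresholds are arguments.

The design is deliberately limited to two groups with $\ge 2$ replicates
each; single-replicate designs are rejected with an explanatory error
rather than silently falling back to pooled-null dispersion estimation.

## lncRNA candidate filtering and positional classes

Candidates must be longer than 200 nt (exonic length) and satisfy an
exon-count rule. The literature phrasing of such filters is ambiguous
between "at least two" and "more than two" exons — and a strict reading
would exclude the single- and two-exon lincRNAs that dominate real
catalogues — so the default is `min_exons = 2` with the stricter reading
available as `min_exons = 3`.

Classification against a reference annotation uses 0-based half-open
intervals (converted from GTF once at parse time, so touching ranges
never count as overlapping) and the precedence

1. **sense** — a novel exon overlaps a reference exon, same strand;
2. **antisense** — the novel span overlaps a reference *gene span*
   (first exon start to last exon end across the gene's transcripts) on
   the opposite strand;
3. **intronic** — the novel span is contained in a same-strand gene span
   with no exonic overlap;
4. **lincRNA** — otherwise.

Most-specific-overlap-first is a design choice: no published tie rule
exists for transcripts satisfying several conditions at once. The rules
make the classifier total and deterministic, and on generated annotations
(where every novel transcript satisfies exactly one class by
construction, including boundary-touching cases) it recovers 100% of
planted classes — which validates the interval arithmetic, not the
biological ambiguity of real overlapping loci.

## The ceRNA hypergeometric test

For an unordered pair of transcripts targeted by $K$ and $n$ of the $N$
miRNAs in the prediction universe and sharing $c$ of them, the p-value is
the upper hypergeometric tail

$$P \;=\; \sum_{i=c}^{\min(K,n)} \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}},$$

evaluated as a log-sum-exp of `lchoose` terms so that universes of
hundreds of miRNAs cannot overflow. The implementation is exact to
better than $10^{-12}$ relative error against direct enumeration for all
$N \le 25$ (and cross-checked against `phyper`).

Pairs sharing no miRNA have $P = 1$ identically and are excluded before
BH adjustment, so the BH family is the set of tested pairs ($c \ge 1$) —
stated explicitly because the family size is otherwise invisible in the
output. Filters follow the sponge-screen convention: both endpoints must
be targeted by at least 5 miRNAs ($\min(K,n) \ge 5$; a one-sided variant
is available via `symmetric = FALSE`) and FDR strictly below 0.05. The
candidate universe is any mix of mRNA/lncRNA/circRNA; `pair_types`
restricts combinations when desired. Surviving edges are reported as
connected components ranked by node count (ties: edge count, then
smallest node id), with the `top_k = 3` largest flagged.

## Enrichment and length bias

The central test reuses the hypergeometric tail with
$(N, K, n, c) = (N_u, K_{cat}, n_{de}, k)$. The length-corrected test
models gene selection as a biased urn: each gene carries a sampling
weight from an isotonic (monotone non-decreasing, parameter-free)
regression of the DE indicator on transcript length, rescaled to mean 1
and floored at $10^{-6}$. Each category is reduced to two weight
classes — odds = mean weight inside / mean weight outside — and the
p-value is the upper tail of the Wallenius non-central hypergeometric
distribution. The two-class reduction is the standard practical form;
the full per-gene-weight distribution is exponential in the category
size.

**Numerics.** The textbook integral representation
$P(X=x) = \binom{m_1}{x}\binom{m_2}{n-x}\int_0^1 (1-t^{w/D})^x (1-t^{1/D})^{n-x}\,dt$
with $D = w(m_1-x) + m_2-(n-x)$ concentrates all of its mass within
$e^{-D}$ of $t = 0$ once $D$ is large, which silently defeats quadrature
on $[0,1]$. Substituting $t = s^D$ yields
$D\int_0^1 s^{D-1}(1-s^w)^x(1-s)^{n-x}\,ds$, a smooth unimodal
beta-kernel integrand; it is evaluated in log space with the peak value
factored out, by adaptive quadrature at absolute tolerance $10^{-10}$
per mass term. At $w = 1$ the integral is an exact beta function and the
expression collapses to the central pmf — the test suite verifies
agreement to $10^{-6}$ across a parameter grid, that point masses sum to
1 within $10^{-9}$, and that the tail matches a $10^5$-draw sequential
biased-urn Monte-Carlo oracle within 3 standard errors.

The pathway network connects significant categories (default
$p_{adj} < 0.05$; `top_n` restricts to the most significant) by edges
weighted with the number of shared significant genes, dropping edges
below `min_shared`. The cutoff is configurable because no canonical
threshold exists for this display.

## What the simulators emulate — and what they do not

`simulate_counts` draws NB counts with
$\mu_{ij} = s_j\,\mu_i\,2^{\beta_i g_j}$: log-uniform size factors on
$[0.5, 2]$ renormalised to geometric mean 1 (so median-of-ratios is
identifiable), a planted fraction `frac_de = 0.1` of features with
$\beta_i = \pm 2$ (a typical DE fraction and a comfortably detectable
effect at 3 vs 3), baseline mean $\mu = 100$ and dispersion
$\alpha = 0.1$ — mid-range values for moderately expressed genes.
Replicate structure defaults to 3 per group, a common design for this
kind of experiment, and is a parameter. Not emulated: mean-dependent
dispersion trends, outlier samples, batch effects, or correlated
features; calibration results on these simulations therefore bound
behaviour under the model's own assumptions, not under real-data
pathologies.

`simulate_interactions` gives every target `background_degree`
uniform-random miRNAs (so a random pair shares
$N(d/N)^2$ miRNAs in expectation) and plants ceRNA modules whose
members all receive a dedicated block of shared miRNAs; module member
sets and shared blocks are disjoint by default so that recovery can be
scored against unambiguous truth. Real target predictions are
heavy-tailed in degree and correlated by sequence family; the uniform
background is the cleanest null for testing FDR control, not a model of
a real interactome.

`simulate_annotation` places two-exon reference genes with wide introns
and intergenic gaps on one chromosome and constructs novel transcripts
(200–2000 nt, one or two exons) that satisfy exactly one positional
class, including exact boundary-touching placements. It makes no attempt
at sequence content realism.

Problem sizes used by the test suite and the acceptance script — 2000
features for DE calibration, 200 replicate null interaction maps,
100-target networks, $N \le 25$ for exhaustive kernel enumeration —
were chosen as the smallest sizes at which the Monte-Carlo intervals in
the checks are informative.

## Known limitations

- Two-group designs only; no covariates, batch terms or multi-factor
  contrasts.
- The Wald/moderated-t test is approximate at extreme dispersions or
  very low counts; an exact conditional test is out of scope.
- ceRNA inference is purely combinatorial (shared-miRNA counts); it does
  not weight edges by expression correlation or predict miRNA targets.
- The Wallenius reduction uses one odds parameter per category; per-gene
  weights enter only through the category means.
- GO/KEGG semantics (DAG propagation, pathway topology) are out of
  scope: categories are opaque gene sets.
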