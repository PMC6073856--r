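# Synthetic-data generators.  These emulate the statistical structure the
# downstream analysis assumes -- negative-binomial counts with planted
# fold-changes, a bipartite miRNA-target map with planted ceRNA modules,
# and a toy genome annotation with novel transcripts of known positional
# class -- and record the ground truth alongside, so every stage of the
# pipeline can be validated without external data.

#' Simulate a negative-binomial count matrix with planted fold-changes
#'
#' Counts for feature i in sample j are drawn from
#' NB(mean = s_j * mu_i * 2^(beta_i * g_j), dispersion alpha_i), where g_j
#' is 0 for control and 1 for treatment samples, s_j is a per-sample size
#' factor drawn log-uniformly on `size_factor_range` and renormalised to
#' geometric mean 1, and beta_i is `+/- mean_log2fc` for a planted
#' fraction `frac_de` of features (sign chosen at random) and 0 otherwise.
#'
#' @param n_features Named integer vector of features per class, e.g.
#'   `c(mRNA = 2000, lncRNA = 300)`.  An unnamed scalar means mRNA only.
#' @param n_per_group Samples per group (default 3 per group, a common
#'   replicate structure for this kind of experiment).
#' @param mu Baseline mean expression, scalar or one value per feature.
#' @param mean_log2fc Magnitude of the planted log2 fold-change.
#' @param frac_de Fraction of features with a planted fold-change, in
#'   `[0, 1]`.
#' @param dispersion NB dispersion alpha (Var = mu + alpha mu^2), scalar
#'   or per feature.  Must be positive.
#' @param size_factor_range Length-2 positive range for the log-uniform
#'   size-factor draw.
#' @param seed Integer seed; recorded in the truth object.
#' @return A list with `counts` (a [count_matrix]) and `truth` (a list
#'   with `de_features` -- data frame of feature_id and true log2fc for
#'   planted features -- `log2fc` for all features, `size_factors`, and
#'   `params`).
#' @export
simulate_counts <- function(n_features = c(mRNA = 2000),
                            n_per_group = 3,
                            mu = 100,
                            mean_log2fc = 2,
                            frac_de = 0.1,
                            dispersion = 0.1,
                            size_factor_range = c(0.5, 2),
                            seed = 1L) {
  if (is.null(names(n_features))) {
    if (length(n_features) != 1L)
      stop("n_features must be named per class or a single number")
    n_features <- c(mRNA = as.integer(n_features))
  }
  bad <- setdiff(names(n_features), FEATURE_CLASSES)
  if (length(bad)) stop("unknown feature class: ", paste(bad, collapse = ", "))
  if (any(n_features <= 0) || n_per_group < 1)
    stop("feature and sample counts must be positive")
  if (frac_de < 0 || frac_de > 1) stop("frac_de must be in [0, 1]")
  if (any(dispersion <= 0)) stop("dispersion must be positive")
  if (length(size_factor_range) != 2L || any(size_factor_range <= 0))
    stop("size_factor_range must be two positive numbers")
  set.seed(seed)

  nf <- sum(n_features)
  ns <- 2L * n_per_group
  prefix <- c(mRNA = "gene", lncRNA = "lnc", circRNA = "circ", miRNA = "mir")
  fids <- unlist(lapply(names(n_features), function(cl)
    sprintf("%s_%05d", prefix[[cl]], seq_len(n_features[[cl]]))),
    use.names = FALSE)
  fclass <- rep(names(n_features), n_features)
  sids <- c(sprintf("control_%d", seq_len(n_per_group)),
            sprintf("treatment_%d", seq_len(n_per_group)))
  grp <- rep(c("control", "treatment"), each = n_per_group)

  sf <- exp(stats::runif(ns, log(size_factor_range[1]), log(size_factor_range[2])))
  sf <- sf / exp(mean(log(sf)))
  mu <- rep_len(mu, nf)
  alpha <- rep_len(dispersion, nf)
  beta <- numeric(nf)
  n_de <- round(frac_de * nf)
  if (n_de > 0) {
    de_idx <- sample.int(nf, n_de)
    beta[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) * mean_log2fc
  }
  mean_mat <- outer(mu, sf) * 2^(outer(beta, ifelse(grp == "treatment", 1, 0)))
  cnt <- matrix(stats::rnbinom(nf * ns, mu = mean_mat, size = 1 / alpha),
                nrow = nf, dimnames = list(fids, sids))
  cm <- count_matrix(cnt, fclass, grp)
  truth <- list(
    de_features = data.frame(feature_id = fids[beta != 0],
                             log2fc = beta[beta != 0]),
    log2fc = stats::setNames(beta, fids),
    size_factors = stats::setNames(sf, sids),
    params = list(n_features = n_features, n_per_group = n_per_group,
                  mu = mu[1], mean_log2fc = mean_log2fc, frac_de = frac_de,
                  dispersion = alpha[1],
                  size_factor_range = size_factor_range, seed = seed))
  list(counts = cm, truth = truth)
}

#' Simulate a miRNA-target interaction map with planted ceRNA modules
#'
#' Background interactions: every target independently draws
#' `background_degree` miRNAs uniformly without replacement from the
#' universe, so the expected number of miRNAs shared by a random target
#' pair is `n_mirna * (background_degree / n_mirna)^2`.  Each planted
#' module additionally assigns a dedicated set of `shared` miRNAs to all
#' of its member targets, so every within-module pair shares at least
#' `shared` miRNAs.  Planted member sets and shared-miRNA sets are
#' disjoint across modules by default, giving clean truth for recovery
#' tests.
#'
#' @param n_mirna Size of the miRNA universe N.
#' @param n_targets Named integer vector of targets per class (default
#'   `c(mRNA = 60, lncRNA = 30, circRNA = 10)`); an unnamed scalar means
#'   mRNA only.  Ignored when `target_ids` is given.
#' @param target_ids Optional named character vector of target feature
#'   ids to use instead of generated ones, with names or values giving
#'   the class per target (a plain character vector gets class
#'   `"mRNA"`).
#' @param background_degree Number of background miRNAs per target
#'   (>= 0).
#' @param planted_modules List of `list(size =, shared =)` entries, one
#'   per module.
#' @param allow_overlap If `TRUE`, module shared-miRNA sets may overlap.
#' @param seed Integer seed.
#' @return A list with `map` (an [interaction_map]), `classes` (named
#'   vector target -> class) and `truth` (data frame of planted
#'   within-module pairs: `target_a`, `target_b`, `module`,
#'   `planted_shared`, plus `params`).
#' @export
simulate_interactions <- function(n_mirna = 200,
                                  n_targets = c(mRNA = 60, lncRNA = 30,
                                                circRNA = 10),
                                  background_degree = 8,
                                  planted_modules = list(),
                                  allow_overlap = FALSE,
                                  target_ids = NULL,
                                  seed = 1L) {
  if (is.null(names(n_targets))) {
    if (length(n_targets) != 1L)
      stop("n_targets must be named per class or a single number")
    n_targets <- c(mRNA = as.integer(n_targets))
  }
  if (n_mirna < 1) stop("n_mirna must be >= 1")
  if (background_degree < 0) stop("background_degree must be >= 0")
  if (background_degree > n_mirna)
    stop("background_degree cannot exceed the universe size")
  sizes <- vapply(planted_modules, function(m) as.integer(m$size), 1L)
  shared <- vapply(planted_modules, function(m) as.integer(m$shared), 1L)
  nt <- if (is.null(target_ids)) sum(n_targets) else length(target_ids)
  if (sum(sizes) > nt)
    stop("planted modules are larger than the target pool")
  if (!allow_overlap && sum(shared) > n_mirna)
    stop("disjoint planted modules need more miRNAs than the universe holds")
  if (any(shared > n_mirna))
    stop("a module cannot share more miRNAs than the universe holds")
  set.seed(seed)

  mirnas <- sprintf("mir_%04d", seq_len(n_mirna))
  if (is.null(target_ids)) {
    prefix <- c(mRNA = "gene", lncRNA = "lnc", circRNA = "circ")
    targets <- unlist(lapply(names(n_targets), function(cl)
      sprintf("%s_%05d", prefix[[cl]], seq_len(n_targets[[cl]]))),
      use.names = FALSE)
    classes <- stats::setNames(rep(names(n_targets), n_targets), targets)
  } else {
    targets <- if (is.null(names(target_ids))) as.character(target_ids) else
      names(target_ids)
    if (anyDuplicated(targets)) stop("duplicate target ids")
    cls <- if (is.null(names(target_ids))) rep("mRNA", length(targets)) else
      as.character(target_ids)
    classes <- stats::setNames(cls, targets)
  }

  # per-target background regulator sets
  mirnas_of <- lapply(targets, function(t)
    if (background_degree > 0) sample(mirnas, background_degree) else character(0))
  names(mirnas_of) <- targets

  # planted modules
  free_targets <- sample(targets)      # random disjoint member assignment
  free_mirnas <- sample(mirnas)
  truth_pairs <- list()
  for (k in seq_along(planted_modules)) {
    members <- free_targets[seq_len(sizes[k])]
    free_targets <- free_targets[-seq_len(sizes[k])]
    if (allow_overlap) {
      mod_mirnas <- sample(mirnas, shared[k])
    } else {
      mod_mirnas <- free_mirnas[seq_len(shared[k])]
      free_mirnas <- free_mirnas[-seq_len(shared[k])]
    }
    for (m in members)
      mirnas_of[[m]] <- union(mirnas_of[[m]], mod_mirnas)
    if (sizes[k] >= 2L) {
      cmb <- utils::combn(sort(members), 2L)
      truth_pairs[[k]] <- data.frame(target_a = cmb[1L, ], target_b = cmb[2L, ],
                                     module = k, planted_shared = shared[k])
    }
  }
  truth_pairs <- if (length(truth_pairs)) do.call(rbind, truth_pairs) else
    data.frame(target_a = character(0), target_b = character(0),
               module = integer(0), planted_shared = integer(0))

  # invert target -> miRNA into miRNA -> targets
  pairs <- data.frame(
    mirna = unlist(mirnas_of, use.names = FALSE),
    target = rep(names(mirnas_of), lengths(mirnas_of)))
  targets_of <- split(pairs$target, pairs$mirna)
  map <- interaction_map(targets_of, universe = mirnas)
  list(map = map, classes = classes,
       truth = list(planted_pairs = truth_pairs,
                    params = list(n_mirna = n_mirna, n_targets = n_targets,
                                  background_degree = background_degree,
                                  planted_modules = planted_modules,
                                  allow_overlap = allow_overlap,
                                  seed = seed)))
}

#' Simulate a toy annotation with novel transcripts of known class
#'
#' Places reference two-exon genes along a single chromosome with
#' intergenic gaps and wide introns, then constructs novel transcripts
#' that satisfy exactly one positional class by construction: `sense`
#' (same-strand exonic overlap with a reference exon), `antisense`
#' (opposite-strand overlap with a gene span), `intronic` (same strand,
#' contained in a reference intron) and `lincRNA` (no overlap with any
#' gene span).  Some lincRNAs and intronic transcripts touch reference
#' boundaries exactly (half-open coordinates: touching is not overlap), to
#' exercise boundary arithmetic.  Novel transcripts are single- or
#' two-exon with lengths between 200 and 2000 nt, spanning the candidate
#' length-filter boundary.
#'
#' @param n_reference_genes Number of reference genes to place.
#' @param n_novel Named integer vector of novel transcripts per class
#'   (names among lincRNA, antisense, sense, intronic), or an unnamed
#'   scalar meaning that many of each class.
#' @param chrom_length Chromosome length in nt; must be large enough to
#'   place all genes without forced overlap.
#' @param seed Integer seed.
#' @return A list with `reference` and `novel` ([transcript_models]
#'   tables) and `truth` (data frame `transcript_id`, `class`, plus
#'   `params`).
#' @export
simulate_annotation <- function(n_reference_genes = 20,
                                n_novel = c(lincRNA = 6, antisense = 6,
                                            sense = 6, intronic = 6),
                                chrom_length = 1e6,
                                seed = 1L) {
  if (is.null(names(n_novel))) {
    if (length(n_novel) != 1L)
      stop("n_novel must be named per class or a single number")
    n_novel <- stats::setNames(rep(as.integer(n_novel), 4L), LNC_CLASSES)
  }
  bad <- setdiff(names(n_novel), LNC_CLASSES)
  if (length(bad)) stop("unknown lncRNA class: ", paste(bad, collapse = ", "))
  need_genes <- max(n_novel[c("antisense", "sense", "intronic")], 0)
  if (n_reference_genes < max(need_genes, 2))
    stop("not enough reference genes for the requested novel transcripts")
  set.seed(seed)

  # reference layout: gap, exon1, intron, exon2, gap, ...
  ref <- list()
  pos <- 0
  gene_start <- gene_end <- e1s <- e1e <- e2s <- e2e <- numeric(n_reference_genes)
  strand <- character(n_reference_genes)
  for (i in seq_len(n_reference_genes)) {
    pos <- pos + sample(2500:4000, 1)          # intergenic gap
    e1 <- sample(300:800, 1)
    intr <- sample(1500:3000, 1)
    e2 <- sample(300:800, 1)
    e1s[i] <- pos; e1e[i] <- pos + e1
    e2s[i] <- e1e[i] + intr; e2e[i] <- e2s[i] + e2
    gene_start[i] <- e1s[i]; gene_end[i] <- e2e[i]
    strand[i] <- sample(c("+", "-"), 1)
    pos <- e2e[i]
  }
  pos <- pos + 3000
  if (pos > chrom_length)
    stop("chrom_length too small to place ", n_reference_genes,
         " genes without forced overlap")
  gid <- sprintf("refgene_%03d", seq_len(n_reference_genes))
  reference <- transcript_models(data.frame(
    transcript_id = rep(sprintf("reftx_%03d", seq_len(n_reference_genes)), each = 2),
    gene_id = rep(gid, each = 2),
    seqnames = "chr1",
    strand = rep(strand, each = 2),
    start = as.vector(rbind(e1s, e2s)),
    end = as.vector(rbind(e1e, e2e))))

  flip <- function(s) if (s == "+") "-" else "+"
  novel <- list()
  truth <- list()
  idx <- 0L
  add_novel <- function(cls, exons, str) {
    idx <<- idx + 1L
    tid <- sprintf("novel_%03d", idx)
    novel[[idx]] <<- data.frame(transcript_id = tid,
                                gene_id = paste0(tid, ".g"),
                                seqnames = "chr1", strand = str,
                                start = exons[, 1], end = exons[, 2])
    truth[[idx]] <<- data.frame(transcript_id = tid, class = cls)
  }
  pick_len <- function() sample(200:2000, 1)

  for (j in seq_len(n_novel[["sense"]])) {
    g <- ((j - 1L) %% n_reference_genes) + 1L
    # exon starting inside reference exon1, extending into the intron
    len <- min(pick_len(), e2s[g] - e1e[g] + 100)
    s <- e1e[g] - 100                        # 100 bp exonic overlap
    add_novel("sense", cbind(s, s + len), strand[g])
  }
  for (j in seq_len(n_novel[["antisense"]])) {
    g <- ((j - 1L) %% n_reference_genes) + 1L
    # opposite strand, straddling the gene start
    len <- pick_len()
    s <- gene_start[g] - round(len / 2)
    add_novel("antisense", cbind(s, s + len), flip(strand[g]))
  }
  for (j in seq_len(n_novel[["intronic"]])) {
    g <- ((j - 1L) %% n_reference_genes) + 1L
    gap <- e2s[g] - e1e[g]
    len <- min(pick_len(), gap - 40)
    if (j == 1L) {
      s <- e1e[g]                            # touches exon1 end exactly
      add_novel("intronic", cbind(s, s + len), strand[g])
    } else if (len > 420) {
      # two-exon intronic transcript
      half <- floor((len - 20) / 2)
      s <- e1e[g] + 5
      add_novel("intronic",
                rbind(c(s, s + half), c(s + half + 20, s + half + 20 + (len - half))),
                strand[g])
    } else {
      s <- e1e[g] + floor((gap - len) / 2)
      add_novel("intronic", cbind(s, s + len), strand[g])
    }
  }
  for (j in seq_len(n_novel[["lincRNA"]])) {
    g <- ((j - 1L) %% (n_reference_genes - 1L)) + 1L
    gap_lo <- gene_end[g]; gap_hi <- gene_start[g + 1L]
    len <- min(pick_len(), gap_hi - gap_lo - 4)
    if (j == 1L) {
      s <- gap_hi - len                      # ends exactly at next gene start
    } else if (j == 2L) {
      s <- gap_lo                            # starts exactly at gene end
    } else {
      s <- gap_lo + floor((gap_hi - gap_lo - len) / 2)
    }
    add_novel("lincRNA", cbind(s, s + len), sample(c("+", "-"), 1))
  }
  novel <- transcript_models(do.call(rbind, novel))
  truth_df <- do.call(rbind, truth)
  list(reference = reference, novel = novel,
       truth = list(classes = truth_df,
                    params = list(n_reference_genes = n_reference_genes,
                                  n_novel = n_novel,
                                  chrom_length = chrom_length, seed = seed)))
}

#' Simulate a category-to-gene map for enrichment testing
#'
#' Draws category memberships uniformly at random from a gene universe;
#' used to exercise the enrichment stage of the pipeline end to end.
#'
#' @param genes Character vector, the gene universe.
#' @param n_categories Number of categories.
#' @param size_range Length-2 integer range of category sizes.
#' @param seed Integer seed.
#' @return Named list category id -> character vector of gene ids.
#' @export
simulate_categories <- function(genes, n_categories = 30,
                                size_range = c(10, 40), seed = 1L) {
  if (length(genes) < max(size_range))
    stop("gene universe smaller than the largest category size")
  set.seed(seed)
  out <- lapply(seq_len(n_categories), function(i)
    sort(sample(genes, sample(size_range[1]:size_range[2], 1))))
  names(out) <- sprintf("cat_%03d", seq_len(n_categories))
  out
}
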