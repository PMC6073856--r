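FEATURE_CLASSES <- c("mRNA", "lncRNA", "circRNA", "miRNA")
SAMPLE_GROUPS <- c("control", "treatment")
LNC_CLASSES <- c("lincRNA", "antisense", "sense", "intronic")

#' Feature-by-sample count matrix with class and group labels
#'
#' The basic expression container of the pipeline: a non-negative integer
#' matrix of features (mRNA, lncRNA, circRNA or miRNA) by samples, each
#' sample labelled as `control` or `treatment`.
#'
#' @param counts Integer matrix, features in rows and samples in columns.
#'   Row and column names are required and must be unique.
#' @param feature_class Character vector, one of `"mRNA"`, `"lncRNA"`,
#'   `"circRNA"`, `"miRNA"` per feature (recycled if length 1).
#' @param group Character or factor vector, one of `"control"`,
#'   `"treatment"` per sample.  Both groups must be non-empty.
#'
#' @return An object of class `count_matrix`: a list with elements
#'   `counts` (integer matrix), `feature_class` (named character) and
#'   `group` (named factor with levels control, treatment).
#' @export
#' @examples
#' m <- matrix(c(10L, 30L, 20L, 60L), 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' cm <- count_matrix(m, "mRNA", c("control", "treatment"))
#' feature_ids(cm)
count_matrix <- function(counts, feature_class, group) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have row (feature) and column (sample) names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate feature ids in count matrix")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids in count matrix")
  if (any(is.na(counts)))
    stop("counts contain missing values")
  if (any(counts < 0))
    stop("counts must be non-negative")
  if (any(counts != round(counts)))
    stop("counts must be integral")
  storage.mode(counts) <- "integer"
  if (length(feature_class) == 1L)
    feature_class <- rep(feature_class, nrow(counts))
  if (length(feature_class) != nrow(counts))
    stop("feature_class must have one entry per feature")
  bad <- setdiff(unique(feature_class), FEATURE_CLASSES)
  if (length(bad))
    stop("unknown feature class token(s): ", paste(bad, collapse = ", "))
  if (length(group) != ncol(counts))
    stop("group must have one entry per sample")
  group <- as.character(group)
  bad <- setdiff(unique(group), SAMPLE_GROUPS)
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         " (expected control/treatment)")
  group <- factor(group, levels = SAMPLE_GROUPS)
  if (any(table(group) == 0L))
    stop("both control and treatment groups must be non-empty")
  names(feature_class) <- rownames(counts)
  names(group) <- colnames(counts)
  structure(list(counts = counts, feature_class = feature_class,
                 group = group),
            class = "count_matrix")
}

#' @rdname count_matrix
#' @param x A `count_matrix`.
#' @export
feature_ids <- function(x) rownames(x$counts)

#' @rdname count_matrix
#' @export
sample_ids <- function(x) colnames(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("  classes:", paste(sprintf("%s=%d", names(table(x$feature_class)),
                                  table(x$feature_class)), collapse = ", "), "\n")
  cat("  groups: ", paste(sprintf("%s=%d", levels(x$group),
                                  table(x$group)), collapse = ", "), "\n")
  invisible(x)
}

#' Bipartite miRNA-to-target interaction map
#'
#' Stores, for each miRNA, the set of transcripts it is predicted to
#' target, together with the full miRNA universe.  The universe size N is
#' the total number of miRNAs used for target prediction and is the
#' population size of the hypergeometric ceRNA test.
#'
#' @param targets_of Named list: miRNA id -> character vector of target
#'   feature ids.  Target sets must be non-empty; duplicates are dropped
#'   (set semantics).
#' @param universe Character vector of miRNA ids.  Defaults to the miRNAs
#'   observed in `targets_of`.  Every key of `targets_of` must belong to
#'   the universe.
#'
#' @return An object of class `interaction_map` with elements `targets_of`
#'   and `universe`.
#' @export
interaction_map <- function(targets_of, universe = NULL) {
  if (!is.list(targets_of) || is.null(names(targets_of)))
    stop("targets_of must be a named list (miRNA -> targets)")
  if (anyDuplicated(names(targets_of)))
    stop("duplicate miRNA keys in targets_of")
  targets_of <- lapply(targets_of, function(t) sort(unique(as.character(t))))
  if (any(lengths(targets_of) == 0L))
    stop("every miRNA in targets_of must have a non-empty target set")
  if (is.null(universe)) {
    universe <- names(targets_of)
  } else {
    universe <- unique(as.character(universe))
    missing <- setdiff(names(targets_of), universe)
    if (length(missing))
      stop("miRNA universe is missing observed miRNA(s): ",
           paste(utils::head(missing, 5), collapse = ", "))
  }
  if (length(universe) < 1L)
    stop("miRNA universe must contain at least one miRNA")
  structure(list(targets_of = targets_of[order(names(targets_of))],
                 universe = sort(universe)),
            class = "interaction_map")
}

#' @export
print.interaction_map <- function(x, ...) {
  cat(sprintf("interaction_map: %d miRNAs with targets, universe N = %d, %d edges\n",
              length(x$targets_of), length(x$universe),
              sum(lengths(x$targets_of))))
  invisible(x)
}

#' Exon-level transcript models
#'
#' A flat exon table used for both reference annotation and novel
#' transcripts.  Coordinates are 0-based half-open internally; the GTF
#' readers/writers convert to and from the 1-based closed convention at
#' the boundary.
#'
#' @param df A data frame with columns `transcript_id`, `gene_id`,
#'   `seqnames`, `strand` (`+` or `-`), `start`, `end` (0-based half-open),
#'   one row per exon.
#'
#' @return The validated data frame with class `transcript_models`
#'   prepended, exons sorted within transcript.
#' @export
transcript_models <- function(df) {
  need <- c("transcript_id", "gene_id", "seqnames", "strand", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("transcript table is missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[, need]
  df$transcript_id <- as.character(df$transcript_id)
  df$gene_id <- as.character(df$gene_id)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-' for every exon")
  if (any(df$end <= df$start))
    stop("exon end must exceed exon start (0-based half-open)")
  df <- df[order(df$transcript_id, df$start), ]
  rownames(df) <- NULL
  # exons within a transcript must not overlap
  by_tx <- split(df, df$transcript_id)
  for (tx in by_tx) {
    if (nrow(tx) > 1L && any(tx$start[-1L] < tx$end[-nrow(tx)]))
      stop("overlapping exons in transcript ", tx$transcript_id[1L])
    if (length(unique(tx$strand)) != 1L || length(unique(tx$seqnames)) != 1L)
      stop("inconsistent strand/chromosome in transcript ", tx$transcript_id[1L])
  }
  class(df) <- c("transcript_models", "data.frame")
  df
}

#' Transcript lengths (sum of exon widths)
#'
#' @param tx A `transcript_models` table.
#' @return Named numeric vector of transcript lengths in nt.
#' @export
transcript_lengths <- function(tx) {
  w <- tapply(tx$end - tx$start, tx$transcript_id, sum)
  out <- as.numeric(w)
  names(out) <- names(w)
  out
}

#' Exon counts per transcript
#'
#' @param tx A `transcript_models` table.
#' @return Named integer vector of exon counts.
#' @export
exon_counts <- function(tx) {
  n <- tapply(tx$transcript_id, tx$transcript_id, length)
  out <- as.integer(n)
  names(out) <- names(n)
  out
}

# GRanges of exons, one range per row of the transcript table
.tx_exon_granges <- function(tx) {
  GenomicRanges::GRanges(
    seqnames = tx$seqnames,
    ranges = IRanges::IRanges(start = tx$start + 1L, end = tx$end),
    strand = tx$strand,
    transcript_id = tx$transcript_id,
    gene_id = tx$gene_id)
}

# gene spans: union interval from first exon start to last exon end per gene
.tx_gene_spans <- function(tx) {
  st <- tapply(tx$start, tx$gene_id, min)
  en <- tapply(tx$end, tx$gene_id, max)
  chr <- tapply(tx$seqnames, tx$gene_id, function(x) x[1L])
  str <- tapply(tx$strand, tx$gene_id, function(x) x[1L])
  GenomicRanges::GRanges(
    seqnames = as.character(chr),
    ranges = IRanges::IRanges(start = as.numeric(st) + 1L, end = as.numeric(en)),
    strand = as.character(str),
    gene_id = names(st))
}
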