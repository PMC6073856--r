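# lncRNA candidate filtering, positional classification against a
# reference annotation, and the descriptive profiles (length / exon /
# ORF histograms and miRNA positional nucleotide bias).

#' Filter lncRNA candidates on length and exon count
#'
#' Keeps transcripts with total exonic length strictly over `min_length`
#' nt and at least `min_exons` exons.  The default exon rule is
#' `min_exons = 2`; a stricter literal "more than two exons" reading is
#' available via `min_exons = 3`.
#'
#' @param tx A [transcript_models] table.
#' @param min_length Length threshold in nt (kept if length >
#'   `min_length`; default 200).
#' @param min_exons Minimum exon count (kept if exons >= `min_exons`;
#'   default 2).
#' @return The surviving subset of `tx` (possibly empty).
#' @export
filter_candidates <- function(tx, min_length = 200, min_exons = 2) {
  if (nrow(tx) == 0L) return(tx)
  len <- transcript_lengths(tx)
  nex <- exon_counts(tx)
  keep_ids <- names(len)[len > min_length & nex[names(len)] >= min_exons]
  out <- tx[tx$transcript_id %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(tx)
  out
}

#' Positional classification of novel transcripts
#'
#' Each novel transcript is assigned exactly one class by precedence:
#' \enumerate{
#'   \item \strong{sense} -- a novel exon overlaps a reference exon on
#'     the same strand;
#'   \item \strong{antisense} -- the novel transcript span overlaps a
#'     reference gene span on the opposite strand;
#'   \item \strong{intronic} -- the novel span is contained in a
#'     same-strand reference gene span with no exonic overlap;
#'   \item \strong{lincRNA} -- otherwise (no overlap with any gene
#'     span).
#' }
#' A gene span is the union interval from the gene's first exon start to
#' its last exon end across its reference transcripts.  Coordinates are
#' 0-based half-open, so ranges that merely touch do not overlap.
#' Transcripts on chromosomes absent from the reference are classified
#' lincRNA with a warning.
#'
#' @param novel A [transcript_models] table of novel transcripts.
#' @param reference A [transcript_models] table of reference transcripts.
#' @return Data frame with columns `transcript_id`, `class`.
#' @export
classify_transcripts <- function(novel, reference) {
  nov_ex <- .tx_exon_granges(novel)
  ref_ex <- .tx_exon_granges(reference)
  spans <- .tx_gene_spans(reference)
  tx_ids <- unique(novel$transcript_id)

  miss_chr <- setdiff(unique(novel$seqnames), unique(reference$seqnames))
  if (length(miss_chr))
    warning("chromosome(s) absent from reference, classifying as lincRNA: ",
            paste(miss_chr, collapse = ", "))

  # novel transcript spans
  nov_span <- .tx_gene_spans(
    data.frame(gene_id = novel$transcript_id, seqnames = novel$seqnames,
               strand = novel$strand, start = novel$start, end = novel$end))

  # (1) same-strand exonic overlap (seqlevel-mismatch chatter suppressed:
  # novel-only chromosomes are handled above)
  hit_sense <- suppressWarnings(
    GenomicRanges::findOverlaps(nov_ex, ref_ex, ignore.strand = FALSE))
  sense_tx <- unique(nov_ex$transcript_id[S4Vectors::queryHits(hit_sense)])

  # span-vs-gene-span overlaps, split by relative strand
  hit_any <- suppressWarnings(
    GenomicRanges::findOverlaps(nov_span, spans, ignore.strand = TRUE))
  q <- S4Vectors::queryHits(hit_any); s <- S4Vectors::subjectHits(hit_any)
  same_strand <- as.character(GenomicRanges::strand(nov_span))[q] ==
    as.character(GenomicRanges::strand(spans))[s]
  anti_tx <- unique(nov_span$gene_id[q[!same_strand]])

  # (3) containment in a same-strand gene span
  contained <- same_strand &
    (GenomicRanges::start(nov_span)[q] >= GenomicRanges::start(spans)[s]) &
    (GenomicRanges::end(nov_span)[q] <= GenomicRanges::end(spans)[s])
  intron_tx <- unique(nov_span$gene_id[q[contained]])

  cls <- stats::setNames(rep("lincRNA", length(tx_ids)), tx_ids)
  cls[tx_ids %in% intron_tx] <- "intronic"
  cls[tx_ids %in% anti_tx] <- "antisense"
  cls[tx_ids %in% sense_tx] <- "sense"
  data.frame(transcript_id = tx_ids, class = unname(cls[tx_ids]),
             stringsAsFactors = FALSE)
}

#' Histogram profiles of transcript length, exon count and ORF length
#'
#' Length histograms use fixed 200-nt bins capped at a final ">= 3000"
#' bin; exon histograms use unit bins capped at ">= 15"; ORF-length
#' histograms use 100-nt bins capped at ">= 1200".  Bin totals equal the
#' number of input transcripts.
#'
#' @param tx A [transcript_models] table.
#' @param orf_lengths Optional named numeric vector transcript id -> ORF
#'   length (nt).
#' @return Named list of data frames (`length`, `exons`, and `orf` when
#'   supplied), each with columns `bin` and `count`.
#' @export
profile_features <- function(tx, orf_lengths = NULL) {
  bin_up <- function(x, width, cap) {
    edges <- c(seq(0, cap, by = width), Inf)
    lo <- as.integer(utils::head(edges, -2))
    labs <- c(sprintf("[%d,%d)", lo, lo + as.integer(width)),
              sprintf(">=%d", as.integer(cap)))
    cut(x, breaks = edges, labels = labs, right = FALSE)
  }
  tab <- function(f) {
    t <- table(f)
    data.frame(bin = names(t), count = as.integer(t),
               stringsAsFactors = FALSE)
  }
  out <- list(
    length = tab(bin_up(transcript_lengths(tx), 200, 3000)),
    exons = tab(bin_up(exon_counts(tx), 1, 15)))
  if (!is.null(orf_lengths))
    out$orf <- tab(bin_up(orf_lengths, 100, 1200))
  out
}

#' Positional nucleotide bias of miRNA sequences
#'
#' Computes the per-position base composition of a set of mature miRNA
#' sequences (RNA alphabet A/C/G/U, minimum length 18 nt) and reports the
#' modal first and last base.  Sequences of unequal length are handled
#' with per-position denominators (position p counts only sequences of
#' length >= p); "last base" is the final base of each sequence
#' regardless of its length.
#'
#' @param sequences Character vector or `Biostrings::RNAStringSet` of
#'   miRNA sequences.
#' @return A list with `freq` (4 x max-length matrix of per-position
#'   frequencies, rows A/C/G/U, each column summing to 1 over observed
#'   bases), `first_base`, `last_base` (modal bases) and `n` (number of
#'   sequences).
#' @export
mirna_positional_bias <- function(sequences) {
  if (inherits(sequences, "XStringSet"))
    sequences <- as.character(sequences)
  sequences <- toupper(as.character(sequences))
  if (length(sequences) == 0L) stop("no sequences supplied")
  chars <- strsplit(sequences, "")
  bad <- vapply(chars, function(x) any(!x %in% c("A", "C", "G", "U")), TRUE)
  if (any(bad))
    stop("invalid character in sequence(s): only A/C/G/U are allowed")
  if (any(nchar(sequences) < 18L))
    stop("miRNA sequences must be at least 18 nt long")
  maxlen <- max(nchar(sequences))
  freq <- matrix(0, nrow = 4, ncol = maxlen,
                 dimnames = list(c("A", "C", "G", "U"),
                                 paste0("pos", seq_len(maxlen))))
  for (p in seq_len(maxlen)) {
    at_p <- vapply(chars, function(x) if (length(x) >= p) x[p] else NA_character_, "")
    at_p <- at_p[!is.na(at_p)]
    t <- table(factor(at_p, levels = c("A", "C", "G", "U")))
    freq[, p] <- as.numeric(t) / length(at_p)
  }
  modal <- function(x) names(which.max(table(x)))
  first <- vapply(chars, `[`, "", 1L)
  last <- vapply(chars, function(x) x[length(x)], "")
  list(freq = freq, first_base = modal(first), last_base = modal(last),
       n = length(sequences))
}
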