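# shared reference annotation: two genes on chr1, one per strand
ref_fixture <- function() {
  transcript_models(data.frame(
    transcript_id = c("rt1", "rt1", "rt2", "rt2"),
    gene_id = c("rg1", "rg1", "rg2", "rg2"),
    seqnames = "chr1",
    strand = c("+", "+", "-", "-"),
    start = c(1000, 3000, 10000, 12000),
    end = c(1500, 3600, 10800, 12700)))
}

novel_tx <- function(id, start, end, strand, chrom = "chr1") {
  transcript_models(data.frame(
    transcript_id = id, gene_id = paste0(id, ".g"), seqnames = chrom,
    strand = strand, start = start, end = end))
}

test_that("candidate filtering applies the length and exon rules", {
  tx <- transcript_models(data.frame(
    transcript_id = c("a", "a", "b", "c", "c"),
    gene_id = c("a", "a", "b", "c", "c"),
    seqnames = "chr1", strand = "+",
    start = c(0, 100, 500, 900, 1300),
    end = c(80, 170, 701, 1000, 1402)))
  # a: 2 exons, length 150 -> removed (length); b: 1 exon, 201 -> removed
  # (exons); c: 2 exons, 201 -> kept (boundary just above threshold)
  out <- filter_candidates(tx, min_length = 200, min_exons = 2)
  expect_identical(unique(out$transcript_id), "c")
  # literal "more than two exons" reading removes c as well
  expect_identical(nrow(filter_candidates(tx, min_exons = 3)), 0L)
  # a 200-nt transcript is not "over 200 nt"
  tx200 <- novel_tx("d", c(0, 300), c(100, 400), "+")
  expect_identical(nrow(filter_candidates(tx200)), 0L)
  # subset of input, idempotent, empty-safe
  expect_identical(filter_candidates(out), out)
  expect_identical(nrow(filter_candidates(out[0, ])), 0L)
})

test_that("positional classification follows the precedence rules", {
  ref <- ref_fixture()
  # wholly between the two genes, no overlap -> lincRNA
  expect_identical(classify_transcripts(novel_tx("n1", 5000, 5900, "+"), ref)$class,
                   "lincRNA")
  # exon overlapping a reference exon, same strand -> sense
  expect_identical(classify_transcripts(novel_tx("n2", 1400, 2000, "+"), ref)$class,
                   "sense")
  # exon overlapping a reference exon on the opposite strand -> antisense
  expect_identical(classify_transcripts(novel_tx("n3", 1400, 2000, "-"), ref)$class,
                   "antisense")
  # contained in the intron, same strand, no exon overlap -> intronic
  expect_identical(classify_transcripts(novel_tx("n4", 1600, 2100, "+"), ref)$class,
                   "intronic")
  # contained in the intron but opposite strand -> antisense (precedence 2)
  expect_identical(classify_transcripts(novel_tx("n5", 1600, 2100, "-"), ref)$class,
                   "antisense")
  # touching the gene span boundary exactly (half-open) is not overlap
  expect_identical(classify_transcripts(novel_tx("n6", 500, 1000, "+"), ref)$class,
                   "lincRNA")
  # touching exon end inside the gene is intronic, not sense
  expect_identical(classify_transcripts(novel_tx("n7", 1500, 2000, "+"), ref)$class,
                   "intronic")
})

test_that("unknown chromosomes classify as lincRNA with a warning", {
  ref <- ref_fixture()
  expect_warning(
    cls <- classify_transcripts(novel_tx("nx", 100, 600, "+", chrom = "chr9"), ref),
    "absent")
  expect_identical(cls$class, "lincRNA")
})

test_that("classification is invariant to reference row order", {
  ref <- ref_fixture()
  ann <- simulate_annotation(seed = 8)
  c1 <- classify_transcripts(ann$novel, ann$reference)
  shuf <- ann$reference[sample(nrow(ann$reference)), ]
  class(shuf) <- class(ann$reference)
  c2 <- classify_transcripts(ann$novel, shuf)
  expect_identical(c1[order(c1$transcript_id), ],
                   c2[order(c2$transcript_id), ])
})

test_that("the classifier recovers every planted class", {
  ann <- simulate_annotation(n_reference_genes = 15,
                             n_novel = c(lincRNA = 8, antisense = 8,
                                         sense = 8, intronic = 8),
                             seed = 9)
  got <- classify_transcripts(ann$novel, ann$reference)
  truth <- ann$truth$classes
  m <- merge(got, truth, by = "transcript_id")
  expect_identical(nrow(m), nrow(truth))
  expect_identical(m$class.x, m$class.y)
})

test_that("feature profiles bin lengths and exons with conserved totals", {
  tx <- transcript_models(data.frame(
    transcript_id = c("a", "b", "c", "c"), gene_id = c("a", "b", "c", "c"),
    seqnames = "chr1", strand = "+",
    start = c(0, 0, 0, 5000), end = c(450, 3500, 4500, 9500)))
  pf <- profile_features(tx, orf_lengths = c(a = 120, b = 350, c = 1500))
  # single transcript of length 450 -> one count in [400,600)
  expect_identical(pf$length$count[pf$length$bin == "[400,600)"], 1L)
  # lengths 3500 and 9000 both land in the >=3000 cap bin
  expect_identical(pf$length$count[pf$length$bin == ">=3000"], 2L)
  expect_identical(sum(pf$length$count), 3L)
  expect_identical(sum(pf$exons$count), 3L)
  expect_identical(pf$exons$count[pf$exons$bin == "[1,2)"], 2L)
  expect_identical(pf$exons$count[pf$exons$bin == "[2,3)"], 1L)
  expect_identical(pf$orf$count[pf$orf$bin == ">=1200"], 1L)
  expect_identical(sum(pf$orf$count), 3L)
})

test_that("miRNA positional bias counts bases per position", {
  seqs <- c(paste0("UAG", strrep("C", 18)),  # length 21
            paste0("UGG", strrep("C", 15)))  # length 18
  b <- mirna_positional_bias(seqs)
  expect_identical(b$first_base, "U")
  expect_equal(b$freq["U", 1], 1.0)
  expect_equal(b$freq["A", 2], 0.5)
  expect_equal(b$freq["G", 2], 0.5)
  # ragged tail: positions beyond 18 only count the longer sequence
  expect_equal(b$freq["C", 21], 1.0)
  # each position sums to 1 over observed bases
  expect_true(all(abs(colSums(b$freq) - 1) < 1e-12))
  # last base is the final base of each sequence regardless of length
  expect_identical(b$last_base, "C")
  # degenerate single sequence: frequencies are 0 or 1
  b1 <- mirna_positional_bias(seqs[1])
  expect_true(all(b1$freq %in% c(0, 1)))
  # validation
  expect_error(mirna_positional_bias("UAGT"), "18 nt|invalid")
  expect_error(mirna_positional_bias(paste0("UAGX", strrep("C", 20))),
               "invalid")
  # accepts Biostrings input
  rs <- Biostrings::RNAStringSet(seqs)
  expect_equal(mirna_positional_bias(rs)$freq, b$freq)
})
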