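test_that("clean prefix and single-substitution reads score as forced", {
  set.seed(21)
  ref <- random_seq(120)
  sc <- scoring_scheme()
  al <- align_semiglobal(substr(ref, 1L, 30L), ref, sc)
  expect_equal(al$cigar, "30M")
  expect_equal(al$score, 30 * sc$match)
  expect_equal(al$identity, 1)
  expect_equal(al$start, 1L)

  read <- ref
  substr(read, 60L, 60L) <- if (substr(ref, 60L, 60L) == "A") "C" else "A"
  al2 <- align_semiglobal(read, ref, sc)
  expect_equal(al2$score, 119 * sc$match + sc$mismatch)
  expect_equal(al2$cigar, "120M")

  expect_error(align_semiglobal("", ref), "non-empty")
})

test_that("banded DP equals the brute-force oracle on random pairs", {
  set.seed(22)
  sc <- scoring_scheme()
  for (k in 1:60) {
    rd <- random_seq(sample(5:40, 1L))
    rf <- random_seq(sample(5:40, 1L))
    expect_equal(align_semiglobal(rd, rf, sc, band = 60L)$score,
                 affine_score_oracle(rd, rf, sc))
  }
})

test_that("scores agree with an independent semi-global library aligner", {
  set.seed(23)
  sc <- scoring_scheme()
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = sc$match,
                                                  mismatch = sc$mismatch)
  for (k in 1:25) {
    rd <- random_seq(sample(10:60, 1L))
    rf <- random_seq(sample(40:80, 1L))
    ours <- align_semiglobal(rd, rf, sc, band = 100L)$score
    bs <- Biostrings::score(Biostrings::pairwiseAlignment(
      rd, rf, type = "global-local", substitutionMatrix = mat,
      gapOpening = -(sc$gap_open - sc$gap_extend),
      gapExtension = -sc$gap_extend))
    expect_equal(ours, bs)
  }
})

test_that("CIGAR bookkeeping invariants hold on every emitted record", {
  set.seed(24)
  sc <- scoring_scheme()
  for (k in 1:40) {
    rd <- random_seq(sample(10:80, 1L))
    rf <- random_seq(sample(10:80, 1L))
    al <- align_semiglobal(rd, rf, sc, band = 100L)
    expect_equal(cigar_query_length(al$cigar), nchar(rd))
    expect_lte(al$start - 1L + cigar_reference_length(al$cigar), nchar(rf))
    expect_gte(al$start, 1L)
  }
})

test_that("an intron-retaining read maps back as a single insertion op", {
  gA <- small_genes()$gA
  genome <- build_pseudogenome(unname(small_genes()), default_barcodes())
  ip <- gA$intron_insertion_point
  read <- make_reads("u", paste0("ATGCTAGC", unspliced_variant(gA)))
  best <- choose_best(read, genome)
  expect_identical(best$chrom, "gA_R1")
  expect_true(best$from_unspliced)
  ops <- parse_cigar(best$cigar)
  expect_identical(ops$op, c("M", "I", "M"))
  expect_equal(ops$len[2L], nchar(gA$intron))
  expect_equal(ops$len[1L], 8L + ip)
  # spliced reads on the same gene carry no indel ops at zero error
  clean <- choose_best(make_reads("c", paste0("CGTACGTA", gA$cdna)), genome)
  expect_identical(clean$chrom, "gA_R2")
  expect_identical(clean$cigar, paste0(8L + nchar(gA$cdna), "M"))
  expect_equal(clean$identity, 1)
})

test_that("best-chromosome choice honours barcode, floor, and tie rules", {
  genes <- small_genes()
  genome <- build_pseudogenome(unname(genes), default_barcodes())
  # random sequence stays unaligned at the identity floor
  set.seed(25)
  expect_null(choose_best(make_reads("x", random_seq(300L)), genome))
  # a barcode-free read ties across chromosomes of its gene: first wins
  tie <- choose_best(make_reads("t", genes$gB$cdna), genome)
  expect_identical(tie$chrom, "gB_R1")
  expect_true(tie$tie)
})

test_that("aligned plus unaligned counts conserve the input", {
  run <- simulate_run(small_config(seed = 303, reads_per_replicate = 8L))
  dx <- demultiplex(run$reads, default_barcodes())
  corrected <- do.call(rbind, dx$assigned)
  al <- align_all(corrected, genome <- run$genome, band = 80L)
  expect_equal(nrow(al$alignments) + al$unaligned, nrow(corrected))
  al0 <- align_all(corrected[0L, ], genome)
  expect_equal(nrow(al0$alignments), 0L)
  expect_equal(al0$unaligned, 0L)
})

test_that("imported SAM and built-in alignments agree on insertion calls", {
  gA <- small_genes()$gA
  genome <- build_pseudogenome(unname(small_genes()), default_barcodes())
  read <- make_reads("u1", paste0("ATGCTAGC", unspliced_variant(gA)))
  best <- choose_best(read, genome)
  ev_builtin <- scan_insertions(best, read, small_retention_config())

  sam <- c("@HD\tVN:1.6",
           paste0("@SQ\tSN:gA_R1\tLN:", nchar(genome$chromosomes[["gA_R1"]])),
           paste("u1", 0L, best$chrom, best$start, 60L, best$cigar, "*",
                 0L, 0L, read$seq, read$qual, sep = "\t"))
  f <- tempfile(fileext = ".sam")
  writeLines(sam, f)
  imported <- import_sam(f, genome)$alignments
  ev_sam <- scan_insertions(imported, read, small_retention_config())
  expect_equal(ev_sam, ev_builtin)
  expect_equal(nrow(ev_sam), 1L)
  expect_equal(ev_sam$insert_length, nchar(gA$intron))
})
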