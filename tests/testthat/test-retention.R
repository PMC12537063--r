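scan_case <- function(cigar, read_len, config = retention_config(),
                      start = 1L) {
  set.seed(41)
  read <- make_reads("r", random_seq(read_len))
  aln <- data.frame(read_id = "r", chrom = "gA_R1", start = start,
                    cigar = cigar, strand = "forward", score = 0,
                    identity = 1, stringsAsFactors = FALSE)
  scan_insertions(aln, read, config)
}

test_that("insertion scanning applies closed length bounds per I op", {
  ev <- scan_case("100M685I620M", 1405L)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$insert_length, 685L)
  expect_equal(ev$ref_position, 100L)
  expect_equal(ev$query_start, 101L)
  expect_equal(nchar(ev$insert_sequence), 685L)

  expect_equal(nrow(scan_case("1405M", 1405L)), 0L)
  expect_equal(nrow(scan_case("50M649I706M", 1405L)), 0L)
  expect_equal(nrow(scan_case("50M701I654M", 1405L)), 0L)
  # bounds are closed: exactly 650 and 700 count
  expect_equal(nrow(scan_case("50M650I705M", 1405L)), 1L)
  expect_equal(nrow(scan_case("50M700I655M", 1405L)), 1L)
})

test_that("nearby insertions merge only when a merge gap is allowed", {
  ev <- scan_case("100M300I2M400I603M", 1405L,
                  retention_config(merge_gap = 10L))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$insert_length, 700L)
  expect_equal(ev$ref_position, 100L)
  # default single-op semantics: the split insertions stay out of window
  expect_equal(nrow(scan_case("100M300I2M400I603M", 1405L)), 0L)
})

test_that("CIGAR/read length mismatches are rejected", {
  expect_error(scan_case("100M685I620M", 1400L), "read")
})

test_that("retention frequency and summaries reproduce reported values", {
  expect_equal(round(retention_frequency(4, 531), 2), 0.75)
  expect_equal(retention_frequency(0, 100), 0)
  expect_error(retention_frequency(5, 0), "undefined|U <= N")
  expect_error(retention_frequency(7, 5))

  wt <- retention_frequency(c(4, 4, 4), c(531, 439, 196))
  s <- summarize_retention(wt)
  expect_equal(round(s$mean, 1), 1.2)
  expect_equal(round(s$sd, 1), 0.7)
})

test_that("insert extraction names entries and recovers exact sequences", {
  gA <- small_genes()$gA
  genome <- build_pseudogenome(unname(small_genes()), default_barcodes())
  read <- make_reads("u1", paste0("ATGCTAGC", unspliced_variant(gA)))
  best <- choose_best(read, genome)
  ev <- scan_insertions(best, read, small_retention_config())
  expect_equal(nrow(ev), 1L)
  f <- tempfile(fileext = ".fasta")
  seqs <- extract_inserts(ev, read, f)
  expect_identical(names(seqs),
                   paste("u1", ev$ref_position, ev$insert_length, sep = "_"))
  expect_identical(unname(seqs), gA$intron)
  expect_identical(read_fasta(f), seqs)
  expect_error(extract_inserts(ev, read[0L, ]), "missing")
})

test_that("insert validation against the intron has an explicit contract", {
  intron <- synthetic_genes()[[1L]]$intron
  hit <- align_insert_to_intron(intron, intron)
  expect_equal(hit$identity, 100)
  expect_equal(hit$alignment_length, 685L)
  expect_true(hit$matched)

  # seven interior substitutions: identity 678/685
  mut <- intron
  for (p in seq(50L, 650L, by = 100L)) {
    substr(mut, p, p) <- chartr("ACGT", "CATG", substr(mut, p, p))
  }
  hit2 <- align_insert_to_intron(mut, intron)
  expect_equal(hit2$identity, 100 * 678 / 685, tolerance = 1e-6)
  expect_true(hit2$matched)

  set.seed(43)
  hit3 <- align_insert_to_intron(random_seq(685L), intron)
  expect_false(hit3$matched)
})

test_that("retention comparisons default to one-tailed Welch semantics", {
  p112 <- retention_frequency(c(40, 27, 9), c(501, 330, 122))
  wt <- retention_frequency(c(4, 4, 4), c(531, 439, 196))
  cmp <- compare_retention(p112, wt)
  expect_identical(cmp$tails, "one")
  expect_lt(cmp$p, 0.01)

  same <- compare_retention(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 0.5)
  swap <- compare_retention(wt, p112)
  expect_equal(swap$p, 1 - cmp$p, tolerance = 1e-12)
})
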