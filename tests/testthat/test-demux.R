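test_that("reverse complement flips sequence and reverses qualities", {
  x <- make_reads("r", "ACGT", "IIFF")
  rc <- reverse_complement(x)
  expect_identical(rc$seq, "ACGT")       # palindrome
  expect_identical(rc$qual, "FFII")
  expect_identical(rc$id, "r")

  y <- make_reads("r2", "AACN", "ABCD")
  rc2 <- reverse_complement(y)
  expect_identical(rc2$seq, "NGTT")
  expect_identical(rc2$qual, "DCBA")

  # involution
  set.seed(1)
  z <- make_reads("r3", random_seq(57), paste(sample(c("!", "5", "I"), 57,
                                                     TRUE), collapse = ""))
  expect_equal(reverse_complement(reverse_complement(z)), z)

  expect_error(reverse_complement(make_reads("r", "ACRT", "IIII")), "A/C/G/T/N")
})

test_that("orientation detection classifies sense/antisense/none/ambiguous", {
  bcs <- default_barcodes()
  body <- substr(small_genes()$gA$cdna, 1L, 80L)    # scrubbed of look-alikes
  sense <- make_reads("s", paste0("ATGCTAGC", body))
  got <- detect_orientation(sense, bcs)
  expect_identical(got$orientation, "sense")
  expect_identical(got$label, "R1")

  anti <- reverse_complement(sense)
  got <- detect_orientation(anti, bcs)
  expect_identical(got$orientation, "antisense")
  expect_identical(got$label, "R1")

  none <- make_reads("n", body)
  expect_identical(detect_orientation(none, bcs)$orientation, "none")

  amb <- make_reads("a", paste0("ATGCTAGC", substr(body, 1L, 10L),
                                "TACGATCG", body))
  expect_identical(detect_orientation(amb, bcs)$orientation, "ambiguous")
})

test_that("demultiplexing corrects strands and partitions every read", {
  bcs <- default_barcodes()
  body <- small_genes()$gA$cdna
  set.seed(42)
  sense <- make_reads(sprintf("s%02d", 1:10), rep(paste0("CGTACGTA", body), 10))
  anti <- reverse_complement(make_reads(sprintf("a%02d", 1:10),
                                        rep(paste0("CGTACGTA", body), 10)))
  junk <- make_reads(sprintf("j%02d", 1:5),
                     vapply(1:5, function(i) substr(body, 30L, 200L),
                            character(1)))
  dx <- demultiplex(rbind(sense, anti, junk), bcs,
                    demux_config(search_window = 50L, max_mismatches = 0L))
  expect_equal(nrow(dx$assigned$R2), 20L)
  expect_true(all(startsWith(dx$assigned$R2$seq, "CGTACGTA")))
  expect_equal(nrow(dx$unassigned), 5L)
  expect_equal(sum(dx$counts), 25L)

  # orientation idempotence: corrected output is all-sense and unchanged
  again <- demultiplex(dx$assigned$R2, bcs)
  expect_equal(again$assigned$R2$seq, dx$assigned$R2$seq)
  expect_equal(nrow(again$unassigned) + nrow(again$ambiguous), 0L)

  # empty input
  dx0 <- demultiplex(sense[0L, ], bcs)
  expect_equal(sum(dx0$counts), 0L)
})

test_that("demux assignment is perfect on error-free simulated reads", {
  run <- simulate_run(small_config(seed = 301, sub_rate = 0, ins_rate = 0,
                                   del_rate = 0, reads_per_replicate = 25L))
  dx <- demultiplex(run$reads, default_barcodes())
  truth <- setNames(run$truth$label, run$truth$read_id)
  for (lab in names(dx$assigned)) {
    ids <- dx$assigned[[lab]]$id
    expect_true(all(truth[ids] == lab))
  }
  expect_equal(sum(vapply(dx$assigned, nrow, integer(1))), nrow(run$reads))
  # strand correction: every assigned read now starts with its barcode
  for (lab in names(dx$assigned)) {
    bc <- default_barcodes()$sequence[default_barcodes()$label == lab]
    expect_true(all(startsWith(dx$assigned[[lab]]$seq, bc)))
  }
})

test_that("misassignment stays below 1% at 2% substitution error", {
  cfg <- small_config(seed = 302, reads_per_replicate = 334L,
                      sub_rate = 0.02, ins_rate = 0, del_rate = 0,
                      retention_prob = 0)
  cfg$genes <- cfg$genes["gA"]
  cfg$sites <- cfg$sites[cfg$sites$gene == "gA", , drop = FALSE]
  run <- simulate_run(cfg)                     # 1002 reads
  dx <- demultiplex(run$reads, default_barcodes())
  truth <- setNames(run$truth$label, run$truth$read_id)
  assigned <- 0L; wrong <- 0L
  for (lab in names(dx$assigned)) {
    ids <- dx$assigned[[lab]]$id
    assigned <- assigned + length(ids)
    wrong <- wrong + sum(truth[ids] != lab)
  }
  expect_gt(assigned, 900L)
  expect_lt(wrong / assigned, 0.01)
})
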