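# A hand-built pileup fixture: one gene, one replicate, site at CDS 10
# (chromosome position 18 behind the 8-nt barcode).
pileup_fixture <- function() {
  set.seed(31)
  cdna <- random_seq(40L)
  substr(cdna, 10L, 10L) <- "C"
  gene <- gene_reference("g", cdna)
  genome <- build_pseudogenome(gene, barcode_set("R1", "ATGCTAGC"))
  chrom <- genome$chromosomes[["g_R1"]]
  with_T <- chrom; substr(with_T, 18L, 18L) <- "T"
  with_del <- paste0(substr(chrom, 1L, 17L), substr(chrom, 19L, 48L))
  reads <- rbind(
    make_reads(sprintf("c%d", 1:6), rep(chrom, 6)),
    make_reads(sprintf("t%d", 1:3), rep(with_T, 3)),
    make_reads(sprintf("d%d", 1:2), rep(with_del, 2)),
    make_reads("short", substr(chrom, 1L, 10L)))
  aln <- data.frame(
    read_id = reads$id,
    chrom = "g_R1",
    start = 1L,
    cigar = c(rep("48M", 9), rep("17M1D30M", 2), "10M"),
    strand = "forward", score = 0, identity = 1,
    stringsAsFactors = FALSE)
  site <- data.frame(site = "s1", gene = "g", cds_position = 10L,
                     context = substr(cdna, 8L, 12L))
  list(genome = genome, reads = reads, aln = aln, site = site)
}

test_that("pileup tallies bases, deletions, and skips uncovered reads", {
  fx <- pileup_fixture()
  pc <- pileup_counts(fx$aln, fx$reads, fx$genome, fx$site)
  expect_equal(pc$C, 6L)
  expect_equal(pc$T, 3L)
  expect_equal(pc$deletions, 2L)
  expect_equal(pc$other, 0L)
  expect_equal(pc$position, 18L)
  # C + T + other + deletions never exceeds aligned reads
  expect_lte(pc$C + pc$T + pc$other + pc$deletions, nrow(fx$aln))
})

test_that("pileup respects base-quality and indel-window filters", {
  fx <- pileup_fixture()
  # degrade the site base quality of one C read below the floor
  qual <- fx$reads$qual[1L]
  substr(qual, 18L, 18L) <- "!"
  fx$reads$qual[1L] <- qual
  pc <- pileup_counts(fx$aln, fx$reads, fx$genome, fx$site,
                      min_base_quality = 10L)
  expect_equal(pc$C, 5L)

  # an insertion 3 bases from the site excludes the call by default...
  fx2 <- pileup_fixture()
  fx2$aln$cigar[1L] <- "20M1I28M"
  fx2$reads$seq[1L] <- paste0(substr(fx2$reads$seq[1L], 1L, 20L), "A",
                              substr(fx2$reads$seq[1L], 21L, 48L))
  fx2$reads$qual[1L] <- strrep("I", 49L)
  pc2 <- pileup_counts(fx2$aln, fx2$reads, fx2$genome, fx2$site)
  expect_equal(pc2$C, 5L)
  expect_equal(pc2$indel_excluded, 1L)
  # ...but is counted with the window disabled
  pc3 <- pileup_counts(fx2$aln, fx2$reads, fx2$genome, fx2$site,
                       indel_window = 0L)
  expect_equal(pc3$C, 6L)
})

test_that("editing efficiency follows T/(C+T) with bounded range", {
  expect_equal(round(editing_efficiency(52, 210), 2), 80.15)
  expect_equal(editing_efficiency(0, 25), 100)
  expect_equal(editing_efficiency(7, 0), 0)
  expect_error(editing_efficiency(0, 0), "not covered")
  # monotone in T for fixed C, bounded in [0, 100]
  e <- editing_efficiency(rep(10, 50), 1:50)
  expect_true(all(diff(e) > 0))
  expect_true(all(e >= 0 & e <= 100))
})

test_that("replicate summaries reproduce reported mean and SD values", {
  b2 <- editing_efficiency(c(52, 20, 7), c(210, 150, 74))
  s <- summarize_replicates(b2)
  expect_equal(round(s$mean, 1), 86.6)
  expect_equal(round(s$sd, 1), 5.8)
  wt5 <- editing_efficiency(c(3, 2, 2), c(295, 319, 142))
  expect_equal(round(summarize_replicates(wt5)$mean, 1), 99.0)
  s0 <- summarize_replicates(c(50, 50, 50))
  expect_equal(s0$mean, 50)
  expect_equal(s0$sd, 0)
})

test_that("group comparisons run the Welch test with editing defaults", {
  wt <- editing_efficiency(c(3, 2, 2), c(295, 319, 142))
  krab <- editing_efficiency(c(7, 6, 3), c(327, 271, 146))
  cmp <- compare_groups(wt, krab)
  expect_identical(cmp$tails, "two")
  expect_gt(cmp$p, 0.030)
  expect_lt(cmp$p, 0.040)
  cmp2 <- compare_groups(c(10, 11, 12), c(20, 21, 22))
  expect_equal(cmp2$t, -12.247, tolerance = 1e-4)
  expect_equal(cmp2$df, 4)
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("error-free pileups recover simulated editing probabilities", {
  set.seed(32)
  cdna <- random_seq(60L)
  substr(cdna, 20L, 20L) <- "C"
  gene <- gene_reference("g", cdna)
  genome <- build_pseudogenome(gene, barcode_set("R1", "ATGCTAGC"))
  chrom <- genome$chromosomes[["g_R1"]]
  edited_chrom <- chrom; substr(edited_chrom, 28L, 28L) <- "T"
  site <- data.frame(site = "s1", gene = "g", cds_position = 20L,
                     context = substr(cdna, 18L, 22L))
  for (p in c(0.05, 0.5, 0.8, 0.95)) {
    n <- 500L
    flags <- rbinom(n, 1L, p) == 1L
    reads <- make_reads(sprintf("r%03d", seq_len(n)),
                        ifelse(flags, edited_chrom, chrom))
    aln <- data.frame(read_id = reads$id, chrom = "g_R1", start = 1L,
                      cigar = "68M", strand = "forward", score = 0,
                      identity = 1, stringsAsFactors = FALSE)
    pc <- pileup_counts(aln, reads, genome, site)
    est <- editing_efficiency(pc$C, pc$T)
    expect_equal(est, 100 * mean(flags))  # digital identity at zero error
    # recovery of the generating probability; 3-sigma bound so the fixed
    # draw cannot flake (the end-to-end acceptance run asserts the 95%
    # interval on the full pipeline)
    expect_lte(abs(est - 100 * p), binom_margin(p, n, z = 3))
  }
})

test_that("substitution error biases a fully edited site down by at most e", {
  set.seed(33)
  cdna <- random_seq(60L)
  substr(cdna, 20L, 20L) <- "C"
  gene <- gene_reference("g", cdna)
  genome <- build_pseudogenome(gene, barcode_set("R1", "ATGCTAGC"))
  template <- genome$chromosomes[["g_R1"]]
  substr(template, 28L, 28L) <- "T"     # fully edited
  n <- 1000L
  seqs <- vapply(seq_len(n), function(i)
    tipseq:::apply_read_errors(template, 0.02, 0, 0), character(1))
  reads <- make_reads(sprintf("r%04d", seq_len(n)), seqs)
  aln <- data.frame(read_id = reads$id, chrom = "g_R1", start = 1L,
                    cigar = "68M", strand = "forward", score = 0,
                    identity = 1, stringsAsFactors = FALSE)
  site <- data.frame(site = "s1", gene = "g", cds_position = 20L,
                     context = substr(cdna, 18L, 22L))
  pc <- pileup_counts(aln, reads, genome, site)
  est <- editing_efficiency(pc$C, pc$T)
  expect_lt(est, 100)                  # T-to-C errors read as unedited
  expect_gte(est, 100 - 2)             # bias bounded by the error rate
})
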