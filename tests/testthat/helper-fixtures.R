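# Shared small fixtures, built in code.  The short study (300/280-nt
# cDNAs, 60-nt intron) keeps alignment-heavy tests fast; the retention
# window is scaled with the intron.

random_seq <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

make_reads <- function(ids, seqs, quals = strrep("I", nchar(seqs)))
  data.frame(id = ids, seq = seqs, qual = quals, stringsAsFactors = FALSE)

small_genes <- function() {
  gA <- local({
    set.seed(11)
    tipseq:::scrub_barcode_lookalikes(tipseq:::embed_contexts(
      tipseq:::random_dna(300),
      data.frame(site = "sA", gene = "gA", cds_position = 100L,
                 context = "TTCAA")))
  })
  intr <- local({ set.seed(12); tipseq:::random_dna(60) })
  gB <- local({
    set.seed(13)
    tipseq:::scrub_barcode_lookalikes(tipseq:::embed_contexts(
      tipseq:::random_dna(280),
      data.frame(site = "sB", gene = "gB", cds_position = 50L,
                 context = "ATCAT")))
  })
  list(gA = gene_reference("gA", gA, intron = intr,
                           intron_insertion_point = 150L),
       gB = gene_reference("gB", gB))
}

small_sites <- function()
  data.frame(site = c("sA", "sB"), gene = c("gA", "gB"),
             cds_position = c(100L, 50L), context = c("TTCAA", "ATCAT"),
             stringsAsFactors = FALSE)

small_config <- function(seed, reads_per_replicate = 30L,
                         site_edit_prob = c(sA = 0.8, sB = 0.5),
                         retention_prob = 0.2, sub_rate = 0.02,
                         ins_rate = 0.01, del_rate = 0.01, ...) {
  simulation_config(genes = unname(small_genes()), sites = small_sites(),
                    site_edit_prob = site_edit_prob,
                    retention_prob = retention_prob,
                    reads_per_replicate = reads_per_replicate,
                    sub_rate = sub_rate, ins_rate = ins_rate,
                    del_rate = del_rate, seed = seed, ...)
}

small_retention_config <- function() retention_config(50L, 70L)
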