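#' Synthetic gene references for simulation
#'
#' Two synthetic target genes emulating the shape of the chloroplast
#' ndhB/ndhD amplicons: gene A ("ndhB"-like) has a 1405-nt spliced cDNA
#' carrying two editing sites (CDS positions 149 and 467, with TTCAA and
#' TCCAG contexts) and a 685-nt group-II-style intron inserted after CDS
#' position 723; gene B ("ndhD"-like) has a 1503-nt cDNA with one site at
#' position 383 (ATCAT context).  Sequences are generated from a fixed
#' internal seed -- they are synthetic stand-ins, not the biological
#' references -- and are scrubbed so that no 8-mer within Hamming
#' distance 1 of a default barcode (either orientation) occurs inside the
#' demultiplexing search windows, keeping simulated barcode truth
#' unambiguous.
#'
#' @return A list of two [gene_reference()] objects.
#' @export
synthetic_genes <- function() {
  with_local_seed(104729L, {
    sites <- synthetic_sites()
    cdnaB <- random_dna(1405L)
    cdnaB <- embed_contexts(cdnaB, sites[sites$gene == "ndhB", ])
    cdnaB <- scrub_barcode_lookalikes(cdnaB)
    cdnaD <- random_dna(1503L)
    cdnaD <- embed_contexts(cdnaD, sites[sites$gene == "ndhD", ])
    cdnaD <- scrub_barcode_lookalikes(cdnaD)
    intron <- paste0("GTGCG", random_dna(678L), "AT")  # group-II-like ends
    list(gene_reference("ndhB", cdnaB, intron = intron,
                        intron_insertion_point = 723L),
         gene_reference("ndhD", cdnaD))
  })
}

#' @return For [synthetic_sites()]: the editing-site table matching
#'   [synthetic_genes()] (columns `site`, `gene`, `cds_position`,
#'   `context`).
#' @rdname synthetic_genes
#' @export
synthetic_sites <- function() {
  data.frame(site = c("ndhB1", "ndhB2", "ndhD1"),
             gene = c("ndhB", "ndhB", "ndhD"),
             cds_position = c(149L, 467L, 383L),
             context = c("TTCAA", "TCCAG", "ATCAT"),
             stringsAsFactors = FALSE)
}

random_dna <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

embed_contexts <- function(seq, site_rows) {
  for (i in seq_len(nrow(site_rows))) {
    p <- site_rows$cds_position[i]
    substr(seq, p - 2L, p + 2L) <- site_rows$context[i]
  }
  seq
}

# Mutate away any 8-mer within Hamming distance 1 of a default barcode
# (or its reverse complement) inside the first 92 / last 100 cDNA bases
# (the parts of a full-length read that fall into the demux windows).
scrub_barcode_lookalikes <- function(seq, window = 100L) {
  bcs <- default_barcodes()$sequence
  pats <- c(bcs, as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(bcs))))
  L <- nchar(seq)
  regions <- list(c(1L, window - 8L), c(L - window + 1L, L))
  repeat {
    hit <- NULL
    dna <- Biostrings::DNAString(seq)
    for (rg in regions) {
      part <- Biostrings::subseq(dna, rg[1L], rg[2L])
      for (p in pats) {
        m <- Biostrings::matchPattern(p, part, max.mismatch = 1)
        if (length(m) > 0L) {
          hit <- rg[1L] - 1L + Biostrings::start(m)[1L] + 3L  # middle base
          break
        }
      }
      if (!is.null(hit)) break
    }
    if (is.null(hit)) return(seq)
    substr(seq, hit, hit) <- sample(setdiff(c("A", "C", "G", "T"),
                                            substr(seq, hit, hit)), 1L)
  }
}

with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulation configuration for a multiplexed TIP run
#'
#' Defaults reproduce the package's reference study conditions: two genes
#' by three barcoded replicates pooled in one run, 200 reads per
#' replicate (within the observed 122-636 per-replicate range of real
#' runs), per-site editing probabilities 0.95/0.80/0.50, intron-retention
#' probability 0.078 on the intron-bearing gene, 2% substitution and
#' 1%/1% insertion/deletion error rates, constant Phred 20 base
#' qualities, and random read strand.
#'
#' @param genes List of [gene_reference()] objects.
#' @param barcodes A [barcode_set()].
#' @param sites Editing-site table for the genes.
#' @param site_edit_prob Named probability per site label.
#' @param retention_prob Intron-retention probability (intron-bearing
#'   genes only).
#' @param reads_per_replicate Reads per (gene, barcode).
#' @param sub_rate,ins_rate,del_rate Per-base error probabilities.
#' @param base_quality Constant Phred quality for simulated bases.
#' @param truncation_prob Probability that a read is 5'/3'-truncated at a
#'   uniform breakpoint (off by default: full-length amplicons).
#' @param seed Integer seed; randomness is never implicit.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(genes = synthetic_genes(),
                              barcodes = default_barcodes(),
                              sites = synthetic_sites(),
                              site_edit_prob = c(ndhB1 = 0.95, ndhB2 = 0.80,
                                                 ndhD1 = 0.50),
                              retention_prob = 0.078,
                              reads_per_replicate = 200L,
                              sub_rate = 0.02, ins_rate = 0.01,
                              del_rate = 0.01, base_quality = 20L,
                              truncation_prob = 0, seed) {
  if (missing(seed)) stop("an explicit integer seed is required")
  stopifnot(all(c(site_edit_prob, retention_prob, sub_rate, ins_rate,
                  del_rate, truncation_prob) >= 0),
            all(c(site_edit_prob, retention_prob, sub_rate, ins_rate,
                  del_rate, truncation_prob) <= 1),
            reads_per_replicate >= 1L)
  if (inherits(genes, "gene_reference")) genes <- list(genes)
  gnames <- vapply(genes, `[[`, character(1), "name")
  stopifnot(all(sites$gene %in% gnames),
            all(sites$site %in% names(site_edit_prob)))
  for (i in seq_len(nrow(sites))) {
    g <- genes[[match(sites$gene[i], gnames)]]
    p <- sites$cds_position[i]
    if (p > nchar(g$cdna))
      stop("site '", sites$site[i], "' lies beyond the cDNA of its gene")
    if (substr(g$cdna, p, p) != "C")
      stop("site '", sites$site[i], "': reference base at CDS position ",
           p, " is not C")
  }
  structure(list(genes = setNames(genes, gnames), barcodes = barcodes,
                 sites = sites, site_edit_prob = site_edit_prob,
                 retention_prob = retention_prob,
                 reads_per_replicate = as.integer(reads_per_replicate),
                 sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate, base_quality = as.integer(base_quality),
                 truncation_prob = truncation_prob,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Apply per-base sequencing errors to a template (deletion, then
# substitution to a uniformly drawn different base, then single-base
# insertions after surviving bases), consuming the current RNG stream.
apply_read_errors <- function(seq, sub_rate, ins_rate, del_rate) {
  chars <- strsplit(seq, NULL)[[1L]]
  n <- length(chars)
  keep <- runif(n) >= del_rate
  chars <- chars[keep]
  n2 <- length(chars)
  if (n2 == 0L) return("")
  subm <- runif(n2) < sub_rate
  if (any(subm)) {
    alt <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG", N = "ACGT")
    for (i in which(subm)) {
      ch <- strsplit(alt[[chars[i]]], NULL)[[1L]]
      chars[i] <- ch[sample.int(length(ch), 1L)]
    }
  }
  insm <- runif(n2) < ins_rate
  if (any(insm)) {
    counts <- 1L + insm
    res <- character(sum(counts))
    ends <- cumsum(counts)
    res[ends - insm] <- chars
    res[ends[insm]] <- sample(c("A", "C", "G", "T"), sum(insm),
                              replace = TRUE)
    chars <- res
  }
  paste(chars, collapse = "")
}

#' Simulate one barcoded amplicon read
#'
#' Template = barcode + spliced cDNA, or barcode + unspliced variant when
#' the retention draw fires; each site's C is flipped to T with its
#' editing probability; sequencing errors are applied after the
#' editing/retention decisions and before the strand flip (mirroring
#' template state, then sequencing error, then observed strand); with
#' probability 0.5 the read is reverse-complemented.  Consumes the
#' current RNG stream -- [simulate_run()] seeds it.
#'
#' @param config A [simulation_config()].
#' @param gene_name Gene to simulate.
#' @param label Barcode label.
#' @param read_id Identifier for the read.
#' @return List with `record` (one-row read set data frame) and `truth`
#'   (gene, label, strand, retained, and per-site edited flags).
#' @export
simulate_read <- function(config, gene_name, label, read_id) {
  gene <- config$genes[[gene_name]]
  bc <- config$barcodes$sequence[config$barcodes$label == label]
  stopifnot(!is.null(gene), length(bc) == 1L)
  sites <- config$sites[config$sites$gene == gene_name, , drop = FALSE]
  edited <- setNames(rbinom(nrow(sites), 1L,
                            config$site_edit_prob[sites$site]) == 1L,
                     sites$site)
  retained <- !is.null(gene$intron) &&
    rbinom(1L, 1L, config$retention_prob) == 1L
  body <- if (retained) unspliced_variant(gene) else gene$cdna
  ip <- gene$intron_insertion_point
  ilen <- if (is.null(gene$intron)) 0L else nchar(gene$intron)
  for (i in seq_len(nrow(sites))) {
    if (!edited[[i]]) next
    p <- sites$cds_position[i]
    if (retained && p > ip) p <- p + ilen
    substr(body, p, p) <- "T"
  }
  template <- paste0(bc, body)
  if (config$truncation_prob > 0 && runif(1L) < config$truncation_prob) {
    brk <- sample.int(nchar(template) - 1L, 1L)
    template <- if (runif(1L) < 0.5) substr(template, 1L, brk)
                else substr(template, brk + 1L, nchar(template))
  }
  seq <- apply_read_errors(template, config$sub_rate, config$ins_rate,
                           config$del_rate)
  antisense <- runif(1L) < 0.5
  rec <- data.frame(id = read_id, seq = seq,
                    qual = strrep(intToUtf8(33L + config$base_quality),
                                  nchar(seq)),
                    stringsAsFactors = FALSE)
  if (antisense) rec <- reverse_complement(rec)
  list(record = rec,
       truth = data.frame(read_id = read_id, gene = gene_name,
                          label = label,
                          strand = if (antisense) "antisense" else "sense",
                          retained = retained,
                          t(as.integer(edited)) |>
                            `colnames<-`(sites$site) |> as.data.frame(),
                          stringsAsFactors = FALSE))
}

#' Simulate a pooled multiplexed TIP sequencing run
#'
#' Generates `reads_per_replicate` reads for every (gene, barcode) pair,
#' shuffles them into one pooled read set, and returns full ground truth.
#' Byte-identical across runs for a fixed seed (R's default Mersenne
#' Twister RNG).
#'
#' @param config A [simulation_config()].
#' @param outdir Optional directory; when given, writes `run.fastq`,
#'   `truth_reads.tsv`, `truth_summary.tsv`, `pseudogenome.fasta` and
#'   `sites.tsv` there.
#' @return List with `reads` (pooled, shuffled read set), `truth`
#'   (per-read table: gene, label, strand, retained, per-site edited
#'   flags), `truth_summary` (realised per-site editing fraction and
#'   realised retention fraction per replicate), and `genome` (the
#'   matching [build_pseudogenome()] object).
#' @export
simulate_run <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  recs <- list(); truths <- list()
  for (g in names(config$genes)) {
    for (lab in config$barcodes$label) {
      for (k in seq_len(config$reads_per_replicate)) {
        id <- sprintf("sim_%s_%s_%04d", g, lab, k)
        one <- simulate_read(config, g, lab, id)
        recs[[id]] <- one$record
        truths[[id]] <- one$truth
      }
    }
  }
  reads <- do.call(rbind, recs)
  reads <- reads[sample.int(nrow(reads)), , drop = FALSE]
  rownames(reads) <- NULL
  truth <- do.call(rbind, lapply(truths, function(d) {
    for (s in config$sites$site)
      if (!s %in% names(d)) d[[s]] <- NA_integer_
    d[, c("read_id", "gene", "label", "strand", "retained",
          config$sites$site)]
  }))
  rownames(truth) <- NULL
  summ <- list()
  for (g in names(config$genes)) {
    for (lab in config$barcodes$label) {
      sub <- truth[truth$gene == g & truth$label == lab, , drop = FALSE]
      for (s in config$sites$site[config$sites$gene == g])
        summ[[length(summ) + 1L]] <- data.frame(
          gene = g, label = lab, measure = paste0("editing_", s),
          value = mean(sub[[s]]), stringsAsFactors = FALSE)
      if (!is.null(config$genes[[g]]$intron))
        summ[[length(summ) + 1L]] <- data.frame(
          gene = g, label = lab, measure = "retention",
          value = mean(sub$retained), stringsAsFactors = FALSE)
    }
  }
  truth_summary <- do.call(rbind, summ)
  genome <- build_pseudogenome(unname(config$genes), config$barcodes)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_fastq(reads, file.path(outdir, "run.fastq"))
    write_table(truth, file.path(outdir, "truth_reads.tsv"))
    write_table(truth_summary, file.path(outdir, "truth_summary.tsv"))
    write_pseudogenome(genome, file.path(outdir, "pseudogenome.fasta"))
    write_table(config$sites, file.path(outdir, "sites.tsv"))
  }
  list(reads = reads, truth = truth, truth_summary = truth_summary,
       genome = genome)
}
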