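#' Run the full TIP analysis pipeline on one pooled run
#'
#' One sequencing reaction pools two genes by three barcoded replicates
#' for a single genotype; this runs demultiplexing with strand
#' correction, pseudo-genome alignment, editing-site quantification and
#' intron-retention analysis for such a run, asserting read conservation
#' at every stage (input = assigned + unassigned + ambiguous;
#' assigned = aligned + unaligned).  Cross-genotype statistics are
#' computed from per-genotype outputs with [counts_only()].
#'
#' @param reads Read set data frame or path to a pooled FASTQ file.
#' @param genome A [build_pseudogenome()] result.
#' @param sites Editing-site table ([read_site_table()] or compatible
#'   data frame).
#' @param barcodes A [barcode_set()]; defaults to the genome's labels
#'   with [default_barcodes()] sequences must be supplied explicitly if
#'   different.
#' @param demux A [demux_config()].
#' @param scoring A [scoring_scheme()].
#' @param retention A [retention_config()].
#' @param band Alignment band half-width.
#' @param min_identity Alignment identity floor.
#' @param min_base_quality Pileup base-quality floor.
#' @param exclude_unspliced Drop intron-retaining reads from editing
#'   pileups.
#' @param indel_window Exclusion window for indel-adjacent base calls in
#'   the editing pileup (see [pileup_counts()]).
#' @param outdir Optional output directory for TSV/FASTA reports and a
#'   run log.
#' @return List with `demux` (bin counts), `alignments`, `unaligned`,
#'   `editing` (counts/efficiencies/summary), `retention`
#'   (events/table), `aligned_counts`, and `log` (parameter and
#'   conservation record).
#' @export
run_all <- function(reads, genome, sites, barcodes = default_barcodes(),
                    demux = demux_config(), scoring = scoring_scheme(),
                    retention = retention_config(), band = 150L,
                    min_identity = 0.6, min_base_quality = 0L,
                    exclude_unspliced = FALSE, indel_window = 5L,
                    outdir = NULL) {
  if (is.character(reads)) reads <- read_fastq(reads)
  validate_reads(reads)
  stopifnot(inherits(genome, "pseudogenome"))

  dx <- demultiplex(reads, barcodes, demux)
  stopifnot(sum(dx$counts) == nrow(reads))
  corrected <- do.call(rbind, dx$assigned)
  rownames(corrected) <- NULL

  if (nrow(corrected)) {
    al <- align_all(corrected, genome, scoring, band, min_identity)
  } else {
    al <- list(alignments = empty_alignments(), unaligned_ids = character(),
               unaligned = 0L)
  }
  stopifnot(nrow(al$alignments) + al$unaligned == nrow(corrected))

  if (nrow(al$alignments)) {
    ed <- editing_results(al$alignments, corrected, genome, sites,
                          min_base_quality, exclude_unspliced,
                          indel_window)
    rt <- retention_results(al$alignments, corrected, genome, retention)
  } else {
    warning("no reads aligned; reports are empty")
    ed <- list(counts = NULL, efficiencies = NULL, summary = NULL)
    rt <- list(events = empty_insertion_events(), table = NULL)
  }
  ac <- aligned_read_counts(al$alignments, genome)

  log <- list(
    parameters = list(demux = demux, scoring = unclass(scoring),
                      retention = unclass(retention), band = band,
                      min_identity = min_identity,
                      min_base_quality = min_base_quality,
                      exclude_unspliced = exclude_unspliced),
    reads_in = nrow(reads), demux_counts = dx$counts,
    assigned = nrow(corrected), aligned = nrow(al$alignments),
    unaligned = al$unaligned,
    conservation = c(demux_ok = sum(dx$counts) == nrow(reads),
                     align_ok = nrow(al$alignments) + al$unaligned ==
                       nrow(corrected)))

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (lab in names(dx$assigned))
      write_fastq(dx$assigned[[lab]], file.path(outdir,
                                                paste0(lab, ".fastq")))
    write_fastq(dx$unassigned, file.path(outdir, "unassigned.fastq"))
    write_fastq(dx$ambiguous, file.path(outdir, "ambiguous.fastq"))
    write_table(data.frame(bin = names(dx$counts),
                           reads = as.integer(dx$counts)),
                file.path(outdir, "demux_summary.tsv"))
    if (nrow(al$alignments))
      write_table(al$alignments, file.path(outdir, "alignments.tsv"))
    if (!is.null(ed$counts))
      write_table(ed$counts, file.path(outdir, "editing_counts.tsv"))
    if (!is.null(ed$summary))
      write_table(ed$summary, file.path(outdir, "editing_summary.tsv"))
    if (!is.null(rt$table))
      write_table(rt$table, file.path(outdir, "retention_table.tsv"))
    if (nrow(rt$events))
      extract_inserts(rt$events, corrected,
                      file.path(outdir, "inserts.fasta"))
    writeLines(c(
      paste0("tipseq run log (", format(Sys.time(), "%Y-%m-%d"), ")"),
      paste0("reads_in\t", nrow(reads)),
      paste0("assigned\t", nrow(corrected)),
      paste0("aligned\t", nrow(al$alignments)),
      paste0("unaligned\t", al$unaligned),
      paste0("parameters\t", paste(deparse(log$parameters), collapse = ""))),
      file.path(outdir, "run_log.txt"))
  }

  list(demux = dx$counts, alignments = al$alignments,
       unaligned = al$unaligned, editing = ed, retention = rt,
       aligned_counts = ac, log = log)
}

empty_alignments <- function() {
  data.frame(read_id = character(), chrom = character(), start = integer(),
             cigar = character(), strand = character(), score = numeric(),
             identity = numeric(), from_unspliced = logical(),
             tie = logical(), stringsAsFactors = FALSE)
}

#' Replicate statistics straight from count tables
#'
#' Decouples the statistics stage from sequence processing: per-site C/T
#' counts (editing) and unspliced/aligned counts (retention) laid out one
#' replicate per row are summarised exactly as the full pipeline would
#' summarise its own pileups, including Welch comparisons against a
#' control group.
#'
#' @param editing_counts Data frame or TSV path with columns `site`,
#'   `genotype`, `replicate`, `C`, `T` (extra annotation columns such as
#'   `position`/`context` are carried through).
#' @param retention_counts Data frame or TSV path with columns
#'   `genotype`, `replicate`, `unspliced`, `aligned`.
#' @param control Control genotype label for comparisons (optional).
#' @param editing_tails,retention_tails Tails for the Welch tests:
#'   editing comparisons default to two-tailed, retention comparisons to
#'   one-tailed (alternative: treatment above control).
#' @return List with `editing` and `retention` components, each holding
#'   `per_replicate` values, a `summary` (mean, sd, n per group) and,
#'   when `control` is given, `comparisons` (t, df, p per group).
#' @export
counts_only <- function(editing_counts = NULL, retention_counts = NULL,
                        control = NULL, editing_tails = "two",
                        retention_tails = "one") {
  out <- list()
  if (!is.null(editing_counts)) {
    tab <- if (is.character(editing_counts))
      read.delim(editing_counts, stringsAsFactors = FALSE) else editing_counts
    need <- c("site", "genotype", "replicate", "C", "T")
    miss <- setdiff(need, names(tab))
    if (length(miss))
      stop("editing counts table is missing column(s): ",
           paste(miss, collapse = ", "))
    tab$efficiency <- editing_efficiency(tab$C, tab$T)
    summ <- do.call(rbind, lapply(
      split(tab, list(tab$site, tab$genotype), drop = TRUE), function(d) {
        s <- summarize_replicates(d$efficiency)
        data.frame(site = d$site[1L], genotype = d$genotype[1L],
                   n = s$n, mean = s$mean, sd = s$sd,
                   stringsAsFactors = FALSE)
      }))
    rownames(summ) <- NULL
    cmp <- NULL
    if (!is.null(control)) {
      if (!control %in% tab$genotype)
        stop("control genotype '", control, "' not in the editing table")
      cmp <- do.call(rbind, lapply(split(tab, tab$site), function(d) {
        ctrl <- d$efficiency[d$genotype == control]
        do.call(rbind, lapply(setdiff(unique(d$genotype), control),
                              function(g) {
          w <- welch_t_test(d$efficiency[d$genotype == g], ctrl,
                           tails = editing_tails)
          data.frame(site = d$site[1L], genotype = g, control = control,
                     t = w$t, df = w$df, p = w$p, tails = w$tails,
                     stringsAsFactors = FALSE)
        }))
      }))
      rownames(cmp) <- NULL
    }
    out$editing <- list(per_replicate = tab, summary = summ,
                        comparisons = cmp)
  }
  if (!is.null(retention_counts)) {
    tab <- if (is.character(retention_counts))
      read.delim(retention_counts, stringsAsFactors = FALSE)
      else retention_counts
    need <- c("genotype", "replicate", "unspliced", "aligned")
    miss <- setdiff(need, names(tab))
    if (length(miss))
      stop("retention counts table is missing column(s): ",
           paste(miss, collapse = ", "))
    tab$frequency <- retention_frequency(tab$unspliced, tab$aligned)
    summ <- do.call(rbind, lapply(split(tab, tab$genotype), function(d) {
      s <- summarize_retention(d$frequency)
      data.frame(genotype = d$genotype[1L], n = s$n, mean = s$mean,
                 sd = s$sd, stringsAsFactors = FALSE)
    }))
    rownames(summ) <- NULL
    cmp <- NULL
    if (!is.null(control)) {
      if (!control %in% tab$genotype)
        stop("control genotype '", control, "' not in the retention table")
      ctrl <- tab$frequency[tab$genotype == control]
      cmp <- do.call(rbind, lapply(setdiff(unique(tab$genotype), control),
                                   function(g) {
        w <- welch_t_test(tab$frequency[tab$genotype == g], ctrl,
                         tails = retention_tails)
        data.frame(genotype = g, control = control, t = w$t, df = w$df,
                   p = w$p, tails = w$tails, stringsAsFactors = FALSE)
      }))
      rownames(cmp) <- NULL
    }
    out$retention <- list(per_replicate = tab, summary = summ,
                          comparisons = cmp)
  }
  if (!length(out))
    stop("provide at least one of editing_counts / retention_counts")
  out
}

#' Paths to the bundled example count tables
#'
#' Per-site C/T counts and per-replicate unspliced/aligned counts from a
#' TIP sequencing study of Arabidopsis ndhB and ndhD transcripts across
#' MORF2-perturbation genotypes and tissues (three biological replicates
#' each), in the long layout [counts_only()] consumes.
#'
#' @param which `"editing"` or `"retention"`.
#' @return File path.
#' @export
tip_example_counts <- function(which = c("editing", "retention")) {
  which <- match.arg(which)
  f <- c(editing = "editing_counts_morf2.tsv",
         retention = "retention_counts_morf2.tsv")[[which]]
  system.file("extdata", f, package = "tipseq", mustWork = TRUE)
}
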