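#' Intron-retention scan configuration
#'
#' Reads retaining the group II intron appear as large CIGAR insertions
#' against the spliced reference; the length window brackets the intron
#' length (685 nt here).  Bounds are closed: an insertion counts when
#' `min_insert <= length <= max_insert`.
#'
#' @param min_insert,max_insert Closed insertion-length window (bp).
#' @param merge_gap Reference bases allowed between I operations pooled
#'   into one event before the length test.  The default 0 keeps
#'   single-operation semantics; merging is an opt-in for insertions
#'   split by small alignment errors.
#' @return A list of class `retention_config`.
#' @export
retention_config <- function(min_insert = 650L, max_insert = 700L,
                             merge_gap = 0L) {
  stopifnot(min_insert > 0L, min_insert <= max_insert, merge_gap >= 0L)
  structure(list(min_insert = as.integer(min_insert),
                 max_insert = as.integer(max_insert),
                 merge_gap = as.integer(merge_gap)),
            class = "retention_config")
}

#' Scan one alignment's CIGAR for intron-scale insertions
#'
#' Every I operation whose length falls inside the configured closed
#' window yields an event; with `merge_gap > 0`, consecutive I operations
#' separated by at most `merge_gap` reference-consuming bases are pooled
#' before the length test.  Insert sequences are cut from the read at
#' CIGAR-derived offsets.
#'
#' @param alignment One-row alignment data frame.
#' @param read One-row read set data frame for the same read.
#' @param config A [retention_config()].
#' @return Data frame of events: `read_id`, `chrom`, `ref_position`
#'   (1-based reference position preceding the insertion),
#'   `insert_length`, `query_start`, `insert_sequence`.
#' @export
scan_insertions <- function(alignment, read, config = retention_config()) {
  stopifnot(nrow(alignment) == 1L)
  validate_reads(read)
  ops <- parse_cigar(alignment$cigar[1L])
  qlen <- sum(ops$len[ops$op %in% c("M", "=", "X", "I", "S")])
  if (qlen != nchar(read$seq[1L]))
    stop("CIGAR consumes ", qlen, " read bases but read '", read$id[1L],
         "' has ", nchar(read$seq[1L]))
  # collect raw I ops with positions
  raw <- list()
  rpos <- alignment$start[1L]; qpos <- 1L
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op == "I")
      raw[[length(raw) + 1L]] <- list(ref_before = rpos - 1L, qstart = qpos,
                                      len = len)
    if (op %in% c("M", "=", "X", "D")) rpos <- rpos + len
    if (op %in% c("M", "=", "X", "I", "S")) qpos <- qpos + len
  }
  if (!length(raw)) return(empty_insertion_events())
  # pool I ops separated by <= merge_gap reference bases
  groups <- list(); cur <- list(raw[[1L]])
  if (length(raw) > 1L) {
    for (i in 2L:length(raw)) {
      gap <- raw[[i]]$ref_before - cur[[length(cur)]]$ref_before
      if (gap <= config$merge_gap) cur <- c(cur, raw[i]) else {
        groups <- c(groups, list(cur)); cur <- list(raw[[i]])
      }
    }
  }
  groups <- c(groups, list(cur))
  seq <- read$seq[1L]
  out <- lapply(groups, function(g) {
    total <- sum(vapply(g, `[[`, numeric(1), "len"))
    if (total < config$min_insert || total > config$max_insert) return(NULL)
    pieces <- vapply(g, function(e)
      substr(seq, e$qstart, e$qstart + e$len - 1L), character(1))
    data.frame(read_id = read$id[1L], chrom = alignment$chrom[1L],
               ref_position = g[[1L]]$ref_before,
               insert_length = as.integer(total),
               query_start = g[[1L]]$qstart,
               insert_sequence = paste(pieces, collapse = ""),
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty_insertion_events())
  do.call(rbind, out)
}

empty_insertion_events <- function() {
  data.frame(read_id = character(), chrom = character(),
             ref_position = integer(), insert_length = integer(),
             query_start = integer(), insert_sequence = character(),
             stringsAsFactors = FALSE)
}

#' Scan a whole alignment set for intron-scale insertions
#'
#' @param alignments Alignment data frame.
#' @param reads Read set data frame keyed by `id`.
#' @param config A [retention_config()].
#' @return Row-bound events from [scan_insertions()].
#' @export
scan_all_insertions <- function(alignments, reads,
                                config = retention_config()) {
  if (nrow(alignments) == 0L) return(empty_insertion_events())
  idx <- match(alignments$read_id, reads$id)
  if (anyNA(idx))
    stop("alignment read id(s) missing from the read set: ",
         alignments$read_id[which(is.na(idx))[1L]])
  out <- lapply(seq_len(nrow(alignments)), function(i)
    scan_insertions(alignments[i, , drop = FALSE],
                    reads[idx[i], , drop = FALSE], config))
  do.call(rbind, out)
}

#' Intron-retention frequency
#'
#' @param U Unspliced (insertion-bearing) read count.
#' @param N Aligned read count on the same chromosome; `N > 0`.
#' @return Percent `U / N * 100`.
#' @export
retention_frequency <- function(U, N) {
  stopifnot(all(U >= 0), all(U <= N))
  if (any(N == 0)) stop("retention frequency undefined: no aligned reads")
  U / N * 100
}

#' Summarise retention frequencies across replicates
#'
#' @param frequencies Per-replicate percentages.
#' @return See [mean_sd()].
#' @export
summarize_retention <- function(frequencies) mean_sd(frequencies)

#' Write detected inserts as FASTA, cross-referenced to the reads
#'
#' One entry per event, named `<read_id>_<ref_position>_<length>`; the
#' sequence is the read substring of the insertion, in strand-corrected
#' orientation.
#'
#' @param events Insertion-event data frame ([scan_all_insertions()]).
#' @param raw_records Read set containing every event's read.
#' @param path Optional output FASTA path.
#' @return Named character vector of insert sequences (also written to
#'   `path` when given), invisibly when writing.
#' @export
extract_inserts <- function(events, raw_records, path = NULL) {
  idx <- match(events$read_id, raw_records$id)
  if (anyNA(idx))
    stop("event read id missing from the read set: ",
         events$read_id[which(is.na(idx))[1L]])
  seqs <- substr(raw_records$seq[idx], events$query_start,
                 events$query_start + events$insert_length - 1L)
  names(seqs) <- paste(events$read_id, events$ref_position,
                       events$insert_length, sep = "_")
  if (!is.null(path)) {
    write_fasta(seqs, path)
    return(invisible(seqs))
  }
  seqs
}

#' Validate an insert against the intron reference by local alignment
#'
#' Smith-Waterman local alignment of the insert against the intron;
#' identity is identical columns over alignment columns.  An insert is
#' `matched` when identity and alignment length clear explicit floors
#' (default: identity >= 80% and length >= 80% of the intron), giving the
#' reported identity/length statistics a counting contract.
#'
#' @param insert Insert sequence.
#' @param intron Intron reference sequence.
#' @param scoring A [scoring_scheme()].
#' @param min_identity Identity floor, percent.
#' @param min_length_frac Alignment-length floor as a fraction of the
#'   intron length.
#' @return List with `identity` (percent), `alignment_length` (columns),
#'   `score`, and `matched`.
#' @export
align_insert_to_intron <- function(insert, intron,
                                   scoring = scoring_scheme(),
                                   min_identity = 80,
                                   min_length_frac = 0.8) {
  stopifnot(nzchar(insert), nzchar(intron))
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = FALSE)
  al <- Biostrings::pairwiseAlignment(
    insert, intron, type = "local", substitutionMatrix = mat,
    gapOpening = -(scoring$gap_open - scoring$gap_extend),
    gapExtension = -scoring$gap_extend)
  cols <- Biostrings::nchar(al)
  ident <- if (cols > 0) 100 * Biostrings::nmatch(al) / cols else 0
  list(identity = ident, alignment_length = cols,
       score = Biostrings::score(al),
       matched = ident >= min_identity &&
         cols >= min_length_frac * nchar(intron))
}

#' Compare retention frequencies between two groups
#'
#' Retention comparisons default to a one-tailed Welch test (alternative:
#' `group_a` greater than the control `group_b`).
#'
#' @param group_a,group_b Per-replicate frequency vectors.
#' @param tails `"one"` (default) or `"two"`.
#' @return See [welch_t_test()].
#' @export
compare_retention <- function(group_a, group_b, tails = "one")
  welch_t_test(group_a, group_b, tails = tails)

#' Per-replicate retention results from alignments
#'
#' Counts insertion-bearing reads per chromosome of the intron-bearing
#' gene(s) and normalises by aligned reads on the same chromosome.
#'
#' @param alignments Alignment data frame.
#' @param reads Read set data frame.
#' @param genome A [build_pseudogenome()] result.
#' @param config A [retention_config()].
#' @return List with `events`, and `table` (per chromosome of
#'   intron-bearing genes: `chrom`, `gene`, `label`, `unspliced`,
#'   `aligned`, `frequency`).
#' @export
retention_results <- function(alignments, reads, genome,
                              config = retention_config()) {
  stopifnot(inherits(genome, "pseudogenome"))
  has_intron <- vapply(genome$genes, function(g) !is.null(g$intron),
                       logical(1))
  keep <- genome$provenance$gene %in% names(genome$genes)[has_intron]
  prov <- genome$provenance[keep, , drop = FALSE]
  sub <- alignments[alignments$chrom %in% prov$chrom, , drop = FALSE]
  events <- scan_all_insertions(sub, reads, config)
  tab <- prov
  tab$unspliced <- vapply(prov$chrom, function(nm)
    length(unique(events$read_id[events$chrom == nm])), integer(1))
  tab$aligned <- vapply(prov$chrom, function(nm)
    sum(alignments$chrom == nm), integer(1))
  tab$frequency <- ifelse(tab$aligned > 0,
                          100 * tab$unspliced / tab$aligned, NA_real_)
  rownames(tab) <- NULL
  list(events = events, table = tab)
}
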