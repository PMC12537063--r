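#' Barcode sets and demultiplexing configuration
#'
#' A barcode set maps replicate labels to the 8-nt barcodes carried on the
#' forward PCR primers of a TIP sequencing run.  [default_barcodes()]
#' returns the three-replicate set used throughout the package examples.
#'
#' @param labels Character vector of unique replicate labels.
#' @param sequences Character vector of unique 8-nt barcodes over ACGT.
#' @return A data frame with columns `label` and `sequence`.
#' @export
barcode_set <- function(labels, sequences) {
  stopifnot(length(labels) == length(sequences), length(labels) >= 1L)
  sequences <- toupper(sequences)
  if (any(nchar(sequences) != 8L) || any(grepl("[^ACGT]", sequences)))
    stop("barcodes must be 8-nt strings over A/C/G/T")
  if (anyDuplicated(labels)) stop("barcode labels must be unique")
  if (anyDuplicated(sequences)) stop("barcode sequences must be unique")
  data.frame(label = as.character(labels), sequence = sequences,
             stringsAsFactors = FALSE)
}

#' @rdname barcode_set
#' @export
default_barcodes <- function() {
  barcode_set(c("R1", "R2", "R3"),
              c("ATGCTAGC", "CGTACGTA", "TACGATCG"))
}

#' @param search_window Bases scanned from each read end for a barcode.
#'   Barcodes sit at the amplicon 5' end, but nanopore reads may carry
#'   adapter remnants, so the window is wider than the barcode.
#' @param max_mismatches Hamming mismatches tolerated in a barcode match
#'   (0 or 1).  An exact-match tier is always tried first.
#' @rdname barcode_set
#' @export
demux_config <- function(search_window = 100L, max_mismatches = 1L) {
  stopifnot(search_window >= 8L, max_mismatches %in% c(0L, 1L))
  list(search_window = as.integer(search_window),
       max_mismatches = as.integer(max_mismatches))
}

#' Reverse-complement a read, keeping base/quality pairing
#'
#' The sequence is reverse-complemented (N maps to N) and the quality
#' string is reversed, so each base keeps its quality.  Ids are never
#' rewritten.
#'
#' @param records Read set data frame (`id`, `seq`, `qual`).
#' @return The read set with every record flipped to the other strand.
#' @export
reverse_complement <- function(records) {
  validate_reads(records)
  if (nrow(records) == 0L) return(records)
  if (any(grepl("[^ACGTN]", records$seq)))
    stop("reverse_complement: sequences must be over A/C/G/T/N")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(records$seq)))
  rq <- vapply(strsplit(records$qual, NULL),
               function(ch) paste(rev(ch), collapse = ""), character(1))
  data.frame(id = records$id, seq = rc, qual = rq, stringsAsFactors = FALSE)
}

# For every read, find which (label, orientation) pairs carry a barcode
# match at a given mismatch tolerance.  Sense barcodes are searched in the
# first `window` bases, reverse-complemented barcodes in the last `window`
# bases.  Returns a list (per read) of character keys "label|orientation".
match_barcodes_tier <- function(seqs, barcodes, window, max_mismatch) {
  n <- length(seqs)
  w <- nchar(seqs)
  dna <- Biostrings::DNAStringSet(seqs)
  pre <- Biostrings::subseq(dna, 1L, pmin(w, window))
  suf <- Biostrings::subseq(dna, pmax(1L, w - window + 1L), w)
  keys <- rep(list(character()), n)
  for (b in seq_len(nrow(barcodes))) {
    lab <- barcodes$label[b]
    fw <- Biostrings::DNAString(barcodes$sequence[b])
    rv <- Biostrings::reverseComplement(fw)
    hit_f <- S4Vectors::elementNROWS(
      Biostrings::vmatchPattern(fw, pre, max.mismatch = max_mismatch)) > 0L
    hit_r <- S4Vectors::elementNROWS(
      Biostrings::vmatchPattern(rv, suf, max.mismatch = max_mismatch)) > 0L
    for (i in which(hit_f))
      keys[[i]] <- c(keys[[i]], paste0(lab, "|sense"))
    for (i in which(hit_r))
      keys[[i]] <- c(keys[[i]], paste0(lab, "|antisense"))
  }
  keys
}

# Tiered classification of all reads at once: exact matches first, then
# (if none) Hamming <= max_mismatches.  More than one distinct
# (label, orientation) in the deciding tier is ambiguous.
classify_reads <- function(seqs, barcodes, config) {
  n <- length(seqs)
  label <- rep(NA_character_, n)
  orientation <- rep("none", n)
  tiers <- unique(c(0L, config$max_mismatches))
  undecided <- seq_len(n)
  for (tier in tiers) {
    if (!length(undecided)) break
    keys <- match_barcodes_tier(seqs[undecided], barcodes,
                                config$search_window, tier)
    hits <- lengths(keys)
    one <- hits == 1L
    multi <- hits > 1L
    if (any(one)) {
      dec <- strsplit(unlist(keys[one]), "|", fixed = TRUE)
      idx <- undecided[one]
      label[idx] <- vapply(dec, `[`, character(1), 1L)
      orientation[idx] <- vapply(dec, `[`, character(1), 2L)
    }
    orientation[undecided[multi]] <- "ambiguous"
    undecided <- undecided[hits == 0L]
  }
  data.frame(label = label, orientation = orientation,
             stringsAsFactors = FALSE)
}

#' Classify one read's barcode and orientation
#'
#' A read is `sense` if a barcode lies within the first `search_window`
#' bases, `antisense` if a reverse-complemented barcode lies within the
#' last `search_window` bases, `none` if neither, and `ambiguous` if more
#' than one distinct (label, orientation) combination matches in the
#' deciding tier (exact matches are tried before mismatched ones).
#'
#' @param record One-row read set data frame.
#' @param barcodes A [barcode_set()].
#' @param config A [demux_config()].
#' @return A list with `orientation` (one of `"sense"`, `"antisense"`,
#'   `"none"`, `"ambiguous"`) and `label` (`NA` unless assigned).
#' @export
detect_orientation <- function(record, barcodes,
                               config = demux_config()) {
  validate_reads(record)
  stopifnot(nrow(record) == 1L)
  cls <- classify_reads(record$seq, barcodes, config)
  list(orientation = cls$orientation, label = cls$label)
}

#' Demultiplex pooled reads by barcode with strand correction
#'
#' Each read is assigned to a replicate by its 8-nt barcode and oriented
#' to the sense strand: sense reads are copied unchanged, antisense reads
#' are reverse-complemented (with reversed qualities).  Reads matching no
#' barcode, or matching more than one (label, orientation) combination
#' (chimeras/concatemers), are routed to `unassigned` and `ambiguous`
#' bins rather than force-assigned.
#'
#' @param records Read set data frame.
#' @param barcodes A [barcode_set()].
#' @param config A [demux_config()].
#' @return An object of class `demux_result`: list with `assigned` (named
#'   list of strand-corrected read sets, one per label), `unassigned`,
#'   `ambiguous` (read sets), and `counts` (named integer vector; one
#'   entry per label plus `unassigned` and `ambiguous`).
#' @export
demultiplex <- function(records, barcodes, config = demux_config()) {
  validate_reads(records)
  empty <- records[0L, , drop = FALSE]
  assigned <- setNames(rep(list(empty), nrow(barcodes)), barcodes$label)
  if (nrow(records)) {
    cls <- classify_reads(records$seq, barcodes, config)
    for (lab in barcodes$label) {
      sense <- records[which(cls$label == lab & cls$orientation == "sense"), ,
                       drop = FALSE]
      anti <- records[which(cls$label == lab & cls$orientation == "antisense"), ,
                      drop = FALSE]
      both <- rbind(sense, reverse_complement(anti))
      assigned[[lab]] <- both[order(match(both$id, records$id)), , drop = FALSE]
    }
    unassigned <- records[which(cls$orientation == "none"), , drop = FALSE]
    ambiguous <- records[which(cls$orientation == "ambiguous"), , drop = FALSE]
  } else {
    unassigned <- empty
    ambiguous <- empty
  }
  counts <- c(vapply(assigned, nrow, integer(1)),
              unassigned = nrow(unassigned), ambiguous = nrow(ambiguous))
  structure(list(assigned = assigned, unassigned = unassigned,
                 ambiguous = ambiguous, counts = counts),
            class = "demux_result")
}

#' @export
print.demux_result <- function(x, ...) {
  cat("TIP demultiplexing result\n")
  for (nm in names(x$counts))
    cat(sprintf("  %-12s %6d reads\n", nm, x$counts[[nm]]))
  invisible(x)
}
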