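#' Alignment scoring scheme
#'
#' Affine-gap scores: a gap of length L costs
#' `gap_open + (L - 1) * gap_extend`.  The default is a map-ont-like
#' scheme (match +2, mismatch -4, gap open -4, gap extend -2) appropriate
#' for nanopore amplicon reads.
#'
#' @param match Positive match score.
#' @param mismatch Negative mismatch score.
#' @param gap_open Negative score of the first base of a gap.
#' @param gap_extend Negative score of each further gap base;
#'   `gap_extend >= gap_open`.
#' @return A list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 2, mismatch = -4,
                           gap_open = -4, gap_extend = -2) {
  stopifnot(match > 0, mismatch < 0, gap_open < 0, gap_extend < 0,
            gap_extend >= gap_open)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

# ---- CIGAR bookkeeping -----------------------------------------------------

#' Parse a CIGAR string into an operation table
#'
#' @param cigar CIGAR string over M/=/X/I/D/S/H.
#' @return Data frame with integer `len` and character `op` columns.
#' @export
parse_cigar <- function(cigar) {
  stopifnot(is.character(cigar), length(cigar) == 1L, nzchar(cigar))
  if (grepl("[^0-9MIDSH=X]", cigar)) stop("unsupported CIGAR: ", cigar)
  len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]])
  op <- regmatches(cigar, gregexpr("[MIDSH=X]", cigar))[[1L]]
  if (length(len) != length(op)) stop("malformed CIGAR: ", cigar)
  data.frame(len = len, op = op, stringsAsFactors = FALSE)
}

#' @rdname parse_cigar
#' @export
cigar_query_length <- function(cigar) {
  ops <- parse_cigar(cigar)
  sum(ops$len[ops$op %in% c("M", "=", "X", "I", "S")])
}

#' @rdname parse_cigar
#' @export
cigar_reference_length <- function(cigar) {
  ops <- parse_cigar(cigar)
  sum(ops$len[ops$op %in% c("M", "=", "X", "D")])
}

# Query (read) position aligned to a 1-based reference position, walked
# through the CIGAR.  Returns list(status, qpos): status "base" (qpos is
# the 1-based read index), "deletion" (a deletion spans the site), or
# "uncovered".  With indel_window > 0, a base call whose alignment has an
# I or D operation within that many reference bases of the site is
# reported as "indel_near" instead: around an edited site the optimal
# alignment tends to absorb nearby indel errors into the mismatching
# site column (reference bias, worst in homopolymer contexts), and
# excluding indel-adjacent calls on both alleles keeps the C:T ratio
# unbiased.  Deletions spanning the site itself stay "deletion".
query_position_at <- function(cigar, start, ref_position,
                              indel_window = 0L) {
  ops <- parse_cigar(cigar)
  rpos <- start          # next reference base consumed
  qpos <- 1L             # next query base consumed
  hit <- NULL
  indel_near <- FALSE
  lo <- ref_position - indel_window
  hi <- ref_position + indel_window
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("M", "=", "X")) {
      if (is.null(hit) && ref_position < rpos + len && ref_position >= rpos)
        hit <- list(status = "base", qpos = qpos + (ref_position - rpos))
      rpos <- rpos + len; qpos <- qpos + len
    } else if (op == "D") {
      if (is.null(hit) && ref_position < rpos + len && ref_position >= rpos)
        hit <- list(status = "deletion", qpos = NA_integer_)
      else if (indel_window > 0L && rpos <= hi && rpos + len - 1L >= lo)
        indel_near <- TRUE
      rpos <- rpos + len
    } else if (op == "I") {
      if (indel_window > 0L && rpos - 1L <= hi && rpos >= lo)
        indel_near <- TRUE
      qpos <- qpos + len
    } else if (op == "S") {
      qpos <- qpos + len
    }                                   # H consumes neither
  }
  if (is.null(hit)) return(list(status = "uncovered", qpos = NA_integer_))
  if (hit$status == "base" && indel_near)
    return(list(status = "indel_near", qpos = hit$qpos))
  hit
}

# ---- built-in aligner ------------------------------------------------------

#' Semi-global affine-gap alignment of one read against one reference
#'
#' Banded dynamic programming, global in the read with free end gaps on
#' the reference, emitting an explicit M/I/D CIGAR so downstream
#' insertion scanning works on built-in alignments exactly as on imported
#' SAM.  The band is a corridor of half-width `band` around the main
#' diagonal, widened by the reference/read length difference; paths
#' outside it (e.g. bridging a whole retained intron against the spliced
#' reference) are not searched -- callers align against the unspliced
#' variant instead (see [choose_best()]).
#'
#' @param read One-row read set data frame, or a plain sequence string.
#' @param ref Reference sequence string.
#' @param scoring A [scoring_scheme()].
#' @param band Band half-width in bases.
#' @return List with `score`, `start` (1-based reference position),
#'   `cigar`, `identity` (matched columns / alignment columns, in [0,1]),
#'   and `feasible` (FALSE when the read cannot be placed inside the
#'   band, e.g. when it is longer than the reference by more than the
#'   band).
#' @export
align_semiglobal <- function(read, ref, scoring = scoring_scheme(),
                             band = 150L) {
  seq <- if (is.data.frame(read)) read$seq[1L] else read
  stopifnot(is.character(seq), is.character(ref))
  if (!nzchar(seq) || !nzchar(ref))
    stop("read and reference must be non-empty")
  .semiglobal_align_cpp(seq, ref, scoring$match, scoring$mismatch,
                        scoring$gap_open, scoring$gap_extend,
                        as.integer(band))
}

# Re-express an alignment against the unspliced variant chromosome in
# spliced-chromosome coordinates: reference columns inside the intron
# become insertion columns (read-consuming ops turn into I, deletions
# vanish), and downstream positions shift left by the intron length.
lift_unspliced_alignment <- function(cigar, start, offset, gene) {
  ip <- gene$intron_insertion_point
  ilen <- nchar(gene$intron)
  istart <- offset + ip + 1L         # first intron column (unspliced ref)
  iend <- offset + ip + ilen         # last intron column
  ops <- parse_cigar(cigar)
  # expand to per-column ops with the unspliced ref position of each
  out_op <- character(0); out_ref <- integer(0)
  rpos <- start
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("M", "=", "X", "D")) {
      out_op <- c(out_op, rep(op, len))
      out_ref <- c(out_ref, seq.int(rpos, length.out = len))
      rpos <- rpos + len
    } else {
      out_op <- c(out_op, rep(op, len))
      out_ref <- c(out_ref, rep(NA_integer_, len))
    }
  }
  inside <- !is.na(out_ref) & out_ref >= istart & out_ref <= iend
  out_op[inside & out_op %in% c("M", "=", "X")] <- "I"
  keep <- !(inside & out_op == "D")
  out_op <- out_op[keep]; out_ref <- out_ref[keep]; inside <- inside[keep]
  # drop leading/trailing D columns (free end gaps on the reference)
  first_q <- match(TRUE, out_op != "D")
  last_q <- length(out_op) + 1L - match(TRUE, rev(out_op) != "D")
  sel <- seq.int(first_q, last_q)
  out_op <- out_op[sel]; out_ref <- out_ref[sel]; inside <- inside[sel]
  # spliced-reference position of each surviving ref-consuming column
  ref_cons <- !is.na(out_ref) & !inside & out_op %in% c("M", "=", "X", "D")
  spliced_pos <- out_ref
  spliced_pos[ref_cons & out_ref > iend] <-
    out_ref[ref_cons & out_ref > iend] - ilen
  new_start <- if (any(ref_cons)) spliced_pos[which(ref_cons)[1L]] else NA_integer_
  r <- rle(out_op)
  list(cigar = paste0(r$lengths, r$values, collapse = ""),
       start = as.integer(new_start))
}

#' Place a read on its best pseudo-genome chromosome
#'
#' The read is scored against every chromosome and, for genes with an
#' annotated intron, against the unspliced variant of each chromosome
#' (dual-reference strategy: a banded DP never has to bridge the intron
#' as one giant insertion).  The highest score wins; winning
#' unspliced-variant alignments are re-expressed on the spliced
#' chromosome with the intron as a single I operation.  Score ties are
#' broken by chromosome order and flagged.  Reads whose best alignment
#' falls below `min_identity` are reported as unaligned.
#'
#' @param read One-row read set data frame.
#' @param genome A [build_pseudogenome()] result.
#' @param scoring A [scoring_scheme()].
#' @param band Band half-width for the DP.
#' @param min_identity Identity floor in [0,1] to count as aligned.
#' @return A one-row alignment data frame (`read_id`, `chrom`, `start`,
#'   `cigar`, `strand`, `score`, `identity`, `from_unspliced`, `tie`), or
#'   `NULL` if unaligned.
#' @export
choose_best <- function(read, genome, scoring = scoring_scheme(),
                        band = 150L, min_identity = 0.6) {
  stopifnot(inherits(genome, "pseudogenome"))
  validate_reads(read)
  best <- NULL; best_chrom <- NULL; best_unspliced <- FALSE; tie <- FALSE
  for (nm in names(genome$chromosomes)) {
    gene <- genome$genes[[genome$provenance$gene[genome$provenance$chrom == nm]]]
    cands <- list(list(ref = genome$chromosomes[[nm]], unspliced = FALSE))
    if (!is.null(gene$intron)) {
      bc <- substr(genome$chromosomes[[nm]], 1L, genome$offsets[[nm]])
      cands <- c(cands, list(list(ref = paste0(bc, unspliced_variant(gene)),
                                  unspliced = TRUE)))
    }
    for (cand in cands) {
      al <- align_semiglobal(read, cand$ref, scoring, band)
      if (!isTRUE(al$feasible)) next
      if (is.null(best) || al$score > best$score) {
        best <- al; best_chrom <- nm; best_unspliced <- cand$unspliced
        tie <- FALSE
      } else if (al$score == best$score && nm != best_chrom) {
        tie <- TRUE
      }
    }
  }
  if (is.null(best) || best$identity < min_identity) return(NULL)
  cigar <- best$cigar; start <- best$start
  if (best_unspliced) {
    gene <- genome$genes[[
      genome$provenance$gene[genome$provenance$chrom == best_chrom]]]
    lifted <- lift_unspliced_alignment(cigar, start,
                                       genome$offsets[[best_chrom]], gene)
    cigar <- lifted$cigar; start <- lifted$start
  }
  data.frame(read_id = read$id[1L], chrom = best_chrom, start = start,
             cigar = cigar, strand = "forward", score = best$score,
             identity = best$identity, from_unspliced = best_unspliced,
             tie = tie, stringsAsFactors = FALSE)
}

#' Align a whole read set to the pseudo-genome
#'
#' @param records Read set data frame (strand-corrected).
#' @param genome A [build_pseudogenome()] result.
#' @param scoring A [scoring_scheme()].
#' @param band Band half-width for the DP.
#' @param min_identity Identity floor in [0,1] to count as aligned.
#' @return List with `alignments` (data frame, one row per aligned read),
#'   `unaligned_ids` and `unaligned` count; `nrow(alignments) +
#'   unaligned == nrow(records)`.
#' @export
align_all <- function(records, genome, scoring = scoring_scheme(),
                      band = 150L, min_identity = 0.6) {
  validate_reads(records)
  rows <- vector("list", nrow(records))
  for (i in seq_len(nrow(records)))
    rows[[i]] <- choose_best(records[i, , drop = FALSE], genome, scoring,
                             band, min_identity)
  hit <- !vapply(rows, is.null, logical(1))
  aln <- if (any(hit)) do.call(rbind, rows[hit]) else
    data.frame(read_id = character(), chrom = character(), start = integer(),
               cigar = character(), strand = character(), score = numeric(),
               identity = numeric(), from_unspliced = logical(),
               tie = logical(), stringsAsFactors = FALSE)
  list(alignments = aln,
       unaligned_ids = records$id[!hit],
       unaligned = sum(!hit))
}

#' Per-chromosome aligned read counts
#'
#' The per-replicate "aligned reads" denominators used by the retention
#' report.
#'
#' @param alignments Alignment data frame.
#' @param genome A [build_pseudogenome()] result.
#' @return Data frame `chrom`, `gene`, `label`, `n_aligned`.
#' @export
aligned_read_counts <- function(alignments, genome) {
  prov <- genome$provenance
  prov$n_aligned <- vapply(prov$chrom, function(nm)
    sum(alignments$chrom == nm), integer(1))
  prov
}
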