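#' Read a 4-line FASTQ file
#'
#' Reads are returned as a data frame with one row per record, the
#' package's in-memory representation of a read set.  Qualities are kept
#' as Phred+33 strings; no legacy (Solexa/Phred+64) encodings are
#' supported.
#'
#' @param path Path to an uncompressed 4-line FASTQ file.
#' @return A data frame with character columns `id`, `seq`, `qual`.
#'   `id` is the header up to the first whitespace, without the leading
#'   `@`.  Sequences are uppercased.
#' @examples
#' f <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGT", "+", "IIII"), f)
#' read_fastq(f)
#' @export
read_fastq <- function(path) {
  stopifnot(is.character(path), length(path) == 1L, file.exists(path))
  lines <- readLines(path)
  if (length(lines) && lines[length(lines)] == "")
    lines <- lines[-length(lines)]
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ: line count ", length(lines),
         " is not a multiple of 4 in '", path, "'")
  n <- length(lines) %/% 4L
  if (n == 0L)
    return(data.frame(id = character(), seq = character(),
                      qual = character(), stringsAsFactors = FALSE))
  hdr  <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- toupper(lines[seq(2L, by = 4L, length.out = n)])
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]

  bad <- which(!startsWith(hdr, "@"))
  if (length(bad))
    stop("malformed FASTQ: record ", bad[1L], " does not start with '@'")
  bad <- which(!startsWith(plus, "+"))
  if (length(bad))
    stop("malformed FASTQ: record ", bad[1L], " is missing the '+' line")
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad))
    stop("malformed FASTQ: record ", bad[1L],
         " has sequence/quality length mismatch")
  bad <- which(grepl("[^ACGTURYSWKMBDHVN]", seqs))
  if (length(bad))
    stop("malformed FASTQ: record ", bad[1L],
         " contains non-IUPAC characters")

  id <- sub("\\s.*$", "", substring(hdr, 2L))
  data.frame(id = id, seq = seqs, qual = qual, stringsAsFactors = FALSE)
}

#' Write reads as a 4-line FASTQ file
#'
#' @param records Data frame with columns `id`, `seq`, `qual`
#'   (as returned by [read_fastq()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  validate_reads(records)
  if (nrow(records) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  out <- as.vector(rbind(paste0("@", records$id), records$seq,
                         "+", records$qual))
  writeLines(out, path)
  invisible(path)
}

validate_reads <- function(records) {
  if (!is.data.frame(records) ||
      !all(c("id", "seq", "qual") %in% names(records)))
    stop("read set must be a data frame with columns id, seq, qual")
  bad <- which(nchar(records$seq) != nchar(records$qual))
  if (length(bad))
    stop("record ", bad[1L], " (", records$id[bad[1L]],
         "): sequence and quality lengths differ")
  invisible(records)
}

#' Read a FASTA file into a named character vector
#'
#' Wrapped and unwrapped sequence lines are both accepted; sequences are
#' uppercased and names are taken from the header up to the first
#' whitespace.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences, in file order.  An empty
#'   file yields an empty vector.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0L) return(setNames(character(), character()))
  set <- Biostrings::readDNAStringSet(path, format = "fasta")
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm))
    stop("duplicate FASTA name: '", nm[duplicated(nm)][1L], "'")
  setNames(toupper(as.character(set)), nm)
}

#' Write a named character vector of sequences as FASTA
#'
#' Sequences are written unwrapped (one line each) so files diff stably.
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  out <- as.vector(rbind(paste0(">", names(seqs)), unname(seqs)))
  writeLines(out, path)
  invisible(path)
}

#' Import alignments from a SAM text file
#'
#' Consumes mapped primary records from an external long-read aligner
#' (e.g. minimap2 `-ax map-ont`) and converts them into the package's
#' alignment table so downstream editing and retention counting is
#' identical for built-in and external alignments.  Secondary (flag 256)
#' and supplementary (flag 2048) records are excluded from counting
#' denominators; unmapped records are skipped and counted.
#'
#' @param path Path to a SAM file.
#' @param genome A [pseudogenome()] object; `@SQ`/RNAME entries must match
#'   its chromosome names.
#' @return A list with `alignments` (data frame: `read_id`, `chrom`,
#'   `start`, `cigar`, `strand`, `score`, `identity`), `skipped_unmapped`,
#'   and `skipped_secondary` counts.  Reverse-strand records trigger a
#'   warning, since the pipeline expects strand-corrected input.
#' @export
import_sam <- function(path, genome) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  body <- lines[!startsWith(lines, "@")]
  known <- names(genome$chromosomes)
  out <- list()
  skipped_unmapped <- 0L
  skipped_secondary <- 0L
  for (ln in body) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 11L) stop("malformed SAM record: fewer than 11 fields")
    flag <- as.integer(f[2L])
    if (bitwAnd(flag, 4L) > 0L) { skipped_unmapped <- skipped_unmapped + 1L; next }
    if (bitwAnd(flag, 256L) > 0L || bitwAnd(flag, 2048L) > 0L) {
      skipped_secondary <- skipped_secondary + 1L; next
    }
    if (!(f[3L] %in% known))
      stop("SAM reference name '", f[3L], "' not present in the pseudo-genome")
    strand <- if (bitwAnd(flag, 16L) > 0L) "reverse" else "forward"
    out[[length(out) + 1L]] <- data.frame(
      read_id = f[1L], chrom = f[3L], start = as.integer(f[4L]),
      cigar = f[6L], strand = strand, score = NA_real_,
      identity = NA_real_, stringsAsFactors = FALSE)
  }
  aln <- if (length(out)) do.call(rbind, out) else
    data.frame(read_id = character(), chrom = character(),
               start = integer(), cigar = character(), strand = character(),
               score = numeric(), identity = numeric(),
               stringsAsFactors = FALSE)
  if (nrow(aln) && any(aln$strand == "reverse"))
    warning(sum(aln$strand == "reverse"),
            " reverse-strand alignment(s): input does not look ",
            "strand-corrected; pileup bases are taken as stored in the SAM")
  list(alignments = aln,
       skipped_unmapped = skipped_unmapped,
       skipped_secondary = skipped_secondary)
}

#' Write a table of results as TSV
#'
#' @param rows Data frame; all cells must be tab-free scalars.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  chr <- vapply(rows, function(col) any(grepl("\t", as.character(col))), logical(1))
  if (any(chr))
    stop("tab characters are not allowed inside table cells (column '",
         names(rows)[chr][1L], "')")
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
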