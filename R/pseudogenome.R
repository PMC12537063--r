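#' Gene reference for a targeted amplicon
#'
#' Holds the spliced cDNA of one target gene and, when the gene carries an
#' intron, the intron sequence and its 1-based CDS insertion point (the
#' intron sits immediately after that cDNA position in the unspliced
#' form).
#'
#' @param name Gene name (e.g. `"ndhB"`).
#' @param cdna Spliced coding/cDNA sequence.
#' @param intron Optional intron sequence.
#' @param intron_insertion_point Optional 1-based cDNA position after
#'   which the intron sits; required with `intron`.
#' @return An object of class `gene_reference`.
#' @export
gene_reference <- function(name, cdna, intron = NULL,
                           intron_insertion_point = NULL) {
  cdna <- toupper(cdna)
  stopifnot(is.character(name), nzchar(name), nchar(cdna) >= 1L)
  if (!is.null(intron)) {
    intron <- toupper(intron)
    if (!nzchar(intron)) stop("intron sequence must be non-empty")
    if (is.null(intron_insertion_point))
      stop("intron_insertion_point is required when an intron is given")
    ip <- as.integer(intron_insertion_point)
    if (ip < 1L || ip >= nchar(cdna))
      stop("intron_insertion_point must lie in [1, length(cdna) - 1]")
  } else {
    if (!is.null(intron_insertion_point))
      stop("intron_insertion_point given without an intron")
    ip <- NULL
  }
  structure(list(name = name, cdna = cdna, intron = intron,
                 intron_insertion_point = ip),
            class = "gene_reference")
}

#' Unspliced (intron-retaining) variant of a gene reference
#'
#' @param gene A [gene_reference()] with an intron.
#' @return The premature transcript sequence
#'   `cdna[1..ip] + intron + cdna[(ip+1)..]`.
#' @export
unspliced_variant <- function(gene) {
  stopifnot(inherits(gene, "gene_reference"))
  if (is.null(gene$intron)) stop("gene '", gene$name, "' has no intron")
  ip <- gene$intron_insertion_point
  paste0(substr(gene$cdna, 1L, ip), gene$intron,
         substr(gene$cdna, ip + 1L, nchar(gene$cdna)))
}

#' Build the barcoded pseudo-genome
#'
#' One synthetic chromosome per (gene, barcode) pair, named
#' `<gene>_<label>` in gene-major order; each chromosome is the 8-nt
#' barcode followed by the gene's spliced cDNA, so a two-gene,
#' three-replicate run yields six chromosomes.  All coordinates in the
#' package are 1-based and fully closed; a CDS position maps onto a
#' chromosome as `barcode length + position`.
#'
#' @param genes List of [gene_reference()] objects with unique names.
#' @param barcodes A [barcode_set()].
#' @return An object of class `pseudogenome`: list with `chromosomes`
#'   (named character vector), `provenance` (data frame `chrom`, `gene`,
#'   `label`), `offsets` (named integer vector of barcode-prefix
#'   lengths), and `genes` (named list of gene references).
#' @export
build_pseudogenome <- function(genes, barcodes) {
  if (inherits(genes, "gene_reference")) genes <- list(genes)
  stopifnot(length(genes) >= 1L,
            all(vapply(genes, inherits, logical(1), "gene_reference")))
  if (!is.data.frame(barcodes) || nrow(barcodes) == 0L)
    stop("a non-empty barcode set is required")
  gnames <- vapply(genes, `[[`, character(1), "name")
  if (anyDuplicated(gnames)) stop("gene names must be unique")
  chroms <- character()
  prov <- list()
  for (g in genes) {
    for (b in seq_len(nrow(barcodes))) {
      nm <- paste0(g$name, "_", barcodes$label[b])
      chroms[nm] <- paste0(barcodes$sequence[b], g$cdna)
      prov[[length(prov) + 1L]] <- data.frame(
        chrom = nm, gene = g$name, label = barcodes$label[b],
        stringsAsFactors = FALSE)
    }
  }
  structure(list(chromosomes = chroms,
                 provenance = do.call(rbind, prov),
                 offsets = setNames(rep(nchar(barcodes$sequence[1L]),
                                        length(chroms)), names(chroms)),
                 genes = setNames(genes, gnames)),
            class = "pseudogenome")
}

#' @export
print.pseudogenome <- function(x, ...) {
  cat("pseudo-genome:", length(x$chromosomes), "chromosomes\n")
  for (nm in names(x$chromosomes))
    cat(sprintf("  %-14s %6d nt\n", nm, nchar(x$chromosomes[[nm]])))
  invisible(x)
}

#' Map a CDS position onto every chromosome of a gene
#'
#' Editing-site positions are referenced to the first nucleotide of each
#' gene's coding sequence; on a barcoded chromosome the same site sits at
#' `barcode length + position`.
#'
#' @param genome A [build_pseudogenome()] result.
#' @param gene Gene name.
#' @param cds_position 1-based CDS position.
#' @return Data frame with columns `chrom`, `label`, `position`.
#' @export
map_site <- function(genome, gene, cds_position) {
  stopifnot(inherits(genome, "pseudogenome"))
  if (!gene %in% names(genome$genes))
    stop("unknown gene '", gene, "'")
  cds_position <- as.integer(cds_position)
  if (cds_position < 1L || cds_position > nchar(genome$genes[[gene]]$cdna))
    stop("CDS position ", cds_position, " out of range for gene '", gene, "'")
  rows <- genome$provenance[genome$provenance$gene == gene, , drop = FALSE]
  data.frame(chrom = rows$chrom, label = rows$label,
             position = genome$offsets[rows$chrom] + cds_position,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write the pseudo-genome as FASTA
#'
#' @param genome A [build_pseudogenome()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pseudogenome <- function(genome, path) {
  stopifnot(inherits(genome, "pseudogenome"))
  write_fasta(genome$chromosomes, path)
}

#' Read an editing-site table
#'
#' @param path TSV with columns `site`, `gene`, `cds_position`, `context`
#'   (5-mer with the edited C at the centre).
#' @return Data frame of sites.
#' @export
read_site_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("site", "gene", "cds_position", "context")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("site table is missing column(s): ", paste(miss, collapse = ", "))
  tab$cds_position <- as.integer(tab$cds_position)
  bad <- which(nchar(tab$context) != 5L |
                 substr(tab$context, 3L, 3L) != "C")
  if (length(bad))
    stop("site '", tab$site[bad[1L]],
         "': context must be a 5-mer with C at the centre")
  tab
}
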