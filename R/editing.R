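#' Pileup base counts at an editing site
#'
#' Automates per-site base counting from alignments: for each aligned
#' read covering the site's chromosome position, the read base at that
#' reference column is found by walking the CIGAR and tallied as C, T or
#' other (A/G/N); reads with a deletion spanning the site are tallied
#' separately; insertions adjacent to the site contribute no call.
#' Bases below `min_base_quality` are skipped (the default 0 counts every
#' call, matching manual inspection of alignments in a browser).
#'
#' @param alignments Alignment data frame ([align_all()] or
#'   [import_sam()]).
#' @param reads Read set data frame holding the aligned (strand-corrected)
#'   sequences, keyed by `id`.
#' @param genome A [build_pseudogenome()] result.
#' @param site One row of an editing-site table (`site`, `gene`,
#'   `cds_position`, `context`).
#' @param min_base_quality Minimum Phred quality for a call to count.
#' @param exclude_unspliced Drop reads flagged `from_unspliced` from the
#'   pileup (off by default: intron-retaining reads still carry editing
#'   information on their exonic bases).
#' @param indel_window Base calls with an I/D alignment operation within
#'   this many reference bases of the site are excluded (tallied as
#'   `indel_excluded`).  Around an edited site the optimal alignment
#'   absorbs nearby indel sequencing errors into the mismatching site
#'   column -- worst in homopolymer contexts -- which removes edited
#'   reads asymmetrically; excluding indel-adjacent calls on both
#'   alleles keeps the C:T ratio unbiased.  Set 0 to count every call.
#' @return Data frame with one row per replicate chromosome: `site`,
#'   `chrom`, `label`, `position`, `C`, `T`, `other`, `deletions`,
#'   `indel_excluded`.
#' @export
pileup_counts <- function(alignments, reads, genome, site,
                          min_base_quality = 0L,
                          exclude_unspliced = FALSE,
                          indel_window = 5L) {
  stopifnot(inherits(genome, "pseudogenome"))
  mapped <- map_site(genome, site$gene, site$cds_position)
  seq_by_id <- setNames(reads$seq, reads$id)
  qual_by_id <- setNames(reads$qual, reads$id)
  if (exclude_unspliced && "from_unspliced" %in% names(alignments))
    alignments <- alignments[!alignments$from_unspliced, , drop = FALSE]
  out <- mapped
  out$site <- site$site
  out$C <- 0L; out$T <- 0L; out$other <- 0L; out$deletions <- 0L
  out$indel_excluded <- 0L
  for (r in seq_len(nrow(mapped))) {
    chrom <- mapped$chrom[r]; pos <- mapped$position[r]
    if (pos > nchar(genome$chromosomes[[chrom]]))
      stop("site position ", pos, " beyond chromosome '", chrom, "'")
    sub <- alignments[alignments$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      hit <- query_position_at(sub$cigar[i], sub$start[i], pos,
                               indel_window)
      if (hit$status == "uncovered") next
      if (hit$status == "deletion") {
        out$deletions[r] <- out$deletions[r] + 1L
        next
      }
      if (hit$status == "indel_near") {
        out$indel_excluded[r] <- out$indel_excluded[r] + 1L
        next
      }
      id <- sub$read_id[i]
      if (is.na(seq_by_id[id]))
        stop("aligned read '", id, "' missing from the read set")
      q <- utf8ToInt(substr(qual_by_id[[id]], hit$qpos, hit$qpos)) - 33L
      if (length(q) && q < min_base_quality) next
      base <- substr(seq_by_id[[id]], hit$qpos, hit$qpos)
      if (base == "C") out$C[r] <- out$C[r] + 1L
      else if (base == "T") out$T[r] <- out$T[r] + 1L
      else out$other[r] <- out$other[r] + 1L
    }
  }
  out[, c("site", "chrom", "label", "position", "C", "T", "other",
          "deletions", "indel_excluded")]
}

#' Editing efficiency from base counts
#'
#' Efficiency is `T / (C + T) * 100`; other bases and deletions are
#' excluded from the denominator, since C-to-U editing reads out as a
#' C-or-T call.
#'
#' @param C,T Non-negative counts of cytidine and thymidine calls.
#' @return Percent in [0, 100].
#' @export
editing_efficiency <- function(C, T) {
  stopifnot(all(C >= 0), all(T >= 0))
  if (any(C + T == 0))
    stop("editing efficiency undefined: site not covered (C + T == 0)")
  T / (C + T) * 100
}

#' Summarise per-replicate efficiencies
#'
#' @param efficiencies Numeric vector of per-replicate percentages.
#' @return List with `n`, `mean`, `sd` (see [mean_sd()]).
#' @export
summarize_replicates <- function(efficiencies) mean_sd(efficiencies)

#' Compare editing efficiencies between two groups
#'
#' Welch unequal-variance t-test; editing comparisons default to
#' two-tailed.
#'
#' @param group_a,group_b Per-replicate efficiency vectors.
#' @param tails `"two"` (default) or `"one"`.
#' @return See [welch_t_test()].
#' @export
compare_groups <- function(group_a, group_b, tails = "two")
  welch_t_test(group_a, group_b, tails = tails)

#' Per-site editing results across replicates
#'
#' Runs [pileup_counts()] for every site of a site table and derives
#' per-replicate efficiencies with replicate mean and SD.
#'
#' @inheritParams pileup_counts
#' @param sites Editing-site table ([read_site_table()]).
#' @return List with `counts` (long data frame of per-replicate counts)
#'   and `summary` (per site: mean, sd, n of replicate efficiencies;
#'   replicates with zero C+T coverage are dropped with a warning).
#' @export
editing_results <- function(alignments, reads, genome, sites,
                            min_base_quality = 0L,
                            exclude_unspliced = FALSE,
                            indel_window = 5L) {
  counts <- do.call(rbind, lapply(seq_len(nrow(sites)), function(i)
    pileup_counts(alignments, reads, genome, sites[i, , drop = FALSE],
                  min_base_quality, exclude_unspliced, indel_window)))
  covered <- counts$C + counts$T > 0L
  if (any(!covered))
    warning(sum(!covered), " site/replicate combination(s) without C/T ",
            "coverage dropped from efficiencies")
  eff <- counts[covered, , drop = FALSE]
  eff$efficiency <- editing_efficiency(eff$C, eff$T)
  summ <- do.call(rbind, lapply(split(eff, eff$site), function(d) {
    s <- summarize_replicates(d$efficiency)
    data.frame(site = d$site[1L], n = s$n, mean = s$mean, sd = s$sd,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(counts = counts, efficiencies = eff, summary = summ)
}
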