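---
title: "TIP sequencing analysis: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TIP sequencing analysis: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tipseq)
```

## The measurement model

TIP sequencing reads are full-length RT-PCR amplicons of targeted
organelle transcripts, one 8-nt barcode per biological replicate on the
forward primer, pooled into a single nanopore run. Two quantities are
estimated per replicate:

* **Editing efficiency** at a known C-to-U site,
  $E = \dfrac{T}{C + T} \times 100\,\%$, where $C$ and $T$ are
  single-molecule base calls at the site's reference column. Because
  editing converts C to U (read as T in cDNA), only C and T calls enter
  the denominator; A/G/N calls and deletions are tallied but excluded.
* **Intron retention frequency**, $F = \dfrac{U}{N} \times 100\,\%$,
  where $U$ counts reads whose alignment to the spliced reference
  contains an insertion of intron-like length (650–700 bp, closed
  bounds) and $N$ counts all reads aligned to the same replicate
  chromosome of the intron-bearing gene.

Replicates are summarised as mean ± sample SD ($n-1$), and groups are
compared with Welch's unequal-variance t-test
(Welch–Satterthwaite fractional degrees of freedom, via
`stats::t.test`). Editing comparisons default to two-tailed tests;
retention comparisons default to one-tailed tests with the alternative
"treatment above control", reflecting that intron retention is a
gain-of-signal readout. Both defaults are overridable, and no
multiple-testing correction is applied by default (`adjust_p()` offers
Benjamini–Hochberg as an opt-in).

Key assumptions: amplicons are full length (no fragmentation), each read
is one molecule, the barcode identifies the replicate, and editing sites
are known in advance (no de novo site discovery).

## Pipeline stages and their parameters

### Demultiplexing and strand correction

Each read is searched for a barcode in its first `search_window` bases
(sense) and for a reverse-complemented barcode in its last
`search_window` bases (antisense). Defaults: `search_window = 100`
(barcodes sit at the amplicon 5' end but nanopore reads can carry
adapter remnants) and `max_mismatches = 1` (nanopore error rates make
exact-only matching lossy). Matching is tiered: exact matches decide
first; only when no exact match exists anywhere is the mismatch tier
consulted. A read matching more than one distinct (label, orientation)
combination in its deciding tier is *ambiguous* — typical of chimeric or
concatemeric amplicon reads — and is binned rather than force-assigned.
Antisense reads are reverse-complemented with reversed quality strings;
read identifiers are never rewritten. An indel inside the barcode breaks
the Hamming match and sends the read to `unassigned`; this loses a few
percent of reads at ~1% indel rates but does not misassign them.

### Pseudo-genome and coordinates

The alignment target is one synthetic chromosome per (gene, barcode):
the 8-nt barcode followed by the spliced cDNA, named `<gene>_<label>`.
All coordinates are 1-based and fully closed; a CDS position $p$ maps to
chromosome position $8 + p$. Primer bodies beyond the barcode are not
modelled: the barcode prefix is the only replicate-distinguishing
content the analysis needs.

### Alignment

The built-in aligner is a banded affine-gap semi-global dynamic program
(Rcpp): global in the read, free end gaps on the reference, gap cost
`gap_open + (L-1) * gap_extend`. The default scoring
(match +2, mismatch −4, open −4, extend −2) is a map-ont-like scheme.
The band is a corridor of half-width 150 around the main diagonal,
widened by the reference/read length difference, which comfortably
covers indel drift at nanopore error rates over amplicon lengths
(~1.4–2.1 kb) at a fraction of the unbanded cost.

A banded DP cannot bridge a whole retained intron as one 685-bp
insertion, so a *dual-reference* strategy is used: every read is scored
against each spliced chromosome and, for intron-annotated genes, against
the unspliced variant; the best score wins, ties break by chromosome
order (deterministic, flagged), and winning unspliced alignments are
re-expressed on the spliced chromosome with the intron as a single `I`
operation. Reads below an identity floor of 0.6 are reported unaligned,
which keeps random or chimeric sequence out of the retention
denominators. For real runs, SAM text from an external long-read
aligner can be imported instead; both routes feed identical downstream
types, and the test suite checks that they agree on insertion calls.

### Editing pileups and the indel exclusion window

The pileup walks each CIGAR to the site's reference column. Deletions
spanning the site are tallied separately; insertions adjacent to the
site contribute no call; bases below `min_base_quality` (default 0 —
count every call, like visual inspection of an alignment browser) are
skipped.

One further filter is a deliberate design choice: base calls whose
alignment contains an I or D operation within `indel_window = 5`
reference bases of the site are excluded from the tally. The reason is
reference bias. At an *edited* site the read (T) mismatches the
reference (C); when an indel sequencing error occurs nearby — worst in
homopolymer contexts such as TTCAA, whose edited form TTTAA is a T run —
the optimal alignment absorbs the indel into the mismatching site
column, deleting edited reads from the pileup (or occasionally writing a
spurious C onto the column) while leaving unedited reads untouched. This
asymmetry biases $E$ downward by several percent at ~1% indel rates.
Excluding indel-adjacent calls removes reads from *both* alleles at
nearly equal rates, restoring an unbiased C:T ratio at the cost of a
slightly smaller denominator. Setting `indel_window = 0` recovers
count-everything behaviour. Residual bias from substitution errors
remains and is bounded by the substitution rate (a T→C error reads as
unedited); the test suite asserts this bound at a fully edited site.

### Retention scanning and insert validation

Insertion events are single CIGAR `I` operations inside the closed
650–700 bp window (bracketing the 685-bp group II intron). Merging of
I operations separated by at most `merge_gap` reference bases is
available but off by default (`merge_gap = 0`), preserving
single-operation semantics; it is an opt-in for insertions split by
small alignment errors. Extracted inserts are validated against the
intron reference by Smith–Waterman local alignment
(`Biostrings::pairwiseAlignment`); an insert is *matched* when identity
≥ 80% and alignment length ≥ 80% of the intron length. These explicit
floors give the reported identity/length statistics a counting
contract; at zero simulated error, inserts match at identity 100 and
length exactly 685.

## The simulator: what it emulates, and what it does not

`simulation_config()` defaults define the package's reference study
conditions, mirroring one pooled TIP reaction:

* two genes × three barcoded replicates, 200 reads per replicate
  (within the 122–636 per-replicate range observed in real runs);
* a 1405-nt intron-bearing cDNA (685-nt group-II-style intron inserted
  after CDS position 723) and a 1503-nt intron-less cDNA — synthetic,
  seeded sequences, *not* the biological references — carrying editing
  sites at CDS 149, 467 and 383 with TTCAA/TCCAG/ATCAT contexts;
* per-site editing probabilities 0.95 / 0.80 / 0.50 and intron-retention
  probability 0.078 on the intron-bearing gene;
* 2% substitution, 1% insertion, 1% deletion per-base error rates with
  constant Phred-20 qualities, and uniform random read strand.

Editing and retention are decided per molecule first, errors are applied
second, and the strand flip last — mirroring the physical order
(template state, then sequencing error, then observed strand). A
truncation option (off by default) shortens reads at a uniform
breakpoint. Synthetic cDNAs are scrubbed of 8-mers within Hamming
distance 1 of any barcode (either orientation) inside the
demultiplexing windows, so simulated barcode truth is unambiguous.

Not emulated: signal-level nanopore behaviour, homopolymer-aware error
profiles, PCR chimeras, barcode-dependent read-recovery differences, and
length-biased PCR favouring spliced templates over intron-retaining
ones. Passing tests therefore demonstrate correctness of the
*computational* pipeline under a plausible error model — they do not
certify accuracy on real libraries, where PCR length bias in particular
is expected to underestimate absolute retention frequencies (real-run
comparisons across genotypes rely on the bias being shared).

## Numerical and degenerate-input choices

* Alignment score ties break by chromosome order and are flagged;
  traceback prefers diagonal (match) states, and alignments never end in
  a deletion.
* Reads longer than a reference by more than the band are infeasible for
  that reference and simply lose to the alternative references.
* `N` bases never match (scored as mismatches) and are tallied under
  `other` in pileups, never in the efficiency denominator.
* $E$ is undefined when $C + T = 0$ (an error, reported per
  site/replicate); $F$ is undefined when $N = 0$.
* One constant group is allowed in the Welch test (small replicate
  counts make constant groups possible); two constant groups raise an
  error. SD of a single value is `NA`, never 0.
* All statistics are computed at full precision; rounding (2 d.p. for
  efficiencies, 1 d.p. for summary mean/SD) is applied only in reports.

## Problem sizes in the test suite

Alignment-heavy unit tests run on short synthetic studies (300/280-nt
cDNAs, 60-nt intron, scaled retention window) so the suite stays fast;
the acceptance tests run the full reference conditions: a
1200-read end-to-end recovery under the error model above, a 240-read
zero-error run for the digital-identity and insert-identity properties,
and 210 random read/reference pairs (three scoring schemes) for exact
agreement between the banded aligner and a brute-force affine DP.

## Known limitations

* The built-in aligner is for desk-scale data (thousands of reads); real
  flowcell-scale runs should use an external long-read aligner and
  `import_sam()`.
* Retention detection is limited to the configured insertion-length
  window; partial splicing intermediates, exon skipping, and other
  isoforms outside it are out of scope.
* Editing quantification assumes C-to-U sites known in advance and does
  not model per-molecule editing haplotypes.
* BAM input/output is not implemented (SAM text suffices at this
  scale).
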