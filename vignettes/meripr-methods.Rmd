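---
title: "Methods: comparative MeRIP-seq analysis with meripr"
author: "meripr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative MeRIP-seq analysis with meripr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meripr)
```

# Scope and model

`meripr` analyses a MeRIP-seq (m⁶A-seq) experiment comparing two tissues
(A, B), each with two biological replicates, each replicate consisting of
an anti-m⁶A immunoprecipitated (IP) library and a matched input library.
All analysis happens in transcript space on a longest-transcript-per-gene
reference: each gene contributes a single transcript, coding transcripts
carry a 5′UTR/CDS/3′UTR segmentation, and reads and peaks are intervals
on those transcripts (0-based, half-open). Genome alignment and spliced
projection are deliberately upstream of this package: its inputs are
aligned read intervals.

## Window enrichment test

Each transcript is tiled with 100-nt windows sliding by 50 nt, the scale
of RNA fragmentation in MeRIP protocols; both are configurable. A read
contributes to every window containing its midpoint, so each read counts
at most twice at the default window/step ratio and the merge step can
rejoin adjacent signal. For a window with IP count $x$ and input count
$y$ in libraries of size $N_{IP}$ and $N_{in}$:

* fold enrichment
  $\mathrm{FE} = \dfrac{(x + 0.5)/N_{IP}}{(y + 0.5)/N_{in}}$ — the 0.5
  pseudocount keeps FE finite and defined for empty windows;
* the p-value is the one-sided Fisher exact probability of at-least-$x$
  IP reads in the 2×2 table $[x, N_{IP}-x; y, N_{in}-y]$, computed as a
  hypergeometric upper tail.

P-values are Benjamini–Hochberg adjusted across all windows of the
sample; windows with $q < 0.05$ that overlap or are book-ended merge
into peaks. A merged peak takes the minimum window $q$ and recomputes FE
from the summed window counts with the per-window pseudocounts carried
through — this is the weighted mediant of the window FEs, so a merged
peak's FE always lies between its windows' minimum and maximum.

The exact conditional test assumes near-Poisson counting noise within a
library. That is its known limitation: when window counts are strongly
overdispersed (negative binomial with small size parameter), the test
becomes anti-conservative at the window level. The pipeline's practical
false-discovery control for peaks is the replicate-concordance step
below, which is also how the two-replicate design is meant to be used;
single-replicate window lists should not be interpreted at face value
under heavy overdispersion.

## Concordance and common/specific classification

Two peaks from the two replicates of one tissue are *concordant* when
their overlap strictly exceeds half of the shorter peak's length. The
denominator is a genuine free choice (the overlap rule could anchor on
either peak or require reciprocity); the shorter-peak denominator is the
symmetric, permissive reading and is configurable. Qualifying pairs are
matched greedily by decreasing overlap with a coordinate tie-break, so
each peak is used at most once and the result does not depend on
replicate order. The concordant peak is the union interval with the mean
of the replicate log2 fold enrichments.

Across tissues, a concordant peak is

* **common** if it overlaps (≥ 1 nt) a concordant peak of the other
  tissue;
* **specific** if it overlaps no q < 0.05 peak in *either raw replicate*
  of the other tissue — specificity is judged against raw replicate
  calls, not only concordant ones, because "absent from every replicate"
  is a statement about each replicate;
* **ambiguous** otherwise (typically: present in exactly one replicate
  of the other tissue). The two criteria above are not exhaustive; the
  explicit third label makes the partition total and keeps such peaks
  out of common/specific summaries rather than silently dropping them.

Genes with at least one common peak are commonly methylated RNAs (CMRs);
CMR status takes precedence when a gene also has specific peaks. Genes
with only specific peaks of one tissue are SMRs of that tissue; specific
peaks of both tissues with no common peak give `mixed`; everything else
is `unmethylated`. The gene-level methylation level is the mean of the
gene's concordant-peak log2 fold enrichments. Both the precedence rule
and the mean (rather than median or maximum) are design choices made for
determinism and simplicity; they are localized in `classify_genes()`.

Level comparisons (tissue vs tissue, CMR vs SMR, list vs all) use the
two-sided Wilcoxon rank-sum test throughout. Because CMR sets are much
larger than SMR sets, `subsample_control()` redraws CMR subsets of SMR
cardinality without replacement ten times (seeded) and repeats the
comparison, guarding against set-size artefacts.

## Expression

FPKM is computed from pooled input replicates only:
$\mathrm{FPKM} = c \cdot 10^9 / (L \cdot T)$ with $c$ the fragments
whose midpoint lies on the gene's selected transcript, $L$ the
transcript length and $T$ the total assigned fragments. Genes with FPKM
strictly above 0.2 are "stably expressed". Midpoint assignment avoids
double counting at boundaries.

## Five-region topology and metagene profiles

Coding transcripts are split into 5′UTR, start-codon region, CDS,
stop-codon region and 3′UTR. With 5′UTR length $u$, CDS length $c$,
3′UTR length $w$ (thresholds strict; boundary values fall to the short
rules):

* $u > 100$, $c > 200$: start-codon region = 200 nt centred on the start
  codon; symmetrically for the stop codon when $w > 100$;
* $u \le 100$: the whole 5′UTR joins the start-codon region. The rule
  for the CDS side of that window is an open design point; `meripr`
  keeps the CDS-side 100 nt, preserving the 200-nt intent of the codon
  window. Mirrored at the 3′ end;
* $c \le 200$: the first half of the CDS is the start-codon region, the
  second half the stop-codon region; the UTR-side extensions are then
  suppressed (a UTR that is itself ≤ 100 nt still joins its codon
  region).

The five intervals always form a disjoint cover of the transcript — a
property test sweeps all $u \lessgtr 100$, $c \lessgtr 200$,
$w \lessgtr 100$ combinations against an independent position-painting
oracle. A peak overlapping several regions takes the highest-priority
label in the order stop > start > CDS > 3′UTR > 5′UTR.

Metagene profiles rescale each of 5′UTR/CDS/3′UTR to 100 bins (lncRNAs:
the whole transcript to 100 bins) and count each peak once, in the bin
containing its midpoint — binning the midpoint rather than the full span
follows from counting *peaks* per bin. Bins use the left-closed
convention (a midpoint at exactly 50% of a segment falls in bin 49).
Percentages sum to 100 whenever at least one peak is profiled.

The 5′UTR-length filter (`utr5_filter()`) reports the fraction of genes
with start-codon peaks whose 5′UTR is strictly longer than 100 nt: since
cap-adjacent m⁶Am can cross-react with anti-m⁶A antibodies, start-codon
signal on such genes cannot be attributed to m⁶Am, while shorter-UTR
genes would need single-nucleotide methods to resolve.

## Motif enrichment

A deliberately simple k-mer scorer (default k = 5, the GGACU consensus
length): overlapping k-mer counts in peak sequences versus same-length
background windows sampled from non-peak regions of the same transcripts
(controls composition bias; a shuffled mode is out of scope). Enrichment
uses +0.5 pseudocounts; significance is a one-sided binomial test with
the pseudocounted background frequency as null rate, BH-adjusted.
Reverse complements are not collapsed because m⁶A is strand-specific.
This ranks motifs robustly on data with a planted consensus; it is not a
PWM/EM motif discoverer and makes no attempt to reproduce scores of
dedicated motif tools.

## Gene-set overlays

External lists join on exact, case-sensitive identifiers; unmatched ids
are counted and reported, never silently dropped. A list gene is
"methylated" in a tissue when it has at least one concordant peak there
(methylation status is a per-tissue property, independent of the
common/specific label). `pct_methylated` is returned at full precision;
rounding is left to the caller.

# The synthetic-data generator

`sim_config()` defines the simulated study. Defaults describe the
two-tissue design the analysis targets: 300 genes (10% single-exon
lncRNAs), 150 peaks shared by both tissues plus 25 private to each, 100
nt peaks, 8-fold IP enrichment over an input depth of 50 reads per
100-nt window, and the DNA motif `GGACT` planted at 80% of peak centres.
UTR and CDS length ranges straddle the 100-nt and 200-nt topology
thresholds so the edge rules are always exercised. Sequencing depth and
fragment geometry are chosen for test power — the study this design
emulates published no library-depth figures — and peak counts are an
order of magnitude below a real methylome so the suite runs in seconds.

Window counts are negative binomial (mean = depth, size = `dispersion`),
with Poisson recovered as size → ∞. The default size of 100 adds about
1% extra squared coefficient of variation at the default depth: the
generator's contract is to produce data with the statistical structure
the analysis assumes, and the window test assumes near-Poisson
within-library noise. Smaller sizes are the knob for robustness studies
and will expose the test's anti-conservativeness discussed above.
Replicates are drawn independently; IP windows overlapping a truth peak
active in that tissue have their mean multiplied by `enrichment_fold`.

Every stage draws from an RNG stream derived from the single config
seed, so identical configs give byte-identical GTF/FASTA/BED/FASTQ
output. What the generator does *not* emulate: splice isoforms,
expression-level variation between genes, positional coverage bias,
sequencing errors, strand artefacts, and genome-space alignment. Passing
recovery tests on this generator therefore validates the pipeline's
logic and calibration under its stated assumptions — not performance on
real libraries, where coverage is rougher and the concordance step
carries more of the burden.

The FASTQ arm (`sim_fastq()`) plants the adapter `GATCGGAAGA` (with 0–2
substitutions) after a clean insert in a configurable fraction of reads
and gives a configurable fraction a low-quality 3′ tail, exercising all
four QC rules.

# Numerical and edge-case choices

* "longer than N" and "greater than Q" are read strictly everywhere
  (> 20 nt, > 50 nt, > Q25, > 70%, FPKM > 0.2, UTR > 100 nt,
  CDS > 200 nt, overlap > 50%).
* Adapter search considers only full-length 10-mer windows, leftmost hit
  wins; partial 3′-terminal adapter prefixes are not trimmed (the
  simplest exactly-testable reading; behaviour on partial suffixes is
  not specified by the QC rules this implements).
* Equal-length transcripts tie-break by lexicographic transcript id;
  peak-to-gene assignment is by transcript identity (one transcript per
  gene in transcript space).
* Empty inputs: empty p-vector → empty q-vector; empty peak set → empty
  merge; empty gene set or empty comparison set → error, never NaN.
* Zero-length reads are dropped before the quality-fraction division.
* The subsampling control and all background sampling take explicit
  seeds; nothing depends on ambient RNG state.

# Problem sizes

The test suite and the acceptance script run simulations of 200–800
genes (10⁴–10⁵ reads per library, ≥ 10⁴ windows for calibration checks,
1000 random draws for the region-classifier oracle, 10 seeds for motif
recovery). These sizes give stable Monte-Carlo margins (3–4 standard
errors) while keeping a full run in tens of seconds; they are the
package's chosen defaults for routine validation, and all generators
scale up by configuration for more stringent studies.

# Known limitations

* Single-nucleotide m⁶A resolution is out of reach by design: peaks are
  ~100-nt intervals, and m⁶A cannot be distinguished from m⁶Am within a
  peak (the 5′UTR-length filter only bounds the possible confusion).
* The Fisher window test is anti-conservative under strong
  overdispersion; rely on replicate concordance for peak-level control.
* Two tissues and two replicates are structural assumptions of the
  classification logic.
* The motif stage is a k-mer ranker, not a motif discoverer.
* Gene-level fold enrichment (mean of peak log2 FEs) and the
  50%-of-shorter overlap denominator are documented conventions, not
  community standards; both are configurable or localized for
  replacement.
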