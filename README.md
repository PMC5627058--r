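# meripr

Comparative MeRIP-seq (m⁶A-seq) analysis of two tissues in R.

N⁶-methyladenosine (m⁶A) is the most abundant internal mRNA modification.
In MeRIP-seq, fragmented RNA is immunoprecipitated with an anti-m⁶A
antibody and sequenced alongside a non-IP "input" library; methylated
regions appear as intervals where IP coverage is enriched over input.
`meripr` implements the full desk-side analysis for a two-tissue,
two-replicate design — the layout typically used to ask which transcripts
are commonly methylated across tissues and which carry tissue-specific
marks — plus a seeded synthetic-data generator so that every stage can be
validated against planted ground truth without access to raw sequencing
data.

## What it computes

* **Read QC** — adapter removal (`GATCGGAAGA`, ≤ 2 mismatches, leftmost
  full-window hit), 3′ trimming of bases with Phred < 20, retention of
  reads > 20 nt with > 70% of bases above Q25, and a > 50 nt mapping
  filter. All thresholds are strict inequalities.
* **Expression** — longest transcript per gene;
  FPKM = count · 10⁹ / (length · total) on pooled input replicates;
  genes with FPKM > 0.2 count as stably expressed.
* **Peak calling** — 100-nt windows sliding by 50 nt; per window a
  one-sided Fisher exact test on the 2×2 table
  `[ip, ip_total − ip; input, input_total − input]`, with fold enrichment
  ((ip + ½)/ip_total) / ((input + ½)/input_total); Benjamini–Hochberg FDR
  across all windows of a sample; windows with q < 0.05 merge into peaks.
* **Replicate concordance** — peaks overlapping > 50% of the shorter
  peak's length across replicates form concordant peaks (union interval,
  mean log2 fold enrichment).
* **Common/specific classification** — a concordant peak is *common*
  when it is concordant in both tissues (overlapping peaks), *specific*
  when it appears in both replicates of one tissue and in no replicate of
  the other, and *ambiguous* otherwise. Genes become CMRs (≥ 1 common
  peak), SMRs, mixed, or unmethylated; all level comparisons use the
  two-sided Wilcoxon rank-sum test, with a 10× size-matched subsampling
  control for the unequal CMR/SMR set sizes.
* **Topology** — metagene occupancy profiles (5′UTR/CDS/3′UTR rescaled
  to 100 bins each; lncRNAs to a single 100-bin profile) and a
  five-region classifier (5′UTR, start-codon region, CDS, stop-codon
  region, 3′UTR) with 200-nt codon windows, short-UTR (≤ 100 nt) and
  short-CDS (≤ 200 nt) edge rules, and the priority
  stop > start > CDS > 3′UTR > 5′UTR.
* **Motif enrichment** — overlapping k-mer counts (default k = 5, the
  GGACU consensus length) in peak versus matched non-peak background
  sequences, one-sided binomial tests, BH-ranked.
* **Gene-set overlays** — external gene lists (FMRP targets, synaptic or
  cell-type-enriched genes) joined to methylation status: percent
  methylated, peaks per gene, peak-region distribution, and
  fold-enrichment CDF/median comparisons.

## Worked example

```r
library(meripr)

cfg <- sim_config(n_genes = 100, n_common_peaks = 40,
                  n_specA_peaks = 10, n_specB_peaks = 10, seed = 7)
ds  <- sim_dataset(cfg)   # annotation, sequences, truth peaks, reads

calls <- lapply(c(A = "A", B = "B"), function(tissue)
  lapply(1:2, function(r)
    call_peaks(ds$reads[[tissue]][[r]]$IP, ds$reads[[tissue]][[r]]$input,
               ds$annotation)))
conc <- lapply(calls, function(x) concordant_peaks(x[[1]]$peaks, x[[2]]$peaks))

cls <- classify_peaks(conc$A, conc$B,
                      lapply(calls$A, `[[`, "peaks"),
                      lapply(calls$B, `[[`, "peaks"))
table(cls$tissue, cls$label)
#>     common specific_A specific_B
#>   A     36          9          0
#>   B     36          0          8

gm <- classify_genes(cls, ds$annotation)
table(gm$class)
#>  CMR  SMR_A  SMR_B  unmethylated
#>   33      5      6            56

cmp <- compare_levels(gm$gene_log2_fe[gm$class == "CMR"],
                      gm$gene_log2_fe[gm$class %in% c("SMR_A", "SMR_B")])
#> median log2FE  CMR 2.22  SMR 2.06  (Wilcoxon p = 0.0408)

table(assign_regions(conc$A, ds$annotation)$region)
#>  CDS  START  STOP  THREE_UTR
#>    8     12    18          1

head(kmer_enrichment(
  extract_peak_sequences(conc$A, ds$sequences),
  extract_peak_sequences(sample_background(conc$A, ds$sequences, seed = 1),
                         ds$sequences)), 1)
#>    kmer peak_count background_count enrichment      p_value      q_value
#> 1 GGACT         57                9   4.223312 1.594747e-18 1.633020e-15
```

The simulation planted 40 common and 10 + 10 tissue-private peaks with
8-fold IP enrichment and the GGACU (DNA `GGACT`) motif at 80% of peak
centres: the calls recover the common/specific split, the planted
enrichment difference between CMR and SMR genes, and `GGACT` as the
top-ranked k-mer.

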