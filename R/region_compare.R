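# interval overlap length between two 0-based half-open intervals
ov_len <- function(s1, e1, s2, e2) pmax(0L, pmin(e1, e2) - pmax(s1, s2))

# all overlapping peak pairs between two peak tables, same transcript
overlap_pairs <- function(p1, p2) {
  pairs <- list()
  for (tx in intersect(unique(p1$transcript_id), unique(p2$transcript_id))) {
    i1 <- which(p1$transcript_id == tx)
    i2 <- which(p2$transcript_id == tx)
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(p1$start[i1] + 1L, p1$end[i1]),
      IRanges::IRanges(p2$start[i2] + 1L, p2$end[i2]))
    if (length(ov) == 0L) next
    qi <- i1[S4Vectors::queryHits(ov)]
    si <- i2[S4Vectors::subjectHits(ov)]
    pairs[[tx]] <- data.frame(
      i = qi, j = si,
      ov = ov_len(p1$start[qi], p1$end[qi], p2$start[si], p2$end[si]))
  }
  if (length(pairs) == 0L)
    return(data.frame(i = integer(0), j = integer(0), ov = integer(0)))
  do.call(rbind, pairs)
}

# TRUE for each row of `peaks` overlapping (>= 1 nt) any row of `other`
overlaps_any <- function(peaks, other) {
  hit <- logical(nrow(peaks))
  if (nrow(peaks) == 0L || is.null(other) || nrow(other) == 0L) return(hit)
  pr <- overlap_pairs(peaks, other)
  hit[unique(pr$i)] <- TRUE
  hit
}

#' Concordant peaks between two biological replicates
#'
#' A replicate-1 / replicate-2 peak pair is concordant when their overlap
#' exceeds 50% (strictly, by default) of the shorter peak's length. Each
#' peak is used at most once: qualifying pairs are matched greedily by
#' decreasing overlap length (deterministic tie-break on coordinates), so
#' the result is symmetric in replicate order. The emitted interval is the
#' union of the two peaks; its log2 fold enrichment is the mean of the two
#' replicate values.
#'
#' @param peaks1,peaks2 peak data.frames from [call_peaks()] for the two
#'   replicates of one tissue.
#' @param min_frac overlap fraction of the shorter peak that must be
#'   exceeded (default 0.5).
#' @return data.frame with `transcript_id`, `start`, `end` (union),
#'   `log2_fe`, `fold_enrichment`, `q_rep1`, `q_rep2`.
#' @export
concordant_peaks <- function(peaks1, peaks2, min_frac = 0.5) {
  empty <- data.frame(transcript_id = character(0), start = integer(0),
                      end = integer(0), log2_fe = numeric(0),
                      fold_enrichment = numeric(0),
                      q_rep1 = numeric(0), q_rep2 = numeric(0),
                      stringsAsFactors = FALSE)
  pr <- overlap_pairs(peaks1, peaks2)
  if (nrow(pr) == 0L) return(empty)
  len1 <- peaks1$end[pr$i] - peaks1$start[pr$i]
  len2 <- peaks2$end[pr$j] - peaks2$start[pr$j]
  pr <- pr[pr$ov > min_frac * pmin(len1, len2), , drop = FALSE]
  if (nrow(pr) == 0L) return(empty)
  # greedy best-overlap matching, each peak used once; symmetric tie-break
  pr <- pr[order(-pr$ov, peaks1$transcript_id[pr$i],
                 pmin(peaks1$start[pr$i], peaks2$start[pr$j]),
                 pr$i, pr$j), , drop = FALSE]
  used1 <- logical(nrow(peaks1)); used2 <- logical(nrow(peaks2))
  keep <- logical(nrow(pr))
  for (r in seq_len(nrow(pr))) {
    if (!used1[pr$i[r]] && !used2[pr$j[r]]) {
      keep[r] <- TRUE
      used1[pr$i[r]] <- TRUE
      used2[pr$j[r]] <- TRUE
    }
  }
  pr <- pr[keep, , drop = FALSE]
  out <- data.frame(
    transcript_id = peaks1$transcript_id[pr$i],
    start = pmin(peaks1$start[pr$i], peaks2$start[pr$j]),
    end = pmax(peaks1$end[pr$i], peaks2$end[pr$j]),
    log2_fe = (peaks1$log2_fe[pr$i] + peaks2$log2_fe[pr$j]) / 2,
    q_rep1 = peaks1$q_value[pr$i], q_rep2 = peaks2$q_value[pr$j],
    stringsAsFactors = FALSE)
  out$fold_enrichment <- 2^out$log2_fe
  out <- out[order(out$transcript_id, out$start),
             c("transcript_id", "start", "end", "log2_fe",
               "fold_enrichment", "q_rep1", "q_rep2")]
  rownames(out) <- NULL
  out
}

#' Classify concordant peaks as common, tissue-specific or ambiguous
#'
#' A concordant peak of tissue A is `common` when it overlaps (>= 1 nt) a
#' concordant peak of tissue B; `specific_A` when it overlaps no peak in
#' either raw replicate peak set of B; otherwise `ambiguous` (present in
#' exactly one B replicate — it satisfies neither the common nor the
#' specific criterion and is excluded from common/specific analyses).
#' Symmetric for tissue B. Common peaks therefore appear once per tissue
#' in the output.
#'
#' @param conc_a,conc_b concordant peak tables ([concordant_peaks()]) for
#'   tissues A and B.
#' @param raw_a,raw_b lists of the two raw replicate peak tables per
#'   tissue (consulted for the "not in any replicate" specificity rule).
#' @return the concordant peaks of both tissues with added columns
#'   `tissue` and `label` (one of `common`, `specific_A`, `specific_B`,
#'   `ambiguous`).
#' @export
classify_peaks <- function(conc_a, conc_b, raw_a, raw_b) {
  side <- function(conc, conc_other, raw_other, tissue) {
    if (nrow(conc) == 0L) {
      out <- conc
      out$tissue <- character(0); out$label <- character(0)
      return(out)
    }
    common <- overlaps_any(conc, conc_other)
    in_rep1 <- overlaps_any(conc, raw_other[[1]])
    in_rep2 <- overlaps_any(conc, raw_other[[2]])
    label <- ifelse(common, "common",
                    ifelse(!in_rep1 & !in_rep2,
                           paste0("specific_", tissue), "ambiguous"))
    out <- conc
    out$tissue <- tissue
    out$label <- label
    out
  }
  out <- rbind(side(conc_a, conc_b, raw_b, "A"),
               side(conc_b, conc_a, raw_a, "B"))
  rownames(out) <- NULL
  out
}

#' Classify genes by the methylation status of their peaks
#'
#' A gene containing at least one common peak is a commonly methylated RNA
#' (`CMR`) regardless of additional specific peaks (CMR precedence); a
#' gene with specific peaks of one tissue only is an `SMR_A`/`SMR_B`; a
#' gene with specific peaks of both tissues and no common peak is
#' `mixed`; genes without classified peaks are `unmethylated`. The
#' gene-level methylation level `gene_log2_fe` is the mean of the gene's
#' concordant-peak log2 fold enrichments (ambiguous peaks included, since
#' they are concordant within their tissue). Per-tissue methylation flags
#' (any concordant peak in that tissue) are provided for overlays.
#'
#' @param classified_peaks output of [classify_peaks()].
#' @param annotation one-transcript-per-gene annotation (defines the gene
#'   universe; peaks map to the gene of the transcript they sit on).
#' @return data.frame with `gene_id`, `n_peaks`, `n_common`,
#'   `n_specific_A`, `n_specific_B`, `gene_log2_fe`, `class`,
#'   `methylated_A`, `methylated_B`.
#' @export
classify_genes <- function(classified_peaks, annotation) {
  gene_of <- setNames(annotation$gene_id, annotation$transcript_id)
  cp <- classified_peaks
  cp$gene_id <- gene_of[cp$transcript_id]
  per_gene <- function(g) {
    p <- cp[!is.na(cp$gene_id) & cp$gene_id == g, , drop = FALSE]
    n_common <- sum(p$label == "common") / 2  # common peaks listed per tissue
    n_sa <- sum(p$label == "specific_A")
    n_sb <- sum(p$label == "specific_B")
    cls <- if (nrow(p) == 0L) "unmethylated"
    else if (n_common >= 1) "CMR"
    else if (n_sa >= 1 && n_sb >= 1) "mixed"
    else if (n_sa >= 1) "SMR_A"
    else if (n_sb >= 1) "SMR_B"
    else "unmethylated"  # only ambiguous peaks: no common/specific evidence
    data.frame(gene_id = g, n_peaks = nrow(p), n_common = n_common,
               n_specific_A = n_sa, n_specific_B = n_sb,
               gene_log2_fe = if (nrow(p)) mean(p$log2_fe) else NA_real_,
               class = cls,
               methylated_A = any(p$tissue == "A"),
               methylated_B = any(p$tissue == "B"),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(unique(annotation$gene_id), per_gene))
  rownames(out) <- NULL
  out
}

#' Compare methylation levels between two sets (Wilcoxon rank-sum)
#'
#' @param fe1,fe2 numeric vectors of log2 fold enrichments (peak-level or
#'   gene-level), both non-empty.
#' @return list with `median1`, `median2`, `p_value` (two-sided Wilcoxon
#'   rank-sum), `n1`, `n2`.
#' @export
compare_levels <- function(fe1, fe2) {
  if (length(fe1) == 0L || length(fe2) == 0L)
    stop("both sets must be non-empty")
  # ties are routine in fold-enrichment data; the normal approximation
  # wilcox.test falls back to is fine, silence its tie warning
  p <- suppressWarnings(wilcox.test(fe1, fe2)$p.value)
  list(median1 = median(fe1), median2 = median(fe2),
       p_value = p, n1 = length(fe1), n2 = length(fe2))
}

#' Size-matched subsampling control for CMR vs SMR comparisons
#'
#' CMRs outnumber SMRs; to rule out a set-size artefact, the same number
#' of items as the SMR set is drawn from the CMR set without replacement
#' and the comparison rerun, `draws` times (default 10).
#'
#' @param cmr_fe,smr_fe numeric vectors of log2 fold enrichments;
#'   `length(cmr_fe) >= length(smr_fe)`.
#' @param draws number of subsampling draws.
#' @param seed integer seed; fixed seed gives identical draws.
#' @return data.frame with one row per draw: `draw`, `median_cmr`,
#'   `median_smr`, `p_value`.
#' @export
subsample_control <- function(cmr_fe, smr_fe, draws = 10L, seed = 1L) {
  if (length(cmr_fe) < length(smr_fe))
    stop("CMR set must be at least as large as the SMR set")
  set.seed(seed)
  res <- lapply(seq_len(draws), function(d) {
    sub <- sample(cmr_fe, length(smr_fe), replace = FALSE)
    cl <- compare_levels(sub, smr_fe)
    data.frame(draw = d, median_cmr = cl$median1, median_smr = cl$median2,
               p_value = cl$p_value)
  })
  do.call(rbind, res)
}

#' Expression versus methylation relationships
#'
#' Compares median expression (FPKM) of methylated versus unmethylated
#' genes (Wilcoxon rank-sum) and computes Spearman's rank correlation
#' between FPKM and the gene-level methylation level among methylated
#' genes.
#'
#' @param expression expression table ([expression_table()]).
#' @param gene_methylation gene classification table ([classify_genes()]).
#' @return list with `median_fpkm_methylated`,
#'   `median_fpkm_unmethylated`, `wilcoxon_p`, `spearman_rho`,
#'   `n_methylated`, `n_unmethylated`.
#' @export
expression_vs_methylation <- function(expression, gene_methylation) {
  m <- merge(expression, gene_methylation, by = "gene_id")
  meth <- m[m$class != "unmethylated", , drop = FALSE]
  unmeth <- m[m$class == "unmethylated", , drop = FALSE]
  if (nrow(meth) < 3L)
    stop("fewer than 3 methylated genes: correlation undefined")
  cl <- compare_levels(meth$fpkm, unmeth$fpkm)
  rho <- cor(meth$fpkm, meth$gene_log2_fe, method = "spearman")
  list(median_fpkm_methylated = cl$median1,
       median_fpkm_unmethylated = cl$median2,
       wilcoxon_p = cl$p_value, spearman_rho = rho,
       n_methylated = nrow(meth), n_unmethylated = nrow(unmeth))
}
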