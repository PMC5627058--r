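#' Overlay an external gene list on methylation results
#'
#' Joins a gene list (cell-type-enriched genes, synaptic proteome, FMRP
#' targets, ...) to the methylation call set of one tissue: how many list
#' genes are methylated (have at least one concordant peak in that
#' tissue), how many peaks they carry, where those peaks sit, and their
#' fold enrichments. Identifier matching is exact-string and
#' case-sensitive; list genes absent from the annotation are counted in
#' `n_unmatched`, not silently dropped.
#'
#' @param gene_list list with `name` and `gene_ids` (see
#'   [read_gene_list()]), or a character vector of ids.
#' @param gene_methylation gene table from [classify_genes()].
#' @param peaks_assigned optional concordant peaks of the queried tissue
#'   with `region` ([assign_regions()]) and `log2_fe` columns, mapped to
#'   genes via `annotation`; enables the region distribution and
#'   fold-enrichment components.
#' @param annotation one-transcript-per-gene annotation (needed with
#'   `peaks_assigned`).
#' @param tissue `"A"` or `"B"`.
#' @return list with `name`, `n_list`, `n_matched`, `n_unmatched`,
#'   `n_methylated`, `pct_methylated` (percent, full precision),
#'   `mean_peaks_per_gene`, `region_distribution` (named percentages over
#'   the five regions, or `NULL`), `fe_values` (log2 fold enrichments of
#'   the list's peaks, or `NULL`).
#' @export
overlay_gene_list <- function(gene_list, gene_methylation,
                              peaks_assigned = NULL, annotation = NULL,
                              tissue = "A") {
  if (is.character(gene_list))
    gene_list <- list(name = "gene_list", gene_ids = unique(gene_list))
  ids <- unique(gene_list$gene_ids)
  if (length(ids) == 0L) stop("gene list is empty")
  meth_col <- paste0("methylated_", tissue)
  gm <- gene_methylation[gene_methylation$gene_id %in% ids, , drop = FALSE]
  n_matched <- nrow(gm)
  meth_ids <- gm$gene_id[gm[[meth_col]]]
  n_meth <- length(meth_ids)
  out <- list(name = gene_list$name, n_list = length(ids),
              n_matched = n_matched, n_unmatched = length(ids) - n_matched,
              n_methylated = n_meth,
              pct_methylated = 100 * n_meth / length(ids),
              mean_peaks_per_gene = NA_real_,
              region_distribution = NULL, fe_values = NULL)
  if (!is.null(peaks_assigned) && !is.null(annotation)) {
    gene_of <- setNames(annotation$gene_id, annotation$transcript_id)
    pk <- peaks_assigned[gene_of[peaks_assigned$transcript_id] %in% meth_ids, ,
                         drop = FALSE]
    out$mean_peaks_per_gene <- if (n_meth > 0) nrow(pk) / n_meth else NA_real_
    if (nrow(pk) > 0L) {
      rc <- region_counts(pk)
      out$region_distribution <- setNames(rc$pct, rc$region)
      out$fe_values <- pk$log2_fe
    }
  }
  out
}

#' Empirical CDFs of fold enrichment for several gene lists
#'
#' Evaluates each list's empirical cumulative distribution of log2 fold
#' enrichment on the pooled support (right-continuous, rising from 0 to
#' 1) and runs pairwise two-sided Wilcoxon rank-sum tests.
#'
#' @param fe_lists named list of non-empty numeric vectors of log2 fold
#'   enrichments.
#' @return list with `support` (sorted pooled values), `cdf` (data.frame,
#'   one column per list evaluated on the support) and `pairwise_p`
#'   (data.frame `list1`, `list2`, `p_value`).
#' @export
compare_fe_cdf <- function(fe_lists) {
  if (any(vapply(fe_lists, length, 0L) == 0L))
    stop("every list must be non-empty")
  support <- sort(unique(unlist(fe_lists)))
  cdf <- as.data.frame(lapply(fe_lists, function(v)
    stats::ecdf(v)(support)))
  names(cdf) <- names(fe_lists)
  nm <- names(fe_lists)
  pairs <- if (length(nm) >= 2) utils::combn(nm, 2, simplify = FALSE) else list()
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    cl <- compare_levels(fe_lists[[pr[1]]], fe_lists[[pr[2]]])
    data.frame(list1 = pr[1], list2 = pr[2], p_value = cl$p_value,
               stringsAsFactors = FALSE)
  }))
  list(support = support, cdf = cdf, pairwise_p = pw)
}

#' Compare a gene list's methylation levels with all methylated genes
#'
#' Median log2 fold enrichment of the list versus the full methylated
#' set, with the two-sided Wilcoxon rank-sum p-value (delegates to
#' [compare_levels()]).
#'
#' @param list_fe,all_fe non-empty numeric vectors of log2 fold
#'   enrichments.
#' @return list with `median_list`, `median_all`, `p_value`.
#' @export
median_fe_compare <- function(list_fe, all_fe) {
  cl <- compare_levels(list_fe, all_fe)
  list(median_list = cl$median1, median_all = cl$median2,
       p_value = cl$p_value)
}
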