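#' Select the longest transcript per gene
#'
#' Builds the reference transcriptome used by every downstream stage: for
#' each gene, the transcript of maximal length is kept. Equal-length ties
#' are broken deterministically by lexicographically smallest
#' `transcript_id`.
#'
#' @param annotation data.frame with at least `gene_id`, `transcript_id`,
#'   `length` (possibly several transcripts per gene).
#' @return the input rows reduced to one per gene, ordered by `gene_id`.
#' @export
select_longest <- function(annotation) {
  ord <- order(annotation$gene_id, -annotation$length,
               annotation$transcript_id)
  ann <- annotation[ord, , drop = FALSE]
  out <- ann[!duplicated(ann$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fragments per kilobase per million (FPKM)
#'
#' `fpkm = count * 1e9 / (length * total)`. Genes with FPKM strictly
#' greater than 0.2 are considered stably expressed; exactly 0.2 is not
#' expressed.
#'
#' @param count fragment count(s) assigned to the gene.
#' @param length transcript length(s), nt (> 0).
#' @param total total mapped fragments in the library (> 0).
#' @return numeric FPKM value(s).
#' @export
fpkm <- function(count, length, total) {
  if (any(total <= 0)) stop("total mapped fragments must be > 0")
  if (any(length <= 0)) stop("transcript length must be > 0")
  count * 1e9 / (length * total)
}

#' FPKM threshold above which a gene counts as stably expressed
#' @export
FPKM_EXPRESSED_THRESHOLD <- 0.2

# assign read intervals to transcripts by midpoint: in transcript space a
# read belongs to the transcript it sits on, provided its midpoint is
# inside [0, length)
count_fragments <- function(reads, annotation) {
  mid <- (reads$start + reads$end) %/% 2L
  len <- setNames(annotation$length, annotation$transcript_id)
  ok <- reads$transcript_id %in% names(len) &
    mid >= 0L & mid < len[reads$transcript_id]
  tab <- table(factor(reads$transcript_id[ok],
                      levels = annotation$transcript_id))
  as.integer(tab)
}

#' Per-gene expression table from input libraries
#'
#' Counts fragments (read midpoints) per selected transcript, pooling the
#' supplied input-library replicates, and computes FPKM with the
#' expressed flag (`fpkm > 0.2`). Expression is always computed from
#' input (non-IP) libraries.
#'
#' @param input_reads a reads data.frame (`transcript_id`, `start`, `end`)
#'   or a list of them (replicates, pooled before counting).
#' @param annotation one-transcript-per-gene annotation (see
#'   [select_longest()]).
#' @return data.frame with `gene_id`, `fragment_count`, `fpkm`,
#'   `expressed`.
#' @export
expression_table <- function(input_reads, annotation) {
  if (is.data.frame(input_reads)) input_reads <- list(input_reads)
  pooled <- do.call(rbind, input_reads)
  counts <- count_fragments(pooled, annotation)
  total <- sum(counts)
  if (total == 0L) stop("no fragments assigned to any transcript")
  vals <- fpkm(counts, annotation$length, total)
  data.frame(gene_id = annotation$gene_id,
             fragment_count = counts,
             fpkm = vals,
             expressed = vals > FPKM_EXPRESSED_THRESHOLD,
             stringsAsFactors = FALSE)
}
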