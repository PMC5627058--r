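#' Segment a coding transcript into five regions
#'
#' Splits a coding transcript into 5'UTR, start-codon region, CDS,
#' stop-codon region and 3'UTR (0-based half-open intervals; some may be
#' empty). With 5'UTR length `u`, CDS length `c` and 3'UTR length `w`:
#'
#' * `u > 100` and `c > 200`: the start-codon region is the 200 nt centred
#'   on the start codon, `[u - 100, u + 100)`; symmetric for the stop
#'   codon when `w > 100`.
#' * `u <= 100` (and `c > 200`): the whole 5'UTR joins the start-codon
#'   region together with the CDS-side 100 nt, giving `[0, u + 100)`;
#'   symmetric for a short 3'UTR.
#' * `c <= 200`: the first half of the CDS is the start-codon region and
#'   the rest the stop-codon region; the UTR-side extensions are
#'   suppressed, but a UTR that is itself `<= 100` nt still joins its
#'   codon region.
#'
#' Thresholds are strict: a 5'UTR of exactly 100 nt or a CDS of exactly
#' 200 nt falls under the short rules. The five intervals always form a
#' disjoint cover of `[0, length)`.
#'
#' @param transcript one-row annotation data.frame (or list) with
#'   `biotype`, `length`, `utr5_len`, `cds_len`, `utr3_len`.
#' @return data.frame with columns `region` (`FIVE_UTR`, `START`, `CDS`,
#'   `STOP`, `THREE_UTR` in 5' to 3' order) and `start`, `end`; empty
#'   regions have `start == end`.
#' @export
segment_transcript <- function(transcript) {
  if (transcript$biotype != "coding")
    stop("only coding transcripts are segmented into five regions")
  u <- as.integer(transcript$utr5_len)
  cl <- as.integer(transcript$cds_len)
  w <- as.integer(transcript$utr3_len)
  len <- u + cl + w
  if (cl <= 200L) {
    half <- cl %/% 2L
    start_s <- if (u <= 100L) 0L else u
    start_e <- u + half
    stop_s <- start_e
    stop_e <- if (w <= 100L) len else u + cl
    cds_s <- start_e; cds_e <- start_e  # CDS fully absorbed
  } else {
    start_s <- if (u <= 100L) 0L else u - 100L
    start_e <- u + 100L
    stop_s <- u + cl - 100L
    stop_e <- if (w <= 100L) len else u + cl + 100L
    cds_s <- start_e; cds_e <- stop_s
  }
  data.frame(
    region = c("FIVE_UTR", "START", "CDS", "STOP", "THREE_UTR"),
    start = c(0L, start_s, cds_s, stop_s, stop_e),
    end = c(start_s, start_e, cds_e, stop_e, len),
    stringsAsFactors = FALSE)
}

#' Region priority used when a peak overlaps several regions
#' @export
REGION_PRIORITY <- c("STOP", "START", "CDS", "THREE_UTR", "FIVE_UTR")

#' Assign a peak to one of the five transcript regions
#'
#' The peak receives the label of the highest-priority region it overlaps
#' by at least 1 nt, in the order stop-codon region > start-codon region >
#' CDS > 3'UTR > 5'UTR.
#'
#' @param peak_start,peak_end peak interval on the transcript, 0-based
#'   half-open.
#' @param segmentation result of [segment_transcript()].
#' @return a single region label.
#' @export
assign_region <- function(peak_start, peak_end, segmentation) {
  len <- max(segmentation$end)
  if (peak_start < 0L || peak_end > len || peak_end <= peak_start)
    stop("peak outside [0, transcript length)")
  ov <- pmin(segmentation$end, peak_end) - pmax(segmentation$start, peak_start)
  hit <- segmentation$region[ov >= 1L]
  REGION_PRIORITY[min(match(hit, REGION_PRIORITY))]
}

#' Assign every peak to a transcript region
#'
#' @param peaks peaks data.frame (`transcript_id`, `start`, `end`).
#' @param annotation one-transcript-per-gene annotation; only peaks on
#'   coding transcripts are assigned (lncRNA peaks get `NA`).
#' @return the peaks with an added `region` column.
#' @export
assign_regions <- function(peaks, annotation) {
  ann <- annotation[match(peaks$transcript_id, annotation$transcript_id), ]
  region <- rep(NA_character_, nrow(peaks))
  for (tx in unique(peaks$transcript_id)) {
    a <- annotation[annotation$transcript_id == tx, ]
    if (nrow(a) == 0L || a$biotype != "coding") next
    seg <- segment_transcript(a)
    for (i in which(peaks$transcript_id == tx))
      region[i] <- assign_region(peaks$start[i], peaks$end[i], seg)
  }
  peaks$region <- region
  peaks
}

# 100-bin index (0-based) of a 0-based position within a segment of
# length len; left-closed convention, so a position at exactly 50% of the
# segment falls in bin 49
bin_of <- function(pos, len) {
  max(0L, as.integer((100L * pos + len - 1L) %/% len) - 1L)
}

#' Metagene peak-occupancy profile
#'
#' Each peak contributes one count to the bin containing its midpoint:
#' for mRNAs the 5'UTR, CDS and 3'UTR are each rescaled to 100 bins
#' (bins 0-99, 100-199, 200-299); for lncRNAs the whole transcript is
#' rescaled to 100 bins. Bin counts are converted to percentages of the
#' total number of profiled peaks. A peak whose midpoint falls in a
#' zero-length segment (possible only at segment boundaries) is counted
#' in the nearest non-empty segment's boundary bin.
#'
#' @param peaks peaks data.frame (`transcript_id`, `start`, `end`).
#' @param annotation one-transcript-per-gene annotation.
#' @param biotype `"coding"` (300-bin mRNA profile) or `"lncRNA"`
#'   (100-bin profile); peaks on the other biotype are ignored.
#' @return numeric vector of bin percentages (length 300 or 100) with a
#'   `"n_peaks"` attribute.
#' @export
metagene_profile <- function(peaks, annotation, biotype = "coding") {
  nbin <- if (biotype == "coding") 300L else 100L
  counts <- numeric(nbin)
  ann <- annotation[match(peaks$transcript_id, annotation$transcript_id), ]
  keep <- !is.na(ann$biotype) & ann$biotype == biotype
  pk <- peaks[keep, , drop = FALSE]
  an <- ann[keep, , drop = FALSE]
  n <- nrow(pk)
  if (n > 0L) for (i in seq_len(n)) {
    mid <- (pk$start[i] + pk$end[i]) %/% 2L
    if (biotype == "lncRNA") {
      bin <- bin_of(mid, an$length[i])
    } else {
      u <- an$utr5_len[i]; cl <- an$cds_len[i]; w <- an$utr3_len[i]
      segs <- data.frame(off = c(0L, 100L, 200L),
                         start = c(0L, u, u + cl),
                         len = c(u, cl, w))
      j <- findInterval(mid, segs$start)
      if (segs$len[j] == 0L) j <- which(segs$len > 0L)[1]  # boundary fallback
      bin <- segs$off[j] + bin_of(mid - segs$start[j], segs$len[j])
    }
    counts[bin + 1L] <- counts[bin + 1L] + 1
  }
  pct <- if (n > 0L) counts / n * 100 else counts
  attr(pct, "n_peaks") <- n
  pct
}

#' Peak counts and percentages per region, by group
#'
#' Cross-tabulates region assignments over peak groups (for example
#' total/common/specific by tissue), reporting counts and within-group
#' percentages for the five regions.
#'
#' @param assigned peaks with a `region` column ([assign_regions()]).
#' @param group factor/character vector, one group label per peak (default
#'   a single group `"all"`).
#' @return data.frame with `group`, `region`, `count`, `pct`.
#' @export
region_counts <- function(assigned, group = NULL) {
  if (is.null(group)) group <- rep("all", nrow(assigned))
  ok <- !is.na(assigned$region)
  tab <- table(factor(group[ok], levels = unique(group)),
               factor(assigned$region[ok], levels = REGION_PRIORITY))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("group", "region", "count")
  tot <- tapply(out$count, out$group, sum)
  out$pct <- as.numeric(ifelse(tot[out$group] > 0,
                               out$count / tot[out$group] * 100, 0))
  rownames(out) <- NULL
  out
}

#' Fraction of genes whose 5'UTR exceeds a length threshold
#'
#' Used to gauge how much of the start-codon-region signal could be
#' cap-adjacent m6Am rather than m6A: m6Am sits at the first transcribed
#' nucleotide, so genes with a 5'UTR strictly longer than the threshold
#' (default 100 nt) have start-codon peaks too far from the cap to be
#' m6Am.
#'
#' @param gene_ids genes with start-codon-region peaks (non-empty).
#' @param annotation one-transcript-per-gene annotation.
#' @param threshold nt threshold, strict (exactly `threshold` is
#'   excluded).
#' @return fraction in `[0, 1]`.
#' @export
utr5_filter <- function(gene_ids, annotation, threshold = 100L) {
  if (length(gene_ids) == 0L) stop("gene set must be non-empty")
  u <- annotation$utr5_len[match(gene_ids, annotation$gene_id)]
  mean(u > threshold, na.rm = TRUE)
}
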