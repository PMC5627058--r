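#' QC parameters for MeRIP-seq read preprocessing
#'
#' Constants of the preprocessing stage: adapter removal by approximate
#' match, 3' quality trimming, the length/quality retention filter, and
#' the minimum mapping length. Length thresholds are strict ("longer than
#' 20 nt" keeps 21 nt and up) and the quality-fraction rule counts bases
#' strictly above `frac_qual`.
#'
#' @param adapter adapter sequence searched for (full-length windows only).
#' @param max_mismatch maximum Hamming mismatches allowed in an adapter hit.
#' @param trim_qual Phred threshold for 3' trimming: trailing bases with
#'   quality strictly below this are removed.
#' @param keep_min_len minimum retained length, nt (strict >).
#' @param frac_qual Phred threshold for the retention fraction (strict >).
#' @param frac_min minimum fraction of bases above `frac_qual` (strict >).
#' @param map_min_len minimum length for mapping, nt (strict >).
#' @return validated list of class `"qc_params"`.
#' @export
qc_params <- function(adapter = "GATCGGAAGA", max_mismatch = 2L,
                      trim_qual = 20L, keep_min_len = 20L,
                      frac_qual = 25L, frac_min = 0.70, map_min_len = 50L) {
  p <- list(adapter = toupper(adapter), max_mismatch = as.integer(max_mismatch),
            trim_qual = as.integer(trim_qual),
            keep_min_len = as.integer(keep_min_len),
            frac_qual = as.integer(frac_qual), frac_min = frac_min,
            map_min_len = as.integer(map_min_len))
  if (any(c(p$max_mismatch, p$trim_qual, p$keep_min_len, p$frac_qual,
            p$map_min_len) < 0L))
    stop("thresholds must be non-negative")
  if (p$frac_min < 0 || p$frac_min > 1) stop("frac_min must lie in [0, 1]")
  class(p) <- "qc_params"
  p
}

#' Convert Phred scores to a Phred+33 string and back
#'
#' @param q integer vector of Phred scores.
#' @return `phred_to_string()`: a single Phred+33 encoded string;
#'   `string_to_phred()`: an integer vector of scores.
#' @export
phred_to_string <- function(q) {
  if (length(q) == 0L) return("")
  intToUtf8(q + 33L)
}

#' @rdname phred_to_string
#' @param s a Phred+33 encoded string.
#' @export
string_to_phred <- function(s) {
  if (!nzchar(s)) return(integer(0))
  utf8ToInt(s) - 33L
}

# leftmost start (1-based) of a full-length adapter window with Hamming
# distance <= max_mismatch, or NA; vectorised over reads
adapter_hit_pos <- function(bases, adapter, max_mismatch) {
  k <- nchar(adapter)
  L <- nchar(bases)
  hit <- rep(NA_integer_, length(bases))
  maxL <- max(L, 0L)
  if (maxL < k) return(hit)
  ad <- strsplit(adapter, "")[[1]]
  for (p in seq_len(maxL - k + 1L)) {
    open <- is.na(hit) & (L - k + 1L >= p)
    if (!any(open)) break
    mism <- integer(sum(open))
    win <- substr(bases[open], p, p + k - 1L)
    for (j in seq_len(k))
      mism <- mism + (substr(win, j, j) != ad[j])
    ok <- mism <= max_mismatch
    hit[which(open)[ok]] <- p
  }
  hit
}

#' Remove adapter sequence from reads
#'
#' Scans every full-length adapter window in each read; at the leftmost
#' position whose Hamming distance to the adapter is at most
#' `params$max_mismatch`, the adapter and everything 3' of it are removed
#' (qualities kept in sync). Reads with no qualifying window — including
#' reads carrying only a partial adapter prefix at the 3' end — are
#' returned unchanged.
#'
#' @param reads reads data.frame with columns `id`, `bases`, `quals`
#'   (Phred+33 strings).
#' @param params a [qc_params()].
#' @return the reads data.frame with trimmed `bases` and `quals`.
#' @export
trim_adapter <- function(reads, params = qc_params()) {
  hit <- adapter_hit_pos(reads$bases, params$adapter, params$max_mismatch)
  cut <- ifelse(is.na(hit), nchar(reads$bases), hit - 1L)
  reads$bases <- substr(reads$bases, 1L, cut)
  reads$quals <- substr(reads$quals, 1L, cut)
  reads
}

#' Trim low-quality bases from the 3' end
#'
#' Removes the maximal trailing run of bases whose Phred score is strictly
#' below `params$trim_qual`. Internal low-quality bases are retained.
#'
#' @inheritParams trim_adapter
#' @return the reads data.frame with trimmed `bases` and `quals`.
#' @export
trim_low_quality_3prime <- function(reads, params = qc_params()) {
  keep_len <- vapply(reads$quals, function(s) {
    q <- string_to_phred(s)
    good <- which(q >= params$trim_qual)
    if (length(good) == 0L) 0L else good[length(good)]
  }, 0L, USE.NAMES = FALSE)
  reads$bases <- substr(reads$bases, 1L, keep_len)
  reads$quals <- substr(reads$quals, 1L, keep_len)
  reads
}

#' Retention filter: length and base-quality fraction
#'
#' A trimmed read is retained iff its length is strictly greater than
#' `params$keep_min_len` and strictly more than `params$frac_min` of its
#' bases have Phred score strictly greater than `params$frac_qual`.
#' Zero-length reads are dropped without division.
#'
#' @inheritParams trim_adapter
#' @return logical vector, `TRUE` = keep.
#' @export
qc_retain <- function(reads, params = qc_params()) {
  L <- nchar(reads$bases)
  frac <- vapply(reads$quals, function(s) {
    q <- string_to_phred(s)
    if (length(q) == 0L) 0 else mean(q > params$frac_qual)
  }, 0, USE.NAMES = FALSE)
  L > params$keep_min_len & frac > params$frac_min
}

#' Mapping-length filter
#'
#' Keeps reads strictly longer than `params$map_min_len` nt for alignment.
#'
#' @inheritParams trim_adapter
#' @return logical vector, `TRUE` = keep.
#' @export
qc_mappable <- function(reads, params = qc_params()) {
  nchar(reads$bases) > params$map_min_len
}

#' Run the complete read-QC pipeline
#'
#' Fixed order: adapter removal, 3' quality trimming, the length/quality
#' retention filter, then the mapping-length filter. Each trimming step is
#' idempotent and every output read is a prefix of its input read.
#'
#' @inheritParams trim_adapter
#' @return list with `reads` (surviving, trimmed reads data.frame) and
#'   `report` (data.frame of read counts entering/dropped at each step).
#' @export
qc_pipeline <- function(reads, params = qc_params()) {
  n0 <- nrow(reads)
  reads <- trim_adapter(reads, params)
  reads <- trim_low_quality_3prime(reads, params)
  keep <- qc_retain(reads, params)
  n_retained <- sum(keep)
  reads <- reads[keep, , drop = FALSE]
  mp <- qc_mappable(reads, params)
  reads <- reads[mp, , drop = FALSE]
  report <- data.frame(
    step = c("input", "retained", "mappable"),
    n = c(n0, n_retained, nrow(reads)),
    dropped = c(0L, n0 - n_retained, n_retained - nrow(reads)))
  rownames(reads) <- NULL
  list(reads = reads, report = report)
}
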