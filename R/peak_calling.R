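#' Sliding-window read counts along transcripts
#'
#' Tiles every transcript with windows of `window` nt advancing by `step`
#' nt (transcripts shorter than `window` get a single full-length window).
#' A read contributes to every window containing its midpoint
#' (`floor((start + end) / 2)`).
#'
#' @param reads reads data.frame (`transcript_id`, `start`, `end`,
#'   transcript space, 0-based half-open).
#' @param annotation one-transcript-per-gene annotation.
#' @param window window width, nt.
#' @param step window step, nt (must not exceed `window`).
#' @return data.frame with `transcript_id`, `start`, `end`, `count`.
#' @export
count_windows <- function(reads, annotation, window = 100L, step = 50L) {
  window <- as.integer(window); step <- as.integer(step)
  if (window < step) stop("window must be >= step")
  mids <- split((reads$start + reads$end) %/% 2L, reads$transcript_id)
  res <- lapply(seq_len(nrow(annotation)), function(i) {
    L <- annotation$length[i]
    tx <- annotation$transcript_id[i]
    if (L <= window) {
      starts <- 0L; ends <- L
    } else {
      starts <- seq(0L, L - window, by = step)
      ends <- starts + window
    }
    m <- mids[[tx]]
    cnt <- if (is.null(m)) integer(length(starts)) else
      IRanges::countOverlaps(IRanges::IRanges(starts + 1L, ends),
                             IRanges::IRanges(m + 1L, m + 1L))
    data.frame(transcript_id = tx, start = starts, end = ends,
               count = as.integer(cnt), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' One-sided exact enrichment test for IP vs input window counts
#'
#' Fold enrichment uses a +0.5 pseudocount on each library-size-normalised
#' count: `((ip + 0.5) / ip_total) / ((input + 0.5) / input_total)`. The
#' p-value is the one-sided Fisher exact probability of at-least-observed
#' IP enrichment from the 2x2 table `[ip, ip_total - ip; input,
#' input_total - input]`, computed as the hypergeometric upper tail.
#' Vectorised over windows.
#'
#' @param ip,input window counts in the IP and input libraries.
#' @param ip_total,input_total library sizes (total counted fragments).
#' @return data.frame with `fold_enrichment`, `log2_fe`, `p_value`.
#' @export
test_window <- function(ip, input, ip_total, input_total) {
  if (any(c(ip_total, input_total) <= 0)) stop("library sizes must be > 0")
  fe <- ((ip + 0.5) / ip_total) / ((input + 0.5) / input_total)
  p <- phyper(ip - 1, ip_total, input_total, ip + input, lower.tail = FALSE)
  data.frame(fold_enrichment = fe, log2_fe = log2(fe), p_value = p)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment: `q_i = min_{j >= i} (m * p_(j) / j)`, capped at
#' 1, mapped back to the input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Merge significant windows into peaks
#'
#' Overlapping or book-ended significant windows on one transcript merge
#' into a single peak. The peak q-value is the minimum window q; the peak
#' fold enrichment is recomputed from the summed window counts over the
#' merged span (with the per-window +0.5 pseudocounts carried through, so
#' a merged peak's fold enrichment always lies between the minimum and
#' maximum of its windows').
#'
#' @param windows data.frame with `transcript_id`, `start`, `end`,
#'   `ip_count`, `input_count`, `q_value` — significant windows only.
#' @param ip_total,input_total library sizes.
#' @return peaks data.frame: `transcript_id`, `start`, `end`, `ip_count`,
#'   `input_count`, `fold_enrichment`, `log2_fe`, `q_value`.
#' @export
merge_significant <- function(windows, ip_total, input_total) {
  empty <- data.frame(transcript_id = character(0), start = integer(0),
                      end = integer(0), ip_count = integer(0),
                      input_count = integer(0), fold_enrichment = numeric(0),
                      log2_fe = numeric(0), q_value = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(windows) == 0L) return(empty)
  windows <- windows[order(windows$transcript_id, windows$start), ]
  res <- lapply(split(windows, windows$transcript_id), function(w) {
    grp <- cumsum(c(1L, as.integer(w$start[-1] > cummax(w$end[-nrow(w)]))))
    agg <- lapply(split(seq_len(nrow(w)), grp), function(ii) {
      n <- length(ii)
      sip <- sum(w$ip_count[ii]); sin <- sum(w$input_count[ii])
      fe <- ((sip + 0.5 * n) / ip_total) / ((sin + 0.5 * n) / input_total)
      data.frame(transcript_id = w$transcript_id[ii[1]],
                 start = min(w$start[ii]), end = max(w$end[ii]),
                 ip_count = sip, input_count = sin,
                 fold_enrichment = fe, log2_fe = log2(fe),
                 q_value = min(w$q_value[ii]), stringsAsFactors = FALSE)
    })
    do.call(rbind, agg)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$transcript_id, out$start), ]
}

#' Call m6A peaks from IP and input reads for one sample
#'
#' Counts sliding windows in both libraries, tests each window for IP
#' enrichment ([test_window()]), adjusts p-values by Benjamini-Hochberg
#' across all windows of the sample, and merges windows with `q < fdr`
#' into peaks ([merge_significant()]).
#'
#' @param ip_reads,input_reads reads data.frames for the IP and input
#'   libraries of one sample.
#' @param annotation one-transcript-per-gene annotation.
#' @param window,step windowing parameters, nt.
#' @param fdr q-value cutoff (default 0.05, i.e. FDR < 5%).
#' @return list with `peaks` (merged significant peaks) and `windows`
#'   (all tested windows with counts, fold enrichment, p and q values).
#' @export
call_peaks <- function(ip_reads, input_reads, annotation,
                       window = 100L, step = 50L, fdr = 0.05) {
  wip <- count_windows(ip_reads, annotation, window, step)
  win <- count_windows(input_reads, annotation, window, step)
  stopifnot(nrow(wip) == nrow(win))
  ip_total <- nrow(ip_reads)
  input_total <- nrow(input_reads)
  tst <- test_window(wip$count, win$count, ip_total, input_total)
  windows <- data.frame(transcript_id = wip$transcript_id,
                        start = wip$start, end = wip$end,
                        ip_count = wip$count, input_count = win$count,
                        tst, q_value = bh_fdr(tst$p_value),
                        stringsAsFactors = FALSE)
  sig <- windows[windows$q_value < fdr, , drop = FALSE]
  peaks <- merge_significant(sig, ip_total, input_total)
  list(peaks = peaks, windows = windows,
       ip_total = ip_total, input_total = input_total)
}

#' Evaluate called peaks against a ground-truth peak set
#'
#' Sensitivity is the fraction of truth peaks (active in the queried
#' tissue) overlapped by at least one called peak; the empirical false
#' discovery rate is the fraction of called peaks overlapping no truth
#' peak. Overlap means >= 1 nt on the same transcript.
#'
#' @param peaks called peaks data.frame.
#' @param truth truth peaks data.frame (from [sim_plant_truth()]).
#' @param tissue `"A"` or `"B"`; truth peaks whose `tissues` field
#'   contains this tissue are the positives.
#' @return list with `sensitivity`, `fdr`, `n_truth`, `n_called`.
#' @export
peak_recovery <- function(peaks, truth, tissue = "A") {
  act <- truth[grepl(tissue, truth$tissues), , drop = FALSE]
  hit_truth <- logical(nrow(act))
  hit_peak <- logical(nrow(peaks))
  for (tx in unique(act$transcript_id)) {
    ti <- which(act$transcript_id == tx)
    pi <- which(peaks$transcript_id == tx)
    if (length(pi) == 0L) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(act$start[ti] + 1L, act$end[ti]),
      IRanges::IRanges(peaks$start[pi] + 1L, peaks$end[pi]))
    hit_truth[ti[unique(S4Vectors::queryHits(ov))]] <- TRUE
    hit_peak[pi[unique(S4Vectors::subjectHits(ov))]] <- TRUE
  }
  list(sensitivity = if (nrow(act)) mean(hit_truth) else NA_real_,
       fdr = if (nrow(peaks)) mean(!hit_peak) else NA_real_,
       n_truth = nrow(act), n_called = nrow(peaks))
}
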