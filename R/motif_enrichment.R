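#' Extract peak sequences from transcript sequences
#'
#' @param peaks peaks data.frame (`transcript_id`, `start`, `end`,
#'   0-based half-open).
#' @param sequences named character vector of transcript sequences.
#' @param flank extra nt taken on each side (clipped at transcript ends).
#' @return character vector of peak subsequences.
#' @export
extract_peak_sequences <- function(peaks, sequences, flank = 0L) {
  out <- character(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    tx <- peaks$transcript_id[i]
    if (!tx %in% names(sequences)) stop("unknown transcript: ", tx)
    s <- sequences[[tx]]
    L <- nchar(s)
    if (peaks$start[i] < 0L || peaks$end[i] > L ||
        peaks$end[i] <= peaks$start[i])
      stop("peak out of sequence bounds on ", peaks$transcript_id[i])
    out[i] <- substr(s, max(1L, peaks$start[i] + 1L - flank),
                     min(L, peaks$end[i] + flank))
  }
  out
}

#' Sample background windows matched to peaks
#'
#' For each peak, a window of the same length is drawn uniformly from the
#' non-peak portion of the same transcript (never overlapping any peak on
#' it). Peaks whose transcript has no room for a disjoint window are
#' skipped.
#'
#' @param peaks peaks data.frame.
#' @param sequences named character vector of transcript sequences.
#' @param seed integer seed.
#' @return data.frame of background windows (`transcript_id`, `start`,
#'   `end`).
#' @export
sample_background <- function(peaks, sequences, seed = 1L) {
  set.seed(seed)
  res <- list()
  for (i in seq_len(nrow(peaks))) {
    tx <- peaks$transcript_id[i]
    w <- peaks$end[i] - peaks$start[i]
    L <- nchar(sequences[[tx]])
    on_tx <- peaks[peaks$transcript_id == tx, , drop = FALSE]
    cand <- seq(0L, L - w)
    # a candidate start s is valid iff [s, s+w) misses every peak
    for (j in seq_len(nrow(on_tx)))
      cand <- cand[cand + w <= on_tx$start[j] | cand >= on_tx$end[j]]
    if (length(cand) == 0L) next
    s <- cand[sample.int(length(cand), 1L)]
    res[[length(res) + 1L]] <- data.frame(transcript_id = tx, start = s,
                                          end = s + w,
                                          stringsAsFactors = FALSE)
  }
  if (length(res) == 0L)
    return(data.frame(transcript_id = character(0), start = integer(0),
                      end = integer(0)))
  do.call(rbind, res)
}

#' k-mer enrichment in peak sequences versus background
#'
#' Counts overlapping occurrences of every k-mer in the peak and
#' background sequence sets, scores enrichment with +0.5 pseudocounts on
#' both frequencies, and tests each k-mer with a one-sided binomial test
#' (null success rate = the k-mer's pseudocounted background frequency;
#' trials = total k-mer positions in the peak set). P-values are
#' Benjamini-Hochberg adjusted; the table is ranked by q, then by
#' decreasing enrichment, then alphabetically. Reverse complements are
#' not collapsed: RNA methylation is strand-specific.
#'
#' @param peak_seqs,background_seqs character vectors of ACGT sequences;
#'   background must be non-empty.
#' @param k k-mer length (default 5, the GGACU consensus length).
#' @return data.frame ranked best-first: `kmer`, `peak_count`,
#'   `background_count`, `enrichment`, `p_value`, `q_value`.
#' @export
kmer_enrichment <- function(peak_seqs, background_seqs, k = 5L) {
  k <- as.integer(k)
  if (length(background_seqs) == 0L) stop("background must be non-empty")
  if (all(nchar(peak_seqs) < k) || all(nchar(background_seqs) < k))
    stop("k exceeds every sequence length")
  count_set <- function(seqs) {
    seqs <- seqs[nchar(seqs) >= k]
    m <- Biostrings::oligonucleotideFrequency(
      Biostrings::DNAStringSet(seqs), width = k)
    colSums(m)
  }
  pc <- count_set(peak_seqs)
  bc <- count_set(background_seqs)
  p_tot <- sum(pc)
  b_tot <- sum(bc)
  rate <- (bc + 0.5) / (b_tot + 0.5)
  enrichment <- ((pc + 0.5) / p_tot) / ((bc + 0.5) / b_tot)
  p <- pbinom(pc - 1, p_tot, rate, lower.tail = FALSE)
  q <- bh_fdr(p)
  out <- data.frame(kmer = names(pc), peak_count = as.integer(pc),
                    background_count = as.integer(bc),
                    enrichment = enrichment, p_value = as.numeric(p),
                    q_value = q, stringsAsFactors = FALSE)
  out <- out[order(out$q_value, -out$enrichment, out$kmer), ]
  rownames(out) <- NULL
  out
}
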