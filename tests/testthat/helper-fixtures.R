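# shared fixture builders; everything is generated in code

# a small but non-trivial simulated dataset reused across files
small_sim_config <- function(seed = 7L, ...) {
  sim_config(n_genes = 60L, n_common_peaks = 25L, n_specA_peaks = 5L,
             n_specB_peaks = 5L, seed = seed, ...)
}

# reads data.frame (QC representation) from explicit bases/quality vectors
make_reads <- function(bases, quals = NULL) {
  if (is.null(quals))
    quals <- vapply(nchar(bases), function(L) phred_to_string(rep(38L, L)), "")
  if (is.numeric(quals)) quals <- phred_to_string(quals)
  data.frame(id = sprintf("r%03d", seq_along(bases)),
             bases = bases, quals = quals, stringsAsFactors = FALSE)
}

# one-row coding annotation from UTR/CDS/UTR lengths
coding_tx <- function(u, c, w, gene_id = "g1", transcript_id = "t1") {
  data.frame(gene_id = gene_id, transcript_id = transcript_id,
             biotype = "coding", length = u + c + w,
             utr5_len = u, cds_len = c, utr3_len = w,
             stringsAsFactors = FALSE)
}

# peaks data.frame from parallel vectors
make_peaks <- function(transcript_id, start, end, log2_fe = 0, q_value = 0.01) {
  data.frame(transcript_id = transcript_id, start = as.integer(start),
             end = as.integer(end),
             log2_fe = rep_len(log2_fe, length(start)),
             fold_enrichment = 2^rep_len(log2_fe, length(start)),
             q_value = rep_len(q_value, length(start)),
             stringsAsFactors = FALSE)
}

# ---- independent oracles ----------------------------------------------

# leftmost full-window adapter hit by brute-force character comparison
oracle_adapter_pos <- function(bases, adapter, max_mm) {
  b <- strsplit(bases, "")[[1]]
  a <- strsplit(adapter, "")[[1]]
  k <- length(a)
  if (length(b) < k) return(NA_integer_)
  for (p in seq_len(length(b) - k + 1)) {
    if (sum(b[p:(p + k - 1)] != a) <= max_mm) return(p)
  }
  NA_integer_
}

# BH step-up q-values: q_(i) = min_{j>=i} m p_(j) / j, capped at 1
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  run_min <- Inf
  for (i in m:1) {
    run_min <- min(run_min, m * p[o[i]] / i)
    q_sorted[i] <- min(1, run_min)
  }
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# one-sided Fisher p for table [ip, ip_tot - ip; input, input_tot - input]
# by direct log-binomial-coefficient tail summation
oracle_fisher_p <- function(ip, input, ip_tot, input_tot) {
  k <- ip + input
  jmax <- min(k, ip_tot)
  j <- ip:jmax
  logs <- lchoose(ip_tot, j) + lchoose(input_tot, k - j) -
    lchoose(ip_tot + input_tot, k)
  sum(exp(logs))
}

# exact two-sided rank-sum p by enumeration of all group assignments
oracle_wilcoxon_p <- function(x, y) {
  vals <- c(x, y)
  stopifnot(!anyDuplicated(vals))
  r <- rank(vals)
  n1 <- length(x)
  obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  all_u <- apply(utils::combn(length(vals), n1), 2, function(ii)
    sum(r[ii]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(y) / 2
  mean(abs(all_u - mu) >= abs(obs - mu))
}

# Spearman rho by the closed-form rank-difference formula (distinct values)
oracle_spearman <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# position-wise painter for the five-region segmentation: returns one
# label per nt, built by painting base regions then codon regions
oracle_region_paint <- function(u, cl, w) {
  len <- u + cl + w
  lab <- rep("CDS", len)
  if (u > 0) lab[1:u] <- "FIVE_UTR"
  if (w > 0) lab[(u + cl + 1):len] <- "THREE_UTR"
  paint <- function(lab, from0, to0, value) {
    if (to0 > from0) lab[(from0 + 1):to0] <- value
    lab
  }
  if (cl <= 200) {
    half <- cl %/% 2
    lab <- paint(lab, u, u + half, "START")
    lab <- paint(lab, u + half, u + cl, "STOP")
    if (u <= 100) lab <- paint(lab, 0, u, "START")
    if (w <= 100) lab <- paint(lab, u + cl, len, "STOP")
  } else {
    if (u > 100) lab <- paint(lab, u - 100, u + 100, "START")
    else lab <- paint(lab, 0, u + 100, "START")
    if (w > 100) lab <- paint(lab, u + cl - 100, u + cl + 100, "STOP")
    else lab <- paint(lab, u + cl - 100, len, "STOP")
  }
  lab
}

# peak label by priority over the painted per-nt labels
oracle_assign_region <- function(peak_start, peak_end, u, cl, w) {
  lab <- oracle_region_paint(u, cl, w)
  covered <- unique(lab[(peak_start + 1):peak_end])
  pri <- c("STOP", "START", "CDS", "THREE_UTR", "FIVE_UTR")
  pri[min(match(covered, pri))]
}

# one-sided binomial upper tail by direct density summation
oracle_binom_tail <- function(x, n, rate) {
  sum(vapply(x:n, function(j)
    choose(n, j) * rate^j * (1 - rate)^(n - j), 0))
}
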