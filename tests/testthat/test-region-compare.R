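test_that("replicate concordance applies the strict >50%-of-shorter rule", {
  # overlap 50 is exactly 50% of the shorter peak: not concordant
  p1 <- make_peaks("t1", 100, 200)
  p2 <- make_peaks("t1", 150, 300)
  expect_equal(nrow(concordant_peaks(p1, p2)), 0L)
  # overlap 80 of shorter length 90: concordant, union [100, 210)
  p2 <- make_peaks("t1", 120, 210)
  cc <- concordant_peaks(p1, p2)
  expect_equal(nrow(cc), 1L)
  expect_equal(c(cc$start, cc$end), c(100L, 210L))
  # identical peaks are concordant with themselves
  cc <- concordant_peaks(p1, p1)
  expect_equal(c(cc$start, cc$end), c(100L, 200L))
  # union log2 fe is the replicate mean
  p1$log2_fe <- 2; p2$log2_fe <- 4
  cc <- concordant_peaks(p1, p2)
  expect_equal(cc$log2_fe, 3)
})

test_that("concordance is symmetric in replicate order and one-to-one", {
  set.seed(53)
  mk <- function() {
    tx <- sample(paste0("t", 1:5), 15, replace = TRUE)
    s <- sample(0:900, 15)
    make_peaks(tx, s, s + sample(c(80, 100, 150), 15, replace = TRUE),
               log2_fe = runif(15, 1, 4))
  }
  for (i in 1:10) {
    a <- mk(); b <- mk()
    ab <- concordant_peaks(a, b)
    ba <- concordant_peaks(b, a)
    key <- function(x) sort(paste(x$transcript_id, x$start, x$end, x$log2_fe))
    expect_equal(key(ab), key(ba))
    # one-to-one: no more concordant peaks than either replicate has
    expect_lte(nrow(ab), min(nrow(a), nrow(b)))
  }
})

# enumeration of all 16 replicate-presence patterns for one peak position;
# expected labels hand-derived from the common/specific criteria:
# common   <=> present in both replicates of both tissues
# specific <=> present in both replicates of one tissue, absent from both
#              replicates of the other
# ambiguous : concordant in one tissue, present in exactly one replicate
#             of the other
# (none)   : not concordant in either tissue
test_that("common/specific labels match the exhaustive presence truth table", {
  peak <- function(present) if (present) make_peaks("t1", 100, 200,
                                                    log2_fe = 2)
  else make_peaks(character(0), integer(0), integer(0))
  for (a1 in 0:1) for (a2 in 0:1) for (b1 in 0:1) for (b2 in 0:1) {
    raw_a <- list(peak(a1 == 1), peak(a2 == 1))
    raw_b <- list(peak(b1 == 1), peak(b2 == 1))
    conc_a <- concordant_peaks(raw_a[[1]], raw_a[[2]])
    conc_b <- concordant_peaks(raw_b[[1]], raw_b[[2]])
    cls <- classify_peaks(conc_a, conc_b, raw_a, raw_b)
    in_a <- a1 & a2
    in_b <- b1 & b2
    expected <- if (in_a && in_b) c("common", "common")
    else if (in_a && !b1 && !b2) "specific_A"
    else if (in_b && !a1 && !a2) "specific_B"
    else if (in_a || in_b) "ambiguous"
    else character(0)
    expect_equal(sort(cls$label), sort(expected),
                 info = sprintf("pattern %d%d%d%d", a1, a2, b1, b2))
    # labels are exhaustive: every concordant peak gets exactly one label
    expect_equal(nrow(cls), nrow(conc_a) + nrow(conc_b))
    expect_true(all(cls$label %in% c("common", "specific_A", "specific_B",
                                     "ambiguous")))
  }
})

test_that("gene classification follows CMR precedence", {
  ann <- rbind(coding_tx(100, 600, 300, "g1", "t1"),
               coding_tx(100, 600, 300, "g2", "t2"),
               coding_tx(100, 600, 300, "g3", "t3"))
  cp <- data.frame(
    transcript_id = c("t1", "t1", "t1", "t2", "t3", "t3"),
    start = c(100L, 100L, 400L, 150L, 100L, 500L),
    end = c(200L, 200L, 500L, 250L, 200L, 600L),
    log2_fe = c(2, 2, 3, 1.5, 2, 2.5),
    tissue = c("A", "B", "A", "B", "A", "B"),
    label = c("common", "common", "specific_A", "specific_B",
              "specific_A", "specific_B"),
    stringsAsFactors = FALSE)
  gm <- classify_genes(cp, ann)
  # common peak wins over the additional specific peak
  expect_equal(gm$class[gm$gene_id == "g1"], "CMR")
  expect_equal(gm$class[gm$gene_id == "g2"], "SMR_B")
  # specific peaks of both tissues, no common: mixed
  expect_equal(gm$class[gm$gene_id == "g3"], "mixed")
  expect_equal(gm$gene_log2_fe[gm$gene_id == "g1"], mean(c(2, 2, 3)))
  expect_true(gm$methylated_A[gm$gene_id == "g1"])
  expect_false(gm$methylated_A[gm$gene_id == "g2"])
})

test_that("peak-less genes are unmethylated", {
  ann <- rbind(coding_tx(100, 600, 300, "g1", "t1"),
               coding_tx(100, 600, 300, "g2", "t2"))
  cp <- data.frame(transcript_id = "t1", start = 100L, end = 200L,
                   log2_fe = 2, tissue = "A", label = "specific_A",
                   stringsAsFactors = FALSE)
  gm <- classify_genes(cp, ann)
  expect_equal(gm$class[gm$gene_id == "g2"], "unmethylated")
  expect_equal(gm$n_peaks[gm$gene_id == "g2"], 0)
})

test_that("compare_levels recovers medians, shifts, and exact small-n p", {
  x <- rnorm(100)
  same <- compare_levels(x, x)
  expect_equal(same$median1, same$median2)
  expect_gt(same$p_value, 0.9)
  set.seed(59)
  x <- rnorm(100)
  shifted <- compare_levels(x + 1, x)
  expect_equal(shifted$median1 - shifted$median2, 1)
  expect_lt(shifted$p_value, 0.01)
  # n = 3 vs 3: exact enumeration oracle
  a <- c(1.1, 2.3, 9.7); b <- c(0.2, 5.1, 6.4)
  expect_equal(compare_levels(a, b)$p_value, oracle_wilcoxon_p(a, b))
  a <- c(10, 11, 12); b <- c(1, 2, 3)
  expect_equal(compare_levels(a, b)$p_value, oracle_wilcoxon_p(a, b))
  expect_error(compare_levels(numeric(0), x), "non-empty")
})

test_that("subsampling control draws are sized, nested, and reproducible", {
  set.seed(61)
  cmr <- rnorm(200, mean = 2)
  smr <- rnorm(40, mean = 2)
  r1 <- subsample_control(cmr, smr, draws = 10, seed = 5)
  r2 <- subsample_control(cmr, smr, draws = 10, seed = 5)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 10L)
  # same-distribution null: median differences hover near zero
  expect_lt(max(abs(r1$median_cmr - r1$median_smr)), 1)
  expect_error(subsample_control(smr, cmr), "at least as large")
})

test_that("expression-methylation relationships recover planted structure", {
  ann <- do.call(rbind, lapply(1:30, function(i)
    coding_tx(100, 600, 300, sprintf("g%02d", i), sprintf("t%02d", i))))
  expr <- data.frame(gene_id = ann$gene_id, fragment_count = 100L,
                     fpkm = exp(seq(0, 3, length.out = 30)),
                     expressed = TRUE, stringsAsFactors = FALSE)
  # methylated genes: the first 20; fpkm strictly decreasing in gene fe
  gm <- data.frame(gene_id = ann$gene_id,
                   gene_log2_fe = c(seq(5, 2, length.out = 20), rep(NA, 10)),
                   class = rep(c("CMR", "unmethylated"), c(20, 10)),
                   stringsAsFactors = FALSE)
  res <- expression_vs_methylation(expr, gm)
  expect_equal(res$spearman_rho, -1)
  expect_equal(res$n_methylated, 20L)
  # rho equals the closed-form rank oracle on arbitrary data
  set.seed(67)
  gm$gene_log2_fe[1:20] <- rnorm(20)
  res <- expression_vs_methylation(expr, gm)
  expect_equal(res$spearman_rho,
               oracle_spearman(expr$fpkm[1:20], gm$gene_log2_fe[1:20]))
  gm$class <- c("CMR", "CMR", rep("unmethylated", 28))
  expect_error(expression_vs_methylation(expr, gm), "fewer than 3")
})
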