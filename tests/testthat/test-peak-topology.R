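as_seg <- function(seg) {
  setNames(lapply(seq_len(nrow(seg)), function(i)
    c(seg$start[i], seg$end[i])), seg$region)
}

test_that("segmentation handles long, short-UTR and short-CDS transcripts", {
  # long everything: centred 200-nt codon windows
  s <- as_seg(segment_transcript(coding_tx(300, 900, 500)))
  expect_equal(s$FIVE_UTR, c(0L, 200L))
  expect_equal(s$START, c(200L, 400L))
  expect_equal(s$CDS, c(400L, 1100L))
  expect_equal(s$STOP, c(1100L, 1300L))
  expect_equal(s$THREE_UTR, c(1300L, 1700L))
  # short 5'UTR: whole UTR plus 100 nt of CDS form the start region
  s <- as_seg(segment_transcript(coding_tx(60, 900, 500)))
  expect_equal(s$FIVE_UTR, c(0L, 0L))
  expect_equal(s$START, c(0L, 160L))
  # short CDS: halves split between start and stop, UTR extensions off
  s <- as_seg(segment_transcript(coding_tx(300, 150, 400)))
  expect_equal(s$FIVE_UTR, c(0L, 300L))
  expect_equal(s$START, c(300L, 375L))
  expect_equal(s$STOP, c(375L, 450L))
  expect_equal(s$CDS[1], s$CDS[2])  # CDS absorbed
  expect_equal(s$THREE_UTR, c(450L, 850L))
  # short CDS with short UTRs: UTRs join the codon regions
  s <- as_seg(segment_transcript(coding_tx(80, 150, 90)))
  expect_equal(s$START, c(0L, 155L))
  expect_equal(s$STOP, c(155L, 320L))
  # boundary values 100/200 fall under the short rules (strict wording)
  s <- as_seg(segment_transcript(coding_tx(100, 201, 500)))
  expect_equal(s$START, c(0L, 200L))
  s <- as_seg(segment_transcript(coding_tx(300, 200, 500)))
  expect_equal(s$START, c(300L, 400L))
  expect_error(segment_transcript(list(biotype = "lncRNA")), "coding")
})

test_that("segmentation is a disjoint cover and matches the painter oracle", {
  set.seed(71)
  grid <- expand.grid(u = c(30, 100, 101, 250), c = c(60, 200, 201, 900),
                      w = c(20, 100, 101, 400))
  extra <- data.frame(u = sample(20:400, 60, TRUE),
                      c = sample(30:1200, 60, TRUE),
                      w = sample(20:500, 60, TRUE))
  for (i in seq_len(nrow(grid) + nrow(extra))) {
    g <- if (i <= nrow(grid)) grid[i, ] else extra[i - nrow(grid), ]
    seg <- segment_transcript(coding_tx(g$u, g$c, g$w))
    len <- g$u + g$c + g$w
    # disjoint cover of [0, len) in 5'->3' order
    expect_true(all(seg$end >= seg$start))
    expect_equal(seg$start[1], 0L)
    expect_equal(seg$end[nrow(seg)], len)
    expect_equal(seg$start[-1], seg$end[-nrow(seg)])
    # position-wise agreement with the independent painter
    painted <- oracle_region_paint(g$u, g$c, g$w)
    from_seg <- rep(seg$region, seg$end - seg$start)
    expect_equal(from_seg, painted,
                 info = sprintf("u=%d c=%d w=%d", g$u, g$c, g$w))
  }
})

test_that("region assignment follows the stop>start>CDS>3'UTR>5'UTR priority", {
  seg <- segment_transcript(coding_tx(300, 900, 500))
  expect_equal(assign_region(1150, 1250, seg), "STOP")
  # spanning START, CDS and STOP: STOP wins
  expect_equal(assign_region(350, 1150, seg), "STOP")
  expect_equal(assign_region(50, 150, seg), "FIVE_UTR")
  expect_equal(assign_region(250, 350, seg), "START")
  expect_equal(assign_region(500, 600, seg), "CDS")
  expect_equal(assign_region(1400, 1500, seg), "THREE_UTR")
  # spanning 5'UTR and START: START wins
  expect_equal(assign_region(150, 250, seg), "START")
  expect_error(assign_region(1600, 1750, seg), "outside")
})

test_that("region assignment matches the painted-position oracle on random draws", {
  set.seed(73)
  for (i in 1:300) {
    u <- sample(c(20:150, 250:350), 1)
    cl <- sample(c(60:250, 600:900), 1)
    w <- sample(c(20:150, 250:400), 1)
    len <- u + cl + w
    s <- sample(0:(len - 30), 1)
    e <- min(len, s + sample(c(30, 100, 300), 1))
    seg <- segment_transcript(coding_tx(u, cl, w))
    expect_equal(assign_region(s, e, seg),
                 oracle_assign_region(s, e, u, cl, w),
                 info = sprintf("u=%d c=%d w=%d peak=[%d,%d)", u, cl, w, s, e))
  }
})

test_that("metagene profiles normalise to 100% with midpoint binning", {
  # one peak with midpoint at 50% of the CDS lands in CDS bin 49 (bin 149)
  ann <- coding_tx(100, 300, 200)
  pk <- make_peaks("t1", 200, 300)  # midpoint 250 = CDS position 150/300
  prof <- metagene_profile(pk, ann)
  expect_length(prof, 300L)
  expect_equal(prof[150], 100)  # 1-based index of bin 149
  expect_equal(sum(prof), 100)
  # two peaks in the same bin: that bin holds 100%
  pk2 <- make_peaks(c("t1", "t1"), c(200, 202), c(300, 298))
  prof <- metagene_profile(pk2, ann)
  expect_equal(sum(prof > 0), 1L)
  expect_equal(sum(prof), 100)
  # lncRNA transcripts use a single 100-bin profile
  lnc <- data.frame(gene_id = "gl", transcript_id = "tl", biotype = "lncRNA",
                    length = 1000L, utr5_len = NA_integer_,
                    cds_len = NA_integer_, utr3_len = NA_integer_,
                    stringsAsFactors = FALSE)
  prof <- metagene_profile(make_peaks("tl", 480, 520), lnc,
                           biotype = "lncRNA")
  expect_length(prof, 100L)
  expect_equal(prof[50], 100)  # midpoint 500 of 1000: bin 49
  expect_equal(sum(prof), 100)
})

test_that("uniform midpoints give a flat mRNA metagene profile", {
  ann <- coding_tx(300, 900, 300)
  set.seed(79)
  n <- 12000
  mids <- sample(0:1499, n, replace = TRUE)
  pk <- make_peaks(rep("t1", n), mids, mids + 1)
  # uniform positions weighted by segment length: rescale each segment's
  # peaks to per-bin expectation and check 3-SE flatness per segment
  prof <- metagene_profile(pk, ann)
  expect_equal(sum(prof), 100, tolerance = 1e-9)
  for (seg in list(c(1, 100, 300), c(101, 200, 900), c(201, 300, 300))) {
    bins <- prof[seg[1]:seg[2]]
    p_bin <- (seg[3] / 100) / 1500
    se <- sqrt(p_bin * (1 - p_bin) / n) * 100
    expect_true(all(abs(bins - 100 * p_bin) < 4 * se))
  }
})

test_that("region counts conserve totals and respect construction", {
  ann <- coding_tx(300, 900, 500)
  seg <- segment_transcript(ann)
  stop_peaks <- make_peaks(rep("t1", 5), seq(1120, 1200, by = 20),
                           seq(1220, 1300, by = 20))
  assigned <- assign_regions(stop_peaks, ann)
  expect_true(all(assigned$region == "STOP"))
  rc <- region_counts(assigned)
  expect_equal(sum(rc$count), 5)
  expect_equal(rc$pct[rc$region == "STOP"], 100)
  # empty set: all-zero table
  rc0 <- region_counts(assign_regions(make_peaks(character(0), integer(0),
                                                 integer(0)), ann))
  expect_true(all(rc0$count == 0))
})

test_that("5'UTR length filter is strict at the threshold", {
  ann <- rbind(coding_tx(200, 600, 300, "g1", "t1"),
               coding_tx(50, 600, 300, "g2", "t2"),
               coding_tx(150, 600, 300, "g3", "t3"),
               coding_tx(100, 600, 300, "g4", "t4"))
  expect_equal(utr5_filter(c("g1", "g1"), ann), 1.0)
  expect_equal(utr5_filter(c("g2", "g3"), ann), 0.5)
  expect_equal(utr5_filter("g4", ann), 0)  # exactly 100 nt: excluded
  expect_error(utr5_filter(character(0), ann), "non-empty")
})
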