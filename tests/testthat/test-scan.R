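test_that("log-odds are zero at background and 2 bits for conserved bases", {
  m <- motif("m", matrix(c(1, 1, 1, 1), 4, 3))      # uniform columns
  p <- build_pssm(m, rep(0.25, 4), pseudocount = 0)
  expect_equal(unname(p$log_odds), matrix(0, 4, 3))
  mc <- consensus_motif("c", "AAA")
  pc <- build_pssm(mc, rep(0.25, 4), pseudocount = 0)
  expect_equal(unname(pc$log_odds["A", ]), rep(2, 3))
  expect_true(all(is.finite(build_pssm(mc, rep(0.25, 4), 0.01)$log_odds)))
  expect_error(build_pssm(mc, c(0, 0.5, 0.25, 0.25)), "positive")
})

test_that("planted consensus and its reverse complement are found at the same start", {
  cons <- "ACGTTGCA"
  m <- consensus_motif("m", cons)
  set.seed(21)
  base <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  p <- build_pssm(m, rep(0.25, 4))
  p$threshold <- 15   # only a full match scores ~15.96
  k <- 700            # 0-based sense offset
  fwd <- scan_region(p, plant_at(base, cons, k), tss_offset = 1500)
  expect_true(any(fwd$start == k - 1500 & fwd$strand == "+"))
  rev <- scan_region(p, plant_at(base, rc(cons), k), tss_offset = 1500)
  expect_true(any(rev$start == k - 1500 & rev$strand == "-"))
  # region shorter than the motif scans to nothing
  expect_equal(nrow(scan_region(p, "ACGT", tss_offset = 0)), 0L)
  # N-containing windows are skipped silently
  withN <- plant_at(base, "NNNNNNNN", 100)
  expect_silent(scan_region(p, withN, tss_offset = 1500))
})

test_that("hit sets mirror under reverse complementation of the region", {
  m <- random_motif("m", 8, conservation = 0.9, seed = 2)
  bg <- random_regions(50, 2000, seed = 3)
  p <- calibrate_threshold(build_pssm(m, estimate_background(bg)), bg,
                           target_rate = 1 / 500)
  flip <- c(`+` = "-", `-` = "+")
  for (s in 1:10) {
    reg <- random_regions(1, 2000, seed = 100 + s)
    h <- scan_region(p, reg, tss_offset = 0)
    hr <- scan_region(p, rc(reg), tss_offset = 0)
    # start i on the sense strand maps to 2000 - 8 - i on the mirror
    mapped <- data.frame(start = 2000L - 8L - hr$start,
                         strand = unname(flip[hr$strand]),
                         score = hr$score)
    expect_equal(h[order(h$start, h$strand), c("start", "strand", "score")],
                 mapped[order(mapped$start, mapped$strand), ],
                 ignore_attr = TRUE)
  }
})

test_that("degenerate calibration rates hit the extreme quantiles", {
  m <- consensus_motif("m", "ACGTACGT")
  bg <- random_regions(2, 100, seed = 4)
  p <- build_pssm(m, rep(0.25, 4))
  pall <- calibrate_threshold(p, bg, target_rate = 1)
  expect_equal(pall$empirical_rate, 1)        # every position a hit
  pmax_ <- calibrate_threshold(p, bg, target_rate = 1e-9)
  scores <- regarch:::best_strand_scores(pmax_, regarch:::encode_seq(bg[1]))
  scores <- c(scores,
              regarch:::best_strand_scores(pmax_, regarch:::encode_seq(bg[2])))
  expect_equal(pmax_$threshold, max(scores))  # threshold = max observed
  expect_error(calibrate_threshold(p, bg, target_rate = 1 / 50),
               "insufficient background")
})

test_that("ORI matches a direct counting oracle on planted data", {
  cons <- "GATTACAG"
  m <- consensus_motif("m", cons)
  p <- build_pssm(m, rep(0.25, 4))
  p$threshold <- 15
  set.seed(31)
  mk <- function() paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  # plant 2 copies in every positive, 1 copy in half the backgrounds
  pos <- vapply(1:20, function(i)
    plant_at(plant_at(mk(), cons, 100), cons, 600), character(1))
  bgr <- vapply(1:20, function(i)
    if (i %% 2) plant_at(mk(), cons, 300) else mk(), character(1))
  ori <- compute_ori(p, pos, bgr)
  # oracle: count full-match windows directly on both strands
  cons_rc <- rc(cons)
  count_hits <- function(s) {
    n <- 0
    for (i in 1:(nchar(s) - 7)) {
      w <- substr(s, i, i + 7)
      n <- n + (w == cons) + (w == cons_rc)
    }
    n
  }
  hp <- sum(vapply(pos, count_hits, numeric(1)))
  hb <- sum(vapply(bgr, count_hits, numeric(1)))
  npos_pos <- sum(nchar(pos) - 7); npos_bg <- sum(nchar(bgr) - 7)
  frac <- mean(vapply(pos, count_hits, numeric(1)) > 0)
  expect_equal(ori, (hp / npos_pos) / (hb / npos_bg) * frac)
  # absent from positives -> 0
  expect_equal(compute_ori(p, rep(strrep("A", 1000), 3), bgr), 0)
  # planting one more occurrence never decreases ORI
  pos2 <- pos
  pos2[1] <- plant_at(pos2[1], cons, 850)
  expect_gte(compute_ori(p, pos2, bgr), ori)
})
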