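test_that("the consensus placement attains the column-maximum sum", {
  pwm <- to_pwm(simulate_motif(6, ic = 1.5, seed = 21))
  cons <- motif_consensus(pwm)
  sc <- scan_raw(cons, pwm)
  expect_equal(sc$forward[1], sum(apply(pwm, 1, max)))
})

test_that("convolution scores equal a naive double loop, mono and di", {
  withr::with_seed(303, {
    seq <- random_dna(50)
    for (i in 1:5) {
      pwm <- to_pwm(simulate_motif(sample(4:9, 1), ic = runif(1, 0.5, 1.5)))
      sc <- scan_raw(seq, pwm)
      expect_equal(sc$forward, naive_scan_forward(seq, pwm))
      expect_equal(sc$reverse, naive_scan_forward(seq, reverse_complement_motif(pwm)))
    }
    dipwm <- to_pwm(simulate_motif(4, ic = 1, alphabet = "di"))
    sc <- scan_raw(seq, dipwm)
    expect_equal(sc$forward, naive_scan_forward(seq, dipwm))
  })
})

test_that("scanning the reverse complement swaps and reverses the strand vectors", {
  seq <- random_dna(40, seed = 9)
  pwm <- to_pwm(simulate_motif(7, ic = 1, seed = 10))
  a <- scan_raw(seq, pwm)
  b <- scan_raw(revcomp_str(seq), pwm)
  expect_equal(b$forward, rev(a$reverse))
  expect_equal(b$reverse, rev(a$forward))
})

test_that("placements overlapping ambiguous bases are masked", {
  pwm <- to_pwm(simulate_motif(4, ic = 1, seed = 12))
  sc <- scan_raw("ACGTNACGT", pwm)
  masked <- !is.finite(sc$forward)
  expect_equal(which(masked), 2:5)  # every placement covering position 5
  expect_true(all(is.finite(sc$forward[-(2:5)])))
  all_n <- scan_raw("NNNNNN", pwm)
  expect_true(all(!is.finite(all_n$forward)))
  expect_true(is.na(pool_scores(normalize_scores(all_n$forward, "fabian", pwm = pwm), "max")))
})

test_that("sequences shorter than the motif span yield an empty, flagged result", {
  pwm <- to_pwm(simulate_motif(6, seed = 1))
  expect_warning(sc <- scan_raw("ACG", pwm), "shorter")
  expect_length(sc$forward, 0)
})

test_that("probability normalization endpoints and oracle agreement", {
  pwm <- to_pwm(simulate_motif(4, ic = 1.2, seed = 31)[1:3, , drop = FALSE])
  bg <- rep(0.25, 4)
  d <- score_distribution(pwm, background = bg, granularity = 0.001)
  # all 64 3-mers, scanned on the distribution's own quantized grid
  grid <- as.matrix(do.call(expand.grid, rep(list(1:4), 3)))
  seqs <- apply(grid, 1, function(r) paste(BASES[r], collapse = ""))
  raw <- vapply(seqs, function(s) scan_raw(s, d$qweights, both_strands = FALSE)$forward[1],
                numeric(1))
  oracle <- enum_pmf_mono(pwm, bg, 0.001)
  emp_cdf <- vapply(oracle$raw, function(s) sum(oracle$weights[oracle$raw <= s + 1e-9]),
                    numeric(1))
  expect_equal(unname(normalize_scores(raw, "probnorm", dist = d)),
               unname(emp_cdf), tolerance = 1e-9)
  # consensus placement maps to exactly 1
  cons_raw <- scan_raw(motif_consensus(pwm), d$qweights, both_strands = FALSE)$forward[1]
  expect_equal(normalize_scores(cons_raw, "probnorm", dist = d), 1)
})

test_that("min-max normalization endpoints: consensus 1, anti-consensus 0", {
  pwm <- to_pwm(simulate_motif(5, ic = 1.4, seed = 41))
  best <- sum(apply(pwm, 1, max))
  worst <- sum(apply(pwm, 1, min))
  expect_equal(normalize_scores(best, "fabian", pwm = pwm), 1)
  expect_equal(normalize_scores(worst, "fabian", pwm = pwm), 0)
  mid <- (best + worst) / 2
  expect_equal(normalize_scores(mid, "fabian", pwm = pwm), 0.5)
})

test_that("normalized scores stay within [0, 1] over random placements", {
  motifs <- make_test_motifs(3, lengths = 6, seed = 51)
  seq <- random_dna(500, seed = 52)
  for (m in 1:3) {
    raw_q <- scan_raw(seq, motifs$dist[[m]]$qweights)
    pn <- normalize_scores(c(raw_q$forward, raw_q$reverse), "probnorm",
                           dist = motifs$dist[[m]])
    raw <- scan_raw(seq, motifs$pwm[[m]])
    fb <- normalize_scores(c(raw$forward, raw$reverse), "fabian",
                           pwm = motifs$pwm[[m]])
    expect_true(all(pn >= 0 & pn <= 1))
    expect_true(all(fb >= 0 & fb <= 1))
  }
})

test_that("pooling arithmetic, and max dominates avg", {
  expect_equal(pool_scores(0.7, "max"), pool_scores(0.7, "avg"))
  expect_equal(pool_scores(c(0.2, 0.9, 0.1), "max"), 0.9)
  expect_equal(pool_scores(c(0.2, 0.9, 0.1), "avg"), 0.4)
  withr::with_seed(61, {
    for (i in 1:20) {
      v <- runif(sample(1:30, 1))
      expect_gte(pool_scores(v, "max"), pool_scores(v, "avg"))
    }
  })
})

test_that("average pooling of unnormalized scores is rejected", {
  motifs <- make_test_motifs(2, seed = 71)
  expect_error(scan_sequences("ACGTACGTACGT", motifs, mode = "none", pooling = "avg"),
               "no natural interpretation")
})

test_that("pooled scores are invariant to reverse-complementing the sequence", {
  motifs <- make_test_motifs(4, lengths = c(5, 8), seed = 81)
  seqs <- vapply(1:6, function(i) random_dna(30, seed = 90 + i), "")
  for (mode in c("probnorm", "fabian", "none")) {
    pooling <- if (mode == "none") "max" else "avg"
    a <- scan_sequences(seqs, motifs, mode = mode, pooling = pooling)
    b <- scan_sequences(vapply(seqs, revcomp_str, ""), motifs,
                        mode = mode, pooling = pooling)
    expect_equal(a$score, b$score)
  }
})
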