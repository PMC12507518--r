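# Independent oracles used across the suite: exhaustive enumeration of the
# score distribution, a naive double-loop scanner, and small fixture
# builders.  These deliberately avoid the package's DP / vectorized paths.

BASES <- c("A", "C", "G", "T")

revcomp_str <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Exhaustive enumeration of the mono score distribution: every L-mer,
# weighted by the product of background probabilities, scores quantized
# per position exactly as the DP does.
enum_pmf_mono <- function(pwm, bg, eps) {
  l <- nrow(pwm)
  qw <- round(pwm / eps)
  grid <- as.matrix(do.call(expand.grid, rep(list(1:4), l)))
  sc <- 0
  wgt <- 1
  for (j in seq_len(l)) {
    sc <- sc + qw[j, grid[, j]]
    wgt <- wgt * bg[grid[, j]]
  }
  agg <- tapply(wgt, sc, sum)
  bins <- as.numeric(names(agg))
  ord <- order(bins)
  list(bins = bins[ord], support = bins[ord] * eps, pmf = as.numeric(agg)[ord],
       raw = sc * eps, weights = wgt)
}

# Same for dinucleotide matrices: enumerate all (D+1)-mers and chain the
# per-dinucleotide scores.
enum_pmf_di <- function(dipwm, bg, eps) {
  d <- nrow(dipwm)
  span <- d + 1L
  qw <- round(dipwm / eps)
  grid <- as.matrix(do.call(expand.grid, rep(list(1:4), span)))
  sc <- 0
  wgt <- 1
  for (p in seq_len(span)) wgt <- wgt * bg[grid[, p]]
  for (j in seq_len(d)) {
    code <- 4L * (grid[, j] - 1L) + grid[, j + 1L]
    sc <- sc + qw[j, code]
  }
  agg <- tapply(wgt, sc, sum)
  bins <- as.numeric(names(agg))
  ord <- order(bins)
  list(bins = bins[ord], support = bins[ord] * eps, pmf = as.numeric(agg)[ord],
       raw = sc * eps, weights = wgt)
}

# Compare a score_distribution against an enumeration oracle, aligning
# support bins on the integer grid.
expect_pmf_equal <- function(dist, oracle, tol = 1e-9) {
  bins <- round(dist$support / dist$granularity)
  expect_equal(sort(bins), sort(oracle$bins))
  m <- match(oracle$bins, bins)
  expect_true(all(abs(dist$pmf[m] - oracle$pmf) < tol))
}

# Naive per-placement double loop (forward strand only).
naive_scan_forward <- function(seq, pwm) {
  chars <- strsplit(toupper(seq), "")[[1]]
  is_di <- ncol(pwm) == 16L
  span <- nrow(pwm) + if (is_di) 1L else 0L
  n <- length(chars)
  out <- numeric(n - span + 1L)
  for (k in seq_along(out)) {
    s <- 0
    for (j in seq_len(nrow(pwm))) {
      if (is_di) {
        x <- match(chars[k + j - 1L], BASES)
        y <- match(chars[k + j], BASES)
        if (is.na(x) || is.na(y)) { s <- -Inf; break }
        s <- s + pwm[j, 4L * (x - 1L) + y]
      } else {
        x <- match(chars[k + j - 1L], BASES)
        if (is.na(x)) { s <- -Inf; break }
        s <- s + pwm[j, x]
      }
    }
    out[k] <- s
  }
  out
}

# A small prepared motif set shared by scanning / variant tests.
make_test_motifs <- function(n = 5L, lengths = 6L, ic = 1.2, seed = 42L,
                             alphabet = "mono", granularity = 0.001) {
  motif_pwm(simulate_motifs(n, lengths = lengths, ic = ic,
                            alphabet = alphabet, seed = seed),
            granularity = granularity)
}

random_dna <- function(n, seed = NULL) {
  gen <- function() paste(sample(BASES, n, replace = TRUE), collapse = "")
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
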