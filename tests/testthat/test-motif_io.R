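write_motif_file <- function(lines) {
  path <- withr::local_tempfile(fileext = ".motif", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("count matrices are parsed and normalized per row, file order kept", {
  path <- write_motif_file(c(
    ">first extra header tokens",
    "10 0 0 0", "0 10 0 0", "0 0 10 0",
    ">second",
    "1 1 1 1", "2 0 0 2"
  ))
  motifs <- read_motifs(path)
  expect_equal(motifs$name, c("first", "second"))
  expect_equal(motifs$positions, c(3L, 2L))
  expect_equal(unname(motifs$pspm[[1]]),
               rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0)))
  expect_equal(unname(motifs$pspm[[2]]),
               rbind(rep(0.25, 4), c(0.5, 0, 0, 0.5)))
  row_err <- vapply(motifs$pspm, function(m) max(abs(rowSums(m) - 1)), numeric(1))
  expect_true(all(row_err < 1e-9))
})

test_that("probability-flavored records are detected by row sums and kept", {
  path <- write_motif_file(c(">p", "0.7 0.1 0.1 0.1", "0.25 0.25 0.25 0.25"))
  motifs <- read_motifs(path)
  expect_equal(unname(motifs$pspm[[1]][1, ]), c(0.7, 0.1, 0.1, 0.1))
})

test_that("format errors name the motif and the offending line", {
  bad_width <- write_motif_file(c(">m1", "1 2 3"))
  expect_error(read_motifs(bad_width), "m1.*line 2.*expected 4 columns")
  negative <- write_motif_file(c(">m1", "1 1 1 1", ">m2", "1 -1 1 1"))
  expect_error(read_motifs(negative), "m2.*line 4.*negative")
  empty <- write_motif_file(character(0))
  expect_warning(out <- read_motifs(empty), "empty")
  expect_equal(nrow(out), 0L)
})

test_that("dinucleotide records require 16 columns", {
  path <- write_motif_file(c(">d", paste(rep(1, 16), collapse = " ")))
  motifs <- read_motifs(path, alphabet = "di")
  expect_equal(ncol(motifs$pspm[[1]]), 16L)
  expect_equal(motifs$span, 2L)
  expect_error(read_motifs(path, alphabet = "mono"), "expected 4 columns")
})

test_that("write/read round trip reproduces probabilities", {
  motifs <- simulate_motifs(3, lengths = c(5, 7, 9), seed = 11)
  path <- withr::local_tempfile(fileext = ".motif")
  write_motifs(motifs, path)
  back <- read_motifs(path)
  expect_equal(back$name, motifs$name)
  for (i in 1:3) {
    expect_true(max(abs(back$pspm[[i]] - motifs$pspm[[i]])) < 1e-9)
  }
})

test_that("log-odds transform matches its closed form", {
  # uniform row, uniform background, no pseudocount -> zeros exactly
  uni <- matrix(0.25, nrow = 3, ncol = 4)
  expect_equal(unname(to_pwm(uni, pseudocount = 0)), matrix(0, 3, 4),
               ignore_attr = TRUE)
  # forced arithmetic on a single row
  p <- matrix(c(0.5, 0.25, 0.125, 0.125), nrow = 1)
  expect_equal(unname(to_pwm(p, pseudocount = 0)),
               matrix(c(log(2), 0, log(0.5), log(0.5)), nrow = 1),
               ignore_attr = TRUE)
  # zero probabilities demand a pseudocount
  hard <- matrix(c(1, 0, 0, 0), nrow = 1)
  expect_error(to_pwm(hard, pseudocount = 0), "pseudocount")
  expect_true(all(is.finite(to_pwm(hard, pseudocount = 0.001))))
})

test_that("pseudocount keeps rows on the simplex before the log", {
  p <- matrix(c(1, 0, 0, 0, 0.25, 0.25, 0.25, 0.25), 2, 4, byrow = TRUE)
  pc <- 0.01
  mixed <- p * (1 - pc * 4) + pc
  expect_equal(rowSums(mixed), c(1, 1))
  w <- to_pwm(p, pseudocount = pc)
  expect_equal(unname(w), unname(log(mixed / 0.25)), ignore_attr = TRUE)
})

test_that("reverse complement permutes and reverses; involution on both alphabets", {
  w <- matrix(c(1, 2, 3, 4), nrow = 1)
  expect_equal(unname(reverse_complement_motif(w)), matrix(c(4, 3, 2, 1), nrow = 1))
  mono <- to_pwm(simulate_motif(7, seed = 5))
  expect_equal(reverse_complement_motif(reverse_complement_motif(mono)), mono)
  di <- to_pwm(simulate_motif(4, alphabet = "di", seed = 6))
  expect_equal(reverse_complement_motif(reverse_complement_motif(di)), di)
})

test_that("reverse complement of a consensus-AC motif has consensus GT", {
  p <- rbind(c(0.97, 0.01, 0.01, 0.01),  # A
             c(0.01, 0.97, 0.01, 0.01))  # C
  w <- to_pwm(p)
  expect_equal(motif_consensus(w), "AC")
  expect_equal(motif_consensus(reverse_complement_motif(w)), "GT")
})

test_that("motif background options: uniform, marginal, explicit", {
  p <- simulate_motif(6, seed = 9)
  expect_equal(unname(motif_background(p)), rep(0.25, 4))
  expect_equal(unname(motif_background(p, "motif")), unname(colMeans(p)))
  expect_equal(unname(motif_background(p, c(2, 1, 1, 2))), c(1, 0.5, 0.5, 1) / 3)
  expect_error(motif_background(p, c(1, 0, 1, 1)), "> 0")
})
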