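test_that("score_window matches closed-form arithmetic", {
  # single-column PWM, uniform background
  p <- pwm(matrix(c(0.97, 0.01, 0.01, 0.01), nrow = 4), id = "one")
  sc <- score_window(p, "A")
  expect_equal(sc$raw_score, log2(0.97 / 0.25), tolerance = 1e-12)
  expect_equal(sc$score_ratio, 1.0)
  worst <- score_window(p, "C")
  expect_equal(worst$score_ratio, 0.0)

  # uniform PWM: max == min, ratio 1 by convention
  pu <- pwm(matrix(0.25, nrow = 4, ncol = 3), id = "uniform")
  expect_equal(score_window(pu, "ACG")$raw_score, 0)
  expect_equal(score_window(pu, "ACG")$score_ratio, 1.0)

  # minus strand scores the reverse complement
  p2 <- consensus_pwm("TGAC")
  expect_equal(score_window(p2, "GTCA", strand = "-")$score_ratio, 1.0)

  # N contributes zero log-odds
  pN <- consensus_pwm("AA")
  expect_equal(score_window(pN, "AN")$raw_score,
               score_window(pN, "AA")$raw_score / 2)

  expect_error(score_window(p2, "TGACT"), "length")
})

test_that("scan/max/count agree with exhaustive window enumeration", {
  withr::local_seed(501)
  p <- consensus_pwm("TGACTCA")
  for (case in 1:8) {
    seqx <- random_dna(200)
    # plant one exact consensus
    pos <- sample(50:150, 1)
    substr(seqx, pos + 1, pos + 7) <- "TGACTCA"
    for (mr in c(0.7, 0.8, 0.95)) {
      got <- scan_pwm(p, seqx, min_ratio = mr)
      want <- oracle_scan(p, seqx, min_ratio = mr)
      expect_equal(nrow(got), nrow(want))
      if (nrow(got) > 0) {
        expect_equal(sort(got$start), sort(want$start))
        expect_equal(sort(got$score_ratio), sort(want$score_ratio),
                     tolerance = 1e-9)
      }
    }
    expect_true(any(scan_pwm(p, seqx, 0.99)$start == pos))
    # max equals brute-force max over all windows/strands
    all_hits <- oracle_scan(p, seqx, min_ratio = -0.01)
    expect_equal(max_score_ratio(p, seqx), max(all_hits$score_ratio),
                 tolerance = 1e-9)
  }
  expect_equal(nrow(scan_pwm(p, "TGA")), 0)
  expect_error(max_score_ratio(p, "TGA"), "shorter")
})

test_that("min_ratio 1 keeps only perfect windows", {
  p <- consensus_pwm("TGACTCA")
  seqx <- paste0(strrep("C", 20), "TGACTCA", strrep("C", 20))
  hits <- scan_pwm(p, seqx, min_ratio = 1)
  expect_true(all(hits$score_ratio == 1))
  expect_equal(unique(hits$start), 20L)
})

test_that("scanning the reverse complement mirrors hits", {
  withr::local_seed(502)
  p <- consensus_pwm("TGACAGT")  # non-palindromic
  seqx <- random_dna(300)
  pos <- 120
  substr(seqx, pos + 1, pos + 7) <- "TGACAGT"
  fwd <- scan_pwm(p, seqx, 0.8)
  rev <- scan_pwm(p, reverse_complement(seqx), 0.8)
  n <- nchar(seqx)
  # positions reflect, strands swap
  reflected <- sort((n - fwd$end))
  expect_equal(sort(rev$start), reflected)
  expect_equal(sort(rev$score_ratio), sort(fwd$score_ratio),
               tolerance = 1e-9)
})

test_that("count_occurrences collapses palindromic double hits", {
  p <- consensus_pwm("TGACGTCA")  # reverse-complement symmetric
  seqx <- paste0(strrep("C", 15), "TGACGTCA", strrep("G", 15))
  raw_hits <- scan_pwm(p, seqx, 0.9)
  expect_equal(sum(raw_hits$start == 15), 2)  # both strands hit
  expect_equal(count_occurrences(p, seqx, 0.9), 1)

  p2 <- consensus_pwm("TGACTCA")
  two <- paste0(strrep("C", 10), "TGACTCA", strrep("G", 12),
                "TGACTCA", strrep("C", 10))
  expect_equal(count_occurrences(p2, two, 0.95), 2)
  # strict PWM on pure background: zero, verified by brute force
  withr::local_seed(503)
  bg <- random_dna(150)
  o <- oracle_scan(p2, bg, 0.99)
  expect_equal(count_occurrences(p2, bg, 0.99),
               if (nrow(o)) length(unique(o$start)) else 0L)
})

test_that("composition features hand-checked and strand-symmetric", {
  f <- composition_features("AAAA")
  expect_equal(f[["mono_AT"]], 1.0)
  expect_equal(f[["di_AA_TT"]], 1.0)

  f2 <- composition_features("ACGT")
  expect_equal(f2[["mono_AT"]], 0.5)
  expect_equal(f2[["mono_CG"]], 0.5)
  # windows AC, CG, GT -> classes AC/GT: 2/3, CG: 1/3
  expect_equal(f2[["di_AC_GT"]], 2 / 3)
  expect_equal(f2[["di_CG"]], 1 / 3)

  # groups sum to 1
  withr::local_seed(504)
  for (case in 1:5) {
    s <- random_dna(80)
    f3 <- composition_features(s)
    expect_equal(f3[["mono_AT"]] + f3[["mono_CG"]], 1)
    expect_equal(sum(f3[grep("^di_", names(f3))]), 1)
    # invariant under reverse complement
    expect_equal(composition_features(reverse_complement(s)), f3,
                 tolerance = 1e-12)
  }
  expect_error(composition_features("NNNN"), "all-N")
  expect_error(composition_features(""), "empty")
})

test_that("reconstruct_pwm recovers counts and a known PWM", {
  # single sequence, no pseudocount: deterministic 0/1 matrix
  p1 <- reconstruct_pwm("ACGT", pseudocount = 0)
  expect_equal(unname(p1$mat[, 1]), c(1, 0, 0, 0))
  expect_equal(unname(p1$mat[, 4]), c(0, 0, 0, 1))

  # sampling oracle: 1000 draws recover entries within 0.05
  withr::local_seed(505)
  truth <- consensus_pwm("TGACTCA", max_prob = 0.85)
  draws <- parabind:::.draw_from_pwm(truth, 1000)
  rec <- reconstruct_pwm(draws, pseudocount = 0)
  expect_lt(max(abs(rec$mat - truth$mat)), 0.05)

  expect_error(reconstruct_pwm(c("ACGT", "ACG")), "same length")
  expect_error(reconstruct_pwm(character(0)), "at least one")
})

test_that("information content reproduces the logo endpoints", {
  # no base preference: 0 bits; single base: 2 bits
  expect_equal(information_content(
    pwm(matrix(0.25, 4, 1)))$per_position, 0)
  expect_equal(information_content(
    pwm(matrix(c(1, 0, 0, 0), 4, 1)))$per_position, 2)
  # half/half column: 1 bit
  expect_equal(information_content(
    pwm(matrix(c(0.5, 0.5, 0, 0), 4, 1)))$per_position, 1)
  # total is the column sum
  p <- pwm(cbind(c(1, 0, 0, 0), c(0.25, 0.25, 0.25, 0.25)))
  expect_equal(information_content(p)$total, 2)
})

test_that("strict occurrences reconstruct to higher IC than degenerate", {
  withr::local_seed(506)
  strict <- parabind:::.strict_pwm()
  degen <- parabind:::.degenerate_pwm()
  ic_s <- information_content(
    reconstruct_pwm(parabind:::.draw_from_pwm(strict, 300)))$total
  ic_d <- information_content(
    reconstruct_pwm(parabind:::.draw_from_pwm(degen, 300)))$total
  expect_gt(ic_s, ic_d)
})

test_that("pwm constructor enforces column sums and row names", {
  expect_error(pwm(matrix(c(0.5, 0.5, 0.5, 0.5), 4, 1)), "sum to 1")
  expect_error(pwm(matrix(0.25, 3, 1)), "4 rows")
  m <- matrix(0.25, 4, 2, dimnames = list(c("T", "G", "C", "A"), NULL))
  expect_equal(rownames(pwm(m)$mat), c("A", "C", "G", "T"))
})
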