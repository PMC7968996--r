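test_that("overlap classification labels and unifies sites", {
  a <- intervals("chr1", 0, 100)
  b <- intervals("chr1", 50, 150)
  cl <- classify_overlap(a, b)
  expect_equal(cl$label, "F1F2")
  expect_equal(cl$start, 0L)
  expect_equal(cl$end, 150L)

  cl2 <- classify_overlap(intervals("chr1", 0, 100),
                          intervals("chr1", 200, 300))
  expect_equal(cl2$label, c("PF1", "PF2"))

  # touching but not overlapping peaks stay separate
  cl3 <- classify_overlap(intervals("chr1", 0, 100),
                          intervals("chr1", 100, 200))
  expect_equal(sort(cl3$label), c("PF1", "PF2"))
})

test_that("classification matches the overlap-graph oracle", {
  withr::local_seed(601)
  for (case in 1:25) {
    a <- random_intervals(sample(5:30, 1))
    b <- random_intervals(sample(5:30, 1))
    got <- classify_overlap(a, b)
    want <- oracle_overlap_classes(a, b)
    expect_equal(got[, c("chrom", "start", "end", "label")], want)
    # base partition: labelled bases == merged union bases
    n_bases <- sum(got$end - got$start)
    merged <- merge_intervals(dplyr::bind_rows(a, b), 0)
    expect_gte(n_bases, sum(merged$end - merged$start))
    # per-base coverage identical (labels may split a touching run)
    expect_equal(occupancy(got, 5000), occupancy(merged, 5000))
  }
})

test_that("classified peaks carry both factors' signals", {
  trk_a <- tibble::tibble(chrom = "chr1", start = 0L, end = 100L,
                          value = 80)
  trk_b <- tibble::tibble(chrom = "chr1", start = 0L, end = 100L,
                          value = 30)
  cl <- classify_overlap(intervals("chr1", 10, 50),
                         intervals("chr1", 200, 210)[0, ],
                         track_a = trk_a, track_b = trk_b)
  expect_equal(cl$signal_a, 80)
  expect_equal(cl$signal_b, 30)
})

test_that("signed fold change follows the inclusive +/-1.5 convention", {
  expect_equal(fold_change(30, 10)$fc, 3)
  expect_equal(fold_change(30, 10)$category, "up")
  # boundary inclusive
  fc <- fold_change(10, 15)
  expect_equal(fc$fc, -1.5)
  expect_equal(fc$category, "down")
  expect_equal(fold_change(14, 10)$category, "unchanged")
  expect_equal(fold_change(14, 10)$fc, 1.4)
  # antisymmetry
  withr::local_seed(602)
  x <- stats::runif(20, 1, 100)
  y <- stats::runif(20, 1, 100)
  expect_equal(fold_change(x, y)$fc, -fold_change(y, x)$fc)
  expect_error(fold_change(-1, 5), ">= 0")
  expect_error(fold_change(5, 5, threshold = 1), "> 1")
})

test_that("element annotation applies the promoter/enhancer rules", {
  tss <- intervals("chr1", 10000, 10001, strand = "+")
  k27 <- intervals("chr1", 9900, 10100)
  k4me1 <- intervals("chr1", 5000, 6000)
  el <- annotate_elements(tss, k27, k4me1)
  cap <- el[el$state == "cAP", ]
  expect_equal(nrow(cap), 1)
  expect_equal(c(cap$start, cap$end), c(8500L, 11500L))
  cie <- el[el$state == "cIE", ]
  expect_equal(nrow(cie), 1)
  expect_equal(c(cie$start, cie$end), c(5000L, 6000L))

  # promoter without K27ac is inactive
  el2 <- annotate_elements(tss, intervals("chr1", 0, 10)[0, ], k4me1)
  expect_equal(el2$state[el2$start == 8500], "cIP")

  # K4me1 straddling a promoter: only the remainder is an enhancer
  k4_straddle <- intervals("chr1", 8000, 12000)
  el3 <- annotate_elements(tss, k27, k4_straddle)
  enh <- el3[el3$state %in% c("cAE", "cIE"), ]
  expect_equal(enh$start, c(8000L, 11500L))
  expect_equal(enh$end, c(8500L, 12000L))
})

test_that("element states are pairwise base-disjoint with promoter precedence", {
  withr::local_seed(603)
  for (case in 1:10) {
    tss <- random_intervals(4, len = 40000, max_w = 1)
    k27 <- random_intervals(8, len = 40000, max_w = 800)
    k4 <- random_intervals(8, len = 40000, max_w = 1500)
    el <- annotate_elements(tss, k27, k4)
    # disjoint states
    occ_total <- integer(45000)
    for (i in seq_len(nrow(el))) {
      idx <- (el$start[i] + 1):el$end[i]
      occ_total[idx] <- occ_total[idx] + 1L
    }
    expect_true(all(occ_total <= 1))
    # promoter precedence: every base of TSS+/-1500 belongs to a promoter
    # state or to no element, never to an enhancer state
    prom_occ <- occupancy(tibble::tibble(
      chrom = tss$chrom, start = pmax(0L, tss$start - 1500L),
      end = tss$start + 1500L), 45000)
    enh_occ <- occupancy(el[el$state %in% c("cAE", "cIE"), ], 45000)
    expect_true(!any(prom_occ & enh_occ))
  }
})

test_that("k4me3 is reported but does not change states", {
  tss <- intervals("chr1", 10000, 10001)
  k27 <- intervals("chr1", 9900, 10100)
  k4me1 <- intervals("chr1", 5000, 6000)
  k4me3 <- intervals("chr1", 9800, 10200)
  el <- annotate_elements(tss, k27, k4me1, k4me3 = k4me3)
  el0 <- annotate_elements(tss, k27, k4me1)
  expect_equal(el[, c("chrom", "start", "end", "state")], el0)
  expect_true(el$k4me3[el$state == "cAP"])
  expect_false(el$k4me3[el$state == "cIE"])
})

test_that("overlap fractions count per-label membership", {
  q <- dplyr::bind_rows(
    dplyr::mutate(intervals("chr1", c(0, 100), c(50, 150)), label = "PF1"),
    dplyr::mutate(intervals("chr1", 300, 350), label = "PF2"))
  tgt <- list(open = intervals("chr1", c(0, 100), c(60, 160)))
  fr <- overlap_fractions(q, tgt)
  expect_equal(fr$fraction[fr$label == "PF1"], 1.0)
  expect_equal(fr$fraction[fr$label == "PF2"], 0.0)
  # empty label -> NA, not 0
  q2 <- q[q$label == "PF1", ]
  q2$label <- factor(q2$label, levels = c("PF1", "PF2"))
  fr2 <- overlap_fractions(dplyr::mutate(q, label = as.character(label)),
                           list(none = intervals("chr2", 0, 10)))
  expect_true(all(fr2$fraction == 0))

  withr::local_seed(604)
  for (case in 1:10) {
    q3 <- random_intervals(20)
    q3$label <- sample(c("x", "y"), 20, replace = TRUE)
    t3 <- random_intervals(15)
    fr3 <- overlap_fractions(q3, list(t = t3))
    for (lb in unique(q3$label)) {
      qs <- q3[q3$label == lb, ]
      want <- mean(vapply(seq_len(nrow(qs)), function(i) {
        any(qs$start[i] < t3$end & t3$start < qs$end[i])
      }, logical(1)))
      expect_equal(fr3$fraction[fr3$label == lb], want)
    }
  }
})
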