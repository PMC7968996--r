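# small deterministic profile: n tiling fragments of width 100 on chrV
toy_profile <- function(counts_list, width = 100) {
  n <- length(counts_list[[1]])
  prof <- tibble::tibble(chrom = "chrV",
                         start = seq(0L, by = width, length.out = n),
                         end = seq(width, by = width, length.out = n))
  for (i in seq_along(counts_list)) {
    prof[[paste0("rep", i)]] <- counts_list[[i]]
  }
  prof
}

test_that("normalisation equalises replicate totals outside the exclusion zone", {
  n <- 21
  vp_pos <- 1050  # fragment 11; exclusion zone = fragments 9:13
  r1 <- rep(5, n)    # total outside zone: 16 * 5 = 80
  r2 <- rep(15, n)   # 240
  prof <- toy_profile(list(r1, r2))
  norm <- normalize_profile(prof, vp_pos)
  excl <- c(9:13)
  expect_equal(sum(norm$rep1[-excl]), sum(norm$rep2[-excl]))
  expect_equal(sum(norm$rep1[-excl]), (80 + 240) / 2)
  # within-replicate ratios preserved
  expect_equal(norm$rep1 / norm$rep1[1], r1 / r1[1])
  # single replicate: unchanged
  p1 <- toy_profile(list(r1))
  expect_equal(normalize_profile(p1, vp_pos)$rep1, r1)
  # zero-total replicate names the culprit
  p0 <- toy_profile(list(r1, rep(0, n)))
  expect_error(normalize_profile(p0, vp_pos), "rep2")
})

test_that("background fit is isotonic and recovers a pure decay", {
  # counts already non-increasing with distance: fit equals input
  n <- 61
  vp_pos <- 3050
  d <- abs(seq(50, by = 100, length.out = n) - vp_pos)
  y <- 100 - d / 100
  prof <- toy_profile(list(y))
  bg <- background_fit(prof, vp_pos)
  callable <- !is.na(bg$expected)
  expect_equal(bg$expected[callable], bg$mean_count[callable],
               tolerance = 1e-9)

  # noiseless hyperbolic decay recovered within discretisation error
  mu <- 120 / (1 + d / 2000)
  prof2 <- toy_profile(list(mu))
  bg2 <- background_fit(prof2, vp_pos)
  ok <- !is.na(bg2$expected)
  expect_lt(max(abs(bg2$expected[ok] - mu[ok])), 1e-6)

  # a single planted spike leaves a positive residual
  y3 <- mu
  y3[45] <- y3[45] * 4
  bg3 <- background_fit(toy_profile(list(y3)), vp_pos)
  expect_gt(bg3$mean_count[45] - bg3$expected[45], 2 * mu[45])

  # too few fragments on a side: warning, side skipped
  short <- toy_profile(list(rep(10, 25)))
  expect_warning(bgs <- background_fit(short, 250), "background not fitted")
  expect_true(all(is.na(bgs$expected[1:2])))
})

test_that("PIR caller guards, consistency filter and merging", {
  cfg <- sim_config(31)
  sim <- sim_capture_profile(cfg, viewpoint_id = 1)
  prof <- background_fit(normalize_profile(sim$profile, sim$viewpoint_pos),
                         sim$viewpoint_pos)
  expect_error(call_pirs(prof, sim$viewpoint_pos,
                         pir_params(n_permutations = 50)), ">= 100")
  expect_error(call_pirs(sim$profile, sim$viewpoint_pos),
               "background_fit")
  # q_wr = Inf suppresses every call regardless of signal
  expect_equal(nrow(call_pirs(prof, sim$viewpoint_pos,
                              pir_params(q_wr = Inf), seed = 1)), 0)
  pirs <- call_pirs(prof, sim$viewpoint_pos, seed = 1)
  expect_gt(nrow(pirs), 0)
  # PIRs are unions of whole fragments and pairwise disjoint
  for (i in seq_len(nrow(pirs))) {
    expect_true(pirs$start[i] %in% prof$start)
    expect_true(pirs$end[i] %in% prof$end)
  }
  if (nrow(pirs) > 1) {
    expect_true(all(pirs$start[-1] >= pirs$end[-nrow(pirs)]))
  }
  expect_true(all(pirs$distance >= 0))
})

test_that("pir_params validates its ranges", {
  expect_error(pir_params(alpha_fdr = 0), "alpha_fdr")
  expect_error(pir_params(w_size = 4), "odd")
  expect_error(pir_params(q_wr = -1), "q_wr")
})

test_that("per-viewpoint statistics match hand computation", {
  pirs <- tibble::tibble(
    chrom = "chrV",
    start = c(1000L, 9000L, 20000L, 1000L, 5000L, 2000L),
    end = c(2000L, 10000L, 21000L, 2000L, 6000L, 3000L),
    distance = c(150000, 4000, 11000, 7000, 2000, 9000),
    viewpoint = c("v1", "v1", "v1", "v2", "v2", "v3"),
    vp_pos = c(5000, 5000, 5000, 10000, 10000, 1000))
  st <- pir_stats(pirs)
  expect_equal(st$n_pirs_median, 2)
  expect_equal(st$n_pirs_range, c(1L, 3L))
  expect_equal(st$distance_median, median(pirs$distance))
  pv <- st$per_viewpoint
  expect_equal(pv$layout[pv$viewpoint == "v1"], "both")
  expect_equal(pv$layout[pv$viewpoint == "v2"], "upstream")
  expect_equal(pv$layout[pv$viewpoint == "v3"], "downstream")
})

test_that("nested PIR annotation reproduces the toy fractions", {
  pirs <- intervals("chr1", c(0, 1000, 2000, 3000) * 10L,
                    c(0, 1000, 2000, 3000) * 10L + 500L)
  # 3 of 4 PIRs contain ATAC peaks; 5 ATAC peaks, 4 inside PIRs
  atac <- intervals("chr1", c(100, 10100, 10300, 20100, 50000),
                    c(200, 10200, 10400, 20200, 50100))
  # of the 4 ATAC-in-PIR sites, 4 in cAE? toy wants 4/5 in-PIR->cAE...
  elements <- tibble::tibble(chrom = "chr1",
                             start = c(0L, 10000L, 20000L),
                             end = c(600L, 10500L, 20500L),
                             state = "cAE")
  tf <- intervals("chr1", c(100, 10100), c(200, 10200))
  ann <- annotate_pirs(pirs, atac, elements, tf)
  fr <- ann$fractions
  expect_equal(fr$fraction[fr$level == "pir_with_atac"], 3 / 4)
  expect_equal(fr$fraction[fr$level == "atac_in_pir_with_cae"], 4 / 4)
  expect_equal(fr$fraction[fr$level == "cae_atac_tf_bound"], 2 / 4)
  # all-empty annotations: zero at the first level
  ann0 <- annotate_pirs(pirs, atac[0, ], elements, tf)
  expect_equal(ann0$fractions$fraction[1], 0)
  # empty PIR list: undefined fractions
  annNA <- annotate_pirs(pirs[0, ], atac, elements, tf)
  expect_true(all(is.na(annNA$fractions$fraction)))
  # invariant under permuting interval order
  ann_perm <- annotate_pirs(pirs[c(3, 1, 4, 2), ], atac[c(5, 3, 1, 2, 4), ],
                            elements, tf)
  expect_equal(ann_perm$fractions, ann$fractions)
})

test_that("delta profile is antisymmetric and localises planted gains", {
  cfg <- sim_config(32)
  a <- sim_capture_profile(cfg, viewpoint_id = 1)
  b <- sim_capture_profile(cfg, viewpoint_id = 1, planted = FALSE)
  pa <- normalize_profile(a$profile, a$viewpoint_pos)
  pb <- normalize_profile(b$profile, b$viewpoint_pos)
  d_ab <- delta_profile(pa, pb)
  d_ba <- delta_profile(pb, pa)
  expect_equal(d_ab$delta, -d_ba$delta)
  expect_equal(delta_profile(pa, pa)$delta, rep(0, nrow(pa)))
  # mean delta inside the planted regions exceeds the background mean
  in_pir <- parabind:::overlap_flag(d_ab, a$truth_pirs)
  expect_gt(mean(d_ab$delta[in_pir]), mean(d_ab$delta[!in_pir]) + 10)
  # mismatched fragment maps are rejected
  pb2 <- pb[-1, ]
  expect_error(delta_profile(pa, pb2), "fragment maps differ")
})
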