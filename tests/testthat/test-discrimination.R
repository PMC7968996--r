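test_that("feature matrix geometry: counts, window, centring", {
  withr::local_seed(701)
  genome <- c(chrT = random_dna(12000))
  pwms <- list(a = consensus_pwm("TGACTCA", id = "a"),
               b = consensus_pwm("GGGCCC", id = "b"))
  peaks <- intervals("chrT", c(4900, 8000), c(5100, 8200))
  peaks$summit <- c(5000L, 8100L)
  fm <- build_feature_matrix(peaks, genome, pwms, window = 1001)
  expect_equal(nrow(fm), 2)
  # n_pwms + 2 mono + 10 dinucleotide classes
  expect_equal(length(attr(fm, "feature_names")), 2 + 12)
  # identical sequences give identical rows
  fm2 <- build_feature_matrix(peaks, genome, pwms, window = 1001)
  expect_identical(fm, fm2)
  # window centred on the summit: plant a perfect site at the edge bases
  g2 <- genome
  substr(g2[["chrT"]], 5000 - 499, 5000 - 493) <- "TGACTCA"  # inside
  fmi <- build_feature_matrix(peaks[1, ], g2, pwms["a"])
  expect_equal(fmi$a, 1.0)
  g3 <- genome
  substr(g3[["chrT"]], 5000 - 507, 5000 - 501) <- "TGACTCA"  # outside
  fmo <- build_feature_matrix(peaks[1, ], g3, pwms["a"])
  expect_lt(fmo$a, 1.0)

  # peaks whose window leaves the contig are dropped with a warning
  edge <- intervals("chrT", 0, 200)
  edge$summit <- 100L
  expect_warning(fme <- build_feature_matrix(edge, genome, pwms),
                 "dropped")
  expect_equal(nrow(fme), 0)
  expect_error(build_feature_matrix(peaks, genome, list()), "empty")
  expect_error(build_feature_matrix(peaks, genome, pwms, window = 1000),
               "odd")
})

test_that("class balancing downsamples to the minority size, seeded", {
  fm <- make_fm(160, seed = 1)
  fm_unbal <- fm[c(1:80, 81:120), ]  # 80 PF1 + 40 PF2
  attr(fm_unbal, "feature_names") <- attr(fm, "feature_names")
  bal <- balance_classes(fm_unbal, seed = 5)
  expect_equal(unname(table(bal$label)), c(40L, 40L), ignore_attr = TRUE)
  expect_identical(balance_classes(fm_unbal, seed = 5), bal)
  expect_false(identical(balance_classes(fm_unbal, seed = 6), bal))
  # already balanced: unchanged row multiset
  bal2 <- balance_classes(fm, seed = 5)
  expect_setequal(bal2$peak_id, fm$peak_id)
  expect_error(balance_classes(fm[fm$label == "PF1", ], 1), "two classes")
})

test_that("midrank AUC matches pROC and is monotone-invariant", {
  withr::local_seed(702)
  scores <- stats::rnorm(200)
  labels <- stats::runif(200) < 0.4
  got <- auc_midrank(scores, labels)
  skip_if_not_installed("pROC")
  want <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                         direction = "<")))
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(auc_midrank(exp(scores), labels), got)
  expect_equal(auc_midrank(rank(scores), labels), got)
})

test_that("classifier protocol: separation, nulls, determinism", {
  # perfectly separated 1-D feature
  fm_sep <- make_fm(200, seed = 2, signal = 50, p_noise = 2)
  fit <- fit_classifier(fm_sep, seed = 3)
  expect_equal(fit$auc, 1.0)
  expect_equal(top_coefficients(fit, 1)$feature, "planted")

  # determinism: same input and seed give identical numbers
  fit_b <- fit_classifier(fm_sep, seed = 3)
  expect_identical(glance(fit), glance(fit_b))
  expect_identical(tidy(fit), tidy(fit_b))

  # labels shuffled against features: AUC near 0.5
  fm_null <- make_fm(600, seed = 4, signal = 0)
  fit_null <- fit_classifier(fm_null, seed = 5)
  expect_gt(fit_null$auc, 0.38)
  expect_lt(fit_null$auc, 0.62)

  # constant features dropped with a warning
  fm_const <- fm_sep
  fm_const$noise_1 <- 1
  expect_warning(fit_classifier(fm_const, seed = 3), "constant")
})

test_that("penalty path: huge lambda shrinks everything to zero", {
  fm <- make_fm(200, seed = 6)
  fit <- fit_classifier(fm, seed = 7)
  beta_inf <- as.matrix(stats::coef(fit$model, s = max(fit$model$lambda)))
  expect_true(all(beta_inf[-1, 1] == 0))
  # and at the selected penalty the planted feature is nonzero
  expect_true(tidy(fit)$coefficient[tidy(fit)$feature == "planted"] != 0)
})

test_that("coefficient signs follow the positive-class encoding", {
  fm <- make_fm(300, seed = 8, signal = 3)
  fit_pf1 <- fit_classifier(fm, seed = 9, positive_class = "PF1")
  fit_pf2 <- fit_classifier(fm, seed = 9, positive_class = "PF2")
  b1 <- tidy(fit_pf1)$coefficient[tidy(fit_pf1)$feature == "planted"]
  b2 <- tidy(fit_pf2)$coefficient[tidy(fit_pf2)$feature == "planted"]
  expect_gt(b1, 0)  # planted is enriched in PF1
  expect_lt(b2, 0)  # flipping the encoding flips the sign
  expect_equal(top_coefficients(fit_pf1, 1)$class, "PF1")
})

test_that("single-feature AUC uses the paired split, direction-corrected", {
  fm <- make_fm(300, seed = 10, signal = 3)
  fit <- fit_classifier(fm, seed = 11)
  a <- single_feature_auc(fm, "planted", fit = fit)
  expect_gt(a, 0.8)
  # feature equal to the label is perfect
  fm$oracle_feature <- as.numeric(fm$label == "PF1")
  attr(fm, "feature_names") <- c(attr(fm, "feature_names"),
                                 "oracle_feature")
  expect_equal(single_feature_auc(fm, "oracle_feature", fit = fit), 1.0)
  # independent feature is near chance
  a_noise <- single_feature_auc(fm, "noise_1", fit = fit)
  expect_lt(abs(a_noise - 0.5), 0.2)
  # reusing the seed reproduces the split
  expect_equal(single_feature_auc(fm, "planted", seed = 11), a)
  expect_error(single_feature_auc(fm, "nope", fit = fit), "unknown")
})

test_that("ratio regressor recovers linear signal, nulls out noise", {
  withr::local_seed(703)
  n <- 300
  x <- stats::rnorm(n)
  fm <- dplyr::bind_cols(
    tibble::tibble(peak_id = paste0("p", 1:n), response = 2 * x,
                   driver = x),
    tibble::as_tibble(matrix(stats::rnorm(n * 4), n, 4,
                             dimnames = list(NULL, paste0("z", 1:4)))))
  attr(fm, "feature_names") <- c("driver", paste0("z", 1:4))
  fit <- fit_ratio_regressor(fm, seed = 12)
  expect_gt(fit$pearson_r, 0.99)

  # permuted response: r near zero
  fm_null <- fm
  fm_null$response <- sample(fm_null$response)
  attr(fm_null, "feature_names") <- attr(fm, "feature_names")
  fit_null <- fit_ratio_regressor(fm_null, seed = 13)
  expect_lt(abs(fit_null$pearson_r), 0.3)

  fm_const <- fm
  fm_const$response <- 1
  attr(fm_const, "feature_names") <- attr(fm, "feature_names")
  expect_error(fit_ratio_regressor(fm_const, seed = 1), "constant")
})

test_that("score distribution summary is normalised per group", {
  fm <- make_fm(200, seed = 14)
  fm$ratio_feature <- stats::runif(200, 0.8, 1)
  attr(fm, "feature_names") <- c(attr(fm, "feature_names"),
                                 "ratio_feature")
  s <- score_distribution_summary(fm, "ratio_feature")
  for (g in unique(s$histogram$group)) {
    expect_equal(sum(s$histogram$density[s$histogram$group == g]), 1)
  }
  expect_equal(nrow(s$medians), 2)
  # identical groups give identical histograms
  fm2 <- fm
  fm2$label <- rep(c("PF1", "PF2"), 100)
  fm2$ratio_feature <- rep(fm$ratio_feature[1:100], each = 2)
  s2 <- score_distribution_summary(fm2, "ratio_feature")
  h <- tidyr::pivot_wider(s2$histogram, names_from = "group",
                          values_from = "density")
  expect_equal(h$PF1, h$PF2)
})
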