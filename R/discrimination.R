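#' Build the PWM/composition feature matrix over peak-centred windows
#'
#' One row per peak: the sequence is the odd-width window (default
#' 1,001 bp) centred on the peak summit; features are the maximum PWM
#' score ratio per library motif plus the 12 composition rates (2
#' mononucleotide + 10 dinucleotide classes), so a 550-PWM library yields
#' 662 feature columns. Peaks whose window leaves the contig are dropped
#' with a warning.
#'
#' @param peaks A peak tibble (`chrom`, `start`, `end`; uses `summit`
#'   when present, else the interval midpoint). A `label` and/or
#'   `response` column is carried through.
#' @param genome Named character vector of contig sequences.
#' @param pwms A named list of `pwm` objects (the motif library).
#' @param window Window width in bases; must be odd (default 1001).
#' @return A tibble `peak_id, [label], [response], <features...>` with the
#'   feature column names stored in `attr(, "feature_names")`.
#' @export
build_feature_matrix <- function(peaks, genome, pwms, window = 1001) {
  check_intervals(peaks)
  if (length(pwms) == 0) stop("empty PWM library", call. = FALSE)
  if (window %% 2 != 1) stop("window width must be odd", call. = FALSE)
  if (is.null(names(pwms))) {
    names(pwms) <- vapply(pwms, function(p) p$id, character(1))
  }
  peaks <- tibble::as_tibble(peaks)
  summit <- if ("summit" %in% names(peaks) && !anyNA(peaks$summit)) {
    peaks$summit
  } else {
    (peaks$start + peaks$end) %/% 2L
  }
  half <- (window - 1L) %/% 2L
  w_start <- summit - half
  w_end <- summit + half + 1L
  contig_len <- nchar(genome)[peaks$chrom]
  keep <- !is.na(contig_len) & w_start >= 0 & w_end <= contig_len
  if (any(!keep)) {
    warning(sum(!keep), " peak(s) dropped: window outside contig",
            call. = FALSE)
  }
  peaks <- peaks[keep, , drop = FALSE]
  w_start <- w_start[keep]
  w_end <- w_end[keep]
  seqs <- vapply(seq_len(nrow(peaks)), function(i) {
    extract_sequence(genome, peaks$chrom[i], w_start[i], w_end[i])
  }, character(1))
  pwm_feats <- vapply(pwms, function(p) {
    vapply(seqs, max_score_ratio, numeric(1), x = p, USE.NAMES = FALSE)
  }, numeric(length(seqs)))
  if (length(seqs) == 1) pwm_feats <- matrix(pwm_feats, nrow = 1,
                                             dimnames = list(NULL,
                                                             names(pwms)))
  comp_feats <- t(vapply(seqs, composition_features, numeric(12),
                         USE.NAMES = FALSE))
  colnames(comp_feats) <- names(composition_features("ACGT"))
  feats <- cbind(pwm_feats, comp_feats)
  out <- tibble::tibble(
    peak_id = if ("name" %in% names(peaks)) peaks$name
              else paste0("peak_", seq_len(nrow(peaks))))
  if ("label" %in% names(peaks)) out$label <- peaks$label
  if ("response" %in% names(peaks)) out$response <- peaks$response
  out <- dplyr::bind_cols(out, tibble::as_tibble(feats,
                                                 .name_repair = "minimal"))
  attr(out, "feature_names") <- colnames(feats)
  out
}

feature_names <- function(fm) {
  fn <- attr(fm, "feature_names")
  if (!is.null(fn)) return(fn)
  setdiff(names(fm), c("peak_id", "label", "response"))
}

#' Balance classes by downsampling the majority class
#'
#' Subsamples every class without replacement to the minority-class size,
#' reproducibly under the seed — the "equal number of sequences per class"
#' step preceding classification.
#'
#' @param fm A labelled feature matrix.
#' @param seed Integer seed.
#' @return The balanced feature matrix (row order: original order within
#'   the kept rows).
#' @export
balance_classes <- function(fm, seed) {
  if (!"label" %in% names(fm)) stop("feature matrix has no label column",
                                    call. = FALSE)
  tab <- table(fm$label)
  if (length(tab) < 2) stop("need at least two classes to balance",
                            call. = FALSE)
  n_min <- min(tab)
  keep <- withr::with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(fm)), fm$label), function(idx) {
      if (length(idx) > n_min) sample(idx, n_min) else idx
    }))
  })
  out <- fm[sort(keep), , drop = FALSE]
  attr(out, "feature_names") <- feature_names(fm)
  out
}

#' Area under the ROC curve (midrank ties)
#'
#' Mann-Whitney formulation with average ranks for ties.
#'
#' @param scores Numeric prediction scores.
#' @param positive Logical vector: `TRUE` for the positive class.
#' @return AUC in `[0, 1]`.
#' @export
auc_midrank <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  positive <- as.logical(positive)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) stop("need both classes to compute AUC",
                               call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# stratified 70/30 split; returns logical is_train
.stratified_split <- function(strata, train_fraction, seed) {
  withr::with_seed(seed, {
    is_train <- logical(length(strata))
    for (idx in split(seq_along(strata), strata)) {
      n_tr <- round(train_fraction * length(idx))
      n_tr <- max(1L, min(length(idx) - 1L, n_tr))
      is_train[sample(idx, n_tr)] <- TRUE
    }
    is_train
  })
}

# standardize columns using training-row means/sds; drop sd-0 columns
.standardize <- function(x, is_train) {
  mu <- colMeans(x[is_train, , drop = FALSE])
  sd <- apply(x[is_train, , drop = FALSE], 2, stats::sd)
  keep <- sd > 0
  if (any(!keep)) {
    warning(sum(!keep), " constant feature(s) dropped: ",
            paste(utils::head(colnames(x)[!keep], 5), collapse = ", "),
            call. = FALSE)
  }
  x <- sweep(sweep(x[, keep, drop = FALSE], 2, mu[keep]), 2, sd[keep], "/")
  list(x = x, mu = mu[keep], sd = sd[keep])
}

# 100 log-spaced lambdas from lambda_max down to lambda_max * 1e-4
.lambda_grid <- function(x, y, family) {
  yc <- if (family == "binomial") y - mean(y) else y - mean(y)
  lmax <- max(abs(crossprod(x, yc))) / nrow(x)
  lmax <- max(lmax, 1e-6)
  exp(seq(log(lmax), log(lmax * 1e-4), length.out = 100))
}

.penalized_fit <- function(fm, y, family, seed, cv_folds, train_fraction,
                           strata) {
  fn <- feature_names(fm)
  x <- as.matrix(fm[, fn, drop = FALSE])
  is_train <- .stratified_split(strata, train_fraction, seed)
  std <- .standardize(x, is_train)
  x_tr <- std$x[is_train, , drop = FALSE]
  x_te <- std$x[!is_train, , drop = FALSE]
  lambda <- .lambda_grid(x_tr, y[is_train], family)
  foldid <- withr::with_seed(seed + 1L, {
    f <- integer(sum(is_train))
    for (idx in split(seq_along(f), strata[is_train])) {
      f[idx] <- sample(rep_len(seq_len(cv_folds), length(idx)))
    }
    f
  })
  cvfit <- glmnet::cv.glmnet(x_tr, y[is_train], family = family,
                             lambda = lambda, foldid = foldid,
                             standardize = FALSE)
  pred <- as.numeric(stats::predict(cvfit, newx = x_te,
                                    s = "lambda.min", type = "response"))
  beta <- as.matrix(stats::coef(cvfit, s = "lambda.min"))
  coefs <- tibble::tibble(feature = rownames(beta),
                          coefficient = as.numeric(beta))
  coefs <- coefs[coefs$feature != "(Intercept)", , drop = FALSE]
  list(cvfit = cvfit, is_train = is_train, pred = pred,
       coefficients = coefs, lambda_min = cvfit$lambda.min,
       standardization = std[c("mu", "sd")])
}

#' Fit the L1-penalised binding-preference classifier
#'
#' Implements the evaluation protocol for discriminating the two
#' preferential peak classes from sequence features: a seeded, stratified
#' 70/30 train/test split; features standardised on the training rows;
#' an L1-penalised logistic model fit on the training rows with the
#' penalty weight chosen by 10-fold cross-validation (`lambda.min`, folds
#' drawn only from the training split); AUC computed from held-out
#' predicted probabilities with midrank tie handling. Coefficients are
#' reported on the standardised scale at the selected penalty; positive
#' coefficients point toward `positive_class`.
#'
#' @param fm A balanced, labelled feature matrix ([build_feature_matrix()]
#'   then [balance_classes()]).
#' @param seed Integer seed (split, folds).
#' @param cv_folds Number of CV folds (default 10).
#' @param train_fraction Training fraction (default 0.7).
#' @param positive_class Class coded 1; default `"PF1"` when present, else
#'   the alphabetically first label. Flipping the encoding flips all
#'   coefficient signs.
#' @return A `binding_fit` object; see [tidy.binding_fit()] /
#'   [glance.binding_fit()].
#' @export
fit_classifier <- function(fm, seed, cv_folds = 10, train_fraction = 0.7,
                           positive_class = NULL) {
  if (!"label" %in% names(fm)) stop("feature matrix has no label column",
                                    call. = FALSE)
  classes <- sort(unique(fm$label))
  if (length(classes) != 2) stop("classification needs exactly 2 classes",
                                 call. = FALSE)
  if (is.null(positive_class)) {
    positive_class <- if ("PF1" %in% classes) "PF1" else classes[1]
  }
  y <- as.numeric(fm$label == positive_class)
  fit <- .penalized_fit(fm, y, "binomial", seed, cv_folds, train_fraction,
                        strata = fm$label)
  auc <- auc_midrank(fit$pred, y[!fit$is_train] == 1)
  structure(list(task = "classification",
                 model = fit$cvfit,
                 auc = auc,
                 coefficients = fit$coefficients,
                 lambda_min = fit$lambda_min,
                 is_train = fit$is_train,
                 seed = seed,
                 positive_class = positive_class,
                 predictions = tibble::tibble(
                   peak_id = fm$peak_id[!fit$is_train],
                   label = fm$label[!fit$is_train],
                   prob = fit$pred),
                 standardization = fit$standardization),
            class = "binding_fit")
}

#' Fit the L1-penalised signal-ratio regressor
#'
#' Models the per-peak log10 signal ratio between the two factors at
#' shared sites from the same features, with the same split and
#' cross-validation protocol as [fit_classifier()]. Evaluation is the
#' Pearson correlation between predicted and observed ratios on the
#' held-out rows, with its p-value.
#'
#' @param fm A feature matrix with a finite `response` column (rows with
#'   non-finite response are dropped with a warning).
#' @inheritParams fit_classifier
#' @return A `binding_fit` object with `pearson_r` and `p_value`.
#' @export
fit_ratio_regressor <- function(fm, seed, cv_folds = 10,
                                train_fraction = 0.7) {
  if (!"response" %in% names(fm)) {
    stop("feature matrix has no response column", call. = FALSE)
  }
  ok <- is.finite(fm$response)
  if (any(!ok)) {
    warning(sum(!ok), " row(s) with non-finite response dropped",
            call. = FALSE)
    fn <- feature_names(fm)
    fm <- fm[ok, , drop = FALSE]
    attr(fm, "feature_names") <- fn
  }
  if (stats::sd(fm$response) == 0) stop("constant response", call. = FALSE)
  strata <- cut(rank(fm$response, ties.method = "first"),
                breaks = min(4, nrow(fm)), labels = FALSE)
  fit <- .penalized_fit(fm, fm$response, "gaussian", seed, cv_folds,
                        train_fraction, strata = strata)
  obs <- fm$response[!fit$is_train]
  r <- stats::cor(fit$pred, obs)
  p <- if (stats::sd(fit$pred) == 0) 1 else
    stats::cor.test(fit$pred, obs)$p.value
  if (stats::sd(fit$pred) == 0) r <- 0
  structure(list(task = "regression",
                 model = fit$cvfit,
                 pearson_r = r,
                 p_value = p,
                 coefficients = fit$coefficients,
                 lambda_min = fit$lambda_min,
                 is_train = fit$is_train,
                 seed = seed,
                 predictions = tibble::tibble(
                   peak_id = fm$peak_id[!fit$is_train],
                   observed = obs, predicted = fit$pred),
                 standardization = fit$standardization),
            class = "binding_fit")
}

#' @exportS3Method base::print
print.binding_fit <- function(x, ...) {
  cat("<binding_fit> ", x$task, "\n", sep = "")
  if (x$task == "classification") {
    cat("  test AUC: ", round(x$auc, 3), " (positive class ",
        x$positive_class, ")\n", sep = "")
  } else {
    cat("  test Pearson r: ", round(x$pearson_r, 3),
        " (p = ", format(x$p_value, digits = 3), ")\n", sep = "")
  }
  cat("  lambda.min: ", format(x$lambda_min, digits = 4), "; ",
      sum(x$coefficients$coefficient != 0), " features selected\n", sep = "")
  invisible(x)
}

#' Tidy the coefficients of a binding fit
#'
#' @param x A `binding_fit`.
#' @param ... Unused.
#' @return A tibble `feature, coefficient` (standardised scale, selected
#'   penalty; zeros included).
#' @export
tidy.binding_fit <- function(x, ...) x$coefficients

#' One-row summary of a binding fit
#'
#' @param x A `binding_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the task, held-out metric, selected
#'   penalty and sizes.
#' @export
glance.binding_fit <- function(x, ...) {
  tibble::tibble(
    task = x$task,
    auc = if (x$task == "classification") x$auc else NA_real_,
    pearson_r = if (x$task == "regression") x$pearson_r else NA_real_,
    p_value = if (x$task == "regression") x$p_value else NA_real_,
    lambda_min = x$lambda_min,
    n_train = sum(x$is_train),
    n_test = sum(!x$is_train),
    n_selected = sum(x$coefficients$coefficient != 0))
}

#' Top coefficients of a binding fit
#'
#' The `k` features with the largest absolute coefficients at the selected
#' penalty. For classification, positive coefficients point toward the
#' fit's `positive_class` and negative ones toward the other class (so the
#' sign convention flips if the class encoding flips).
#'
#' @param x A `binding_fit`.
#' @param k Number of features (default 10); fewer are returned when fewer
#'   are nonzero.
#' @return A tibble `feature, coefficient, class` ranked by
#'   `|coefficient|` (`class` only for classification fits).
#' @export
top_coefficients <- function(x, k = 10) {
  stopifnot(inherits(x, "binding_fit"))
  nz <- x$coefficients[x$coefficients$coefficient != 0, , drop = FALSE]
  nz <- nz[order(-abs(nz$coefficient)), , drop = FALSE]
  out <- utils::head(nz, k)
  if (x$task == "classification") {
    other <- setdiff(unique(c(x$predictions$label, x$positive_class)),
                     x$positive_class)
    out$class <- ifelse(out$coefficient > 0, x$positive_class,
                        if (length(other) == 1) other else "other")
  }
  out
}

#' AUC of a single raw feature
#'
#' Ranks the held-out rows of the paired classifier run by the raw feature
#' value, with the ranking direction chosen on the training rows (so a
#' feature enriched in either class scores above 0.5). No model is fit —
#' this measures how far one variable alone goes.
#'
#' @param fm The feature matrix used for the classifier fit.
#' @param feature Feature column name.
#' @param fit The paired `binding_fit` (reuses its split and positive
#'   class); or `NULL` with `seed` given to recompute the same split.
#' @param seed Seed used if `fit` is `NULL`.
#' @param train_fraction Split fraction used if `fit` is `NULL`.
#' @return The held-out AUC.
#' @export
single_feature_auc <- function(fm, feature, fit = NULL, seed = NULL,
                               train_fraction = 0.7) {
  if (!feature %in% names(fm)) {
    stop(glue::glue("unknown feature '{feature}'"), call. = FALSE)
  }
  if (!"label" %in% names(fm)) stop("feature matrix has no label column",
                                    call. = FALSE)
  if (is.null(fit)) {
    if (is.null(seed)) stop("give either fit or seed", call. = FALSE)
    is_train <- .stratified_split(fm$label, train_fraction, seed)
    positive_class <- if ("PF1" %in% fm$label) "PF1" else
      sort(unique(fm$label))[1]
  } else {
    is_train <- fit$is_train
    positive_class <- fit$positive_class
  }
  v <- fm[[feature]]
  pos <- fm$label == positive_class
  dir_auc <- auc_midrank(v[is_train], pos[is_train])
  sign <- if (dir_auc >= 0.5) 1 else -1
  auc_midrank(sign * v[!is_train], pos[!is_train])
}

#' Histogram summary of a feature's distribution per group
#'
#' Normalised histograms of a feature restricted to a stated score range
#' (default the high-score window 0.85–1 used to compare motif-score
#' distributions between peak classes), with per-group medians.
#'
#' @param fm A feature matrix.
#' @param feature Feature column name.
#' @param group_col Grouping column (default `"label"`).
#' @param breaks Fixed bin edges (default `seq(0.85, 1, by = 0.01)`).
#' @return A list with `histogram` (tibble `group, bin_left, bin_right,
#'   density`; densities sum to 1 within group over nonempty groups) and
#'   `medians` (tibble `group, median`, median of in-range values).
#' @export
score_distribution_summary <- function(fm, feature, group_col = "label",
                                       breaks = seq(0.85, 1, by = 0.01)) {
  if (!feature %in% names(fm)) {
    stop(glue::glue("unknown feature '{feature}'"), call. = FALSE)
  }
  groups <- unique(fm[[group_col]])
  hist_tbl <- purrr::map_dfr(groups, function(g) {
    v <- fm[[feature]][fm[[group_col]] == g]
    v <- v[v >= breaks[1] & v <= breaks[length(breaks)]]
    if (length(v) == 0) {
      return(tibble::tibble(group = g, bin_left = numeric(),
                            bin_right = numeric(), density = numeric()))
    }
    h <- graphics::hist(v, breaks = breaks, plot = FALSE,
                        include.lowest = TRUE)
    tibble::tibble(group = g, bin_left = utils::head(breaks, -1),
                   bin_right = breaks[-1], density = h$counts / length(v))
  })
  medians <- purrr::map_dfr(groups, function(g) {
    v <- fm[[feature]][fm[[group_col]] == g]
    v <- v[v >= breaks[1] & v <= breaks[length(breaks)]]
    tibble::tibble(group = g,
                   median = if (length(v)) stats::median(v) else NA_real_)
  })
  list(histogram = hist_tbl, medians = medians)
}
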