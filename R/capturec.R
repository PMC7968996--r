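#' Validate a viewpoint interaction profile
#'
#' A viewpoint profile is a tibble of restriction fragments on the
#' viewpoint chromosome (`chrom`, `start`, `end`, sorted, non-overlapping)
#' with one count column per replicate (names starting `rep`) holding the
#' unique-interaction counts of each fragment with the captured promoter
#' fragment (the viewpoint).
#'
#' @param profile The profile tibble.
#' @return `profile`, invisibly.
#' @export
check_profile <- function(profile) {
  check_intervals(profile, require_sorted = TRUE)
  reps <- rep_cols(profile)
  if (length(reps) == 0) {
    stop("profile needs at least one replicate column (rep1, rep2, ...)",
         call. = FALSE)
  }
  if (length(unique(profile$chrom)) > 1) {
    stop("a viewpoint profile lives on a single chromosome", call. = FALSE)
  }
  if (nrow(profile) > 1 &&
      any(profile$start[-1] < profile$end[-nrow(profile)])) {
    stop("fragments must be non-overlapping", call. = FALSE)
  }
  for (rc in reps) {
    if (any(profile[[rc]] < 0)) {
      stop(glue::glue("negative counts in {rc}"), call. = FALSE)
    }
  }
  invisible(profile)
}

rep_cols <- function(profile) {
  grep("^rep", names(profile), value = TRUE)
}

# index of the fragment containing the viewpoint position
.vp_index <- function(profile, viewpoint_pos) {
  i <- which(profile$start <= viewpoint_pos & profile$end > viewpoint_pos)
  if (length(i) != 1) {
    stop("viewpoint position falls in no (or several) fragment(s)",
         call. = FALSE)
  }
  i
}

# fragments excluded around the viewpoint (undigested/self-ligation zone)
.excluded <- function(profile, viewpoint_pos, exclusion_zone) {
  vp <- .vp_index(profile, viewpoint_pos)
  seq_len(nrow(profile)) %in%
    seq(max(1, vp - exclusion_zone), min(nrow(profile), vp + exclusion_zone))
}

#' Normalise a viewpoint profile across replicates
#'
#' Scales each replicate so that its total count over fragments outside
#' the viewpoint exclusion zone equals the replicate-mean total, putting
#' replicates of different sequencing depth on a common scale. Counts
#' become reals; within-replicate ratios are preserved.
#'
#' @param profile A viewpoint profile tibble.
#' @param viewpoint_pos Viewpoint position (bp) on the profile chromosome.
#' @param exclusion_zone Fragments skipped on each side of the viewpoint
#'   fragment (default 2).
#' @return The profile with scaled replicate columns.
#' @export
normalize_profile <- function(profile, viewpoint_pos, exclusion_zone = 2) {
  check_profile(profile)
  reps <- rep_cols(profile)
  excl <- .excluded(profile, viewpoint_pos, exclusion_zone)
  totals <- vapply(reps, function(rc) sum(profile[[rc]][!excl]), numeric(1))
  zero <- totals == 0
  if (any(zero)) {
    stop("replicate(s) with zero total counts: ",
         paste(reps[zero], collapse = ", "), call. = FALSE)
  }
  target <- mean(totals)
  out <- tibble::as_tibble(profile)
  for (i in seq_along(reps)) {
    out[[reps[i]]] <- out[[reps[i]]] * (target / totals[i])
  }
  out
}

#' Fit a distance-decay interaction background
#'
#' On each side of the viewpoint independently, the expected count per
#' fragment is the non-increasing isotonic fit of the replicate-mean count
#' against distance from the viewpoint — a distribution-free stand-in for
#' a parametric distance-decay model. Sides with fewer than `min_side`
#' fragments are skipped with a warning (expected stays `NA`).
#'
#' @param profile A normalised viewpoint profile.
#' @param viewpoint_pos Viewpoint position (bp).
#' @param exclusion_zone Fragments skipped around the viewpoint.
#' @param min_side Minimum fragments per side for a stable fit
#'   (default 20).
#' @return The profile with added `dist` (midpoint distance to the
#'   viewpoint, bp), `mean_count` and `expected` columns.
#' @export
background_fit <- function(profile, viewpoint_pos, exclusion_zone = 2,
                           min_side = 20) {
  check_profile(profile)
  reps <- rep_cols(profile)
  out <- tibble::as_tibble(profile)
  mid <- (out$start + out$end) / 2
  out$dist <- abs(mid - viewpoint_pos)
  out$mean_count <- rowMeans(as.matrix(out[, reps, drop = FALSE]))
  excl <- .excluded(out, viewpoint_pos, exclusion_zone)
  out$expected <- NA_real_
  vp <- .vp_index(out, viewpoint_pos)
  for (side in c("left", "right")) {
    idx <- if (side == "left") which(seq_len(nrow(out)) < vp & !excl)
           else which(seq_len(nrow(out)) > vp & !excl)
    if (length(idx) < min_side) {
      warning(glue::glue("{side} side has {length(idx)} fragments ",
                         "(< {min_side}); background not fitted"),
              call. = FALSE)
      next
    }
    d <- out$dist[idx]
    y <- out$mean_count[idx]
    iso_fit <- function(dd, yy) {
      o <- order(dd)
      f <- numeric(length(dd))
      # non-increasing fit = negated non-decreasing isotonic regression
      f[o] <- pmax(0, -stats::isoreg(dd[o], -yy[o])$yf)
      f
    }
    e1 <- iso_fit(d, y)
    # two-pass robustification: refit with strong positive outliers
    # (candidate interactions) masked, so they do not inflate the
    # background they are tested against
    r1 <- y - e1
    mad_r <- stats::mad(r1)
    mask <- r1 > 3 * max(mad_r, 1e-9)
    if (any(mask) && sum(!mask) >= min_side) {
      e2 <- iso_fit(d[!mask], y[!mask])
      exp_side <- numeric(length(idx))
      exp_side[!mask] <- e2
      exp_side[mask] <- stats::approx(d[!mask], e2, xout = d[mask],
                                      rule = 2, ties = mean)$y
      out$expected[idx] <- exp_side
    } else {
      out$expected[idx] <- e1
    }
  }
  out
}

#' Parameters of the promoter-interacting-region caller
#'
#' @param alpha_fdr Benjamini-Hochberg FDR level (default 0.1).
#' @param w_size Odd window size, in fragments, of the smoothed residual
#'   statistic (default 5).
#' @param q_wr Background-ratio multiplier: a fragment is callable only if
#'   its count is at least `q_wr` times the expected background in every
#'   replicate (default 1).
#' @param n_permutations Circular-shift permutations for the empirical
#'   null (default 500; fewer than 100 is refused by the caller).
#' @param exclusion_zone Fragments skipped around the viewpoint
#'   (default 2).
#' @return A `pir_params` list.
#' @export
pir_params <- function(alpha_fdr = 0.1, w_size = 5, q_wr = 1,
                       n_permutations = 500, exclusion_zone = 2) {
  if (alpha_fdr <= 0 || alpha_fdr >= 1) {
    stop("alpha_fdr must be in (0, 1)", call. = FALSE)
  }
  if (w_size < 1 || w_size %% 2 != 1) {
    stop("w_size must be odd and >= 1", call. = FALSE)
  }
  if (q_wr < 0) stop("q_wr must be >= 0", call. = FALSE)
  structure(list(alpha_fdr = alpha_fdr, w_size = w_size, q_wr = q_wr,
                 n_permutations = n_permutations,
                 exclusion_zone = exclusion_zone),
            class = "pir_params")
}

#' Call promoter-interacting regions from a viewpoint profile
#'
#' A simplified, self-contained PIR caller keeping the three published
#' parameter semantics meaningful: per-fragment residuals against the
#' isotonic distance-decay background are smoothed with a centred
#' `w_size`-fragment window; an empirical null is built from seeded
#' circular shifts of the residual vector; one-sided permutation p-values
#' (add-one corrected) are Benjamini-Hochberg adjusted at `alpha_fdr`; a
#' fragment is called only if, additionally, its count is at least
#' `q_wr x expected` in every replicate; and runs of adjacent called
#' fragments merge into one region.
#'
#' @param profile A profile from [background_fit()] (normalised, with
#'   `expected`).
#' @param viewpoint_pos Viewpoint position (bp).
#' @param params A [pir_params()] list.
#' @param seed Integer seed for the permutations.
#' @return A tibble of PIRs: `chrom, start, end, n_fragments,
#'   mean_enrichment` (mean observed/expected over the merged fragments)
#'   and `distance` (viewpoint midpoint to PIR midpoint, bp).
#' @export
call_pirs <- function(profile, viewpoint_pos, params = pir_params(),
                      seed = 1L) {
  stopifnot(inherits(params, "pir_params"))
  if (params$n_permutations < 100) {
    stop("n_permutations must be >= 100", call. = FALSE)
  }
  if (!all(c("expected", "mean_count") %in% names(profile))) {
    stop("run background_fit() before call_pirs()", call. = FALSE)
  }
  reps <- rep_cols(profile)
  callable <- which(!is.na(profile$expected))
  empty <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), n_fragments = integer(),
                          mean_enrichment = numeric(), distance = numeric())
  if (length(callable) < params$w_size) return(empty)
  resid <- profile$mean_count[callable] - profile$expected[callable]
  w <- params$w_size
  wstat <- as.numeric(stats::filter(resid, rep(1 / w, w), sides = 2))
  null_w <- withr::with_seed(seed, {
    # random permutations of the residual vector: the null keeps the
    # marginal residual distribution but no spatial coherence, which is
    # what the window statistic is testing for
    unlist(lapply(seq_len(params$n_permutations), function(s) {
      r <- sample(resid)
      v <- as.numeric(stats::filter(r, rep(1 / w, w), sides = 2))
      v[!is.na(v)]
    }))
  })
  pvals <- rep(NA_real_, length(wstat))
  ok <- !is.na(wstat)
  pvals[ok] <- vapply(wstat[ok], function(W) {
    (sum(null_w >= W) + 1) / (length(null_w) + 1)
  }, numeric(1))
  padj <- rep(NA_real_, length(pvals))
  padj[ok] <- stats::p.adjust(pvals[ok], method = "BH")
  sig <- !is.na(padj) & padj <= params$alpha_fdr
  # per-replicate consistency: count >= q_wr * expected in every replicate
  cons <- rep(TRUE, length(callable))
  for (rc in reps) {
    cons <- cons & (profile[[rc]][callable] >=
                      params$q_wr * profile$expected[callable])
  }
  called <- callable[sig & cons]
  if (length(called) == 0) return(empty)
  runs <- cumsum(c(TRUE, diff(called) != 1))
  vp_mid <- viewpoint_pos
  purrr::map_dfr(split(called, runs), function(idx) {
    tibble::tibble(
      chrom = profile$chrom[idx[1]],
      start = min(profile$start[idx]),
      end = max(profile$end[idx]),
      n_fragments = length(idx),
      mean_enrichment = mean(profile$mean_count[idx] /
                               pmax(profile$expected[idx], 1e-9)),
      distance = abs((min(profile$start[idx]) + max(profile$end[idx])) / 2 -
                       vp_mid))
  })
}

#' Summary statistics over PIRs of many viewpoints
#'
#' @param pirs A tibble of PIRs with a `viewpoint` column identifying the
#'   viewpoint each PIR belongs to and a `side` or signed position; if a
#'   `vp_pos` column is present, sides are derived from PIR midpoint vs
#'   viewpoint position.
#' @return A list with `per_viewpoint` (tibble `viewpoint, n_pirs,
#'   layout` where layout is `upstream`/`downstream`/`both`),
#'   `n_pirs_median`, `distance_median` (over all PIRs, bp) and
#'   `n_pirs_range`.
#' @export
pir_stats <- function(pirs) {
  stopifnot(all(c("viewpoint", "distance") %in% names(pirs)))
  if (nrow(pirs) == 0) {
    return(list(per_viewpoint = tibble::tibble(viewpoint = character(),
                                               n_pirs = integer(),
                                               layout = character()),
                n_pirs_median = NA_real_, distance_median = NA_real_,
                n_pirs_range = c(NA_real_, NA_real_)))
  }
  has_side <- "vp_pos" %in% names(pirs)
  per_vp <- dplyr::group_by(tibble::as_tibble(pirs), .data$viewpoint) |>
    dplyr::summarise(
      n_pirs = dplyr::n(),
      layout = if (!has_side) NA_character_ else {
        mids <- (.data$start + .data$end) / 2
        up <- any(mids < .data$vp_pos)
        down <- any(mids > .data$vp_pos)
        if (up && down) "both" else if (up) "upstream" else "downstream"
      },
      .groups = "drop")
  list(per_viewpoint = per_vp,
       n_pirs_median = stats::median(per_vp$n_pirs),
       distance_median = stats::median(pirs$distance),
       n_pirs_range = range(per_vp$n_pirs))
}

#' Nested annotation of PIRs with open chromatin, elements and TF binding
#'
#' Computes the three nested fractions: the fraction of PIRs containing at
#' least one open-chromatin (ATAC) peak; the fraction of ATAC peaks inside
#' PIRs that carry candidate-active-enhancer marks; and the fraction of
#' the latter bound by the transcription factor. Each annotated open site
#' also records its CTCF co-occurrence when a CTCF peak set is given.
#'
#' @param pirs A PIR tibble (`chrom`, `start`, `end`).
#' @param atac Open-chromatin peak tibble.
#' @param elements Element tibble from [annotate_elements()].
#' @param tf_peaks Factor peak tibble.
#' @param ctcf Optional CTCF peak tibble.
#' @return A list with `fractions` (tibble `level, numerator, denominator,
#'   fraction`) and `sites` (the per-ATAC-peak annotation table).
#'   Fractions are `NA` when their denominator is empty.
#' @export
annotate_pirs <- function(pirs, atac, elements, tf_peaks, ctcf = NULL) {
  pirs <- sort_intervals(pirs)
  atac <- sort_intervals(atac)
  if (nrow(pirs) == 0) {
    return(list(fractions = tibble::tibble(
      level = c("pir_with_atac", "atac_in_pir_with_cae",
                "cae_atac_tf_bound"),
      numerator = NA_integer_, denominator = c(0L, 0L, 0L),
      fraction = NA_real_), sites = tibble::tibble()))
  }
  ov <- intersect_intervals(pirs, atac)
  pir_with_atac <- nrow(dplyr::distinct(
    ov[!is.na(ov$overlap), , drop = FALSE],
    .data$chrom, .data$start, .data$end))
  atac_in_pir <- if (nrow(atac) == 0) atac else {
    hits <- intersect_intervals(atac, pirs)
    dplyr::distinct(hits[!is.na(hits$overlap), c("chrom", "start", "end")])
  }
  cae <- sort_intervals(elements[elements$state == "cAE", , drop = FALSE])
  sites <- atac_in_pir
  if (nrow(sites) > 0) {
    sites$in_cae <- overlap_flag(sites, cae)
    sites$tf_bound <- overlap_flag(sites, sort_intervals(tf_peaks))
    if (!is.null(ctcf)) sites$ctcf <- overlap_flag(sites,
                                                   sort_intervals(ctcf))
  }
  n_atac_in_pir <- nrow(sites)
  n_cae <- if (n_atac_in_pir) sum(sites$in_cae) else 0L
  n_tf <- if (n_cae) sum(sites$in_cae & sites$tf_bound) else 0L
  fractions <- tibble::tibble(
    level = c("pir_with_atac", "atac_in_pir_with_cae", "cae_atac_tf_bound"),
    numerator = c(pir_with_atac, n_cae, n_tf),
    denominator = c(nrow(pirs), n_atac_in_pir, n_cae),
    fraction = ifelse(c(nrow(pirs), n_atac_in_pir, n_cae) > 0,
                      c(pir_with_atac, n_cae, n_tf) /
                        c(nrow(pirs), n_atac_in_pir, n_cae), NA_real_))
  list(fractions = fractions, sites = sites)
}

# TRUE per x interval overlapping >= 1 y interval
overlap_flag <- function(x, y) {
  if (nrow(x) == 0) return(logical(0))
  if (nrow(y) == 0) return(rep(FALSE, nrow(x)))
  ov <- intersect_intervals(x, y)
  key <- paste(x$chrom, x$start, x$end)
  hit_key <- unique(paste(ov$chrom, ov$start, ov$end)[!is.na(ov$overlap)])
  key %in% hit_key
}

#' Difference between two conditions' viewpoint profiles
#'
#' Per-fragment difference of replicate-mean normalised counts
#' (`condition a - condition b`); antisymmetric under swapping conditions.
#' Both profiles must share the identical fragment map.
#'
#' @param profile_a,profile_b Normalised viewpoint profiles on the same
#'   fragment map.
#' @return The fragment tibble with a `delta` column.
#' @export
delta_profile <- function(profile_a, profile_b) {
  check_profile(profile_a)
  check_profile(profile_b)
  if (!identical(profile_a[, c("chrom", "start", "end")],
                 profile_b[, c("chrom", "start", "end")])) {
    stop("fragment maps differ between conditions", call. = FALSE)
  }
  mean_a <- rowMeans(as.matrix(profile_a[, rep_cols(profile_a),
                                         drop = FALSE]))
  mean_b <- rowMeans(as.matrix(profile_b[, rep_cols(profile_b),
                                         drop = FALSE]))
  out <- profile_a[, c("chrom", "start", "end")]
  out$delta <- mean_a - mean_b
  out
}
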