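#' Classify two factors' peak sets into preferential and shared sites
#'
#' Overlapping peaks from factor A and factor B (sharing at least one
#' base, transitively) are unified into one record spanning their union and
#' labelled `F1F2` (bound efficiently by both). Peaks of A touching no B
#' peak are `PF1` (preferentially factor A); B-only peaks are `PF2`. The
#' three labels partition the merged union of the inputs.
#'
#' @param peaks_a,peaks_b Called peak tibbles (already thresholded).
#' @param track_a,track_b Optional signal tracks; when given, each
#'   classified peak records both factors' signals (`signal_a`,
#'   `signal_b`, by `stat`), so sub-threshold signal at preferential sites
#'   can be inspected.
#' @param stat Signal statistic passed to [signal_at()] (default `"max"`).
#' @return A sorted tibble `chrom, start, end, label` (+ `summit`,
#'   `signal_a`, `signal_b` when available). The summit of an `F1F2` site
#'   is the summit of its strongest constituent peak, when summits are
#'   present in the inputs.
#' @export
#' @examples
#' a <- intervals("chr1", 0, 100)
#' b <- intervals("chr1", 50, 150)
#' classify_overlap(a, b)  # one F1F2 site spanning 0-150
classify_overlap <- function(peaks_a, peaks_b, track_a = NULL,
                             track_b = NULL, stat = "max") {
  check_intervals(peaks_a)
  check_intervals(peaks_b)
  peaks_a <- sort_intervals(peaks_a)
  peaks_b <- sort_intervals(peaks_b)
  both <- dplyr::bind_rows(
    dplyr::mutate(peaks_a[, intersect(names(peaks_a),
                                      c("chrom", "start", "end", "score",
                                        "summit"))], .src = "a"),
    dplyr::mutate(peaks_b[, intersect(names(peaks_b),
                                      c("chrom", "start", "end", "score",
                                        "summit"))], .src = "b"))
  both <- sort_intervals(both)
  if (nrow(both) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), label = character()))
  }
  pieces <- lapply(split(both, both$chrom), function(bc) {
    # transitive closure of >=1-base overlap: reduce with min.gapwidth = 0
    regions <- IRanges::reduce(.as_iranges(bc), min.gapwidth = 0L)
    hit <- IRanges::findOverlaps(.as_iranges(bc), regions, minoverlap = 1L)
    grp <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
    bc$.grp <- grp
    out <- dplyr::group_by(bc, .data$.grp) |>
      dplyr::summarise(
        chrom = dplyr::first(.data$chrom),
        start = min(.data$start),
        end = max(.data$end),
        label = if (all(.data$.src == "a")) "PF1"
                else if (all(.data$.src == "b")) "PF2" else "F1F2",
        summit = if ("summit" %in% names(bc) && !anyNA(.data$summit)) {
          if ("score" %in% names(bc) && !anyNA(.data$score)) {
            .data$summit[which.max(.data$score)][1]
          } else .data$summit[1]
        } else NA_integer_,
        .groups = "drop")
      out$.grp <- NULL
      out
  })
  out <- sort_intervals(dplyr::bind_rows(pieces))
  if (all(is.na(out$summit))) out$summit <- NULL
  if (!is.null(track_a)) out <- dplyr::rename(
    signal_at(out, track_a, stat = stat), signal_a = "signal")
  if (!is.null(track_b)) out <- dplyr::rename(
    signal_at(out, track_b, stat = stat), signal_b = "signal")
  out
}

#' Signed fold change between two signals
#'
#' The signed-ratio convention: `fc = c/k` when `c >= k`, else `-k/c`,
#' with `c = signal_cond + floor` and `k = signal_ctl + floor`, so
#' magnitudes are always `>= 1`. Categories use an inclusive threshold:
#' `up` when `fc >= threshold`, `down` when `fc <= -threshold`, else
#' `unchanged` — the three region types of the +/-1.5 fold-change rule.
#'
#' @param signal_cond,signal_ctl Non-negative signal vectors.
#' @param threshold Category threshold (`> 1`, default 1.5).
#' @param floor Pseudo-signal added to both sides to stabilise ratios at
#'   weak signals (default 0; collection-level callers use 5% of the
#'   control median).
#' @return A tibble with `signal_cond`, `signal_ctl`, `fc`, `category`.
#' @export
#' @examples
#' fold_change(30, 10)          # fc +3, up
#' fold_change(10, 15)          # fc -1.5, down (inclusive bound)
fold_change <- function(signal_cond, signal_ctl, threshold = 1.5,
                        floor = 0) {
  if (threshold <= 1) stop("threshold must be > 1", call. = FALSE)
  if (any(signal_cond < 0) || any(signal_ctl < 0)) {
    stop("signals must be >= 0", call. = FALSE)
  }
  cc <- signal_cond + floor
  kk <- signal_ctl + floor
  if (any(cc == 0 & kk == 0)) {
    stop("both signals zero with floor 0: set a positive floor",
         call. = FALSE)
  }
  fc <- ifelse(cc >= kk, cc / kk, -kk / cc)
  category <- dplyr::case_when(fc >= threshold ~ "up",
                               fc <= -threshold ~ "down",
                               TRUE ~ "unchanged")
  tibble::tibble(signal_cond = signal_cond, signal_ctl = signal_ctl,
                 fc = fc, category = category)
}

#' Fold-change categories over a set of peaks
#'
#' Convenience wrapper extracting both conditions' signals at each peak and
#' applying [fold_change()]; the default floor is 5% of the median control
#' signal across peaks.
#'
#' @param peaks An interval tibble.
#' @param track_cond,track_ctl Signal tracks for condition and control.
#' @param threshold Category threshold (default 1.5).
#' @param floor Pseudo-signal; `NULL` (default) uses
#'   `0.05 * median(control signal)`.
#' @param stat Signal statistic (default `"max"`).
#' @return `peaks` with `signal_cond`, `signal_ctl`, `fc`, `category`.
#' @export
fold_change_at <- function(peaks, track_cond, track_ctl, threshold = 1.5,
                           floor = NULL, stat = "max") {
  s_cond <- signal_at(peaks, track_cond, stat = stat)$signal
  s_ctl <- signal_at(peaks, track_ctl, stat = stat)$signal
  if (is.null(floor)) floor <- 0.05 * stats::median(s_ctl)
  fc <- fold_change(s_cond, s_ctl, threshold = threshold, floor = floor)
  dplyr::bind_cols(tibble::as_tibble(peaks),
                   fc[, c("signal_cond", "signal_ctl", "fc", "category")])
}

#' Annotate candidate regulatory elements from histone-mark rules
#'
#' Applies the chromatin-state rules for candidate promoters and
#' enhancers: promoter domains are the 3-kb windows centred on TSSs
#' (`TSS +/- 1500` bp), called `cAP` (candidate active promoter) when
#' overlapping an H3K27ac peak and `cIP` otherwise; enhancer candidates
#' are H3K4me1 peaks with all promoter-domain bases subtracted, the
#' surviving pieces becoming `cAE` (candidate active enhancer) when
#' overlapping H3K27ac and `cIE` otherwise. States are mutually exclusive
#' at every base with promoter precedence. "Low H3K27ac content" is
#' operationalised as no overlap with a called H3K27ac peak.
#'
#' @param tss TSS tibble (point intervals or BED6; the TSS position is the
#'   `start` coordinate). Promoter domains are strand-independent.
#' @param k27ac,k4me1 Called histone-mark peak tibbles.
#' @param k4me3 Optional H3K4me3 peaks; reported per element as the
#'   logical `k4me3` column, but never entering the state rules.
#' @param promoter_halfwidth Half-width of the promoter domain (default
#'   1500 bases, giving the 3-kb domain).
#' @return A sorted element tibble `chrom, start, end, state` (+ `k4me3`).
#' @export
annotate_elements <- function(tss, k27ac, k4me1, k4me3 = NULL,
                              promoter_halfwidth = 1500) {
  check_intervals(tss, require_sorted = TRUE)
  check_intervals(k27ac, require_sorted = TRUE)
  check_intervals(k4me1, require_sorted = TRUE)
  proms <- tibble::tibble(
    chrom = tss$chrom,
    start = pmax(0L, as.integer(tss$start - promoter_halfwidth)),
    end = as.integer(tss$start + promoter_halfwidth))
  # overlapping promoter domains (close TSSs) are unified so element
  # states stay base-disjoint; touching domains stay separate
  proms <- sort_intervals(proms)
  if (nrow(proms) > 1) {
    pieces <- lapply(split(proms, proms$chrom), function(pc) {
      .from_iranges(IRanges::reduce(.as_iranges(pc), min.gapwidth = 0L),
                    pc$chrom[[1]])
    })
    proms <- sort_intervals(dplyr::bind_rows(pieces))
  }
  prom_states <- if (nrow(proms) > 0) {
    ov <- intersect_intervals(proms, k27ac)
    hit <- dplyr::summarise(
      dplyr::group_by(ov, .data$chrom, .data$start, .data$end),
      has = any(!is.na(.data$overlap)), .groups = "drop")
    dplyr::mutate(hit, state = ifelse(.data$has, "cAP", "cIP"),
                  has = NULL)
  } else {
    tibble::tibble(chrom = character(), start = integer(),
                   end = integer(), state = character())
  }
  enh <- subtract_intervals(k4me1, proms)
  enh_states <- if (nrow(enh) > 0) {
    ov <- intersect_intervals(enh, k27ac)
    hit <- dplyr::summarise(
      dplyr::group_by(ov, .data$chrom, .data$start, .data$end),
      has = any(!is.na(.data$overlap)), .groups = "drop")
    dplyr::mutate(hit, state = ifelse(.data$has, "cAE", "cIE"),
                  has = NULL)
  } else {
    tibble::tibble(chrom = character(), start = integer(),
                   end = integer(), state = character())
  }
  out <- sort_intervals(dplyr::bind_rows(prom_states, enh_states))
  if (!is.null(k4me3)) {
    ov <- intersect_intervals(out, sort_intervals(k4me3))
    flags <- dplyr::summarise(
      dplyr::group_by(ov, .data$chrom, .data$start, .data$end),
      k4me3 = any(!is.na(.data$overlap)), .groups = "drop")
    out <- dplyr::left_join(out, flags, by = c("chrom", "start", "end"))
  }
  out
}

#' Fraction of query items overlapping target sets
#'
#' For each query label and each target set, the fraction of query
#' intervals overlapping at least one target interval — the statistic
#' behind "x% of peaks lie in open chromatin" style summaries. Labels with
#' no query items report `NA`, not 0.
#'
#' @param query An interval tibble with a `label` column (peak classes or
#'   element states). A missing `label` column treats all rows as one
#'   group `"all"`.
#' @param targets A named list of interval tibbles.
#' @return A tibble `label, target, n, n_overlapping, fraction`.
#' @export
overlap_fractions <- function(query, targets) {
  check_intervals(query)
  if (!is.list(targets) || is.data.frame(targets)) targets <- list(targets)
  if (is.null(names(targets)) || any(!nzchar(names(targets)))) {
    names(targets) <- paste0("target_", seq_along(targets))
  }
  query <- tibble::as_tibble(query)
  if (!"label" %in% names(query)) query$label <- "all"
  labels <- unique(query$label)
  query <- sort_intervals(query)
  purrr::map_dfr(names(targets), function(tn) {
    tgt <- sort_intervals(targets[[tn]])
    purrr::map_dfr(labels, function(lb) {
      q <- query[query$label == lb, , drop = FALSE]
      n <- nrow(q)
      if (n == 0) {
        return(tibble::tibble(label = lb, target = tn, n = 0L,
                              n_overlapping = NA_integer_,
                              fraction = NA_real_))
      }
      ov <- intersect_intervals(q, tgt)
      n_ov <- nrow(dplyr::distinct(
        ov[!is.na(ov$overlap), , drop = FALSE],
        .data$chrom, .data$start, .data$end))
      tibble::tibble(label = lb, target = tn, n = n,
                     n_overlapping = as.integer(n_ov),
                     fraction = n_ov / n)
    })
  })
}
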