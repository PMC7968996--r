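#' Construct an interval tibble
#'
#' Genomic intervals are plain tibbles in the BED dialect: 0-based,
#' half-open `[start, end)` coordinates with required columns `chrom`,
#' `start`, `end` and optional `name`, `score`, `strand`. Every function in
#' the package that consumes intervals takes such a tibble as its first
#' argument and returns one, so calls chain with the pipe.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors; `0 <= start < end`.
#' @param name,score,strand Optional per-interval annotation columns.
#'
#' @return A tibble sorted by `(chrom, start, end)`.
#' @export
#' @examples
#' intervals(c("chr1", "chr1"), c(0L, 100L), c(50L, 200L))
intervals <- function(chrom, start, end, name = NULL, score = NULL,
                      strand = NULL) {
  x <- tibble::tibble(chrom = as.character(chrom),
                      start = as.integer(start),
                      end = as.integer(end))
  if (!is.null(name)) x$name <- as.character(name)
  if (!is.null(score)) x$score <- as.numeric(score)
  if (!is.null(strand)) x$strand <- as.character(strand)
  check_intervals(x)
  sort_intervals(x)
}

#' Validate an interval tibble
#'
#' Checks the structural invariants: required columns present, `start >= 0`,
#' `end > start`, nonempty `chrom`. Called by every interval operation.
#'
#' @param x A data frame of intervals.
#' @param require_sorted If `TRUE`, additionally reject unsorted input.
#' @return `x`, invisibly.
#' @export
check_intervals <- function(x, require_sorted = FALSE) {
  if (!is.data.frame(x)) stop("intervals must be a data frame", call. = FALSE)
  missing_cols <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(missing_cols) > 0) {
    stop("interval tibble lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom) | x$chrom == "")) {
    stop("chrom must be nonempty", call. = FALSE)
  }
  if (any(x$start < 0)) stop("start must be >= 0", call. = FALSE)
  if (any(x$end <= x$start)) {
    stop("end must be > start (0-based half-open intervals)", call. = FALSE)
  }
  if (require_sorted && !is_sorted_intervals(x)) {
    stop("intervals must be sorted by (chrom, start, end); ",
         "call sort_intervals() first", call. = FALSE)
  }
  invisible(x)
}

is_sorted_intervals <- function(x) {
  if (nrow(x) < 2) return(TRUE)
  o <- order(x$chrom, x$start, x$end)
  all(o == seq_len(nrow(x)))
}

#' Sort intervals by (chrom, start, end)
#' @param x An interval tibble.
#' @return The sorted tibble.
#' @export
sort_intervals <- function(x) {
  check_intervals(x)
  dplyr::arrange(x, .data$chrom, .data$start, .data$end)
}

# 0-based half-open tibble -> 1-based closed IRanges (per single chromosome)
.as_iranges <- function(x) {
  IRanges::IRanges(start = x$start + 1L, end = x$end)
}

.from_iranges <- function(ir, chrom) {
  tibble::tibble(chrom = chrom,
                 start = IRanges::start(ir) - 1L,
                 end = IRanges::end(ir))
}

#' Intersect two interval sets
#'
#' Pairs every interval of `a` with each interval of `b` sharing at least
#' one base (half-open semantics: `[0,10)` and `[10,20)` do not overlap).
#' Intervals of `a` with no partner appear once with `NA` partner columns,
#' so the output always has at least one row per `a` interval.
#'
#' @param a,b Sorted interval tibbles.
#' @return A tibble with `a`'s columns plus `start.b`, `end.b` and
#'   `overlap` (overlap width in bases; `NA` where `a` has no partner).
#' @export
#' @examples
#' a <- intervals("chr1", 0, 10)
#' b <- intervals("chr1", 9, 20)
#' intersect_intervals(a, b)
intersect_intervals <- function(a, b) {
  check_intervals(a, require_sorted = TRUE)
  check_intervals(b, require_sorted = TRUE)
  a <- tibble::as_tibble(a)
  a$.row_a <- seq_len(nrow(a))
  pieces <- lapply(split(a, a$chrom), function(ac) {
    chrom <- ac$chrom[[1]]
    bc <- b[b$chrom == chrom, , drop = FALSE]
    if (nrow(bc) == 0) return(NULL)
    hits <- IRanges::findOverlaps(.as_iranges(ac), .as_iranges(bc),
                                  minoverlap = 1L)
    if (length(hits) == 0) return(NULL)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    out <- ac[qh, , drop = FALSE]
    out$start.b <- bc$start[sh]
    out$end.b <- bc$end[sh]
    out$overlap <- pmin(out$end, out$end.b) - pmax(out$start, out$start.b)
    out
  })
  hit_rows <- dplyr::bind_rows(pieces)
  matched_ids <- if (nrow(hit_rows) > 0) hit_rows$.row_a else integer()
  unmatched <- a[!(a$.row_a %in% matched_ids), , drop = FALSE]
  if (nrow(unmatched) > 0) {
    unmatched$start.b <- NA_integer_
    unmatched$end.b <- NA_integer_
    unmatched$overlap <- NA_integer_
  }
  out <- dplyr::bind_rows(hit_rows, unmatched)
  out <- dplyr::arrange(out, .data$.row_a, .data$start.b)
  out$.row_a <- NULL
  out
}

#' Merge intervals separated by at most a gap
#'
#' Maximal runs of intervals whose pairwise gaps are `<= max_gap` bases
#' collapse to a single interval spanning `min(start)`–`max(end)`. Touching
#' intervals (gap 0) merge at `max_gap = 0`. The result is disjoint and
#' sorted; annotation columns are dropped.
#'
#' @param x An interval tibble.
#' @param max_gap Maximum gap (bases, `>= 0`) bridged by a merge.
#' @return A disjoint, sorted interval tibble.
#' @export
merge_intervals <- function(x, max_gap = 0) {
  check_intervals(x)
  if (length(max_gap) != 1 || is.na(max_gap) || max_gap < 0) {
    stop("max_gap must be a single value >= 0", call. = FALSE)
  }
  x <- sort_intervals(x)
  if (nrow(x) == 0) return(x[, c("chrom", "start", "end")])
  pieces <- lapply(split(x, x$chrom), function(xc) {
    ir <- IRanges::reduce(.as_iranges(xc), min.gapwidth = max_gap + 1)
    .from_iranges(ir, xc$chrom[[1]])
  })
  sort_intervals(dplyr::bind_rows(pieces))
}

#' Subtract one interval set from another
#'
#' Removes every base covered by `y` from the (merged) coverage of `x`,
#' returning the surviving pieces. Overlapping `x` intervals are unified
#' before subtraction, so the result is disjoint.
#'
#' @param x,y Interval tibbles.
#' @return A disjoint, sorted interval tibble of `x`-coverage not in `y`.
#' @export
subtract_intervals <- function(x, y) {
  check_intervals(x)
  check_intervals(y)
  x <- sort_intervals(x)
  if (nrow(x) == 0) return(x[, c("chrom", "start", "end")])
  pieces <- lapply(split(x, x$chrom), function(xc) {
    chrom <- xc$chrom[[1]]
    yc <- y[y$chrom == chrom, , drop = FALSE]
    xr <- IRanges::reduce(.as_iranges(xc))
    if (nrow(yc) == 0) return(.from_iranges(xr, chrom))
    kept <- IRanges::setdiff(xr, IRanges::reduce(.as_iranges(yc)))
    .from_iranges(kept, chrom)
  })
  out <- dplyr::bind_rows(pieces)
  sort_intervals(out[out$end > out$start, , drop = FALSE])
}

#' Threshold peak calling on a signal track
#'
#' Calls peaks as the maximal intervals where the track value is `>=
#' threshold` at every base and whose length is at least `min_length`, the
#' operational definition behind genome-browser thresholding of ChIP-seq
#' coverage. Bases not covered by any step count as signal 0. Peak `score`
#' is the maximum signal within the peak; `summit` is the leftmost base
#' attaining that maximum.
#'
#' @param track A signal-track tibble (`chrom`, `start`, `end`, `value`;
#'   bedGraph semantics, steps non-overlapping per chromosome).
#' @param threshold Signal threshold (`> 0`).
#' @param min_length Minimum peak length in bases (default 1).
#' @return An interval tibble with `score` and `summit` columns.
#' @export
#' @examples
#' trk <- tibble::tibble(chrom = "chr1", start = c(0, 5, 9),
#'                       end = c(5, 9, 12), value = c(0, 60, 0))
#' call_peaks(trk, threshold = 50)
call_peaks <- function(track, threshold, min_length = 1) {
  check_track(track)
  if (length(threshold) != 1 || is.na(threshold) || threshold <= 0) {
    stop("threshold must be a single value > 0", call. = FALSE)
  }
  empty <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), score = numeric(),
                          summit = integer())
  if (nrow(track) == 0) return(empty)
  track <- dplyr::arrange(track, .data$chrom, .data$start)
  track$start <- as.integer(track$start)
  track$end <- as.integer(track$end)
  pieces <- lapply(split(track, track$chrom), function(tc) {
    keep <- tc[tc$value >= threshold, , drop = FALSE]
    if (nrow(keep) == 0) return(NULL)
    # group runs of steps that touch (shared boundary); gaps are signal 0
    new_run <- c(TRUE, keep$start[-1] != keep$end[-nrow(keep)])
    run <- cumsum(new_run)
    idx <- split(seq_len(nrow(keep)), run)
    tibble::tibble(
      chrom = keep$chrom[[1]],
      start = unname(vapply(idx, function(i) min(keep$start[i]),
                            integer(1))),
      end = unname(vapply(idx, function(i) max(keep$end[i]), integer(1))),
      score = unname(vapply(idx, function(i) max(keep$value[i]),
                            numeric(1))),
      summit = unname(vapply(idx, function(i) {
        keep$start[i][which.max(keep$value[i])]
      }, integer(1))))
  })
  out <- dplyr::bind_rows(pieces)
  if (nrow(out) == 0) return(empty)
  out <- out[(out$end - out$start) >= min_length, , drop = FALSE]
  sort_intervals(out)[, c("chrom", "start", "end", "score", "summit")]
}

check_track <- function(track) {
  if (!is.data.frame(track)) stop("track must be a data frame", call. = FALSE)
  missing_cols <- setdiff(c("chrom", "start", "end", "value"), names(track))
  if (length(missing_cols) > 0) {
    stop("signal track lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(track) == 0) return(invisible(track))
  if (any(track$end <= track$start)) {
    stop("track steps must have end > start", call. = FALSE)
  }
  if (any(track$value < 0)) stop("track values must be >= 0", call. = FALSE)
  ok <- tapply(seq_len(nrow(track)), track$chrom, function(i) {
    tc <- track[i, , drop = FALSE]
    tc <- tc[order(tc$start), , drop = FALSE]
    nrow(tc) < 2 || all(tc$start[-1] >= tc$end[-nrow(tc)])
  })
  if (!all(unlist(ok))) {
    stop("track steps overlap within a chromosome", call. = FALSE)
  }
  invisible(track)
}

#' Extract a signal statistic over intervals
#'
#' For each query interval, summarises the track: `max` (the summit height)
#' or the length-weighted `mean` of step values over the interval, with
#' uncovered bases counting as 0. An interval touching no step yields 0.
#'
#' @param x An interval tibble (the queries).
#' @param track A signal-track tibble.
#' @param stat `"max"` (default) or `"mean"`.
#' @return `x` with an added `signal` column.
#' @export
signal_at <- function(x, track, stat = c("max", "mean")) {
  stat <- match.arg(stat)
  check_intervals(x)
  check_track(track)
  x <- tibble::as_tibble(x)
  sig <- numeric(nrow(x))
  if (nrow(x) > 0 && nrow(track) > 0) {
    for (chrom in unique(x$chrom)) {
      xi <- which(x$chrom == chrom)
      tc <- track[track$chrom == chrom, , drop = FALSE]
      if (nrow(tc) == 0) next
      hits <- IRanges::findOverlaps(.as_iranges(x[xi, ]), .as_iranges(tc))
      if (length(hits) == 0) next
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      ov <- pmin(x$end[xi][qh], tc$end[sh]) - pmax(x$start[xi][qh], tc$start[sh])
      if (stat == "max") {
        agg <- tapply(tc$value[sh], qh, max)
      } else {
        agg <- tapply(tc$value[sh] * ov, qh, sum)
        widths <- (x$end[xi] - x$start[xi])[as.integer(names(agg))]
        agg <- agg / widths
      }
      sig[xi[as.integer(names(agg))]] <- as.numeric(agg)
    }
  }
  x$signal <- sig
  x
}
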