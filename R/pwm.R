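#' Construct a position weight matrix
#'
#' A PWM is a per-position base-probability model of a binding motif. The
#' matrix has rows A, C, G, T and one column per motif position; each
#' column must sum to 1 (tolerance 1e-9). Scores are log2 odds against the
#' background; the *score ratio* of a window is its raw score min–max
#' normalised to `[0, 1]` using the best and worst attainable window of the
#' PWM, the scale on which the scanning threshold 0.80 is expressed.
#'
#' @param mat Numeric 4 x L matrix of probabilities (rows A, C, G, T; row
#'   names optional but, if present, must be in that order after matching).
#' @param id Motif identifier.
#' @param background Named base probabilities (default uniform 0.25).
#' @param pseudocount Pseudocount recorded when built from counts.
#' @return An object of class `pwm`.
#' @export
#' @examples
#' pwm(matrix(c(1, 0, 0, 0), nrow = 4, dimnames = list(c("A","C","G","T"))))
pwm <- function(mat, id = "pwm",
                background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                pseudocount = 0) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4) stop("PWM matrix must have 4 rows (A, C, G, T)",
                           call. = FALSE)
  if (ncol(mat) < 1) stop("PWM must have at least one column", call. = FALSE)
  if (!is.null(rownames(mat))) {
    if (!setequal(rownames(mat), c("A", "C", "G", "T"))) {
      stop("PWM row names must be A, C, G, T", call. = FALSE)
    }
    mat <- mat[c("A", "C", "G", "T"), , drop = FALSE]
  } else {
    rownames(mat) <- c("A", "C", "G", "T")
  }
  if (any(mat < 0)) stop("PWM entries must be >= 0", call. = FALSE)
  csums <- colSums(mat)
  if (any(abs(csums - 1) > 1e-9)) {
    stop("each PWM column must sum to 1 (max deviation ",
         format(max(abs(csums - 1))), ")", call. = FALSE)
  }
  background <- background[c("A", "C", "G", "T")]
  if (anyNA(background) || abs(sum(background) - 1) > 1e-9) {
    stop("background must be named A/C/G/T probabilities summing to 1",
         call. = FALSE)
  }
  structure(list(id = id, mat = mat, background = background,
                 pseudocount = pseudocount),
            class = "pwm")
}

#' @exportS3Method base::print
print.pwm <- function(x, ...) {
  cat("<pwm> ", x$id, ": ", ncol(x$mat), " positions, total IC ",
      round(information_content(x)$total, 2), " bits\n", sep = "")
  print(round(x$mat, 3))
  invisible(x)
}

#' Build a PWM from a count matrix
#'
#' Column probabilities are `(count + pseudocount) / (n + 4 * pseudocount)`
#' where `n` is the column count total.
#'
#' @param counts Numeric 4 x L matrix of base counts (rows A, C, G, T).
#' @param id Motif identifier.
#' @param pseudocount Per-cell pseudocount (default 0.01).
#' @param background Background base probabilities.
#' @return A `pwm` object.
#' @export
pwm_from_counts <- function(counts, id = "pwm", pseudocount = 0.01,
                            background = c(A = 0.25, C = 0.25,
                                           G = 0.25, T = 0.25)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stop("count matrix must have 4 rows", call. = FALSE)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  probs <- sweep(counts + pseudocount, 2, colSums(counts) + 4 * pseudocount,
                 "/")
  pwm(probs, id = id, background = background, pseudocount = pseudocount)
}

pwm_length <- function(x) ncol(x$mat)

# log2 odds matrix; zero probabilities map to -Inf (callers needing finite
# scores must build the PWM with a pseudocount)
log_odds <- function(x) log2(x$mat / x$background)

# reverse-complemented PWM: columns reversed, A<->T and C<->G swapped
rc_pwm <- function(x) {
  m <- x$mat[c("T", "G", "C", "A"), rev(seq_len(ncol(x$mat))), drop = FALSE]
  rownames(m) <- c("A", "C", "G", "T")
  pwm(m, id = paste0(x$id, "_rc"), background = x$background,
      pseudocount = x$pseudocount)
}

# extremal raw scores attainable by any window
pwm_score_range <- function(x) {
  lo <- log_odds(x)
  c(min = sum(apply(lo, 2, min)), max = sum(apply(lo, 2, max)))
}

.encode_seq <- function(seq) {
  codes <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1]],
                 c("A", "C", "G", "T"))
  codes[is.na(codes)] <- 0L
  as.integer(codes)
}

.ratio_from_raw <- function(raw, rng) {
  if (rng[["max"]] - rng[["min"]] < 1e-12) return(rep(1, length(raw)))
  (raw - rng[["min"]]) / (rng[["max"]] - rng[["min"]])
}

#' Score one window against a PWM
#'
#' Raw score is the summed log2 odds of the window bases against the
#' background; `N` positions contribute 0. Minus strand scores the reverse
#' complement of the window. The score ratio min–max normalises the raw
#' score to `[0, 1]`; a degenerate PWM whose best and worst windows tie is
#' assigned ratio 1 by convention.
#'
#' @param x A `pwm` object.
#' @param window A sequence of exactly the PWM's length.
#' @param strand `"+"` or `"-"`.
#' @return A list with `raw_score` and `score_ratio`.
#' @export
score_window <- function(x, window, strand = "+") {
  stopifnot(inherits(x, "pwm"))
  if (nchar(window) != pwm_length(x)) {
    stop(glue::glue("window length {nchar(window)} != PWM length ",
                    "{pwm_length(x)}"), call. = FALSE)
  }
  if (identical(strand, "-")) window <- reverse_complement(window)
  codes <- .encode_seq(window)
  lo <- log_odds(x)
  raw <- 0
  for (j in seq_along(codes)) {
    if (codes[j] > 0) raw <- raw + lo[codes[j], j]
  }
  rng <- pwm_score_range(x)
  raw <- unname(raw)
  list(raw_score = raw, score_ratio = .ratio_from_raw(raw, rng)[[1]])
}

# score ratios of all windows on one strand; returns numeric vector
# (length nchar(seq) - L + 1) of ratios, or raw scores if ratio = FALSE
.window_scores <- function(x, codes, ratio = TRUE) {
  lo <- log_odds(x)
  raw <- .pwm_window_scores_cpp(codes, lo)
  if (!ratio) return(raw)
  .ratio_from_raw(raw, pwm_score_range(x))
}

#' Scan a sequence for motif occurrences
#'
#' Reports every window position, on both strands, whose score ratio
#' strictly exceeds `min_ratio` (the scanning threshold of 0.80 used for
#' occurrence calling). At `min_ratio = 1` the comparison becomes
#' inclusive, so perfect-score windows are still reported. Overlapping
#' occurrences are kept; output is sorted by position. Coordinates are
#' 0-based half-open within the sequence.
#'
#' @param x A `pwm` object.
#' @param seq A DNA sequence (A/C/G/T/N).
#' @param min_ratio Score-ratio threshold in `[0, 1]` (default 0.80,
#'   strict inequality).
#' @return A tibble with `start`, `end`, `strand`, `raw_score`,
#'   `score_ratio`, `pwm`. Empty if the sequence is shorter than the PWM.
#' @export
scan_pwm <- function(x, seq, min_ratio = 0.80) {
  stopifnot(inherits(x, "pwm"))
  if (min_ratio < 0 || min_ratio > 1) {
    stop("min_ratio must be in [0, 1]", call. = FALSE)
  }
  empty <- tibble::tibble(start = integer(), end = integer(),
                          strand = character(), raw_score = numeric(),
                          score_ratio = numeric(), pwm = character())
  L <- pwm_length(x)
  if (nchar(seq) < L) return(empty)
  codes <- .encode_seq(seq)
  rng <- pwm_score_range(x)
  raw_p <- .pwm_window_scores_cpp(codes, log_odds(x))
  # minus-strand score at a window = plus-strand score of the rc PWM there
  raw_m <- .pwm_window_scores_cpp(codes, log_odds(rc_pwm(x)))
  ratio_p <- .ratio_from_raw(raw_p, rng)
  ratio_m <- .ratio_from_raw(raw_m, rng)
  starts <- seq_along(raw_p) - 1L
  pass <- function(r) if (min_ratio >= 1) r >= 1 else r > min_ratio
  keep_p <- pass(ratio_p)
  keep_m <- pass(ratio_m)
  hits <- dplyr::bind_rows(
    tibble::tibble(start = starts[keep_p], strand = "+",
                   raw_score = raw_p[keep_p],
                   score_ratio = ratio_p[keep_p]),
    tibble::tibble(start = starts[keep_m], strand = "-",
                   raw_score = raw_m[keep_m],
                   score_ratio = ratio_m[keep_m]))
  if (nrow(hits) == 0) return(empty)
  hits$end <- hits$start + L
  hits$pwm <- x$id
  dplyr::arrange(hits, .data$start, .data$strand)[
    , c("start", "end", "strand", "raw_score", "score_ratio", "pwm")]
}

#' Maximum score ratio of a PWM over a sequence
#'
#' The best min–max-normalised match over all windows and both strands —
#' the per-sequence predictor used in the feature matrix.
#'
#' @inheritParams scan_pwm
#' @return A numeric scalar in `[0, 1]`.
#' @export
max_score_ratio <- function(x, seq) {
  stopifnot(inherits(x, "pwm"))
  L <- pwm_length(x)
  if (nchar(seq) < L) {
    stop(glue::glue("sequence (length {nchar(seq)}) shorter than PWM ",
                    "(length {L})"), call. = FALSE)
  }
  codes <- .encode_seq(seq)
  rng <- pwm_score_range(x)
  raw <- max(max(.pwm_window_scores_cpp(codes, log_odds(x))),
             max(.pwm_window_scores_cpp(codes, log_odds(rc_pwm(x)))))
  .ratio_from_raw(raw, rng)[[1]]
}

#' Count motif occurrences in a sequence
#'
#' Counts [scan_pwm()] hits after collapsing plus/minus occurrences at the
#' identical span to a single site (keeping the higher-scoring strand) —
#' near-palindromic motifs such as the AP-1 TRE would otherwise be double
#' counted.
#'
#' @inheritParams scan_pwm
#' @return An integer count.
#' @export
count_occurrences <- function(x, seq, min_ratio = 0.8) {
  hits <- scan_pwm(x, seq, min_ratio = min_ratio)
  if (nrow(hits) == 0) return(0L)
  length(unique(hits$start))
}

#' Mono- and dinucleotide composition features
#'
#' Strand-symmetric composition of a sequence: the 2 mononucleotide classes
#' `A+T` and `C+G` as fractions of non-N bases, and the 16 dinucleotides
#' collapsed by reverse-complement equivalence into 10 classes as fractions
#' of non-N dinucleotide windows. Each group of rates sums to 1. These are
#' the 12 composition variables accompanying the PWM scores in the feature
#' matrix.
#'
#' @param seq A DNA sequence.
#' @return A named numeric vector of length 12
#'   (`mono_AT`, `mono_CG`, `di_*`).
#' @export
#' @examples
#' composition_features("ACGT")
composition_features <- function(seq) {
  if (nchar(seq) == 0) stop("empty sequence", call. = FALSE)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  non_n <- chars[chars %in% c("A", "C", "G", "T")]
  if (length(non_n) == 0) stop("all-N sequence has no composition",
                               call. = FALSE)
  mono <- c(mono_AT = mean(non_n %in% c("A", "T")),
            mono_CG = mean(non_n %in% c("C", "G")))
  di_classes <- c(AA = "AA/TT", TT = "AA/TT", AC = "AC/GT", GT = "AC/GT",
                  AG = "AG/CT", CT = "AG/CT", AT = "AT", CA = "CA/TG",
                  TG = "CA/TG", CC = "CC/GG", GG = "CC/GG", CG = "CG",
                  GA = "GA/TC", TC = "GA/TC", GC = "GC", TA = "TA")
  class_levels <- c("AA/TT", "AC/GT", "AG/CT", "AT", "CA/TG",
                    "CC/GG", "CG", "GA/TC", "GC", "TA")
  di <- rep(0, length(class_levels))
  names(di) <- paste0("di_", gsub("/", "_", class_levels))
  if (length(chars) >= 2) {
    pairs <- paste0(chars[-length(chars)], chars[-1])
    pairs <- pairs[pairs %in% names(di_classes)]
    if (length(pairs) > 0) {
      tab <- table(factor(di_classes[pairs], levels = class_levels))
      di[] <- as.numeric(tab) / length(pairs)
    }
  }
  c(mono, di)
}

#' Reconstruct a PWM from aligned occurrence sequences
#'
#' Builds a count matrix from equal-length sequences already oriented to
#' the motif strand and converts it to probabilities with the pseudocount
#' rule `(count + pc) / (n + 4 pc)`.
#'
#' @param seqs Character vector of equal-length motif occurrences.
#' @param id Motif identifier for the result.
#' @param pseudocount Per-cell pseudocount (default 0).
#' @return A `pwm` object.
#' @export
reconstruct_pwm <- function(seqs, id = "reconstructed", pseudocount = 0) {
  if (length(seqs) < 1) stop("need at least one sequence", call. = FALSE)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) {
    stop("occurrence sequences must all have the same length", call. = FALSE)
  }
  chars <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  counts <- vapply(seq_len(ncol(chars)), function(j) {
    tabulate(match(chars[, j], c("A", "C", "G", "T")), nbins = 4)
  }, numeric(4))
  rownames(counts) <- c("A", "C", "G", "T")
  pwm_from_counts(counts, id = id, pseudocount = pseudocount)
}

#' Information content of a PWM
#'
#' Per-column information content under uniform background:
#' `IC = 2 + sum_b p(b) log2 p(b)` bits, with `0 * log 0 = 0`. Ranges from
#' 0 bits (no base preference) to 2 bits (a single base used); the total is
#' the sum over columns, the quantity compared between sequence logos of
#' reconstructed motifs.
#'
#' @param x A `pwm` object.
#' @return A list with `per_position` (numeric vector, bits) and `total`.
#' @export
#' @examples
#' information_content(pwm(matrix(c(1, 0, 0, 0), nrow = 4)))$total  # 2 bits
information_content <- function(x) {
  stopifnot(inherits(x, "pwm"))
  per <- apply(x$mat, 2, function(p) {
    terms <- ifelse(p > 0, p * log2(p), 0)
    2 + sum(terms)
  })
  list(per_position = as.numeric(per), total = sum(per))
}
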