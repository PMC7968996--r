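# Independent brute-force oracles and tiny fixtures used across the suite.
# Everything here works per-base / per-window on purpose: these paths must
# stay independent of the package's IRanges/Rcpp implementations.

# random interval set on a single toy chromosome
random_intervals <- function(n, len = 5000, max_w = 200, chrom = "chrT") {
  start <- sample.int(len - max_w, n, replace = TRUE) - 1L
  width <- sample.int(max_w, n, replace = TRUE)
  sort_intervals(tibble::tibble(chrom = chrom, start = start,
                                end = pmin(start + width, len)))
}

# per-base occupancy (logical, positions 1..len represent bases 0..len-1)
occupancy <- function(x, len) {
  occ <- logical(len)
  for (i in seq_len(nrow(x))) {
    occ[(x$start[i] + 1):x$end[i]] <- TRUE
  }
  occ
}

# runs of TRUE in a logical vector -> interval tibble (0-based half-open)
runs_to_intervals <- function(occ, chrom = "chrT") {
  r <- rle(occ)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  tibble::tibble(chrom = chrom, start = as.integer(starts[keep]),
                 end = as.integer(ends[keep]))
}

# brute-force pairwise intersection: one row per overlapping (a, b) pair
oracle_intersect <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          a$start[i] < b$end[j] && b$start[j] < a$end[i]) {
        out[[length(out) + 1]] <- c(i, j)
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(ai = integer(), bi = integer()))
  }
  m <- do.call(rbind, out)
  tibble::tibble(ai = m[, 1], bi = m[, 2])
}

# brute-force merge: bridge gaps <= g between occupied runs
oracle_merge <- function(x, g, len) {
  occ <- occupancy(x, len + g + 2L)
  runs <- runs_to_intervals(occ)
  if (nrow(runs) < 2) return(runs)
  merged <- runs[1, ]
  for (i in 2:nrow(runs)) {
    if (runs$start[i] - merged$end[nrow(merged)] <= g) {
      merged$end[nrow(merged)] <- runs$end[i]
    } else {
      merged <- rbind(merged, runs[i, ])
    }
  }
  tibble::as_tibble(merged)
}

# per-base signal vector from a step track (single chromosome)
signal_vector <- function(track, len) {
  v <- numeric(len)
  for (i in seq_len(nrow(track))) {
    v[(track$start[i] + 1):track$end[i]] <- track$value[i]
  }
  v
}

# brute-force threshold peak caller on the per-base vector
oracle_peaks <- function(track, threshold, min_length, len,
                         chrom = "chrT") {
  v <- signal_vector(track, len)
  runs <- runs_to_intervals(v >= threshold, chrom = chrom)
  runs <- runs[(runs$end - runs$start) >= min_length, , drop = FALSE]
  runs$score <- vapply(seq_len(nrow(runs)), function(i) {
    max(v[(runs$start[i] + 1):runs$end[i]])
  }, numeric(1))
  runs
}

# random step track (non-overlapping steps with gaps)
random_track <- function(n_steps, len = 2000, chrom = "chrT",
                         max_value = 100) {
  bounds <- sort(sample(0:len, 2 * n_steps, replace = FALSE))
  starts <- bounds[seq(1, 2 * n_steps, by = 2)]
  ends <- bounds[seq(2, 2 * n_steps, by = 2)]
  keep <- ends > starts
  tibble::tibble(chrom = chrom, start = starts[keep], end = ends[keep],
                 value = round(stats::runif(sum(keep), 0, max_value), 1))
}

# brute-force PWM scan via score_window() on every substring, both strands
oracle_scan <- function(p, seq, min_ratio) {
  L <- ncol(p$mat)
  n <- nchar(seq)
  hits <- list()
  if (n >= L) {
    for (s in 0:(n - L)) {
      win <- substr(seq, s + 1, s + L)
      for (st in c("+", "-")) {
        sc <- score_window(p, win, strand = st)
        if (sc$score_ratio > min_ratio) {
          hits[[length(hits) + 1]] <-
            tibble::tibble(start = s, strand = st,
                           score_ratio = sc$score_ratio)
        }
      }
    }
  }
  dplyr::bind_rows(hits)
}

# connected components of the interval overlap graph (>= 1 shared base),
# labelled by which source sets contribute
oracle_overlap_classes <- function(a, b) {
  all_iv <- rbind(cbind(a[, c("chrom", "start", "end")], src = "a"),
                  cbind(b[, c("chrom", "start", "end")], src = "b"))
  n <- nrow(all_iv)
  if (n == 0) return(tibble::tibble())
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (all_iv$chrom[i] == all_iv$chrom[j] &&
          all_iv$start[i] < all_iv$end[j] &&
          all_iv$start[j] < all_iv$end[i]) {
        parent[find(j)] <- find(i)
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  out <- lapply(split(seq_len(n), comp), function(idx) {
    srcs <- unique(all_iv$src[idx])
    tibble::tibble(chrom = all_iv$chrom[idx[1]],
                   start = min(all_iv$start[idx]),
                   end = max(all_iv$end[idx]),
                   label = if (length(srcs) == 2) "F1F2"
                           else if (srcs == "a") "PF1" else "PF2")
  })
  sort_intervals(dplyr::bind_rows(out))
}

# deterministic toy PWMs
consensus_pwm <- function(consensus, max_prob = 0.94, id = "toy") {
  bases <- strsplit(consensus, "")[[1]]
  m <- matrix((1 - max_prob) / 3, nrow = 4, ncol = length(bases),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(bases)) m[bases[j], j] <- max_prob
  pwm(m, id = id)
}

random_dna <- function(n, probs = c(A = .25, C = .25, G = .25, T = .25)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs),
        collapse = "")
}
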