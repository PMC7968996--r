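#' Simulation configuration
#'
#' One seeded configuration object drives every generator, so each
#' synthetic dataset is a pure function of `(config)`. Defaults are the
#' study conditions the pipeline assumes; override any block entry via
#' `...` (e.g. `sim_config(1, peaks = list(n_pf1 = 1000))` replaces only
#' that entry).
#'
#' @param seed Mandatory integer seed.
#' @param ... Named blocks (`genome`, `motifs`, `peaks`, `histone`,
#'   `capture`, `expression`) whose entries override the defaults.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed, ...) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  cfg <- list(
    seed = as.integer(seed),
    genome = list(n_chroms = 1L, chrom_length = 1000000L, gc = 0.5,
                  n_tss = 20L, tss_min_spacing = 10000L),
    motifs = list(strict_max_prob = 0.91, degenerate_max_prob = 0.55,
                  n_decoy_pwms = 10L),
    peaks = list(n_pf1 = 150L, n_pf2 = 150L, n_f1f2 = 150L,
                 peak_width = 200L, spacing = 1500L,
                 height_high = c(80, 200), height_low = c(15, 40),
                 background_max = 10, background_step = 1000L,
                 at_rich_flank_boost = 0.10, flank_halfwidth = 500L,
                 beta = 1.0, ratio_noise_sd = 0.15),
    histone = list(n_cae = 40L, n_cie = 40L, element_width = c(800, 2000),
                   prom_active_prob = 0.6, dropout = 0,
                   atac_prob = c(cAE = 0.733, cAP = 0.886,
                                 cIE = 0.254, cIP = 0.134)),
    capture = list(n_fragments = 400L, mean_frag = 400L, min_frag = 80L,
                   amplitude = 120, d0 = 50000, dispersion = 0.3,
                   n_reps = 3L, n_pirs = 2L, pir_width_frags = 5L,
                   pir_enrichment = 4),
    expression = list(n_genes = 400L,
                      proportions = c(A = 0.2, B = 0.2, C = 0.15,
                                      D = 0.15, none = 0.3),
                      fc_range = c(1.6, 4), error_rate = 0))
  overrides <- list(...)
  for (blk in names(overrides)) {
    if (!blk %in% names(cfg)) stop("unknown config block: ", blk,
                                   call. = FALSE)
    for (key in names(overrides[[blk]])) {
      cfg[[blk]][[key]] <- overrides[[blk]][[key]]
    }
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a genome and TSS annotation
#'
#' I.i.d. background sequence at the configured GC content, with TSSs
#' placed on a grid guaranteeing the minimum spacing. Deterministic under
#' the config seed.
#'
#' @param config A [sim_config()].
#' @return A list with `genome` (named character vector) and `tss`
#'   (point-interval tibble with `name`, `strand`).
#' @export
sim_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$genome
  withr::with_seed(config$seed + 101L, {
    probs <- c(A = (1 - g$gc) / 2, C = g$gc / 2, G = g$gc / 2,
               T = (1 - g$gc) / 2)
    genome <- vapply(seq_len(g$n_chroms), function(i) {
      paste(sample(names(probs), g$chrom_length, replace = TRUE,
                   prob = probs), collapse = "")
    }, character(1))
    names(genome) <- paste0("chrS", seq_len(g$n_chroms))
    grid <- seq(5000L, g$chrom_length - 5000L, by = g$tss_min_spacing)
    if (length(grid) < g$n_tss) {
      stop("TSS spacing infeasible: ", length(grid), " slots for ",
           g$n_tss, " TSSs", call. = FALSE)
    }
    pos <- sort(sample(grid, g$n_tss))
    tss <- tibble::tibble(chrom = names(genome)[1], start = pos,
                          end = pos + 1L,
                          name = sprintf("gene_%03d", seq_along(pos)),
                          score = 0,
                          strand = rep_len(c("+", "-"), length(pos)))
    list(genome = genome, tss = tss)
  })
}

# strict motif: near-canonical TGACTCA core, high information content
.strict_pwm <- function(max_prob = 0.91) {
  .consensus_pwm("TGACTCA", max_prob, id = "strict_core")
}

# degenerate motif: same core, lower IC, two near-uniform end positions
.degenerate_pwm <- function(max_prob = 0.55) {
  p <- .consensus_pwm("TGACTCA", max_prob, id = "degenerate_core")
  m <- p$mat
  for (j in c(1, ncol(m))) {
    cons <- which.max(m[, j])
    m[, j] <- 0.24
    m[cons, j] <- 0.28
  }
  pwm(m, id = "degenerate_core")
}

.consensus_pwm <- function(consensus, max_prob, id) {
  bases <- strsplit(consensus, "", fixed = TRUE)[[1]]
  m <- matrix((1 - max_prob) / 3, nrow = 4, ncol = length(bases),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(bases)) m[bases[j], j] <- max_prob
  pwm(m, id = id)
}

#' Simulated PWM library
#'
#' The strict and degenerate core motifs that drive the planted binding
#' preferences, plus seeded random decoy PWMs emulating the bulk of a
#' motif database.
#'
#' @param config A [sim_config()].
#' @return A named list of `pwm` objects (first two: `strict_core`,
#'   `degenerate_core`).
#' @export
sim_pwm_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$motifs
  lib <- list(strict_core = .strict_pwm(m$strict_max_prob),
              degenerate_core = .degenerate_pwm(m$degenerate_max_prob))
  if (m$n_decoy_pwms > 0) {
    decoys <- withr::with_seed(config$seed + 202L, {
      lapply(seq_len(m$n_decoy_pwms), function(i) {
        L <- sample(8:12, 1)
        mat <- vapply(seq_len(L), function(j) {
          w <- stats::rgamma(4, shape = 0.8)
          w / sum(w)
        }, numeric(4))
        rownames(mat) <- c("A", "C", "G", "T")
        pwm(mat, id = sprintf("decoy_%02d", i))
      })
    })
    names(decoys) <- vapply(decoys, function(p) p$id, character(1))
    lib <- c(lib, decoys)
  }
  lib
}

# one random draw (sequence) per call from a PWM
.draw_from_pwm <- function(p, n = 1) {
  L <- ncol(p$mat)
  vapply(seq_len(n), function(i) {
    paste(vapply(seq_len(L), function(j) {
      sample(rownames(p$mat), 1, prob = p$mat[, j])
    }, character(1)), collapse = "")
  }, character(1))
}

#' Plant factor-specific binding sites and signal tracks
#'
#' Realises the generative assumption behind the binding-preference
#' analysis: sites preferentially bound by factor B (`PF2` truth) receive
#' a draw from the strict high-information motif; factor-A-preferential
#' sites (`PF1`) a draw from the degenerate motif with AT-enriched
#' flanks; shared sites (`F1F2`) draws spanning the stringency range,
#' with the planted signal log-ratio
#' `log10(Y1/Y2) = -beta * strict_score_ratio + noise`. Signal tracks are
#' rectangular peaks at the planted heights over a low uniform background,
#' so threshold peak calling at 50 recovers the planted sites.
#'
#' @param config A [sim_config()].
#' @param genome_data Output of [sim_genome()].
#' @return A list: `genome` (with motifs planted), `track_a`, `track_b`
#'   (signal-track tibbles), and `truth` (one row per planted site:
#'   `site_id, chrom, summit, class, motif_start, motif_seq,
#'   strict_ratio, y1, y2, log_ratio`).
#' @export
sim_peaks <- function(config, genome_data) {
  stopifnot(inherits(config, "sim_config"))
  pk <- config$peaks
  strict <- .strict_pwm(config$motifs$strict_max_prob)
  degen <- .degenerate_pwm(config$motifs$degenerate_max_prob)
  genome <- genome_data$genome
  chrom <- names(genome)[1]
  len <- nchar(genome[[chrom]])
  n_total <- pk$n_pf1 + pk$n_pf2 + pk$n_f1f2
  withr::with_seed(config$seed + 303L, {
    grid <- seq(2000L, len - 2000L, by = pk$spacing)
    if (length(grid) < n_total) {
      stop("genome too short for ", n_total, " planted peaks", call. = FALSE)
    }
    summits <- sort(sample(grid, n_total))
    classes <- sample(rep(c("PF1", "PF2", "F1F2"),
                          c(pk$n_pf1, pk$n_pf2, pk$n_f1f2)))
    chars <- strsplit(genome[[chrom]], "", fixed = TRUE)[[1]]
    L <- ncol(strict$mat)
    motif_start <- summits - L %/% 2
    truth <- tibble::tibble(site_id = sprintf("site_%04d",
                                              seq_len(n_total)),
                            chrom = chrom, summit = summits,
                            class = classes, motif_start = motif_start,
                            motif_seq = NA_character_,
                            strict_ratio = NA_real_,
                            y1 = NA_real_, y2 = NA_real_,
                            log_ratio = NA_real_)
    for (i in seq_len(n_total)) {
      cls <- classes[i]
      if (cls == "PF2") {
        motif <- .draw_from_pwm(strict)
      } else if (cls == "PF1") {
        motif <- .draw_from_pwm(degen)
      } else {
        u <- stats::runif(1)
        mix <- pwm((1 - u) * degen$mat + u * strict$mat, id = "mix")
        motif <- .draw_from_pwm(mix)
      }
      mpos <- motif_start[i]
      chars[(mpos + 1):(mpos + L)] <- strsplit(motif, "", fixed = TRUE)[[1]]
      if (cls == "PF1" && pk$at_rich_flank_boost > 0) {
        flank <- setdiff(seq(summits[i] - pk$flank_halfwidth,
                             summits[i] + pk$flank_halfwidth),
                         (mpos + 1):(mpos + L))
        flank <- flank[flank >= 1 & flank <= len]
        # replacing a base by A/T w.p. 2*boost raises the expected AT
        # fraction by ~boost at background AT 0.5
        hit <- flank[stats::runif(length(flank)) <
                       2 * pk$at_rich_flank_boost]
        if (length(hit) > 0) {
          chars[hit] <- sample(c("A", "T"), length(hit), replace = TRUE)
        }
      }
      sw <- score_window(strict, motif)
      truth$motif_seq[i] <- motif
      truth$strict_ratio[i] <- sw$score_ratio
      if (cls == "PF1") {
        truth$y1[i] <- stats::runif(1, pk$height_high[1], pk$height_high[2])
        truth$y2[i] <- stats::runif(1, pk$height_low[1], pk$height_low[2])
      } else if (cls == "PF2") {
        truth$y1[i] <- stats::runif(1, pk$height_low[1], pk$height_low[2])
        truth$y2[i] <- stats::runif(1, pk$height_high[1], pk$height_high[2])
      } else {
        # shared sites stay in the high-SNR regime: base height >= 100
        # and |log ratio| <= 0.4 keep both factors' signals above the
        # calling threshold
        h <- stats::runif(1, max(pk$height_high[1], 100),
                          pk$height_high[2])
        delta <- -pk$beta * (truth$strict_ratio[i] - 0.5) +
          stats::rnorm(1, 0, pk$ratio_noise_sd)
        delta <- max(-0.4, min(0.4, delta))
        truth$y1[i] <- h * 10^(delta / 2)
        truth$y2[i] <- h * 10^(-delta / 2)
      }
      truth$log_ratio[i] <- log10(truth$y1[i] / truth$y2[i])
    }
    genome[[chrom]] <- paste(chars, collapse = "")
    half <- pk$peak_width %/% 2
    peaks_a <- tibble::tibble(start = summits - half,
                              end = summits + half, value = truth$y1)
    peaks_b <- tibble::tibble(start = summits - half,
                              end = summits + half, value = truth$y2)
    track_a <- .steps_with_peaks(chrom, len, peaks_a, pk)
    track_b <- .steps_with_peaks(chrom, len, peaks_b, pk)
    list(genome = genome, track_a = track_a, track_b = track_b,
         truth = truth)
  })
}

# uniform-noise background steps with rectangular peaks overlaid
.steps_with_peaks <- function(chrom, len, peaks, pk) {
  bounds <- sort(unique(c(seq(0L, len, by = pk$background_step),
                          len, peaks$start, peaks$end)))
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1]
  keep <- ends > starts
  starts <- starts[keep]
  ends <- ends[keep]
  # segment falls inside peak i iff start >= peaks$start[i] & end <= end[i]
  idx <- findInterval(starts, peaks$start)
  inside <- idx >= 1 & idx <= nrow(peaks) & ends <= peaks$end[pmax(idx, 1)]
  value <- stats::runif(length(starts), 0, pk$background_max)
  value[inside] <- peaks$value[idx[inside]]
  tibble::tibble(chrom = chrom, start = starts, end = ends, value = value)
}

#' Plant a histone-mark and open-chromatin landscape
#'
#' Generates truth regulatory elements (active/inactive promoters from
#' the TSS annotation; intergenic active/inactive enhancers) and emits
#' the H3K4me1 / H3K27ac / H3K4me3 / ATAC peak sets their classes
#' dictate (cAE: K4me1 + K27ac + ATAC; cIE: K4me1 only; cAP: promoter
#' K27ac; cIP: promoter only), with a configurable mark-dropout rate to
#' create "other" regions. At dropout 0, [annotate_elements()] on the
#' output recovers the truth classes.
#'
#' @param config A [sim_config()].
#' @param genome_data Output of [sim_genome()].
#' @return A list of peak tibbles `k4me1`, `k27ac`, `k4me3`, `atac` and a
#'   `truth` element tibble (`chrom, start, end, class`).
#' @export
sim_histone_landscape <- function(config, genome_data) {
  stopifnot(inherits(config, "sim_config"))
  h <- config$histone
  tss <- genome_data$tss
  chrom <- tss$chrom[1]
  len <- nchar(genome_data$genome[[chrom]])
  withr::with_seed(config$seed + 404L, {
    prom_active <- stats::runif(nrow(tss)) < h$prom_active_prob
    prom_truth <- tibble::tibble(chrom = chrom,
                                 start = pmax(0L, tss$start - 1500L),
                                 end = tss$start + 1500L,
                                 class = ifelse(prom_active, "cAP", "cIP"))
    grid <- seq(3000L, len - 3000L, by = 6000L)
    near_tss <- vapply(grid, function(p) {
      any(abs(p - tss$start) < 4000)
    }, logical(1))
    grid <- grid[!near_tss]
    n_enh <- h$n_cae + h$n_cie
    if (length(grid) < n_enh) {
      stop("genome too short for ", n_enh, " planted elements",
           call. = FALSE)
    }
    centers <- sort(sample(grid, n_enh))
    widths <- round(stats::runif(n_enh, h$element_width[1],
                                 h$element_width[2]))
    cls <- sample(rep(c("cAE", "cIE"), c(h$n_cae, h$n_cie)))
    enh_truth <- tibble::tibble(chrom = chrom,
                                start = as.integer(centers - widths %/% 2),
                                end = as.integer(centers + widths %/% 2),
                                class = cls)
    truth <- sort_intervals(dplyr::bind_rows(prom_truth, enh_truth))
    drop <- function(n) stats::runif(n) >= h$dropout
    k4me1 <- enh_truth[drop(nrow(enh_truth)), c("chrom", "start", "end")]
    k27ac_enh <- enh_truth[enh_truth$class == "cAE", , drop = FALSE]
    k27ac_enh <- k27ac_enh[drop(nrow(k27ac_enh)), , drop = FALSE]
    # element K27ac kept inside the element so it cannot touch a promoter
    k27ac_prom <- prom_truth[prom_truth$class == "cAP", , drop = FALSE]
    k27ac_prom <- k27ac_prom[drop(nrow(k27ac_prom)), , drop = FALSE]
    k27ac_prom <- tibble::tibble(chrom = k27ac_prom$chrom,
                                 start = k27ac_prom$start + 1000L,
                                 end = k27ac_prom$end - 1000L)
    k27ac <- dplyr::bind_rows(
      k27ac_enh[, c("chrom", "start", "end")], k27ac_prom)
    k4me3 <- tibble::tibble(chrom = chrom,
                            start = tss$start[prom_active] - 400L,
                            end = tss$start[prom_active] + 400L)
    all_truth <- truth
    atac_p <- h$atac_prob[all_truth$class]
    atac_hit <- stats::runif(nrow(all_truth)) < atac_p
    atac_mid <- (all_truth$start + all_truth$end) %/% 2L
    atac <- tibble::tibble(chrom = chrom,
                           start = atac_mid[atac_hit] - 150L,
                           end = atac_mid[atac_hit] + 150L)
    list(k4me1 = sort_intervals(k4me1), k27ac = sort_intervals(k27ac),
         k4me3 = sort_intervals(k4me3), atac = sort_intervals(atac),
         truth = truth)
  })
}

#' Simulate one Capture-C viewpoint profile
#'
#' Pseudo-digests a region into restriction fragments, then draws
#' per-fragment unique-interaction counts from a negative binomial with
#' distance-decaying mean `A / (1 + d/d0)`, multiplied by the planted
#' enrichment over promoter-interacting-region fragments. Replicates are
#' i.i.d. given the means.
#'
#' @param config A [sim_config()].
#' @param viewpoint_id Integer distinguishing viewpoints (enters the
#'   seed, so each viewpoint is reproducible independently).
#' @param planted If `FALSE`, no interacting regions are planted (null
#'   profile).
#' @return A list: `profile` (fragment tibble with `rep*` count columns),
#'   `viewpoint_pos` (bp) and `truth_pirs` (interval tibble, empty when
#'   `planted = FALSE`).
#' @export
sim_capture_profile <- function(config, viewpoint_id = 1L,
                                planted = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  cp <- config$capture
  chrom <- paste0("chrV", viewpoint_id)
  withr::with_seed(config$seed + 505L + 131L * as.integer(viewpoint_id), {
    spac <- cp$min_frag +
      round(stats::rexp(cp$n_fragments, 1 / (cp$mean_frag - cp$min_frag)))
    ends <- cumsum(spac)
    starts <- c(0L, ends[-length(ends)])
    n <- length(starts)
    vp_idx <- n %/% 2L
    vp_pos <- (starts[vp_idx] + ends[vp_idx]) / 2
    dist <- abs((starts + ends) / 2 - vp_pos)
    mu <- cp$amplitude / (1 + dist / cp$d0)
    enrich <- rep(1, n)
    truth <- tibble::tibble(chrom = character(), start = integer(),
                            end = integer())
    if (planted && cp$n_pirs > 0) {
      # plant alternating sides, clear of the viewpoint exclusion zone
      offsets <- round(seq(40, n %/% 2 - 20,
                           length.out = max(cp$n_pirs, 2)))[
                             seq_len(cp$n_pirs)]
      side <- rep_len(c(1, -1), cp$n_pirs)
      for (k in seq_len(cp$n_pirs)) {
        first <- vp_idx + side[k] * offsets[k]
        idx <- first:(first + cp$pir_width_frags - 1L)
        idx <- idx[idx >= 1 & idx <= n]
        enrich[idx] <- cp$pir_enrichment
        truth <- dplyr::bind_rows(truth, tibble::tibble(
          chrom = chrom, start = starts[min(idx)], end = ends[max(idx)]))
      }
    }
    counts <- vapply(seq_len(cp$n_reps), function(r) {
      stats::rnbinom(n, mu = mu * enrich, size = 1 / cp$dispersion)
    }, numeric(n))
    profile <- tibble::tibble(chrom = chrom, start = as.integer(starts),
                              end = as.integer(ends))
    for (r in seq_len(cp$n_reps)) {
      profile[[paste0("rep", r)]] <- counts[, r]
    }
    list(profile = profile, viewpoint_pos = vp_pos,
         truth_pirs = sort_intervals(truth))
  })
}

#' Simulate gene-level knockdown modulation calls
#'
#' Assigns genes to truth regulation groups at the configured
#' proportions, emits modulation calls realising each group's defining
#' pattern (fold-change magnitudes from `fc_range`; for group D the
#' double-knockdown effect is strictly stronger than both singles), then
#' corrupts each modulation boolean independently at the configured error
#' rate. At error rate 0, [classify_genes()] recovers the truth groups
#' exactly.
#'
#' @param config A [sim_config()].
#' @return A list with `calls` (input to [classify_genes()]) and `truth`
#'   (`gene, group, direction`).
#' @export
sim_expression_calls <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ex <- config$expression
  withr::with_seed(config$seed + 606L, {
    n <- ex$n_genes
    groups <- sample(names(ex$proportions), n, replace = TRUE,
                     prob = ex$proportions)
    dirs <- sample(c("up", "down"), n, replace = TRUE)
    rfc <- function(k) stats::runif(k, ex$fc_range[1], ex$fc_range[2])
    sgn <- ifelse(dirs == "up", 1, -1)
    calls <- tibble::tibble(
      gene = sprintf("gene_%04d", seq_len(n)),
      modulated_si1 = groups %in% c("A", "D"),
      modulated_si2 = groups %in% c("B", "D"),
      modulated_si12 = groups %in% c("C", "D") |
        (groups %in% c("A", "B") & stats::runif(n) < 0.7))
    fc1 <- ifelse(calls$modulated_si1, sgn * rfc(n), NA_real_)
    fc2 <- ifelse(calls$modulated_si2, sgn * rfc(n), NA_real_)
    fc12 <- rep(NA_real_, n)
    is_d <- groups == "D"
    fc12[is_d] <- sgn[is_d] * pmax(abs(fc1[is_d]), abs(fc2[is_d])) *
      stats::runif(sum(is_d), 1.2, 1.8)
    other12 <- calls$modulated_si12 & !is_d
    fc12[other12] <- sgn[other12] * rfc(sum(other12))
    calls$dir_si1 <- ifelse(calls$modulated_si1, dirs, NA_character_)
    calls$dir_si2 <- ifelse(calls$modulated_si2, dirs, NA_character_)
    calls$dir_si12 <- ifelse(calls$modulated_si12, dirs, NA_character_)
    calls$fc_si1 <- fc1
    calls$fc_si2 <- fc2
    calls$fc_si12 <- fc12
    if (ex$error_rate > 0) {
      for (cond in c("si1", "si2", "si12")) {
        mcol <- paste0("modulated_", cond)
        flip <- stats::runif(n) < ex$error_rate
        newm <- xor(calls[[mcol]], flip)
        turned_on <- flip & newm
        turned_off <- flip & !newm
        calls[[paste0("dir_", cond)]][turned_off] <- NA_character_
        calls[[paste0("fc_", cond)]][turned_off] <- NA_real_
        if (any(turned_on)) {
          nd <- sample(c("up", "down"), sum(turned_on), replace = TRUE)
          calls[[paste0("dir_", cond)]][turned_on] <- nd
          calls[[paste0("fc_", cond)]][turned_on] <-
            ifelse(nd == "up", 1, -1) * rfc(sum(turned_on))
        }
        calls[[mcol]] <- newm
      }
    }
    truth <- tibble::tibble(gene = calls$gene, group = groups,
                            direction = ifelse(groups == "none",
                                               NA_character_, dirs))
    list(calls = calls, truth = truth)
  })
}
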