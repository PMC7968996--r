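#' Run the full synthetic analysis pipeline
#'
#' End-to-end demonstration on generated data: simulate a genome with
#' planted binding sites, call and classify peaks, annotate regulatory
#' elements, build the feature matrix and fit the penalised
#' classification and regression models, classify knockdown regulation
#' groups, and call/annotate promoter-interacting regions with a
#' condition delta-profile. Stages run in the order of the analyses they
#' realise; omitting the `capture` block of the config (set it to `NULL`)
#' skips the interaction stages with a message.
#'
#' Every stochastic step derives its seed from `config$seed`, so the
#' summary is identical across runs with the same config.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional output directory; when given, per-stage files
#'   (BED/bedGraph/TSV), the serialized config and the machine-readable
#'   `summary.json` are written there.
#' @param peak_threshold Peak-calling threshold (default 50).
#' @param min_ratio Motif score-ratio threshold (default 0.80).
#' @param fc_threshold Fold-change category threshold (default 1.5).
#' @return Invisibly, a list with `summary` (the JSON-serializable
#'   summary) and the per-stage objects (`classified`, `elements`, `fits`,
#'   `groups`, `pirs`, ...).
#' @export
run_pipeline <- function(config, out_dir = NULL, peak_threshold = 50,
                         min_ratio = 0.80, fc_threshold = 1.5) {
  stopifnot(inherits(config, "sim_config"))
  log_msg <- function(...) message("[parabind] ", ...)
  log_msg("simulating genome (seed ", config$seed, ")")
  gen <- sim_genome(config)
  pwms <- sim_pwm_library(config)
  planted <- sim_peaks(config, gen)
  gen$genome <- planted$genome

  log_msg("calling and classifying peaks (threshold ", peak_threshold, ")")
  peaks_a <- call_peaks(planted$track_a, threshold = peak_threshold)
  peaks_b <- call_peaks(planted$track_b, threshold = peak_threshold)
  classified <- classify_overlap(peaks_a, peaks_b,
                                 track_a = planted$track_a,
                                 track_b = planted$track_b)

  log_msg("annotating regulatory elements")
  marks <- sim_histone_landscape(config, gen)
  elements <- annotate_elements(gen$tss, marks$k27ac, marks$k4me1,
                                k4me3 = marks$k4me3)
  fractions <- overlap_fractions(
    dplyr::rename(classified, label = "label"),
    list(atac = marks$atac,
         cAE = elements[elements$state == "cAE", , drop = FALSE]))

  log_msg("building feature matrix and fitting models")
  cls_peaks <- classified[classified$label %in% c("PF1", "PF2"), ,
                          drop = FALSE]
  fm <- build_feature_matrix(cls_peaks, gen$genome, pwms)
  fm_bal <- balance_classes(fm, seed = config$seed + 11L)
  fit_cls <- fit_classifier(fm_bal, seed = config$seed + 12L)
  strict_auc <- single_feature_auc(fm_bal, "strict_core", fit = fit_cls)
  f1f2 <- classified[classified$label == "F1F2" &
                       classified$signal_a > 0 & classified$signal_b > 0, ,
                     drop = FALSE]
  fit_reg <- NULL
  if (nrow(f1f2) >= 40) {
    f1f2$response <- log10(f1f2$signal_a / f1f2$signal_b)
    fm_reg <- build_feature_matrix(f1f2, gen$genome, pwms)
    fit_reg <- fit_ratio_regressor(fm_reg, seed = config$seed + 13L)
  }

  log_msg("classifying knockdown regulation groups")
  expr <- sim_expression_calls(config)
  groups <- classify_genes(expr$calls)
  groups_filt <- apply_fc_filter(groups, min_abs_fc = fc_threshold)
  grp_sum <- group_summary(groups)

  pirs <- NULL
  pir_summary <- NULL
  delta <- NULL
  if (is.null(config$capture)) {
    log_msg("capture block absent: skipping interaction stages")
  } else {
    log_msg("calling promoter-interacting regions")
    n_vp <- 3L
    pir_list <- lapply(seq_len(n_vp), function(v) {
      sim <- sim_capture_profile(config, viewpoint_id = v)
      prof <- normalize_profile(sim$profile, sim$viewpoint_pos)
      prof <- background_fit(prof, sim$viewpoint_pos)
      p <- call_pirs(prof, sim$viewpoint_pos,
                     seed = config$seed + 500L + v)
      if (nrow(p) > 0) {
        p$viewpoint <- paste0("vp", v)
        p$vp_pos <- sim$viewpoint_pos
      }
      p
    })
    pirs <- dplyr::bind_rows(pir_list)
    pir_summary <- pir_stats(pirs)
    sim_a <- sim_capture_profile(config, viewpoint_id = 1L)
    sim_b <- sim_capture_profile(config, viewpoint_id = 1L,
                                 planted = FALSE)
    delta <- delta_profile(normalize_profile(sim_a$profile,
                                             sim_a$viewpoint_pos),
                           normalize_profile(sim_b$profile,
                                             sim_b$viewpoint_pos))
  }

  summary <- list(
    seed = config$seed,
    peaks = as.list(table(classified$label)),
    elements = as.list(table(elements$state)),
    classification = list(
      auc = fit_cls$auc,
      strict_single_feature_auc = strict_auc,
      n_selected = sum(fit_cls$coefficients$coefficient != 0),
      top_features = utils::head(top_coefficients(fit_cls)$feature, 5)),
    regression = if (is.null(fit_reg)) NULL else list(
      pearson_r = fit_reg$pearson_r, p_value = fit_reg$p_value),
    regulation_groups = stats::setNames(
      as.list(grp_sum$n), paste(grp_sum$group, grp_sum$direction,
                                sep = "_")),
    n_genes_after_fc_filter = nrow(groups_filt),
    pirs = if (is.null(pirs)) NULL else list(
      n_total = nrow(pirs),
      median_per_viewpoint = pir_summary$n_pirs_median,
      median_distance = pir_summary$distance_median))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_bed(classified[, c("chrom", "start", "end", "label")] |>
                dplyr::rename(name = "label"),
              file.path(out_dir, "classified_peaks.bed"))
    write_bed(dplyr::rename(elements[, c("chrom", "start", "end",
                                         "state")], name = "state"),
              file.path(out_dir, "elements.bed"))
    readr::write_tsv(tidy(fit_cls), file.path(out_dir,
                                              "classifier_coefficients.tsv"))
    readr::write_tsv(groups, file.path(out_dir, "regulation_groups.tsv"))
    if (!is.null(pirs) && nrow(pirs) > 0) {
      write_bed(dplyr::rename(
        pirs[, c("chrom", "start", "end", "viewpoint",
                 "mean_enrichment")],
        name = "viewpoint", score = "mean_enrichment"),
        file.path(out_dir, "pirs.bed"))
    }
    jsonlite::write_json(unclass(config),
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(summary = summary, classified = classified,
                 elements = elements, fractions = fractions,
                 feature_matrix = fm_bal,
                 fits = list(classification = fit_cls,
                             regression = fit_reg),
                 groups = groups, group_summary = grp_sum,
                 pirs = pirs, pir_summary = pir_summary, delta = delta,
                 marks = marks, truth = planted$truth))
}
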