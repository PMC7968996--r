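#' Classify genes into knockdown regulation groups
#'
#' From per-gene modulation calls under single and double knockdown of two
#' paralogous factors (conditions `si1`, `si2`, `si12`), assigns each gene
#' to one of the four regulation groups:
#'
#' * **A** — preferential factor-1 regulation: `si1` alone modulates, `si2`
#'   alone does not (`si12` is ignored for A/B);
#' * **B** — the symmetric preferential factor-2 case;
#' * **C** — redundant regulation: only the double knockdown modulates;
#' * **D** — complementary regulation: both singles modulate in the same
#'   direction AND the double effect is strictly stronger
#'   (`|fc(si12)| > max(|fc(si1)|, |fc(si2)|)`);
#' * **none** — nothing modulated, or both singles modulated but failing
#'   the D test (flagged rather than silently assigned).
#'
#' Flags: `discordant` when the two single-knockdown directions differ;
#' `both_nonadditive` when both singles modulate concordantly but the
#' double effect is not stronger.
#'
#' @param calls A tibble with columns `gene`, and for each condition
#'   `c` in `si1, si2, si12`: `modulated_<c>` (logical),
#'   `dir_<c>` (`"up"`/`"down"`, `NA` when not modulated),
#'   `fc_<c>` (signed fold change, `NA` when not modulated).
#' @return `calls` with added `group`, `direction`, `discordant`,
#'   `both_nonadditive` columns; exactly one group per gene.
#' @export
classify_genes <- function(calls) {
  needed <- as.vector(outer(c("modulated_", "dir_", "fc_"),
                            c("si1", "si2", "si12"), paste0))
  missing_cols <- setdiff(c("gene", needed), names(calls))
  if (length(missing_cols) > 0) {
    stop("calls table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  calls <- tibble::as_tibble(calls)
  for (cond in c("si1", "si2", "si12")) {
    calls[[paste0("dir_", cond)]] <- as.character(calls[[paste0("dir_",
                                                                cond)]])
    calls[[paste0("fc_", cond)]] <- as.numeric(calls[[paste0("fc_",
                                                             cond)]])
  }
  m1 <- calls$modulated_si1
  m2 <- calls$modulated_si2
  m12 <- calls$modulated_si12
  if (anyNA(m1) || anyNA(m2) || anyNA(m12)) {
    stop("modulated_* must be complete (TRUE/FALSE) for all conditions",
         call. = FALSE)
  }
  same_dir <- m1 & m2 & calls$dir_si1 == calls$dir_si2
  same_dir[is.na(same_dir)] <- FALSE
  stronger <- m1 & m2 &
    !is.na(calls$fc_si12) &
    abs(calls$fc_si12) > pmax(abs(calls$fc_si1), abs(calls$fc_si2))
  stronger[is.na(stronger)] <- FALSE
  group <- dplyr::case_when(
    m1 & !m2 ~ "A",
    m2 & !m1 ~ "B",
    !m1 & !m2 & m12 ~ "C",
    m1 & m2 & same_dir & stronger ~ "D",
    TRUE ~ "none")
  direction <- dplyr::case_when(
    group == "A" ~ calls$dir_si1,
    group == "B" ~ calls$dir_si2,
    group == "C" ~ calls$dir_si12,
    group == "D" ~ calls$dir_si1,
    TRUE ~ NA_character_)
  out <- tibble::as_tibble(calls)
  out$group <- group
  out$direction <- direction
  out$discordant <- m1 & m2 & !same_dir
  out$both_nonadditive <- m1 & m2 & same_dir & !stronger
  out
}

#' Filter regulation-group assignments by fold-change magnitude
#'
#' Keeps genes whose strongest modulated fold change reaches the threshold
#' (inclusive, matching the `FC >= 1.5 or <= -1.5` convention).
#'
#' @param assignments Output of [classify_genes()].
#' @param min_abs_fc Fold-change magnitude threshold (`> 1`, default 1.5).
#' @return The filtered tibble.
#' @export
apply_fc_filter <- function(assignments, min_abs_fc = 1.5) {
  if (min_abs_fc <= 1) stop("min_abs_fc must be > 1", call. = FALSE)
  fc_mat <- cbind(
    ifelse(assignments$modulated_si1, abs(assignments$fc_si1), NA),
    ifelse(assignments$modulated_si2, abs(assignments$fc_si2), NA),
    ifelse(assignments$modulated_si12, abs(assignments$fc_si12), NA))
  strongest <- apply(fc_mat, 1, function(v) {
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  })
  assignments[!is.na(strongest) & strongest >= min_abs_fc, , drop = FALSE]
}

#' Count regulation groups by direction
#'
#' Exhaustive counts of genes per group and direction — the numbers behind
#' "up- and downregulated genes in each class" summaries. The total equals
#' the number of classified genes.
#'
#' @param assignments Output of [classify_genes()].
#' @return A tibble `group, direction, n` over the complete grid
#'   A/B/C/D x up/down plus a `none` row.
#' @export
group_summary <- function(assignments) {
  grid <- tidyr::expand_grid(group = c("A", "B", "C", "D"),
                             direction = c("up", "down"))
  grid <- dplyr::bind_rows(grid, tibble::tibble(group = "none",
                                                direction = NA_character_))
  counts <- dplyr::count(tibble::as_tibble(assignments),
                         .data$group, .data$direction, name = "n")
  out <- dplyr::left_join(grid, counts, by = c("group", "direction"))
  out$n[is.na(out$n)] <- 0L
  out
}
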