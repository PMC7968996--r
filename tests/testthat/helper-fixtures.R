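# shared in-code fixtures

# small synthetic feature matrix built directly (no genome involved)
make_fm <- function(n, seed, signal = 2, p_noise = 5) {
  withr::with_seed(seed, {
    label <- rep(c("PF1", "PF2"), each = n / 2)
    x <- matrix(stats::rnorm(n * p_noise), n, p_noise,
                dimnames = list(NULL, paste0("noise_", seq_len(p_noise))))
    planted <- stats::rnorm(n) + signal * (label == "PF1")
    fm <- dplyr::bind_cols(
      tibble::tibble(peak_id = paste0("p", seq_len(n)), label = label,
                     planted = planted),
      tibble::as_tibble(x))
    attr(fm, "feature_names") <- c("planted", colnames(x))
    fm
  })
}

make_calls <- function(m1, m2, m12, d1 = "up", d2 = "up", d12 = "up",
                       f1 = 2, f2 = 2, f12 = 3, gene = "g1") {
  tibble::tibble(
    gene = gene,
    modulated_si1 = m1, dir_si1 = ifelse(m1, d1, NA), fc_si1 = ifelse(m1, f1, NA),
    modulated_si2 = m2, dir_si2 = ifelse(m2, d2, NA), fc_si2 = ifelse(m2, f2, NA),
    modulated_si12 = m12, dir_si12 = ifelse(m12, d12, NA),
    fc_si12 = ifelse(m12, f12, NA))
}
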