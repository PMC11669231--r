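#!/usr/bin/env Rscript
# Stage 2: calibrate the three models on the 14 calibration mixtures and
# examine their tuning diagnostics: PLS latent-variable selection by
# cross-validated F test, the ANN hidden-layer scan, and the MCR-ALS
# lack-of-fit trace with the resolved spectra.

library(chemocal)

dir.create("results", showWarnings = FALSE)
dir.create("results/figures", showWarnings = FALSE)

config <- run_config()
study <- run_study(config)

# -- PLS: error versus model size ------------------------------------
cv <- study$cv
cat("PLS PRESS by latent variables:\n")
print(round(cv$per_lv_rmsecv, 4))
cat("F-test selection picks", study$n_lv, "latent variables\n")
utils::write.csv(
  data.frame(
    n_lv = seq_along(cv$per_lv_rmsecv),
    rmsecv = cv$per_lv_rmsecv, press = cv$per_lv_press
  ),
  "results/pls_cv.csv",
  row.names = FALSE
)

# -- ANN: hidden-layer sizing ---------------------------------------
cal <- study$split$calibration_rows
Xc <- apply_center(study$centering, study$spectra$absorbance[cal, ])
Y <- unclass(study$concentrations)[cal, ]
cfg <- config$ann
cfg$seed <- config$seed + 1L
scan <- scan_hidden(Xc, Y, sizes = c(2, 3, 4, 5, 8), cfg)
cat("\nANN hidden-layer scan (final training RMSEC, ug/mL):\n")
print(scan)
utils::write.csv(scan, "results/ann_hidden_scan.csv", row.names = FALSE)

# -- MCR-ALS: convergence and resolved spectra -----------------------
mcr <- study$models$`MCR-ALS`
cat("\nMCR-ALS: lack of fit", round(mcr$lof, 5), "% , r2",
    round(mcr$r2, 4), "% after", mcr$n_iter, "iterations\n")
S_true <- vapply(
  study$pure_spectra, `[[`, numeric(config$grid$points), "absorptivity"
)
sim <- spectral_similarity(mcr$S, S_true)
cat("cosine similarity of resolved vs pure spectra:\n")
print(round(sim, 5))

resolved <- structure(
  list(
    grid = config$grid, absorbance = t(mcr$S),
    sample_ids = colnames(S_true)
  ),
  class = "spectra_matrix"
)
write_spectra_csv(resolved, "results/mcr_resolved_spectra.csv")

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  p <- ggplot(
    data.frame(n_lv = seq_along(cv$per_lv_rmsecv), rmsecv = cv$per_lv_rmsecv),
    aes(n_lv, rmsecv)
  ) +
    geom_line() +
    geom_point() +
    geom_vline(xintercept = study$n_lv, linetype = 2) +
    labs(
      x = "latent variables", y = "RMSECV (ug/mL, pooled)",
      title = "PLS cross-validation error by model size"
    ) +
    theme_minimal()
  ggsave("results/figures/02_pls_rmsecv.pdf", p, width = 6, height = 4)
}
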