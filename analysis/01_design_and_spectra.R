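#!/usr/bin/env Rscript
# Stage 1: lay out the five-level four-factor calibration design, map it to
# concentrations, split calibration/validation, and simulate the mixture
# spectra. Artefacts are written under results/ so later stages can be
# re-run in isolation.

library(chemocal)

dir.create("results", showWarnings = FALSE)
dir.create("results/figures", showWarnings = FALSE)

config <- run_config() # seed 1, noise sd 0.002 AU, 250-315 nm / 0.2 nm

design <- brereton_design(5, 4)
conc <- map_design(design, config$factor_specs)
split <- split_design(design, config$validation_rows)

write_design_csv(design, "results/design_coded.csv")
write_concentrations_csv(conc, "results/design_concentrations.csv")

cat("design:", nrow(design), "runs;",
    length(split$calibration_rows), "calibration /",
    length(split$validation_rows), "validation\n")
r <- cor(unclass(design) + 0)
cat("max |pairwise column correlation|:", max(abs(r[upper.tri(r)])), "\n")

check <- all.equal(
  sort(apply(unclass(conc)[split$validation_rows, ], 1, paste, collapse = ",")),
  sort(apply(unclass(validation_set_concentrations()), 1, paste, collapse = ",")),
  check.attributes = FALSE
)
cat("validation rows reproduce the printed validation mixtures:",
    isTRUE(check), "\n")

pure <- default_pure_spectra(config$grid)
spectra <- simulate_spectra(conc, pure, noise_model(config$noise_sd, config$seed))
write_spectra_csv(spectra, "results/mixture_spectra.csv")

S <- vapply(pure, `[[`, numeric(config$grid$points), "absorptivity")
cat("pure-spectra correlation ANT vs ANT_impA:",
    round(cor(S[, "ANT"], S[, "ANT_impA"]), 3), "\n")
cat("max simulated absorbance:", round(max(spectra$absorbance), 3), "AU\n")

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  df <- data.frame(
    wavelength = rep(config$grid$wavelengths, 4),
    absorptivity = as.vector(S),
    component = rep(colnames(S), each = config$grid$points)
  )
  p <- ggplot(df, aes(wavelength, absorptivity, colour = component)) +
    geom_line() +
    labs(
      x = "wavelength (nm)", y = "absorptivity (AU per ug/mL)",
      title = "Emulated pure-component spectra"
    ) +
    theme_minimal()
  ggsave("results/figures/01_pure_spectra.pdf", p, width = 7, height = 4)
}
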