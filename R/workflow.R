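#' Printed validation-set concentrations
#'
#' The eleven external validation mixtures of the default study layout
#' (ug/mL, fixed component order), shipped as a package fixture.
#'
#' @return An 11 x 4 [concentration_matrix()].
#' @export
validation_set_concentrations <- function() {
  df <- utils::read.csv(
    system.file("extdata", "validation_concentrations.csv", package = "chemocal")
  )
  m <- as.matrix(df[, component_names()])
  rownames(m) <- paste0("mix_", df$mix)
  concentration_matrix(m)
}

#' Published per-mixture validation recoveries
#'
#' Long-format table of the reported prediction recoveries of the eleven
#' validation mixtures under the three calibration models, with the actual
#' concentrations. Used to recompute the published summary statistics and
#' prediction-error figures of merit.
#'
#' @return `data.frame` with columns `mix`, `component`, `model`, `actual`,
#'   `recovery`.
#' @export
validation_set_recoveries <- function() {
  utils::read.csv(
    system.file("extdata", "validation_recoveries.csv", package = "chemocal"),
    stringsAsFactors = FALSE
  )
}

#' Reference-method summary statistics
#'
#' Mean recovery, SD and replicate count of the reported HPLC assay used
#' as the comparison method for the two active ingredients.
#'
#' @return Named list of [summary_stats()]: `ANT` (100.03 +/- 0.961, n 5)
#'   and `BEN` (99.08 +/- 0.854, n 5).
#' @export
reference_method_stats <- function() {
  list(
    ANT = summary_stats(100.03, 0.961, 5),
    BEN = summary_stats(99.08, 0.854, 5)
  )
}

#' Study configuration
#'
#' Bundles every tunable of the end-to-end simulated study. The defaults
#' are the study conditions themselves: the 250--315 nm / 0.2 nm window,
#' the five-level four-factor design mapped to the calibrated ranges,
#' additive noise of 0.002 AU, a 14/11 calibration/validation split, up to
#' 10 PLS latent variables selected by the F test, a 326-5-4 network
#' trained for 50 epochs at learning rate 0.1, and four-component MCR-ALS
#' initialised from the purest samples.
#'
#' @param seed master seed; all stochastic stages derive from it.
#' @param grid a [wavelength_grid()].
#' @param factor_specs list of [factor_spec()] per component.
#' @param noise_sd additive spectral noise (AU).
#' @param validation_rows design rows held out for validation.
#' @param max_lv largest PLS model size assessed in cross-validation.
#' @param lv_select `"ftest"` for the F-test rule, `"min"` for the PRESS
#'   minimiser.
#' @param ann an [ann_config()] (its seed is re-derived from `seed`).
#' @param mcr an [mcr_config()].
#' @param mcr_init `"pure"` initialises the ALS from the pure-standard
#'   spectra (the laboratory situation here: every analyte is available as
#'   a measured standard), `"purest"` from the blind purest-sample
#'   estimates of [initial_spectra()].
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L,
                       grid = wavelength_grid(),
                       factor_specs = default_factor_specs(),
                       noise_sd = 0.002,
                       validation_rows = default_validation_rows(),
                       max_lv = 10,
                       lv_select = c("ftest", "min"),
                       ann = ann_config(),
                       mcr = mcr_config(),
                       mcr_init = c("pure", "purest")) {
  lv_select <- match.arg(lv_select)
  mcr_init <- match.arg(mcr_init)
  structure(
    list(
      seed = as.integer(seed), grid = grid, factor_specs = factor_specs,
      noise_sd = noise_sd, validation_rows = validation_rows,
      max_lv = as.integer(max_lv), lv_select = lv_select,
      ann = ann, mcr = mcr, mcr_init = mcr_init
    ),
    class = "run_config"
  )
}

# match resolved MCR components to analytes by the contribution/known-
# concentration correlation on the calibration rows (best assignment over
# permutations), returning the fit with reordered columns
.match_mcr_components <- function(fit, cal_rows, known_conc) {
  k <- ncol(fit$C)
  cors <- abs(stats::cor(fit$C[cal_rows, , drop = FALSE], known_conc))
  perms <- .permutations(k)
  scores <- vapply(
    perms,
    function(p) sum(cors[cbind(p, seq_len(k))]),
    numeric(1)
  )
  best <- perms[[which.max(scores)]]
  fit$C <- fit$C[, best, drop = FALSE]
  fit$S <- fit$S[, best, drop = FALSE]
  colnames(fit$C) <- colnames(known_conc)
  colnames(fit$S) <- colnames(known_conc)
  fit
}

#' Run the full simulated calibration study
#'
#' Executes the whole workflow: design generation, mapping to
#' concentrations, spectra simulation, mean-centring, calibration of the
#' three models on the 14 calibration mixtures, prediction of the 11
#' validation mixtures, and per-component figures of merit with the
#' statistical comparison against the reference method and the Eco-scale
#' greenness score. Fully reproducible from `config$seed`.
#'
#' @param config a [run_config()].
#' @return A `study_report`: list with the design artefacts, fitted
#'   models, per-model prediction matrices, nested `merit[[model]][[component]]`
#'   reports, `comparison` t/F tables, `eco_scale`, and `provenance`.
#' @export
run_study <- function(config = run_config()) {
  design <- brereton_design(5, 4)
  conc <- map_design(design, config$factor_specs)
  split <- split_design(design, config$validation_rows)
  cal <- split$calibration_rows
  val <- split$validation_rows

  pure <- default_pure_spectra(config$grid)
  spectra <- simulate_spectra(
    conc, pure,
    noise_model(config$noise_sd, seed = config$seed)
  )
  X <- spectra$absorbance
  Y <- unclass(conc)

  # mean-centring fitted on the calibration block only
  fc <- fit_center(X[cal, , drop = FALSE])
  Xc_cal <- fc$centered
  Xc_val <- apply_center(fc$model, X[val, , drop = FALSE])

  # -- PLS ------------------------------------------------------------
  cv <- loo_cv(Xc_cal, Y[cal, ], config$max_lv)
  n_lv <- if (config$lv_select == "ftest") {
    cv$selected_lv
  } else {
    which.min(cv$per_lv_press)
  }
  pls <- fit_pls(Xc_cal, Y[cal, ], n_lv)
  pred_pls <- predict_pls(pls, Xc_val)

  # -- ANN ------------------------------------------------------------
  ann_cfg <- config$ann
  ann_cfg$n_input <- ncol(X)
  ann_cfg$n_output <- ncol(Y)
  ann_cfg$seed <- config$seed + 1L
  ann <- train_ann(Xc_cal, Y[cal, ], ann_cfg)
  pred_ann <- predict_ann(ann, Xc_val)

  # -- MCR-ALS --------------------------------------------------------
  # raw (uncentred) absorbances: the non-negativity constraints require
  # them; all 25 mixtures enter the factorisation, quantification uses the
  # calibration rows only
  S0 <- if (identical(config$mcr_init, "purest")) {
    initial_spectra(X, ncol(Y))
  } else {
    vapply(pure, `[[`, numeric(config$grid$points), "absorptivity")
  }
  mcr <- fit_mcr(X, S0, config$mcr)
  mcr <- .match_mcr_components(mcr, cal, Y[cal, , drop = FALSE])
  pred_mcr <- quantify_mcr(mcr, cal, Y[cal, , drop = FALSE])

  preds <- list(PLS = pred_pls, ANN = pred_ann, `MCR-ALS` = pred_mcr)
  merit <- lapply(preds, function(P) {
    out <- lapply(colnames(Y), function(comp) {
      merit_report(Y[val, comp], P[, comp], component = comp)
    })
    names(out) <- colnames(Y)
    out
  })

  ref <- reference_method_stats()
  comparison <- lapply(names(preds), function(model) {
    rows <- lapply(names(ref), function(comp) {
      g <- from_recoveries(merit[[model]][[comp]]$recoveries)
      tt <- pooled_t_test(g, ref[[comp]])
      ff <- variance_f_test(g, ref[[comp]])
      data.frame(
        model = model, component = comp,
        mean = g$mean, sd = g$sd, n = g$n,
        t = tt$t, t_crit = tt$t_crit,
        F = ff$F, F_crit = ff$F_crit
      )
    })
    do.call(rbind, rows)
  })
  comparison <- do.call(rbind, c(comparison, list(make.row.names = FALSE)))

  structure(
    list(
      config = config,
      design = design, concentrations = conc, split = split,
      pure_spectra = pure, spectra = spectra,
      centering = fc$model,
      models = list(PLS = pls, ANN = ann, `MCR-ALS` = mcr),
      cv = cv, n_lv = n_lv,
      predictions = preds,
      merit = merit,
      comparison = comparison,
      eco_scale = eco_scale(read_penalty_items(method = "proposed")),
      provenance = list(
        seed = config$seed,
        package_version = as.character(utils::packageVersion("chemocal")),
        r_version = R.version.string
      )
    ),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat(sprintf(
    "  %d calibration / %d validation mixtures, noise sd %.4g AU, seed %d\n",
    length(x$split$calibration_rows), length(x$split$validation_rows),
    x$config$noise_sd, x$config$seed
  ))
  cat(sprintf("  PLS latent variables: %d\n", x$n_lv))
  for (model in names(x$merit)) {
    mr <- vapply(x$merit[[model]], `[[`, numeric(1), "mean")
    cat(sprintf(
      "  %-7s mean recoveries: %s\n", model,
      paste(sprintf("%s %.2f%%", names(mr), mr), collapse = ", ")
    ))
  }
  cat(sprintf(
    "  Eco-scale score: %d (%s)\n",
    x$eco_scale$score, x$eco_scale$classification
  ))
  invisible(x)
}

#' Dosage-form assay with standard addition
#'
#' Simulates the two-drug ear-drop scenario: an excipient-free sample
#' containing 5.0 ug/mL ANT and 1.0 ug/mL BEN (impurity and degradant
#' absent) assayed in triplicate with each fitted model, followed by the
#' standard-addition series -- ANT taken 3.0 ug/mL spiked with 1.5, 3.0
#' and 6.0 ug/mL against a 1.0 ug/mL BEN background, and BEN taken
#' 1.0 ug/mL spiked with 0.5, 1.0 and 2.0 ug/mL against a 3.0 ug/mL ANT
#' background.
#'
#' @param study a `study_report` from [run_study()] (supplies the fitted
#'   models, centring and noise settings).
#' @param n_replicates replicate determinations of the plain dosage sample.
#' @return An `assay_report`: per-model `found` (% of label claim,
#'   mean and sd per drug) and `standard_addition` results.
#' @export
run_assay_scenario <- function(study, n_replicates = 3) {
  if (!inherits(study, "study_report")) {
    stop("`study` must be a fitted study_report", call. = FALSE)
  }
  config <- study$config
  pure <- study$pure_spectra
  comps <- component_names()

  make_conc <- function(ant, ben) {
    concentration_matrix(cbind(ant, ben, 0, 0), components = comps)
  }
  predict_all <- function(conc_mat, seed_offset) {
    sp <- simulate_spectra(
      conc_mat, pure,
      noise_model(config$noise_sd, seed = config$seed + seed_offset)
    )
    Xc <- apply_center(study$centering, sp$absorbance)
    list(
      PLS = predict_pls(study$models$PLS, Xc),
      ANN = predict_ann(study$models$ANN, Xc),
      `MCR-ALS` = {
        # append to the study matrix so the factorisation context is shared
        D <- rbind(study$spectra$absorbance, sp$absorbance)
        fit <- fit_mcr(D, study$models$`MCR-ALS`$S, config$mcr)
        cal <- study$split$calibration_rows
        fit <- .match_mcr_components(
          fit, cal,
          unclass(study$concentrations)[cal, , drop = FALSE]
        )
        all_pred <- quantify_mcr(
          fit, cal,
          unclass(study$concentrations)[cal, , drop = FALSE]
        )
        n_new <- nrow(sp$absorbance)
        all_pred[seq(nrow(all_pred) - n_new + 1, nrow(all_pred)), ,
          drop = FALSE
        ]
      }
    )
  }

  # plain dosage-form determinations
  label <- c(ANT = 5.0, BEN = 1.0)
  plain <- make_conc(rep(label["ANT"], n_replicates), rep(label["BEN"], n_replicates))
  plain_pred <- predict_all(plain, seed_offset = 100L)
  found <- lapply(plain_pred, function(P) {
    lapply(c("ANT", "BEN"), function(d) {
      pct <- 100 * P[, d] / label[[d]]
      list(mean = mean(pct), sd = stats::sd(pct))
    }) |> stats::setNames(c("ANT", "BEN"))
  })

  # standard addition series
  spikes <- list(
    ANT = list(taken = 3.0, added = c(1.5, 3.0, 6.0), background_ben = 1.0),
    BEN = list(taken = 1.0, added = c(0.5, 1.0, 2.0), background_ant = 3.0)
  )
  ant_conc <- make_conc(
    spikes$ANT$taken + spikes$ANT$added,
    rep(spikes$ANT$background_ben, 3)
  )
  ben_conc <- make_conc(
    rep(spikes$BEN$background_ant, 3),
    spikes$BEN$taken + spikes$BEN$added
  )
  ant_pred <- predict_all(ant_conc, seed_offset = 200L)
  ben_pred <- predict_all(ben_conc, seed_offset = 300L)
  std_add <- lapply(names(plain_pred), function(model) {
    list(
      ANT = standard_addition(
        spikes$ANT$taken, spikes$ANT$added, ant_pred[[model]][, "ANT"]
      ),
      BEN = standard_addition(
        spikes$BEN$taken, spikes$BEN$added, ben_pred[[model]][, "BEN"]
      )
    )
  })
  names(std_add) <- names(plain_pred)

  structure(
    list(
      label_claim = label, found = found,
      spike_levels = list(ANT = spikes$ANT$added, BEN = spikes$BEN$added),
      standard_addition = std_add
    ),
    class = "assay_report"
  )
}

#' @export
print.assay_report <- function(x, ...) {
  cat("<assay_report> dosage form: ANT 5.0, BEN 1.0 ug/mL\n")
  for (model in names(x$found)) {
    f <- x$found[[model]]
    s <- x$standard_addition[[model]]
    cat(sprintf(
      "  %-7s found ANT %.2f +/- %.3f%%, BEN %.2f +/- %.3f%%; std-add ANT %.2f%%, BEN %.2f%%\n",
      model, f$ANT$mean, f$ANT$sd, f$BEN$mean, f$BEN$sd,
      s$ANT$mean, s$BEN$mean
    ))
  }
  invisible(x)
}

#' Serialise a study report's headline numbers to JSON
#'
#' @param study a `study_report`.
#' @param path output file.
#' @export
write_study_json <- function(study, path) {
  merit <- lapply(study$merit, function(by_comp) {
    lapply(by_comp, function(r) {
      r[c(
        "component", "n", "mean", "sd", "rsd", "slope", "intercept",
        "r", "bias", "sep", "rmsep", "lod", "loq"
      )]
    })
  })
  jsonlite::write_json(
    list(
      n_lv = study$n_lv,
      merit = merit,
      comparison = study$comparison,
      eco_scale = unclass(study$eco_scale),
      provenance = study$provenance
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
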