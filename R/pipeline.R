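#' Pipeline run configuration
#'
#' Assembles the configuration consumed by [run_pipeline()]: cohort spec,
#' optional phantom stage, noise level, seed fan-out and output directory.
#' Every stage seed is derived deterministically from the single top-level
#' seed, so a rerun with the same config is byte-identical.
#'
#' @param outdir output directory (created if missing).
#' @param seed top-level integer seed.
#' @param cohort a [cohort_spec()]; its seed is overridden by the fan-out.
#' @param run_phantom logical: include the phantom simulation + voxel-wise
#'   fitting + image-quality stage (slower).
#' @param phantom a [phantom_spec()] used when `run_phantom` is TRUE
#'   (default: a small two-lesion phantom with 2\% Rician noise).
#' @param calibration_B bootstrap replicates for the calibration stage.
#' @return list of class `run_config`.
#' @export
run_config <- function(outdir = tempfile("frocdwi_run_"), seed = 1L,
                       cohort = cohort_spec(), run_phantom = FALSE,
                       phantom = NULL, calibration_B = 200L) {
  if (is.null(phantom) && run_phantom) phantom <- default_phantom_spec()
  structure(list(outdir = outdir, seed = as.integer(seed), cohort = cohort,
                 run_phantom = isTRUE(run_phantom), phantom = phantom,
                 calibration_B = as.integer(calibration_B)),
            class = "run_config")
}

#' Small demonstration phantom
#'
#' A 24 x 16 x 6 grid with an air slab, background tissue, and two
#' ellipsoidal lesions whose FROC parameters sit at the benign and
#' malignant group means, with 2\% Rician noise.
#'
#' @param noise_sigma Gaussian channel SD relative to S0 = 100.
#' @param seed integer seed.
#' @return a [phantom_spec()].
#' @export
default_phantom_spec <- function(noise_sigma = 2, seed = 1L) {
  phantom_spec(
    grid_shape = c(24, 16, 6), voxel_size = c(0.9, 0.9, 4),
    lesions = list(
      list(center = c(12, 5, 3), semi_axes = c(3, 3, 2),
           params = froc_params(1.17, 0.86, 3.06), s0 = 100),
      list(center = c(19, 11, 3), semi_axes = c(3, 3, 2),
           params = froc_params(0.73, 0.77, 3.39), s0 = 100)),
    background = list(params = froc_params(1.8, 0.95, 5), s0 = 60),
    air_fraction = 0.25, noise_sigma = noise_sigma, seed = seed)
}

.stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full analysis pipeline
#'
#' Orchestrates cohort simulation, two-group statistics, between-sequence
#' agreement, ROC/diagnostic modelling (logistic D + beta model, nomogram,
#' Hosmer-Lemeshow, bootstrap calibration, decision curves) and — when
#' enabled — the phantom simulation, voxel-wise fitting and image-quality
#' stage. All tables are written as CSV and a JSON summary bundles the
#' headline numbers; the run is a pure function of the config.
#'
#' @param config a [run_config()] (or path to a YAML file with its fields).
#' @return invisibly, the summary list (also written to summary.json).
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) {
    y <- yaml::read_yaml(config)
    config <- run_config(
      outdir = y$outdir %||% tempfile("frocdwi_run_"),
      seed = y$seed %||% 1L,
      cohort = cohort_spec(n_benign = y$n_benign %||% 73L,
                           n_malignant = y$n_malignant %||% 105L),
      run_phantom = isTRUE(y$run_phantom),
      calibration_B = y$calibration_B %||% 200L)
  }
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  seeds <- config$seed + c(cohort = 1L, phantom = 2L, calib = 3L)
  summary <- list(seed = config$seed)

  .stage_log("cohort", "simulating %d benign / %d malignant lesions",
             config$cohort$n_benign, config$cohort$n_malignant)
  cohort <- simulate_cohort(config$cohort, seed = seeds[["cohort"]])
  write_cohort(cohort, file.path(config$outdir, "cohort.csv"))

  params <- c("D", "beta", "mu", "adc")
  seqs <- sort(unique(cohort$sequence))

  .stage_log("group_stats", "two-group tests per parameter and sequence")
  gs <- list()
  for (s in seqs) for (p in params) {
    cs <- cohort[cohort$sequence == s, ]
    xb <- cs[[p]][cs$group == "benign"]
    xm <- cs[[p]][cs$group == "malignant"]
    cmp <- compare_groups(xb, xm)
    gs[[paste(s, p)]] <- data.frame(
      sequence = s, parameter = p,
      benign_mean = mean(xb), benign_sd = stats::sd(xb),
      malignant_mean = mean(xm), malignant_sd = stats::sd(xm),
      test = cmp$test, p_value = cmp$p)
  }
  group_stats <- do.call(rbind, gs); rownames(group_stats) <- NULL
  utils::write.csv(group_stats,
                   file.path(config$outdir, "group_stats.csv"),
                   row.names = FALSE)

  .stage_log("agreement", "between-sequence correlation and Bland-Altman")
  ag <- list()
  for (p in params) {
    wide <- merge(
      cohort[cohort$sequence == seqs[1], c("lesion_id", p)],
      cohort[cohort$sequence == seqs[2], c("lesion_id", p)],
      by = "lesion_id", suffixes = c("_a", "_b"))
    sp <- spearman_with_category(wide[[2]], wide[[3]])
    ba <- bland_altman(wide[[2]], wide[[3]])
    ag[[p]] <- data.frame(
      parameter = p, spearman_r = sp$estimate,
      spearman_lo = sp$ci[1], spearman_hi = sp$ci[2],
      category = sp$category, bias = ba$bias,
      loa_lower = ba$loa_lower, loa_upper = ba$loa_upper)
  }
  agreement <- do.call(rbind, ag); rownames(agreement) <- NULL
  utils::write.csv(agreement, file.path(config$outdir, "agreement.csv"),
                   row.names = FALSE)

  .stage_log("diagnostics", "ROC, logistic model, nomogram, calibration, DCA")
  roc_rows <- list()
  models <- list()
  for (s in seqs) {
    cs <- cohort[cohort$sequence == s, ]
    for (p in params) {
      dirn <- if (p == "mu") "higher" else "lower"
      rr <- roc_analysis(cs[[p]], cs$group, direction = dirn)
      roc_rows[[paste(s, p)]] <- data.frame(
        sequence = s, score = p, cutoff = rr$cutoff, auc = rr$auc,
        auc_lo = rr$auc_ci[1], auc_hi = rr$auc_ci[2],
        sensitivity = rr$sensitivity, specificity = rr$specificity,
        accuracy = rr$accuracy)
    }
    mod <- suppressWarnings(
      fit_logistic_with_selection(cs, features = c("D", "beta", "mu")))
    if (length(mod$retained) == 0L) {
      .stage_log("diagnostics",
                 "no feature passed selection in %s; keeping all features", s)
      mod <- suppressWarnings(
        fit_logistic_with_selection(cs, features = c("D", "beta", "mu"),
                                    alpha = 1))
    }
    models[[s]] <- mod
    rr <- combined_roc(mod)
    roc_rows[[paste(s, "model")]] <- data.frame(
      sequence = s, score = paste(mod$retained, collapse = "+"),
      cutoff = rr$cutoff, auc = rr$auc,
      auc_lo = rr$auc_ci[1], auc_hi = rr$auc_ci[2],
      sensitivity = rr$sensitivity, specificity = rr$specificity,
      accuracy = rr$accuracy)
    hl <- hosmer_lemeshow(mod)
    cal <- bootstrap_calibration(mod, B = config$calibration_B,
                                 seed = seeds[["calib"]])
    utils::write.csv(cal, file.path(config$outdir,
                                    paste0("calibration_", s, ".csv")),
                     row.names = FALSE)
    dca <- decision_curve(mod$fitted, mod$y)
    utils::write.csv(dca, file.path(config$outdir,
                                    paste0("dca_", s, ".csv")),
                     row.names = FALSE)
    nom <- build_nomogram(mod)
    utils::write.csv(nom$probability_table,
                     file.path(config$outdir, paste0("nomogram_", s, ".csv")),
                     row.names = FALSE)
    summary[[paste0("model_", s)]] <- list(
      retained = mod$retained,
      coefficients = round(mod$coefficients, 6),
      hosmer_lemeshow_p = hl$p,
      max_calibration_gap = max(abs(cal$observed_corrected - cal$predicted)))
  }
  roc_table <- do.call(rbind, roc_rows); rownames(roc_table) <- NULL
  utils::write.csv(roc_table, file.path(config$outdir, "roc_table.csv"),
                   row.names = FALSE)
  # paired DeLong: D vs ADC within sequence
  delong_rows <- lapply(seqs, function(s) {
    cs <- cohort[cohort$sequence == s, ]
    dt <- delong_test(-cs$D, -cs$adc, cs$group)
    data.frame(sequence = s, comparison = "D vs ADC", z = dt$z, p = dt$p)
  })
  delong_table <- do.call(rbind, delong_rows)
  utils::write.csv(delong_table, file.path(config$outdir, "delong.csv"),
                   row.names = FALSE)

  if (config$run_phantom) {
    .stage_log("phantom", "simulating and fitting the digital phantom")
    ph <- config$phantom
    sim <- list(maps = generate_parameter_maps(ph),
                series = NULL)
    sim$series <- simulate_dwi_series(sim$maps, protocol_14b(),
                                      ph$noise_sigma, seeds[["phantom"]])
    mask <- sim$maps$label >= 1L
    fits <- fit_volume(sim$series, mask)
    qt <- series_quality_table(sim$series,
                               lesion_mask = sim$maps$label == 2L,
                               tissue_mask = sim$maps$label == 1L,
                               background_mask = sim$maps$label == 0L)
    utils::write.csv(qt, file.path(config$outdir, "quality_table.csv"),
                     row.names = FALSE)
    les_stats <- lapply(seq_along(ph$lesions), function(k) {
      voi <- sim$maps$label == k + 1L
      data.frame(
        lesion = k,
        beta_hat = voi_statistics(fits$beta, voi, fits$converged)$mean,
        beta_true = ph$lesions[[k]]$params$beta,
        adc_hat = voi_statistics(fits$adc, voi, fits$converged)$mean,
        decay_hat = voi_statistics(fits$decay_coefficient, voi,
                                   fits$converged)$mean,
        decay_true = froc_decay_coefficient(ph$lesions[[k]]$params),
        nonconverged = mean(!fits$converged[voi]))
    })
    phantom_table <- do.call(rbind, les_stats)
    utils::write.csv(phantom_table,
                     file.path(config$outdir, "phantom_recovery.csv"),
                     row.names = FALSE)
    summary$phantom <- list(
      snr_b0 = qt$snr[qt$b == 0], snr_bmax = qt$snr[nrow(qt)],
      max_beta_error = max(abs(phantom_table$beta_hat -
                                 phantom_table$beta_true)))
  }

  summary$group_stats <- group_stats
  summary$roc <- roc_table
  summary$agreement <- agreement
  summary$delong <- delong_table
  json <- jsonlite::toJSON(summary, auto_unbox = TRUE, digits = 10,
                           pretty = TRUE)
  writeLines(json, file.path(config$outdir, "summary.json"))
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
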