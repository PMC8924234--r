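#' Default pipeline configuration
#'
#' All defaults reproduce the study constants: 768-px canvas, 1-cycle/image
#' annular bins with a 25\% first-harmonic threshold, preferred-numerosity
#' range 1.05--6.95, 0.2-degree eccentricity bins and 1000 bootstrap
#' resamples.  Scaled-down values are convenient for quick runs.
#'
#' @param canvas_px Canvas side in pixels.
#' @param numerosities Numerosities per configuration.
#' @param configurations fMRI stimulus configurations to simulate.
#' @param displays_per_numerosity Rendered displays per numerosity and
#'   configuration.
#' @param n_voxels Synthetic voxels per cohort.
#' @param n_boot Bootstrap resamples for profile fits.
#' @param seed Global seed for the run.
#'
#' @return Named list of settings.
#' @export
pipeline_config <- function(canvas_px = DEFAULT_CANVAS,
                            numerosities = c(1:7, 20),
                            configurations = c("constant_area",
                                               "constant_size",
                                               "constant_perimeter",
                                               "high_density"),
                            displays_per_numerosity = 4,
                            n_voxels = 60,
                            n_boot = 100,
                            seed = 1) {
  list(canvas_px = canvas_px, numerosities = numerosities,
       configurations = configurations,
       displays_per_numerosity = displays_per_numerosity,
       n_voxels = n_voxels, n_boot = n_boot, seed = seed)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes every stage end-to-end with a single seed: display generation
#' for each configuration and numerosity, aggregate Fourier power, stimulus
#' sequences from the per-numerosity mean power, a synthetic voxel cohort,
#' monotonic and tuned model fits with split-half cross-validation,
#' eccentricity binning and profile fitting, and a model comparison.
#' Outputs are returned as tibbles and optionally written as CSV files.
#'
#' @param config From [pipeline_config()].
#' @param out_dir Optional directory for CSV outputs.
#'
#' @return List: `power` (per-display power table), `power_by_numerosity`,
#'   `sequence`, `fits`, `bins`, `profile`, `comparison`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  set.seed(config$seed)
  power <- purrr::list_rbind(purrr::map(config$configurations, function(cf) {
    purrr::list_rbind(purrr::map(config$numerosities, function(n) {
      purrr::list_rbind(purrr::map(seq_len(config$displays_per_numerosity),
        function(rep) {
          sp <- make_configuration_display(cf, n,
                                           canvas_px = config$canvas_px)
          dplyr::bind_cols(
            tibble(configuration = cf, numerosity = n, replicate = rep),
            aggregate_power(sp))
        }))
    }))
  }))
  power_by_n <- power |>
    dplyr::group_by(.data$configuration, .data$numerosity) |>
    dplyr::summarise(mean_power = mean(.data$normalized), .groups = "drop")

  # sequence driven by the pooled mean power per numerosity; design labels
  # not simulated directly are interpolated on log-log axes
  pooled <- power_by_n |>
    dplyr::group_by(.data$numerosity) |>
    dplyr::summarise(value = mean(.data$mean_power), .groups = "drop")
  design <- numerosity_sequence()
  labels <- sort(unique(design$label))
  vals <- exp(approx(log(pooled$numerosity), log(pooled$value),
                     xout = log(labels), rule = 2)$y)
  seq <- build_sequence(setNames(vals, labels), design)

  cohort <- simulate_cohort(n_voxels = config$n_voxels,
                            model_kind = "monotonic_increasing",
                            profile = "sigmoid")
  fits <- fit_voxels(cohort$ts, numerosity_sequence(),
                     ts_heldout = cohort$ts_heldout)
  mono <- dplyr::filter(fits, .data$model == "monotonic")
  tuned <- dplyr::filter(fits, .data$model == "tuned")
  keep <- apply_inclusion_rule(fits)
  bins <- bin_by_eccentricity(mono)
  profile <- fit_eccentricity_profile(mono, "sigmoid",
                                      n_boot = config$n_boot)
  comparison <- compare_models_wilcoxon(
    mono$r2_cv[mono$voxel_id %in% keep],
    tuned$r2_cv[tuned$voxel_id %in% keep])

  out <- list(power = power, power_by_numerosity = power_by_n,
              sequence = seq, fits = fits, bins = bins, profile = profile,
              comparison = comparison)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(power, file.path(out_dir, "power.csv"),
                     row.names = FALSE)
    utils::write.csv(power_by_n,
                     file.path(out_dir, "power_by_numerosity.csv"),
                     row.names = FALSE)
    utils::write.csv(fits, file.path(out_dir, "fits.csv"), row.names = FALSE)
    utils::write.csv(bins, file.path(out_dir, "bins.csv"), row.names = FALSE)
    utils::write.csv(comparison, file.path(out_dir, "comparison.csv"),
                     row.names = FALSE)
  }
  out
}
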