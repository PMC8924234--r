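#' Simulate one voxel's BOLD response to the numerosity sequence
#'
#' Generates the noiseless model prediction for a monotonic or tuned voxel,
#' convolved with the HRF, plus additive Gaussian noise (optionally AR(1)).
#'
#' @param model_kind `"monotonic_increasing"`, `"monotonic_decreasing"` or
#'   `"tuned"`.
#' @param seq Stimulus sequence.
#' @param beta,baseline Monotonic scaling and offset (monotonic kinds).
#' @param mu,sigma,amplitude Tuned parameters (tuned kind); `mu` may lie
#'   outside \[1.05, 6.95\] to probe boundary behaviour.
#' @param scaling Scaling of the monotonic predictor.
#' @param noise_sd Standard deviation of the additive noise.
#' @param ar1 AR(1) coefficient of the noise (0 = white).
#' @param kernel Optional HRF kernel.
#'
#' @return Numeric BOLD vector, one sample per TR.
#' @export
simulate_voxel <- function(model_kind, seq,
                           beta = 1, baseline = 0,
                           mu = 3, sigma = 0.3, amplitude = 1,
                           scaling = "log",
                           noise_sd = 0, ar1 = 0, kernel = NULL) {
  model_kind <- match.arg(model_kind, c("monotonic_increasing",
                                        "monotonic_decreasing", "tuned"))
  stopifnot(noise_sd >= 0)
  clean <- switch(model_kind,
    monotonic_increasing = baseline +
      abs(beta) * monotonic_prediction(seq, scaling, kernel),
    monotonic_decreasing = baseline -
      abs(beta) * monotonic_prediction(seq, scaling, kernel),
    tuned = baseline + amplitude * tuned_prediction(seq, mu, sigma, kernel))
  n <- length(clean)
  if (noise_sd == 0) return(clean)
  eps <- rnorm(n, sd = noise_sd)
  if (ar1 != 0) {
    innov_sd <- noise_sd * sqrt(1 - ar1^2)
    eps <- as.numeric(stats::filter(rnorm(n, sd = innov_sd), ar1,
                                    method = "recursive",
                                    init = rnorm(1, sd = noise_sd)))
  }
  clean + eps
}

#' Simulate a synthetic voxel cohort with a known eccentricity profile
#'
#' Emulates the statistical structure of a visual-field-map voxel
#' population: each voxel has a pRF eccentricity drawn uniformly over
#' \[0, 5.5\] degrees, a response model (monotonic or tuned) with known
#' parameters, and additive noise scaled so that the expected variance
#' explained follows the map's generating eccentricity profile -- a
#' decreasing cumulative-Gaussian sigmoid for early visual maps (best fits
#' near fixation, falling to zero in the periphery) or a flat/quadratic
#' profile for association maps.  Two independent-noise split halves are
#' generated for cross-validation.
#'
#' @param n_voxels Number of voxels.
#' @param model_kind Generating response model for all voxels (or a vector,
#'   recycled).
#' @param profile `"sigmoid"` or `"flat"`.
#' @param inflection,slope,max_ve,min_ve Sigmoid profile parameters
#'   (inflection and slope in degrees; asymptotic variance explained at
#'   fixation and in the far periphery).
#' @param flat_ve Expected variance explained under the flat profile.
#' @param seq Stimulus sequence.
#' @param beta,mu_range,sigma,amplitude Generating response parameters;
#'   tuned voxels draw preferred numerosities log-uniformly from `mu_range`.
#' @param map_label Label stored with each voxel.
#'
#' @return List with `specs` (one row per voxel: generating parameters,
#'   eccentricity, noise SD) and `ts` / `ts_heldout` (tibbles of BOLD
#'   samples, columns `t1...`).
#' @export
simulate_cohort <- function(n_voxels = 200,
                            model_kind = "monotonic_increasing",
                            profile = c("sigmoid", "flat"),
                            inflection = 1.5, slope = 0.5,
                            max_ve = 0.6, min_ve = 0.02,
                            flat_ve = 0.3,
                            seq = numerosity_sequence(),
                            beta = 1, mu_range = c(1.5, 6),
                            sigma = 0.35, amplitude = 1,
                            map_label = "V1") {
  profile <- match.arg(profile)
  kinds <- rep_len(model_kind, n_voxels)
  ecc <- runif(n_voxels, 0, 5.5)
  target_ve <- if (profile == "sigmoid") {
    min_ve + (max_ve - min_ve) * (1 - stats::pnorm((ecc - inflection) / slope))
  } else {
    rep(flat_ve, n_voxels)
  }
  target_ve <- pmin(pmax(target_ve, 1e-4), 0.999)
  mus <- exp(runif(n_voxels, log(mu_range[1]), log(mu_range[2])))
  kernel <- hrf_kernel(attr(seq, "tr_s") %||% 2.1)
  rows <- purrr::map(seq_len(n_voxels), function(i) {
    clean <- simulate_voxel(kinds[i], seq, beta = beta, mu = mus[i],
                            sigma = sigma, amplitude = amplitude,
                            noise_sd = 0, kernel = kernel)
    sig_sd <- sd(clean)
    # E[VE] = signal_var / (signal_var + noise_var)
    noise_sd <- sig_sd * sqrt((1 - target_ve[i]) / target_ve[i])
    tibble(voxel_id = i, model_kind = kinds[i], eccentricity_deg = ecc[i],
           map_label = map_label, beta = beta,
           mu = ifelse(kinds[i] == "tuned", mus[i], NA_real_),
           sigma = ifelse(kinds[i] == "tuned", sigma, NA_real_),
           noise_sd = noise_sd, target_ve = target_ve[i],
           clean = list(clean))
  })
  specs <- purrr::list_rbind(rows)
  make_half <- function() {
    m <- do.call(rbind, purrr::map2(specs$clean, specs$noise_sd,
                                    function(cl, ns) cl + rnorm(length(cl),
                                                                sd = ns)))
    colnames(m) <- paste0("t", seq_len(ncol(m)))
    dplyr::bind_cols(specs[, c("voxel_id", "eccentricity_deg", "map_label")],
                     as_tibble(m))
  }
  list(specs = dplyr::select(specs, -"clean"),
       ts = make_half(), ts_heldout = make_half())
}
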