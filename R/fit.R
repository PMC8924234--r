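#' Fit a monotonic response model to a voxel time series
#'
#' The feature amplitude sequence (log- or linearly-scaled) is convolved with
#' the HRF and the resulting predictor is fit to the observed BOLD series by
#' ordinary least squares with an intercept, giving the baseline and the
#' scaling factor beta.  The sign of beta distinguishes monotonically
#' increasing from decreasing responses.
#'
#' @param bold Numeric vector of BOLD samples, one per TR of `seq`.
#' @param seq Stimulus sequence ([numerosity_sequence()] /
#'   [build_sequence()]).
#' @param scaling `"log"` or `"linear"`.
#' @param kernel Optional HRF kernel.
#'
#' @return One-row tibble of class `monotonic_fit`: `model`, `scaling`,
#'   `beta`, `baseline`, `direction`, `r2`.
#' @export
fit_monotonic <- function(bold, seq, scaling = c("log", "linear"),
                          kernel = NULL) {
  scaling <- match.arg(scaling)
  stopifnot(length(bold) == nrow(seq))
  if (var(bold) < .Machine$double.eps) {
    stop("fit_monotonic: zero-variance time series, R^2 undefined")
  }
  pred <- monotonic_prediction(seq, scaling, kernel)
  f <- lm_two_param(bold, pred)
  out <- tibble(model = "monotonic", scaling = scaling, beta = f$beta,
                baseline = f$baseline, direction = sign(f$beta), r2 = f$r2)
  class(out) <- c("monotonic_fit", class(out))
  attr(out, "predictor") <- pred
  out
}

lm_two_param <- function(y, x) {
  vx <- var(x)
  beta <- if (vx < .Machine$double.eps) 0 else cov(y, x) / vx
  baseline <- mean(y) - beta * mean(x)
  res <- y - baseline - beta * x
  list(beta = beta, baseline = baseline,
       r2 = 1 - sum(res^2) / sum((y - mean(y))^2))
}

#' @importFrom stats cov
NULL

#' Fit a tuned (logarithmic Gaussian) response model by grid search
#'
#' Builds candidate neural time courses for every (mu, sigma) pair on the
#' grid, convolves them with the HRF, selects the candidate best correlated
#' with the observed response, and then estimates amplitude and baseline for
#' that candidate by least squares.  Preferred values are restricted to
#' 1.05--6.95, within the presented numerosity range, because tuning
#' parameters beyond the presented range are not identifiable.
#'
#' @param bold BOLD vector.
#' @param seq Stimulus sequence.
#' @param mu_grid Candidate preferred values (log-spaced by default).
#' @param sigma_grid Candidate tuning widths, log units.
#' @param kernel Optional HRF kernel.
#'
#' @return One-row tibble of class `tuned_fit`: `model`, `mu`, `sigma`,
#'   `beta`, `baseline`, `r2`.
#' @export
fit_tuned <- function(bold, seq,
                      mu_grid = default_mu_grid(),
                      sigma_grid = default_sigma_grid(),
                      kernel = NULL) {
  stopifnot(length(bold) == nrow(seq))
  if (length(mu_grid) == 0 || length(sigma_grid) == 0) {
    stop("fit_tuned: empty parameter grid")
  }
  if (any(mu_grid < 1.05 - 1e-9) || any(mu_grid > 6.95 + 1e-9)) {
    stop("fit_tuned: mu grid must lie within [1.05, 6.95]")
  }
  if (is.null(kernel)) kernel <- hrf_kernel(attr(seq, "tr_s") %||% 2.1)
  cands <- tuned_candidates(seq, mu_grid, sigma_grid, kernel)
  cc <- as.numeric(cor(bold, cands$preds))
  cc[is.na(cc)] <- -Inf
  best <- which.max(cc)
  pred <- cands$preds[, best]
  f <- lm_two_param(bold, pred)
  out <- tibble(model = "tuned", mu = cands$grid$mu[best],
                sigma = cands$grid$sigma[best],
                beta = f$beta, baseline = f$baseline, r2 = f$r2)
  class(out) <- c("tuned_fit", class(out))
  attr(out, "predictor") <- pred
  out
}

#' @rdname fit_tuned
#' @export
default_mu_grid <- function() exp(seq(log(1.05), log(6.95), length.out = 60))

#' @rdname fit_tuned
#' @export
default_sigma_grid <- function() exp(seq(log(0.05), log(2), length.out = 40))

# candidate predictions are cached per (sequence values, grids, kernel)
candidate_cache <- new.env(parent = emptyenv())

tuned_candidates <- function(seq, mu_grid, sigma_grid, kernel) {
  key <- paste(c(signif(seq$value, 10), "|", signif(mu_grid, 8), "|",
                 signif(sigma_grid, 8), "|", signif(kernel, 8)),
               collapse = ",")
  hit <- candidate_cache[[key]]
  if (!is.null(hit)) return(hit)
  grid <- tidyr::expand_grid(mu = mu_grid, sigma = sigma_grid)
  logx <- log(seq$value)
  n <- length(logx)
  # neural amplitudes for all candidates at once: n x n_candidates
  amps <- exp(-(outer(logx, log(grid$mu), "-"))^2 /
                matrix(2 * grid$sigma^2, n, nrow(grid), byrow = TRUE))
  kv <- numeric(n)
  idx <- seq_len(min(length(kernel), n))
  kv[idx] <- kernel[idx]
  if (length(kernel) > n) {
    extra <- kernel[-seq_len(n)]
    for (i in seq_along(extra)) {
      j <- (i - 1) %% n + 1
      kv[j] <- kv[j] + extra[i]
    }
  }
  fk <- fft(kv)
  preds <- Re(mvfft(mvfft(amps) * matrix(fk, n, ncol(amps)),
                    inverse = TRUE)) / n
  out <- list(grid = grid, preds = preds)
  candidate_cache[[key]] <- out
  out
}

#' @importFrom stats mvfft
NULL

#' Choose the scaling mode for a monotonic feature model
#'
#' Given per-voxel fits under logarithmic and linear scaling, selects the
#' single scaling giving the highest summed variance explained across all
#' recording sites.  Ties break to logarithmic scaling.
#'
#' @param fits_log,fits_linear Data frames (or vectors) of `r2` values for
#'   the same voxels under the two scalings.
#'
#' @return `"log"` or `"linear"`.
#' @export
choose_scaling <- function(fits_log, fits_linear) {
  ve <- function(x) if (is.data.frame(x)) sum(x$r2) else sum(x)
  if (ve(fits_linear) > ve(fits_log)) "linear" else "log"
}

#' Cross-validate a fitted response model on held-out data
#'
#' Freezes the model's shape parameters (the tuned mu and sigma, or the
#' monotonic predictor), refits only amplitude and baseline on the held-out
#' half -- response amplitude varies between scan sessions -- and evaluates
#' variance explained there.  For monotonic models the refit scaling factor
#' may not change sign; when the unconstrained refit would flip the sign,
#' beta is clamped to zero and the recorded cross-validated variance
#' explained is non-positive by construction.
#'
#' @param fit A `monotonic_fit` or `tuned_fit`.
#' @param bold_heldout BOLD vector from the complementary half.
#' @param seq Stimulus sequence of the held-out half (same design).
#' @param kernel Optional HRF kernel.
#'
#' @return The fit with columns `beta_cv` and `r2_cv` added.
#' @export
cross_validate_fit <- function(fit, bold_heldout, seq = NULL, kernel = NULL) {
  pred <- attr(fit, "predictor")
  if (is.null(pred)) {
    stopifnot(!is.null(seq))
    pred <- if (inherits(fit, "tuned_fit")) {
      if (is.null(kernel)) kernel <- hrf_kernel(attr(seq, "tr_s") %||% 2.1)
      tuned_prediction(seq, fit$mu, fit$sigma, kernel)
    } else {
      monotonic_prediction(seq, fit$scaling, kernel)
    }
  }
  f <- lm_two_param(bold_heldout, pred)
  beta_cv <- f$beta
  if (inherits(fit, "monotonic_fit") && sign(beta_cv) != 0 &&
      sign(beta_cv) != sign(fit$beta)) {
    beta_cv <- 0
  }
  baseline <- mean(bold_heldout) - beta_cv * mean(pred)
  res <- bold_heldout - baseline - beta_cv * pred
  r2_cv <- 1 - sum(res^2) / sum((bold_heldout - mean(bold_heldout))^2)
  fit$beta_cv <- beta_cv
  fit$r2_cv <- r2_cv
  fit
}

#' Pool variance explained across stimulus configurations
#'
#' Computes the proportion of the total response variance across all
#' configurations that a model explains -- summed explained variance divided
#' by summed total variance -- rather than averaging per-configuration
#' variance-explained values, so that configurations with larger signal
#' variance weigh more.
#'
#' @param r2 Per-configuration variance explained.
#' @param total_variance Per-configuration total signal variance (same
#'   length).
#'
#' @return Pooled variance explained (scalar).
#' @export
pool_configurations <- function(r2, total_variance) {
  stopifnot(length(r2) == length(total_variance), length(r2) >= 1)
  sum(r2 * total_variance) / sum(total_variance)
}

#' Fit monotonic and tuned models to a table of voxel time series
#'
#' @param ts Tibble with one row per voxel: `voxel_id` plus BOLD samples in
#'   columns `t1 ... t44` (or a `bold` list-column), and optional metadata
#'   (`eccentricity_deg`, `map_label`, `hemisphere`).
#' @param seq Stimulus sequence shared by all voxels.
#' @param ts_heldout Optional table with the complementary split half (same
#'   voxel order) used for cross-validation.
#' @param models Character subset of `c("monotonic", "tuned")`.
#' @param scaling Scaling for the monotonic model.
#' @param ... Passed to [fit_tuned()].
#'
#' @return Tidy tibble, one row per voxel x model, with fitted parameters,
#'   `r2` and (when a held-out half is given) `r2_cv`.
#' @export
fit_voxels <- function(ts, seq, ts_heldout = NULL,
                       models = c("monotonic", "tuned"),
                       scaling = "log", ...) {
  bold_mat <- bold_matrix(ts, nrow(seq))
  bold_mat_b <- if (!is.null(ts_heldout)) bold_matrix(ts_heldout, nrow(seq))
  meta_cols <- intersect(c("voxel_id", "eccentricity_deg", "map_label",
                           "hemisphere"), names(ts))
  rows <- purrr::map(seq_len(nrow(bold_mat)), function(i) {
    y <- bold_mat[i, ]
    fits <- purrr::map(models, function(mod) {
      f <- if (mod == "monotonic") {
        fit_monotonic(y, seq, scaling)
      } else {
        fit_tuned(y, seq, ...)
      }
      if (!is.null(bold_mat_b)) f <- cross_validate_fit(f, bold_mat_b[i, ])
      attr(f, "predictor") <- NULL
      f
    })
    fits <- dplyr::bind_rows(fits)
    dplyr::bind_cols(ts[i, meta_cols, drop = FALSE], fits)
  })
  purrr::list_rbind(rows)
}

bold_matrix <- function(ts, n_tr) {
  if ("bold" %in% names(ts) && is.list(ts$bold)) {
    do.call(rbind, ts$bold)
  } else {
    cols <- grep("^t\\d+$", names(ts), value = TRUE)
    stopifnot(length(cols) == n_tr)
    as.matrix(ts[, cols[order(as.integer(sub("^t", "", cols)))]])
  }
}
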