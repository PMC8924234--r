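#' The block-design numerosity stimulus sequence
#'
#' One averaged stimulus cycle of 44 repetition times (TRs): numerosities one
#' through seven ascending (two TRs each), eight TRs of the 20-item baseline
#' pattern, seven through one descending, and another eight TRs at 20.  The
#' long 20-item periods distinguish very small from very large tuning widths.
#'
#' @param tr_s Repetition time in seconds.
#'
#' @return A `stimulus_sequence` tibble with columns `tr` (1-based index),
#'   `time_s`, `label` (presented numerosity) and `value` (feature amplitude,
#'   initially equal to the label).
#' @export
numerosity_sequence <- function(tr_s = 2.1) {
  labels <- c(rep(1:7, each = 2), rep(20L, 8), rep(7:1, each = 2), rep(20L, 8))
  out <- tibble(tr = seq_along(labels), time_s = (seq_along(labels) - 1) * tr_s,
                label = labels, value = as.numeric(labels))
  attr(out, "tr_s") <- tr_s
  class(out) <- c("stimulus_sequence", class(out))
  out
}

#' Substitute feature amplitudes into a stimulus sequence
#'
#' Replaces each presented numerosity label by the corresponding feature
#' amplitude (for aggregate Fourier power, the mean over all displays of the
#' same numerosity and configuration).
#'
#' @param feature_values Named numeric vector or two-column data frame
#'   (`numerosity`, value) covering every label in the design (1--7 and 20).
#' @param design A [numerosity_sequence()] template.
#'
#' @return The design with its `value` column replaced.
#' @export
build_sequence <- function(feature_values, design = numerosity_sequence()) {
  if (is.data.frame(feature_values)) {
    vals <- setNames(feature_values[[2]], feature_values[[1]])
  } else {
    vals <- feature_values
  }
  need <- as.character(unique(design$label))
  missing_labels <- setdiff(need, names(vals))
  if (length(missing_labels)) {
    stop("build_sequence: no feature value for label(s) ",
         paste(missing_labels, collapse = ", "))
  }
  design$value <- as.numeric(vals[as.character(design$label)])
  design
}

#' Canonical double-gamma hemodynamic response function
#'
#' The SPM-convention difference of two gamma densities (response peak near
#' 5--6 s, undershoot near 16 s), sampled at the TR, truncated at
#' `duration_s`, and scaled to unit peak amplitude.
#'
#' @param tr_s Sampling interval, seconds.
#' @param peak_delay_s,undershoot_delay_s Delays of the response and
#'   undershoot gamma components, seconds.
#' @param peak_dispersion_s,undershoot_dispersion_s Dispersions, seconds.
#' @param undershoot_ratio Peak-to-undershoot amplitude ratio.
#' @param duration_s Kernel length, seconds.
#'
#' @return Numeric vector of kernel samples (first sample at t = 0).
#' @export
hrf_kernel <- function(tr_s = 2.1,
                       peak_delay_s = 6, undershoot_delay_s = 16,
                       peak_dispersion_s = 1, undershoot_dispersion_s = 1,
                       undershoot_ratio = 1 / 6,
                       duration_s = 30) {
  stopifnot(peak_delay_s > 0, undershoot_delay_s > 0,
            peak_dispersion_s > 0, undershoot_dispersion_s > 0)
  dg <- function(t) {
    dgamma(t, shape = peak_delay_s / peak_dispersion_s,
           scale = peak_dispersion_s) -
      undershoot_ratio * dgamma(t, shape = undershoot_delay_s /
                                  undershoot_dispersion_s,
                                scale = undershoot_dispersion_s)
  }
  # unit peak of the continuous kernel, so that kernels sampled at
  # different TRs are samples of one common response function
  peak <- max(dg(seq(0, duration_s, by = 0.001)))
  dg(seq(0, duration_s, by = tr_s)) / peak
}

# circular convolution of a per-TR amplitude series with an HRF kernel; the
# stimulus cycle repeats continuously, so wrap-around is the physical model
convolve_cyclic <- function(x, kernel) {
  n <- length(x)
  k <- numeric(n)
  idx <- seq_len(min(length(kernel), n))
  k[idx] <- k[idx] + kernel[idx]
  if (length(kernel) > n) {
    # fold kernel tails longer than one cycle back onto the cycle
    extra <- kernel[-seq_len(n)]
    for (i in seq_along(extra)) {
      j <- (i - 1) %% n + 1
      k[j] <- k[j] + extra[i]
    }
  }
  Re(fft(fft(x) * fft(k), inverse = TRUE)) / n
}

#' Predicted fMRI time course for a monotonic response model
#'
#' @param seq A [numerosity_sequence()] (with feature amplitudes in `value`).
#' @param scaling `"log"` or `"linear"` transform applied to the feature
#'   amplitude before HRF convolution.
#' @param kernel HRF kernel samples (defaults to [hrf_kernel()] at the
#'   sequence TR).
#'
#' @return Numeric vector, one value per TR.
#' @export
monotonic_prediction <- function(seq, scaling = c("log", "linear"),
                                 kernel = NULL) {
  scaling <- match.arg(scaling)
  if (is.null(kernel)) kernel <- hrf_kernel(attr(seq, "tr_s") %||% 2.1)
  amp <- if (scaling == "log") log(seq$value) else seq$value
  convolve_cyclic(amp, kernel)
}

#' Predicted time course for a tuned (logarithmic Gaussian) response model
#'
#' Neural amplitude at each TR is the value of a Gaussian in log feature
#' space, `exp(-(log(x) - log(mu))^2 / (2 sigma^2))`, convolved with the HRF.
#' During the 20-item baseline periods the Gaussian is evaluated at 20 (its
#' far tail), which is what distinguishes narrow from broad tuning.
#'
#' @param seq Stimulus sequence.
#' @param mu Preferred numerosity (or preferred feature amplitude).
#' @param sigma Tuning width in log units.
#' @param kernel HRF kernel.
#'
#' @return Numeric vector, one value per TR.
#' @export
tuned_prediction <- function(seq, mu, sigma, kernel = NULL) {
  if (is.null(kernel)) kernel <- hrf_kernel(attr(seq, "tr_s") %||% 2.1)
  amp <- exp(-(log(seq$value) - log(mu))^2 / (2 * sigma^2))
  convolve_cyclic(amp, kernel)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
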