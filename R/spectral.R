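#' Normalize a stimulus image for spectral analysis
#'
#' Maps the background to exactly zero.  Under `binary_mask` every item pixel
#' maps to one regardless of its contrast; under `signed_deviation` item
#' pixels map to their signed Weber contrast (luminance deviation divided by
#' the background level), which preserves the distinction between darker and
#' lighter items for the contrast-manipulation analyses.
#'
#' @param img A `stimulus_image` (or numeric matrix with a
#'   `background_level` attribute / explicit `background_level`).
#' @param contrast_mode `"binary_mask"` or `"signed_deviation"`.
#' @param background_level Background luminance fraction; defaults to the
#'   image attribute.
#'
#' @return Numeric matrix, zero on the background.
#' @export
normalize_image <- function(img,
                            contrast_mode = c("binary_mask",
                                              "signed_deviation"),
                            background_level = NULL) {
  contrast_mode <- match.arg(contrast_mode)
  if (is.null(background_level)) background_level <- attr(img, "background_level")
  if (is.null(background_level)) background_level <- 0.5
  m <- unclass(img)
  attributes(m) <- list(dim = dim(m))
  if (!any(abs(m - background_level) < 1e-12)) {
    stop("normalize_image: no background-valued pixels found")
  }
  dev <- m - background_level
  if (contrast_mode == "binary_mask") {
    (abs(dev) > 1e-12) * 1
  } else {
    dev / background_level
  }
}

# per-canvas cache of the annular bin index (radial frequency rounded to the
# nearest integer cycle/image) for coefficients between 0.5 and Nyquist
bin_cache <- new.env(parent = emptyenv())

radial_bins <- function(n) {
  key <- as.character(n)
  if (!is.null(bin_cache[[key]])) return(bin_cache[[key]])
  ix <- 0:(n - 1)
  u <- ifelse(ix <= n / 2, ix, ix - n)
  r <- sqrt(outer(u^2, u^2, "+"))
  b <- as.integer(round(r))
  kmax <- n %/% 2L
  keep <- which(b >= 1L & b <= kmax)
  out <- list(keep = keep, bin = b[keep],
              counts = tabulate(b[keep], nbins = kmax), kmax = kmax)
  bin_cache[[key]] <- out
  out
}

#' Radial Fourier power spectral density of an image field
#'
#' Takes the 2-D discrete Fourier transform of a (normalized) square field
#' and sums the magnitude of the coefficients within annular frequency bins
#' of one cycle/image, excluding the zero-frequency term, up to the Nyquist
#' frequency (`canvas / 2` cycles/image).  Bin `k` collects radial
#' frequencies in `(k - 0.5, k + 0.5]`.
#'
#' @param field Square numeric matrix (e.g. from [normalize_image()]).
#'
#' @return A `radial_psd` tibble with columns `frequency` (cycles/image) and
#'   `psd`, plus attributes `canvas_px`, `counts` (coefficients per bin),
#'   `total_power` and `global_peak_freq`.
#' @export
radial_psd <- function(field) {
  if (!is.matrix(field) || nrow(field) != ncol(field)) {
    stop("radial_psd: field must be a square matrix")
  }
  n <- nrow(field)
  bins <- radial_bins(n)
  mag <- Mod(fft(field))[bins$keep]
  psd <- as.numeric(rowsum(mag, bins$bin))
  out <- tibble(frequency = seq_len(bins$kmax), psd = psd)
  attr(out, "canvas_px") <- n
  attr(out, "counts") <- bins$counts
  attr(out, "total_power") <- sum(psd)
  attr(out, "global_peak_freq") <- which.max(psd)
  class(out) <- c("radial_psd", class(out))
  out
}

#' Detect the end of the first spatial-frequency harmonic
#'
#' Finds the lowest frequency above the global PSD maximum at which the
#' spectrum has dropped below a fraction (default 25\%) of the global maximum
#' and the first or second discrete derivative of the PSD attains a local
#' maximum -- i.e. the sharpest change in the PSD, the pronounced minimum that
#' closes the first harmonic.  If no frequency qualifies, the global PSD
#' minimum above the peak is used.  With `basis = "counts_corrected"` the
#' peak and threshold are evaluated on the per-annulus mean PSD, which
#' compensates for the linear growth of annulus population with frequency
#' and resolves the very shallow minima of single large items.
#'
#' @param rps A [radial_psd()] object.
#' @param threshold Fraction of the global maximum below which the PSD must
#'   fall at the detected limit.
#' @param basis `"sum"` (annulus sums, the default) or `"counts_corrected"`.
#'
#' @return Integer frequency (cycles/image) of the first-harmonic limit.
#' @export
first_harmonic_limit <- function(rps, threshold = 0.25,
                                 basis = c("sum", "counts_corrected")) {
  basis <- match.arg(basis)
  psd <- rps$psd
  ref <- if (basis == "counts_corrected") psd / attr(rps, "counts") else psd
  detect_limit(ref, threshold)
}

detect_limit <- function(ref, threshold = 0.25) {
  nb <- length(ref)
  pk <- which.max(ref)
  if (pk >= nb) stop("first_harmonic_limit: spectrum peaks at Nyquist")
  d1 <- diff(ref)
  d2 <- diff(d1)
  # a local maximum of the forward first difference at k marks the steepest
  # rise out of a dip just after k; of the second difference, the sharpest
  # change in slope at k + 1.  Ties break toward the lower frequency.
  cand <- sort(unique(c(local_maxima(d1), local_maxima(d2) + 1L)))
  cand <- cand[cand > pk & cand <= nb & ref[cand] < threshold * ref[pk]]
  if (length(cand)) {
    cand[1]
  } else {
    rest <- ref[(pk + 1):nb]
    if (all(diff(rest) >= 0)) {
      stop("first_harmonic_limit: no candidate and no interior minimum; ",
           "spectrum head: ", paste(signif(head(ref, 12), 4), collapse = " "))
    }
    pk + which.min(rest)
  }
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 2L) return(integer())
  left <- c(-Inf, x[-n])
  right <- c(x[-1], -Inf)
  which(x >= left & x >= right)
}

#' Aggregate Fourier power within the first harmonic
#'
#' Sums the radial PSD over all orientations and all spatial frequencies up
#' to the first-harmonic limit, and normalizes the sum by
#' `canvas_px^2 * sqrt(2)` so that a single unit-contrast circle has a power
#' of approximately one at any display resolution.
#'
#' @param img A `stimulus_image`, a [display_spec()] (rendered on the fly),
#'   or an already-normalized field matrix.
#' @param contrast_mode Passed to [normalize_image()].
#' @param threshold,basis Passed to [first_harmonic_limit()].
#'
#' @return One-row tibble: `raw` (summed PSD within the first harmonic),
#'   `normalized`, `f1_limit`, `global_peak_freq`, `canvas_px`.
#' @export
aggregate_power <- function(img,
                            contrast_mode = c("binary_mask",
                                              "signed_deviation"),
                            threshold = 0.25,
                            basis = c("sum", "counts_corrected")) {
  contrast_mode <- match.arg(contrast_mode)
  basis <- match.arg(basis)
  field <- as_field(img, contrast_mode)
  rps <- radial_psd(field)
  f1 <- first_harmonic_limit(rps, threshold, basis)
  raw <- sum(rps$psd[seq_len(f1)])
  n <- attr(rps, "canvas_px")
  tibble(raw = raw, normalized = raw / (n^2 * sqrt(2)),
         f1_limit = f1, global_peak_freq = attr(rps, "global_peak_freq"),
         canvas_px = n)
}

as_field <- function(img, contrast_mode) {
  if (inherits(img, "display_spec")) img <- render_display(img)
  if (inherits(img, "stimulus_image")) {
    normalize_image(img, contrast_mode)
  } else {
    img
  }
}

#' Aggregate power of the second harmonic
#'
#' Applies the first-harmonic detection rule to the part of the spectrum
#' above the first-harmonic limit to locate the end of the second harmonic,
#' and returns the normalized PSD sum between the two limits.
#'
#' @param rps A [radial_psd()] object.
#' @param f1 First-harmonic limit; computed from `rps` when missing.
#' @param threshold,basis Passed to the detection rule.
#'
#' @return One-row tibble: `raw`, `normalized`, `f1_limit`, `f2_limit`.
#' @export
second_harmonic_power <- function(rps, f1 = NULL, threshold = 0.25,
                                  basis = c("sum", "counts_corrected")) {
  basis <- match.arg(basis)
  if (is.null(f1)) f1 <- first_harmonic_limit(rps, threshold, basis)
  nb <- nrow(rps)
  if (f1 >= nb - 2L) {
    stop("second_harmonic_power: second harmonic exceeds the Nyquist ",
         "frequency and cannot be evaluated")
  }
  sub <- rps$psd[(f1 + 1):nb]
  if (max(sub) <= .Machine$double.eps * max(rps$psd)) {
    # no spectral content above the first harmonic (e.g. a pure sinusoid)
    n <- attr(rps, "canvas_px")
    return(tibble(raw = 0, normalized = 0, f1_limit = f1,
                  f2_limit = NA_integer_))
  }
  ref <- if (basis == "counts_corrected") {
    sub / attr(rps, "counts")[(f1 + 1):nb]
  } else {
    sub
  }
  f2 <- f1 + detect_limit(ref, threshold)
  raw <- sum(rps$psd[(f1 + 1):f2])
  n <- attr(rps, "canvas_px")
  tibble(raw = raw, normalized = raw / (n^2 * sqrt(2)),
         f1_limit = f1, f2_limit = f2)
}

#' Orientation-resolved aggregate Fourier power
#'
#' For shapes whose spatial frequency content differs with orientation
#' (polygons, stars), the first-harmonic limit is determined separately
#' within each orientation sector of the frequency half-plane (default 36
#' sectors of 5 degrees), and the PSD is summed within each sector up to its
#' own limit before totalling and normalizing.  Sectors with too few
#' occupied bins fall back to the global limit.
#'
#' @param img As in [aggregate_power()].
#' @param n_sectors Number of orientation sectors over the half-plane.
#' @param contrast_mode,threshold Passed through.
#'
#' @return One-row tibble: `raw`, `normalized`, `n_sectors`, and the global
#'   `f1_limit` used as fallback.
#' @export
orientation_resolved_power <- function(img, n_sectors = 36,
                                       contrast_mode = c("binary_mask",
                                                         "signed_deviation"),
                                       threshold = 0.25) {
  contrast_mode <- match.arg(contrast_mode)
  field <- as_field(img, contrast_mode)
  n <- nrow(field)
  bins <- radial_bins(n)
  mag <- Mod(fft(field))[bins$keep]
  # orientation of each retained coefficient, folded to [0, pi)
  ix <- 0:(n - 1)
  u <- ifelse(ix <= n / 2, ix, ix - n)
  uu <- outer(u, rep(1, n))[bins$keep]
  vv <- outer(rep(1, n), u)[bins$keep]
  ang <- atan2(vv, uu) %% pi
  sector <- pmin(floor(ang / (pi / n_sectors)), n_sectors - 1) + 1L
  rps_all <- radial_psd(field)
  f1_global <- first_harmonic_limit(rps_all, threshold)
  raw <- 0
  for (s in seq_len(n_sectors)) {
    sel <- sector == s
    psd_s <- numeric(bins$kmax)
    acc <- rowsum(mag[sel], bins$bin[sel])
    occ <- as.integer(rownames(acc))
    psd_s[occ] <- acc[, 1]
    # narrow sectors leave many annular bins empty; the detection rule runs
    # on the profile over occupied bins only, normalized per coefficient so
    # the uneven bin occupancy of a sector does not masquerade as structure
    cnt_s <- numeric(bins$kmax)
    cnt_acc <- rowsum(rep(1, sum(sel)), bins$bin[sel])
    cnt_s[as.integer(rownames(cnt_acc))] <- cnt_acc[, 1]
    f1_s <- if (length(occ) < 3) {
      f1_global
    } else {
      prof <- psd_s[occ] / cnt_s[occ]
      idx <- tryCatch(detect_limit(prof, threshold), error = function(e) NA)
      if (is.na(idx)) f1_global else occ[idx]
    }
    raw <- raw + sum(psd_s[seq_len(f1_s)])
  }
  tibble(raw = raw, normalized = raw / (n^2 * sqrt(2)),
         n_sectors = n_sectors, f1_limit = f1_global)
}
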