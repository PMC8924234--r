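#' Quantify candidate non-numerical features of a display
#'
#' Computes, for one display, the battery of features commonly proposed to
#' co-vary with numerosity: per-item and total area and perimeter (analytic
#' geometry where the shape allows it), area and perimeter of the convex hull
#' of the item pixels, densities of luminance, edges and number within the
#' hull, root-mean-square contrast over the whole display and within the
#' hull, and the normalized aggregate Fourier power.
#'
#' @param spec A [display_spec()].
#' @param img Optional pre-rendered `stimulus_image` (rendered when missing).
#' @param ... Passed to [aggregate_power()].
#'
#' @return One-row tibble (a `FeatureTable` record).
#' @export
quantify_features <- function(spec, img = NULL, ...) {
  stopifnot(inherits(spec, "display_spec"))
  if (is.null(img)) img <- render_display(spec)
  items <- spec$items[spec$items$shape %in%
                        c("circle", "regular_polygon", "star"), ]
  n <- spec$numerosity
  geom <- purrr::pmap(items, function(shape, size, n_vertices, inner_radius,
                                      ...) {
    switch(shape,
      circle = c(area = pi * (size / 2)^2, per = pi * size),
      regular_polygon = {
        k <- n_vertices
        c(area = 0.5 * k * size^2 * sin(2 * pi / k),
          per = 2 * k * size * sin(pi / k))
      },
      star = {
        k <- n_vertices
        side <- sqrt(size^2 + inner_radius^2 -
                       2 * size * inner_radius * cos(pi / k))
        c(area = k * size * inner_radius * sin(pi / k), per = 2 * k * side)
      })
  })
  areas <- purrr::map_dbl(geom, "area")
  pers <- purrr::map_dbl(geom, "per")

  field <- normalize_image(img, "binary_mask")
  mask <- field > 0
  pix <- which(mask, arr.ind = TRUE) - 1L  # 0-based pixel coordinates
  hull <- convex_hull_stats(pix)
  in_hull <- matrix(FALSE, nrow(mask), ncol(mask))
  if (nrow(hull$vertices) >= 3) {
    ix <- 0:(nrow(mask) - 1)
    xr <- range(hull$vertices[, 1])
    yr <- range(hull$vertices[, 2])
    xs <- ix[ix >= floor(xr[1]) & ix <= ceiling(xr[2])]
    ys <- ix[ix >= floor(yr[1]) & ix <= ceiling(yr[2])]
    px <- rep(xs, times = length(ys))
    py <- rep(ys, each = length(xs))
    ins <- point_in_polygon(px, py, hull$vertices)
    in_hull[cbind(px[ins] + 1L, py[ins] + 1L)] <- TRUE
  } else {
    in_hull[mask] <- TRUE
  }
  edges <- mask & !erode_mask(mask)
  lum <- unclass(img)
  hull_area_px <- max(sum(in_hull), 1L)
  pow <- aggregate_power(img, ...)

  tibble(
    numerosity = n,
    item_area = mean(areas),
    item_perimeter = mean(pers),
    total_area = sum(areas),
    total_perimeter = sum(pers),
    hull_area = hull$area,
    hull_perimeter = hull$perimeter,
    luminance_density = sum(abs(field[in_hull])) / hull_area_px,
    edge_density = sum(edges[in_hull]) / hull_area_px,
    number_density = n / hull$area,
    rms_contrast_display = sd(as.numeric(lum)),
    rms_contrast_hull = sd(lum[in_hull]),
    aggregate_fourier_power = pow$normalized,
    configuration = spec$configuration)
}

# hull over the item pixel coordinates; area/perimeter from the hull polygon
convex_hull_stats <- function(pix) {
  if (nrow(pix) == 0) {
    return(list(vertices = matrix(numeric(), 0, 2), area = 0, perimeter = 0))
  }
  h <- chull(pix[, 1], pix[, 2])
  v <- pix[h, , drop = FALSE]
  if (nrow(v) < 3) {
    return(list(vertices = v, area = max(nrow(pix), 1),
                perimeter = 2 * max(dist(v), 0)))
  }
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  list(vertices = v,
       area = abs(sum(x * yn - xn * y)) / 2,
       perimeter = sum(sqrt((xn - x)^2 + (yn - y)^2)))
}

# 4-neighbourhood erosion by one pixel
erode_mask <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  up <- rbind(mask[-1, , drop = FALSE], FALSE)
  down <- rbind(FALSE, mask[-n, , drop = FALSE])
  left <- cbind(mask[, -1, drop = FALSE], FALSE)
  right <- cbind(FALSE, mask[, -m, drop = FALSE])
  mask & up & down & left & right
}

#' Summed Laplacian-of-Gaussian filter response
#'
#' Convolves a zero-mean Laplacian-of-Gaussian filter with the
#' background-zeroed field and sums the rectified (absolute) response over
#' all image locations.  (A zero-mean filter summed without rectification is
#' identically zero; squared-energy summation is available via `rectify`.)
#' Convolution is performed in the frequency domain with zero-padding to
#' avoid wrap-around of wide filters.
#'
#' @param img Image, spec or field as in [aggregate_power()].
#' @param sigma Filter standard deviation, pixels.
#' @param contrast_mode Passed to [normalize_image()].
#' @param rectify `"abs"` (default) or `"square"`.
#'
#' @return Scalar filter response.
#' @export
log_filter_response <- function(img, sigma = 2,
                                contrast_mode = c("binary_mask",
                                                  "signed_deviation"),
                                rectify = c("abs", "square")) {
  contrast_mode <- match.arg(contrast_mode)
  rectify <- match.arg(rectify)
  field <- as_field(img, contrast_mode)
  n <- nrow(field)
  stopifnot(sigma > 0)
  if (sigma >= n / 4) stop("log_filter_response: sigma too large for canvas")
  resp <- log_convolve(field, sigma)
  if (rectify == "abs") sum(abs(resp)) else sum(resp^2)
}

log_convolve <- function(field, sigma) {
  n <- nrow(field)
  half <- ceiling(4 * sigma)
  pad <- next_fast_size(n + 2 * half)
  # square-support LoG kernel, zero-mean on its own (2 half + 1)^2 support,
  # embedded at the origin of the padded grid in wrap-around layout
  kx <- -half:half
  r2 <- outer(kx^2, kx^2, "+")
  small <- (r2 - 2 * sigma^2) / sigma^4 * exp(-r2 / (2 * sigma^2))
  small <- small - mean(small)
  ker <- matrix(0, pad, pad)
  ker[((kx + pad) %% pad) + 1, ((kx + pad) %% pad) + 1] <- small
  fpad <- matrix(0, pad, pad)
  fpad[seq_len(n), seq_len(n)] <- field
  conv <- Re(fft(fft(fpad) * fft(ker), inverse = TRUE)) / pad^2
  conv[seq_len(n), seq_len(n)]
}

# smallest 2^a * 3^b >= n (keeps the padded FFT fast)
next_fast_size <- function(n) {
  k <- n
  repeat {
    m <- k
    while (m %% 2 == 0) m <- m / 2
    while (m %% 3 == 0) m <- m / 3
    if (m == 1) return(k)
    k <- k + 1
  }
}

#' Ratio of high and low spatial-frequency filter responses
#'
#' The response-ratio statistic: the summed rectified response of a
#' high-spatial-frequency (small sigma) Laplacian-of-Gaussian filter divided
#' by that of a low-spatial-frequency (large sigma) filter.  The default
#' pair (1, 34 pixels) is the pair whose prediction correlates most strongly
#' with numerosity in these displays.
#'
#' @param img Image, spec or field.
#' @param sigma_hi,sigma_lo Standard deviations of the high- and
#'   low-frequency filters (`sigma_hi < sigma_lo`).
#' @param ... Passed to [log_filter_response()].
#'
#' @return Scalar ratio.
#' @export
response_ratio <- function(img, sigma_hi = 1, sigma_lo = 34, ...) {
  stopifnot(sigma_hi <= sigma_lo)
  field <- as_field(img, "binary_mask")
  hi <- log_filter_response(field, sigma_hi, ...)
  lo <- log_filter_response(field, sigma_lo, ...)
  if (lo == 0) stop("response_ratio: zero denominator response")
  hi / lo
}

#' Spatial population-receptive-field predictor
#'
#' Predicts the response of a visual-position-selective population: a 2-D
#' Gaussian pRF weights either the edge map (item boundary pixels) or the
#' absolute luminance-deviation map of each display, and the weighted sums
#' are accumulated over all displays of the same numerosity.
#'
#' @param displays Tibble with list-column `spec` (or list of specs) and a
#'   `numerosity` column (taken from the specs when absent).
#' @param prf_center Centre of the pRF in visual-field degrees, length 2
#'   (relative to fixation at the canvas centre).
#' @param prf_size Gaussian standard deviation, degrees.
#' @param source `"edges"` or `"luminance"`.
#' @param px_per_degree Pixel mapping.
#'
#' @return Tibble with `numerosity` and `predictor` (one row per numerosity).
#' @export
spatial_prf_predictor <- function(displays, prf_center = c(0, 0),
                                  prf_size = 1,
                                  source = c("edges", "luminance"),
                                  px_per_degree = PX_PER_DEGREE) {
  source <- match.arg(source)
  specs <- if (inherits(displays, "display_spec")) {
    list(displays)
  } else if (is.data.frame(displays)) {
    displays$spec
  } else {
    displays
  }
  rows <- purrr::map(specs, function(sp) {
    img <- render_display(sp)
    field <- normalize_image(img, "signed_deviation")
    n <- nrow(field)
    cx <- n / 2 + prf_center[1] * px_per_degree
    cy <- n / 2 + prf_center[2] * px_per_degree
    sd_px <- prf_size * px_per_degree
    ix <- 0:(n - 1)
    w <- exp(-outer((ix - cx)^2, (ix - cy)^2, "+") / (2 * sd_px^2))
    map <- if (source == "edges") {
      mask <- abs(field) > 1e-12
      (mask & !erode_mask(mask)) * 1
    } else {
      abs(field)
    }
    if (max(w) < 1e-10) {
      warning("spatial_prf_predictor: pRF lies outside the canvas")
    }
    tibble(numerosity = sp$numerosity, value = sum(w * map))
  })
  purrr::list_rbind(rows) |>
    dplyr::group_by(.data$numerosity) |>
    dplyr::summarise(predictor = sum(.data$value), .groups = "drop")
}
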