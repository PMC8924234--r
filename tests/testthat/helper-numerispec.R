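# Shared fixtures and independent oracles, all built in code.

# brute-force O(N^4) 2-D DFT magnitude, independent of stats::fft
brute_dft_mag <- function(field) {
  n <- nrow(field)
  out <- matrix(0, n, n)
  ix <- 0:(n - 1)
  for (u in ix) {
    for (v in ix) {
      ph <- exp(-2i * pi * (outer(ix * u, ix * v, "+")) / n)
      out[u + 1, v + 1] <- Mod(sum(field * ph))
    }
  }
  out
}

# independent radial binning of a magnitude spectrum (round-to-nearest bins)
brute_radial_bins <- function(mag) {
  n <- nrow(mag)
  ix <- 0:(n - 1)
  u <- ifelse(ix <= n / 2, ix, ix - n)
  r <- sqrt(outer(u^2, u^2, "+"))
  b <- round(r)
  kmax <- n %/% 2
  vapply(seq_len(kmax), function(k) sum(mag[b == k]), numeric(1))
}

# gift-wrapping convex hull (independent of grDevices::chull); returns the
# hull polygon area by the shoelace formula
brute_hull_area <- function(pts) {
  pts <- unique(pts)
  if (nrow(pts) < 3) return(0)
  start <- which.min(pts[, 2])
  hull <- start
  ref_angle <- 0
  repeat {
    cur <- hull[length(hull)]
    ang <- atan2(pts[, 2] - pts[cur, 2], pts[, 1] - pts[cur, 1])
    rel <- (ang - ref_angle) %% (2 * pi)
    rel[cur] <- Inf
    d2 <- (pts[, 1] - pts[cur, 1])^2 + (pts[, 2] - pts[cur, 2])^2
    cand <- which(rel == min(rel))
    nxt <- cand[which.max(d2[cand])]
    if (nxt == start) break
    hull <- c(hull, nxt)
    ref_angle <- atan2(pts[nxt, 2] - pts[cur, 2], pts[nxt, 1] - pts[cur, 1])
    if (length(hull) > nrow(pts)) stop("hull oracle failed to terminate")
  }
  v <- pts[hull, , drop = FALSE]
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# single centred circle on the default canvas
single_circle_spec <- function(diameter, canvas = 768) {
  display_spec(tibble::tibble(shape = "circle", x = canvas / 2,
                              y = canvas / 2, size = diameter),
               canvas_px = canvas)
}

# non-background pixel mask of a rendered spec
item_pixel_mask <- function(spec) {
  img <- render_display(spec)
  abs(unclass(img) - spec$background_level) > 1e-12
}

# normalized aggregate power of a 7-item 16-px dot group (shared by the
# contrast-manipulation tests); geometry via place_items in a compact group
dot_group_power <- function(contrasts, group_radius = 50, seed_pts = NULL) {
  pts <- if (is.null(seed_pts)) {
    place_items(length(contrasts), 8, group_radius, min_gap = 0,
                center = c(384, 384))
  } else {
    seed_pts
  }
  sp <- display_spec(
    tibble::tibble(shape = "circle", x = pts$x, y = pts$y, size = 16,
                   n_vertices = NA_integer_, inner_radius = NA_real_,
                   orientation = 0, width = NA_real_, contrast = contrasts),
    region_radius_px = 350)
  aggregate_power(sp, contrast_mode = "signed_deviation")$normalized
}
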