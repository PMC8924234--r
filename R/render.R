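#' Render a display specification to a grayscale image
#'
#' Rasterizes a [display_spec()] onto its canvas.  A pixel belongs to an item
#' when its centre (integer coordinates, 0-based) lies inside the analytic
#' shape; no anti-aliasing is applied, so rendering is deterministic and
#' bit-identical for identical specs.  Item pixels take the value
#' `background_level * (1 + contrast)`; illusory-contour inducers are carved
#' at exactly the background level.  Values are clipped to \[0, 1\].
#'
#' @param spec A [display_spec()].
#'
#' @return A `stimulus_image`: numeric matrix of luminance fractions with
#'   attributes `canvas_px` and `background_level`.
#' @export
render_display <- function(spec) {
  stopifnot(inherits(spec, "display_spec"))
  n <- spec$canvas_px
  bg <- spec$background_level
  img <- matrix(bg, n, n)
  items <- spec$items
  # inducers are carved after all solid items have been drawn
  ord <- order(items$shape == "illusory_inducer")
  for (i in ord) {
    it <- items[i, ]
    mask <- item_mask(it, n)
    value <- if (it$shape == "illusory_inducer") bg else bg * (1 + it$contrast)
    img[mask] <- min(max(value, 0), 1)
  }
  structure(img, canvas_px = n, background_level = bg,
            class = c("stimulus_image", "matrix", "array"))
}

# logical index matrix (rows = x, cols = y) of pixels inside one item,
# restricted to the item's bounding box for speed
item_mask <- function(it, n) {
  half <- switch(it$shape,
    circle = it$size / 2,
    regular_polygon = it$size,
    star = it$size,
    it$size / 2 + it$width)
  xr <- max(0, floor(it$x - half - 1)):min(n - 1, ceiling(it$x + half + 1))
  yr <- max(0, floor(it$y - half - 1)):min(n - 1, ceiling(it$y + half + 1))
  px <- rep(xr, times = length(yr))
  py <- rep(yr, each = length(xr))
  inside <- switch(it$shape,
    circle = (px - it$x)^2 + (py - it$y)^2 <= (it$size / 2)^2,
    regular_polygon = {
      v <- polygon_vertices(it$x, it$y, it$size, it$n_vertices,
                            it$orientation)
      point_in_polygon(px, py, v)
    },
    star = {
      v <- star_vertices(it$x, it$y, it$size, it$inner_radius,
                         it$n_vertices, it$orientation)
      point_in_polygon(px, py, v)
    },
    bar = ,
    illusory_inducer = {
      # oriented rectangle, half-open on both axes so that pixel counts equal
      # length x width exactly for axis-aligned orientations
      dx <- px - it$x
      dy <- py - it$y
      co <- cos(it$orientation)
      si <- sin(it$orientation)
      # snap to exact values at multiples of pi/2 so that axis-aligned
      # rectangles have clean half-open pixel boundaries
      if (abs(co) < 1e-12) co <- 0 else if (abs(abs(co) - 1) < 1e-12) co <- sign(co)
      if (abs(si) < 1e-12) si <- 0 else if (abs(abs(si) - 1) < 1e-12) si <- sign(si)
      u <- dx * co + dy * si
      v <- -dx * si + dy * co
      u >= -it$size / 2 & u < it$size / 2 &
        v >= -it$width / 2 & v < it$width / 2
    })
  cbind(px[inside] + 1L, py[inside] + 1L)
}

polygon_vertices <- function(x, y, radius, k, orientation = 0) {
  a <- orientation + 2 * pi * (seq_len(k) - 1) / k
  cbind(x + radius * cos(a), y + radius * sin(a))
}

star_vertices <- function(x, y, outer, inner, k, orientation = 0) {
  a_out <- orientation + 2 * pi * (seq_len(k) - 1) / k
  a_in <- a_out + pi / k
  v <- matrix(NA_real_, 2 * k, 2)
  v[seq(1, 2 * k, by = 2), ] <- cbind(x + outer * cos(a_out),
                                      y + outer * sin(a_out))
  v[seq(2, 2 * k, by = 2), ] <- cbind(x + inner * cos(a_in),
                                      y + inner * sin(a_in))
  v
}

# even-odd (crossing number) point-in-polygon test, vectorized over points
point_in_polygon <- function(px, py, vertices) {
  nv <- nrow(vertices)
  inside <- rep(FALSE, length(px))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- vertices[i, 1]; yi <- vertices[i, 2]
    xj <- vertices[j, 1]; yj <- vertices[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' @export
print.stimulus_image <- function(x, ...) {
  cat("<stimulus_image> ", attr(x, "canvas_px"), "x", attr(x, "canvas_px"),
      " px, background ", attr(x, "background_level"), "\n", sep = "")
  invisible(x)
}
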