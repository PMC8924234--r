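#' Parametric description of a numerosity display
#'
#' A `display_spec` couples a tibble of items (one row per item, with shape,
#' position, size, orientation and Weber contrast) with the canvas geometry
#' needed to render it.  All positions and sizes are in pixels; the canvas is
#' square with 0-based pixel coordinates and its centre at `canvas_px / 2`.
#'
#' @param items Tibble with columns `shape` (one of `"circle"`,
#'   `"regular_polygon"`, `"star"`, `"bar"`, `"illusory_inducer"`), `x`, `y`
#'   (centre, pixels), `size` (circle diameter, polygon/star outer radius, or
#'   bar length), `n_vertices`, `inner_radius`, `orientation` (radians),
#'   `width` (bars/inducers) and `contrast` (signed Weber contrast in
#'   \[-1, 1\]; negative items are darker than the background).
#' @param canvas_px Side of the square canvas in pixels.
#' @param background_level Background luminance fraction (0.5 = mid grey).
#' @param region_radius_px Radius of the placement region, pixels.
#' @param configuration Configuration label, one of `"constant_area"`,
#'   `"constant_size"`, `"constant_perimeter"`, `"high_density"`, `"custom"`.
#' @param numerosity Number of countable items (bars and inducers attached to
#'   dot pairs do not count).
#'
#' @return An object of class `display_spec`.
#' @export
display_spec <- function(items,
                         canvas_px = DEFAULT_CANVAS,
                         background_level = 0.5,
                         region_radius_px = 350,
                         configuration = "custom",
                         numerosity = NULL) {
  items <- complete_items(items)
  countable <- items$shape %in% c("circle", "regular_polygon", "star")
  if (is.null(numerosity)) numerosity <- sum(countable)
  stopifnot(all(items$size > 0), all(abs(items$contrast) <= 1))
  half <- item_half_extent(items)
  inside <- items$x - half >= 0 & items$x + half <= canvas_px - 1 &
    items$y - half >= 0 & items$y + half <= canvas_px - 1
  if (!all(inside)) {
    stop("display_spec: item(s) ", paste(which(!inside), collapse = ", "),
         " extend beyond the canvas")
  }
  structure(
    list(items = items,
         canvas_px = as.integer(canvas_px),
         background_level = background_level,
         region_radius_px = region_radius_px,
         configuration = configuration,
         numerosity = as.integer(numerosity)),
    class = "display_spec")
}

#' @export
print.display_spec <- function(x, ...) {
  cat("<display_spec> ", x$configuration, ": ", x$numerosity, " item(s), ",
      x$canvas_px, "x", x$canvas_px, " px canvas\n", sep = "")
  print(x$items, n = 5)
  invisible(x)
}

complete_items <- function(items) {
  items <- as_tibble(items)
  defaults <- list(n_vertices = NA_integer_, inner_radius = NA_real_,
                   orientation = 0, width = NA_real_, contrast = -1)
  for (nm in names(defaults)) {
    if (!nm %in% names(items)) items[[nm]] <- defaults[[nm]]
  }
  items
}

# conservative half-extent used for the canvas-containment check
item_half_extent <- function(items) {
  ifelse(items$shape == "circle", items$size / 2,
    ifelse(items$shape %in% c("regular_polygon", "star"), items$size,
      items$size / 2 + ifelse(is.na(items$width), 2, items$width)))
}

circle_items <- function(x, y, diameter, contrast = -1) {
  tibble(shape = "circle", x = x, y = y, size = diameter,
         n_vertices = NA_integer_, inner_radius = NA_real_,
         orientation = 0, width = NA_real_, contrast = contrast)
}

#' Place items randomly but approximately homogeneously in a circular region
#'
#' Draws `n` centres uniformly within a circular region subject to a minimum
#' edge-to-edge gap between items.  Placement uses rejection sampling; for
#' packings too dense for rejection sampling to terminate (dense displays
#' approach the random sequential adsorption jamming density) an iterative
#' pairwise-repulsion relaxation from a random start produces an amorphous
#' jammed packing instead.
#'
#' @param n Number of items.
#' @param item_radius Item radius (scalar), pixels.
#' @param region_radius Placement region radius, pixels.  Items are contained
#'   entirely within the region.
#' @param min_gap Minimum edge-to-edge distance between items, pixels.
#' @param center Region centre, length-2 numeric (pixels).
#'
#' @return Tibble with columns `x`, `y` (one row per item).  Errors with a
#'   packing-failure message if the constraint set is infeasible.
#' @export
place_items <- function(n, item_radius, region_radius, min_gap = 2,
                        center = c(DEFAULT_CANVAS / 2, DEFAULT_CANVAS / 2)) {
  stopifnot(n >= 1, item_radius > 0, region_radius > 0, min_gap >= 0)
  if (item_radius > region_radius) {
    stop("packing failure: item radius ", item_radius,
         " exceeds region radius ", region_radius)
  }
  if (n == 1) {
    cmax <- region_radius - item_radius
    th <- runif(1, 0, 2 * pi)
    rr <- cmax * sqrt(runif(1))
    return(tibble(x = center[1] + rr * cos(th), y = center[2] + rr * sin(th)))
  }
  # coverage of the centre disc by half-exclusion discs; RSA jams near 0.547
  coverage <- n * (item_radius + min_gap / 2)^2 /
    max(1e-9, (region_radius - item_radius)^2)
  pts <- NULL
  if (coverage < 0.4) {
    pts <- rsa_place(n, item_radius, region_radius, min_gap, center)
  }
  if (is.null(pts)) {
    pts <- relax_place(n, item_radius, region_radius, min_gap, center)
  }
  if (is.null(pts)) {
    stop("packing failure: could not place n=", n, " items of radius ",
         item_radius, " with min gap ", min_gap, " in region radius ",
         region_radius)
  }
  tibble(x = pts[, 1], y = pts[, 2])
}

rsa_place <- function(n, r, region, min_gap, center,
                      batch = 2000L, max_batches = 20L) {
  cmax <- region - r
  minc2c2 <- (2 * r + min_gap)^2
  px <- numeric(n)
  py <- numeric(n)
  got <- 0L
  for (bb in seq_len(max_batches)) {
    th <- runif(batch, 0, 2 * pi)
    rr <- cmax * sqrt(runif(batch))
    cxs <- center[1] + rr * cos(th)
    cys <- center[2] + rr * sin(th)
    for (i in seq_len(batch)) {
      if (got == 0L ||
          min((px[1:got] - cxs[i])^2 + (py[1:got] - cys[i])^2) >= minc2c2) {
        got <- got + 1L
        px[got] <- cxs[i]
        py[got] <- cys[i]
        if (got == n) return(cbind(px, py))
      }
    }
  }
  NULL
}

relax_place <- function(n, r, region, min_gap, center, restarts = 6L) {
  for (a in seq_len(restarts)) {
    p <- relax_once(n, r, region, min_gap, center)
    if (!is.null(p)) return(p)
  }
  NULL
}

relax_once <- function(n, r, region, min_gap, center, max_iter = 4000L) {
  cmax <- region - r
  minc2c <- (2 * r + min_gap) * (1 + 1e-6)
  th <- runif(n, 0, 2 * pi)
  rr <- cmax * sqrt(runif(n))
  P <- cbind(center[1] + rr * cos(th), center[2] + rr * sin(th))
  worst_prev <- Inf
  stall <- 0L
  for (it in seq_len(max_iter)) {
    D <- as.matrix(dist(P))
    diag(D) <- Inf
    vi <- which(D < minc2c, arr.ind = TRUE)
    vi <- vi[vi[, 1] < vi[, 2], , drop = FALSE]
    dc <- sqrt((P[, 1] - center[1])^2 + (P[, 2] - center[2])^2)
    out <- which(dc > cmax + 1e-9)
    if (nrow(vi) == 0L && length(out) == 0L) return(P)
    disp <- matrix(0, n, 2)
    if (nrow(vi) > 0L) {
      i <- vi[, 1]; j <- vi[, 2]
      d <- D[vi]
      vx <- P[j, 1] - P[i, 1]
      vy <- P[j, 2] - P[i, 2]
      deg <- d < 1e-9
      if (any(deg)) {
        a <- runif(sum(deg), 0, 2 * pi)
        vx[deg] <- cos(a); vy[deg] <- sin(a); d[deg] <- 1
      }
      push <- (minc2c - d) / 2 * 1.2 / d
      agg <- rowsum(cbind(c(-vx * push, vx * push),
                          c(-vy * push, vy * push)), c(i, j))
      idx <- as.integer(rownames(agg))
      disp[idx, ] <- disp[idx, ] + agg
    }
    if (length(out)) {
      v <- (P[out, , drop = FALSE] -
              matrix(center, length(out), 2, byrow = TRUE)) / dc[out]
      disp[out, ] <- disp[out, ] - v * (dc[out] - cmax) * 1.2
    }
    worst <- max(c(0, minc2c - D[vi], dc[out] - cmax))
    stall <- if (worst >= worst_prev - 1e-9) stall + 1L else 0L
    worst_prev <- worst
    if (stall > 150L) {
      kick <- unique(c(vi, out))
      disp[kick, ] <- disp[kick, ] +
        matrix(rnorm(2 * length(kick), sd = minc2c * 0.2), ncol = 2)
      stall <- 0L
      worst_prev <- Inf
    }
    P <- P + disp
  }
  NULL
}

#' Build one display in an fMRI stimulus configuration
#'
#' The four configurations hold total item area (and so display luminance),
#' individual item size, or total item perimeter constant across numerosities,
#' or pack the constant total area into a dense sub-group (half the stimulus
#' radius) that is itself placed at random within the stimulus region.
#'
#' @param configuration One of `"constant_area"`, `"constant_size"`,
#'   `"constant_perimeter"`, `"high_density"`.
#' @param n Numerosity (number of items).
#' @param canvas_px Canvas side, pixels.
#' @param region_radius Stimulus region radius, pixels (0.75 degrees of
#'   visual angle at the default pixel mapping).
#' @param reference_diameter Diameter of the single item at numerosity 1,
#'   pixels.  Total area (`constant_area`, `high_density`) and total perimeter
#'   (`constant_perimeter`) are conserved at this item's values; under
#'   `constant_size` every item has this diameter at every numerosity.
#' @param min_gap Minimum edge-to-edge gap between items, pixels.
#' @param contrast Signed Weber contrast of the items.
#'
#' @return A [display_spec()].
#' @export
make_configuration_display <- function(configuration, n,
                                       canvas_px = DEFAULT_CANVAS,
                                       region_radius = 350,
                                       reference_diameter = NULL,
                                       min_gap = 2,
                                       contrast = -1) {
  configuration <- match.arg(configuration,
    c("constant_area", "constant_size", "constant_perimeter", "high_density"))
  stopifnot(n >= 1)
  if (is.null(reference_diameter)) {
    reference_diameter <- if (configuration == "constant_size") 30 else 60
  }
  diam <- switch(configuration,
    constant_area = reference_diameter / sqrt(n),
    high_density = reference_diameter / sqrt(n),
    constant_size = reference_diameter,
    constant_perimeter = reference_diameter / n)
  center <- c(canvas_px / 2, canvas_px / 2)
  if (configuration == "high_density") {
    sub_radius <- region_radius / 2
    # random position of the dense sub-group, fully inside the region
    th <- runif(1, 0, 2 * pi)
    rr <- (region_radius - sub_radius) * sqrt(runif(1))
    sub_center <- center + rr * c(cos(th), sin(th))
    pts <- place_items(n, diam / 2, sub_radius, min_gap, center = sub_center)
  } else {
    pts <- place_items(n, diam / 2, region_radius, min_gap, center = center)
  }
  display_spec(circle_items(pts$x, pts$y, diam, contrast),
               canvas_px = canvas_px,
               region_radius_px = region_radius,
               configuration = configuration,
               numerosity = n)
}

#' Generalization series of displays over item size, spacing, number and shape
#'
#' Builds the display families used to probe how aggregate Fourier power
#' generalizes beyond the fMRI stimulus configurations:
#' * `single_circle_diameters`: one centred circle, diameters 1--240 px;
#' * `seven_circle_spacing`: seven 16-px circles spread evenly within circular
#'   group areas of 50--528 px diameter (minimum centre-to-centre distance
#'   grows with the group area; at 50 px all items touch);
#' * `numerosity_1_to_175`: 16-px circles, numerosities 1--175, within a
#'   700-px diameter region, at least 24 px apart edge-to-edge;
#' * `polygons`: regular convex polygons with 3--10 corners plus a circle,
#'   corners 30 px from the image centre;
#' * `stars`: regular stars with 3--10 points at 30 px outer radius and 10 px
#'   inner (concave) radius.
#'
#' @param kind Series name (see above).
#' @param canvas_px Canvas side, pixels.
#' @param numerosities,area_diameters,diameters Optional subsets of the series
#'   parameter grid (defaults reproduce the full quoted ranges).
#' @param displays_per_level Random displays generated per parameter level for
#'   the stochastic series (spacing and numerosity series).
#'
#' @return Tibble with one row per display: `kind`, `level` (the series
#'   parameter: diameter, group diameter, numerosity, or corner count),
#'   `replicate` and a `spec` list-column of [display_spec()] objects.
#' @export
make_generalization_series <- function(kind,
                                       canvas_px = DEFAULT_CANVAS,
                                       numerosities = 1:175,
                                       area_diameters = seq(50, 528, by = 22),
                                       diameters = 1:240,
                                       displays_per_level = 1L) {
  kind <- match.arg(kind, c("single_circle_diameters", "seven_circle_spacing",
                            "numerosity_1_to_175", "polygons", "stars"))
  cx <- canvas_px / 2
  one <- function(level, replicate, spec) {
    tibble(kind = kind, level = level, replicate = replicate, spec = list(spec))
  }
  rows <- switch(kind,
    single_circle_diameters = purrr::map(diameters, function(d) {
      one(d, 1L, display_spec(circle_items(cx, cx, d), canvas_px = canvas_px,
                              configuration = "custom"))
    }),
    seven_circle_spacing = purrr::map(area_diameters, function(D) {
      purrr::map(seq_len(displays_per_level), function(rep) {
        # centre-to-centre floor grows linearly from touching at D = 50
        min_c2c <- 16 * D / 50
        pts <- place_items(7, 8, D / 2, min_gap = min_c2c - 16,
                           center = c(cx, cx))
        one(D, rep, display_spec(circle_items(pts$x, pts$y, 16),
                                 canvas_px = canvas_px,
                                 region_radius_px = D / 2))
      }) |> purrr::list_rbind()
    }),
    numerosity_1_to_175 = purrr::map(numerosities, function(n) {
      purrr::map(seq_len(displays_per_level), function(rep) {
        pts <- place_items(n, 8, 350, min_gap = 24, center = c(cx, cx))
        one(n, rep, display_spec(circle_items(pts$x, pts$y, 16),
                                 canvas_px = canvas_px,
                                 region_radius_px = 350, numerosity = n))
      }) |> purrr::list_rbind()
    }),
    polygons = purrr::map(c(3:10, Inf), function(k) {
      items <- if (is.infinite(k)) {
        circle_items(cx, cx, 60)
      } else {
        tibble(shape = "regular_polygon", x = cx, y = cx, size = 30,
               n_vertices = as.integer(k), inner_radius = NA_real_,
               orientation = 0, width = NA_real_, contrast = -1)
      }
      one(unclass(k), 1L, display_spec(items, canvas_px = canvas_px))
    }),
    stars = purrr::map(3:10, function(k) {
      items <- tibble(shape = "star", x = cx, y = cx, size = 30,
                      n_vertices = as.integer(k), inner_radius = 10,
                      orientation = 0, width = NA_real_, contrast = -1)
      one(k, 1L, display_spec(items, canvas_px = canvas_px))
    }))
  purrr::list_rbind(rows)
}

#' Dot pairs with connecting bars or illusory-contour inducers
#'
#' Two 30-px diameter dots separated by `separation` pixels (edge-to-edge),
#' optionally joined by a 4-px wide bar spanning the gap, or carrying 4-px
#' wide background-coloured illusory-contour inducers that extend 10 px into
#' each dot.  The `rotated_*` controls split the bar (or inducer pair) at the
#' midpoint and rotate each half by 90 degrees about its dot centre: the same
#' change is applied to each dot but no connection is formed.
#'
#' @param connection One of `"dots_only"`, `"bar"`, `"rotated_bar"`,
#'   `"illusory"`, `"rotated_illusory"`.
#' @param separation Edge-to-edge distance between the dots, pixels.
#' @param canvas_px Canvas side, pixels.
#' @param contrast Signed Weber contrast of dots (and bars).
#'
#' @return A [display_spec()] with `numerosity = 2`.
#' @export
make_dot_pair_display <- function(connection, separation = 60,
                                  canvas_px = DEFAULT_CANVAS,
                                  contrast = -1) {
  connection <- match.arg(connection,
    c("dots_only", "bar", "rotated_bar", "illusory", "rotated_illusory"))
  stopifnot(separation > 0)
  dot_d <- 30
  cx <- canvas_px / 2
  # integer centres so that 90-degree rotation maps pixel centres onto pixel
  # centres and the rotated controls carry exactly the same pixel mass
  half_c2c <- round((separation + dot_d) / 2)
  x1 <- cx - half_c2c
  x2 <- cx + half_c2c
  sep_eff <- (x2 - x1) - dot_d
  items <- circle_items(c(x1, x2), c(cx, cx), dot_d, contrast)
  bar_row <- function(x, y, length, orientation, level) {
    tibble(shape = if (level == "background") "illusory_inducer" else "bar",
           x = x, y = y, size = length, n_vertices = NA_integer_,
           inner_radius = NA_real_, orientation = orientation, width = 4,
           contrast = if (level == "background") 0 else contrast)
  }
  extra <- switch(connection,
    dots_only = NULL,
    bar = bar_row(cx, cx, sep_eff, 0, "item"),
    rotated_bar = {
      # each half-bar occupies the same radial pixel interval from its dot
      # centre as the corresponding half of the connected bar (the split bar
      # halves differ by half a pixel because of the half-open rasterization
      # of the connected bar), so the rotated pair carries exactly the same
      # pixel mass as the connected bar
      dplyr::bind_rows(
        bar_row(x1, cx - (dot_d / 2 + sep_eff / 4 - 0.5), sep_eff / 2,
                pi / 2, "item"),
        bar_row(x2, cx - (dot_d / 2 + sep_eff / 4), sep_eff / 2,
                pi / 2, "item"))
    },
    illusory = {
      # carved 10 px deep from the facing edge pixel of each dot inward
      dplyr::bind_rows(
        bar_row(x1 + dot_d / 2 - 4, cx, 10, 0, "background"),
        bar_row(x2 - dot_d / 2 + 5, cx, 10, 0, "background"))
    },
    rotated_illusory = {
      off <- dot_d / 2 - 4.5
      dplyr::bind_rows(
        bar_row(x1, cx - off, 10, pi / 2, "background"),
        bar_row(x2, cx - off, 10, pi / 2, "background"))
    })
  if (connection %in% c("rotated_bar", "rotated_illusory")) {
    # rotated element must not touch the other dot
    reach <- sqrt((dot_d / 2 + sep_eff / 2)^2 + 2^2)
    if (reach >= (x2 - x1) - dot_d / 2) {
      stop("rotated element would overlap the other dot at separation ",
           separation)
    }
  }
  display_spec(dplyr::bind_rows(items, extra), canvas_px = canvas_px,
               configuration = "custom", numerosity = 2L)
}
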