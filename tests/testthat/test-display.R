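test_that("placement respects pairwise gaps, containment and reproducibility", {
  set.seed(42)
  pts <- place_items(5, 8, 350, min_gap = 24)
  d <- as.matrix(dist(cbind(pts$x, pts$y)))
  diag(d) <- Inf
  # exhaustive pairwise edge-to-edge check
  expect_true(all(d >= 16 + 24 - 1e-6))
  expect_true(all(sqrt((pts$x - 384)^2 + (pts$y - 384)^2) <= 350 - 8 + 1e-6))

  set.seed(7)
  a <- place_items(20, 8, 350, min_gap = 24)
  set.seed(7)
  b <- place_items(20, 8, 350, min_gap = 24)
  expect_identical(a, b)

  set.seed(1)
  one <- place_items(1, 10, 350)
  expect_equal(nrow(one), 1)
  expect_lte(sqrt((one$x - 384)^2 + (one$y - 384)^2), 340)
})

test_that("seven touching items pack into a 25-px region and infeasible packings error", {
  set.seed(11)
  pts <- place_items(7, 8, 25, min_gap = 0)
  d <- as.matrix(dist(cbind(pts$x, pts$y)))
  diag(d) <- Inf
  expect_true(all(d >= 16 - 1e-4))
  expect_true(all(sqrt((pts$x - 384)^2 + (pts$y - 384)^2) <= 17 + 1e-4))

  expect_error(place_items(10, 10, 25, min_gap = 0), "packing failure")
  expect_error(place_items(2, 30, 25), "packing failure")
})

test_that("dense numerosity-series packings remain feasible", {
  set.seed(3)
  pts <- place_items(175, 8, 350, min_gap = 24)
  d <- as.matrix(dist(cbind(pts$x, pts$y)))
  diag(d) <- Inf
  expect_true(all(d >= 40 - 1e-4))
  expect_true(all(sqrt((pts$x - 384)^2 + (pts$y - 384)^2) <= 342 + 1e-4))
})

test_that("configurations satisfy their conservation rules", {
  set.seed(5)
  # constant size: identical diameters at every numerosity
  d3 <- make_configuration_display("constant_size", 3)
  d6 <- make_configuration_display("constant_size", 6)
  expect_equal(unique(d3$items$size), unique(d6$items$size))

  # constant area: summed rendered pixel area conserved within 2%
  areas <- vapply(c(1, 4, 7), function(n) {
    sum(item_pixel_mask(make_configuration_display("constant_area", n)))
  }, numeric(1))
  expect_lt(diff(range(areas)) / mean(areas), 0.02)
  # per-item area quartered between n = 1 and n = 4
  expect_equal(areas[2] / areas[1], 1, tolerance = 0.02)

  # constant perimeter: summed analytic circumference conserved exactly
  per <- vapply(c(1, 4, 7), function(n) {
    sp <- make_configuration_display("constant_perimeter", n)
    sum(pi * sp$items$size)
  }, numeric(1))
  expect_lt(diff(range(per)) / mean(per), 0.02)

  # high density: all items contained in a sub-region of half the radius
  hd <- make_configuration_display("high_density", 7)
  r <- hd$items$size[1] / 2
  ctr <- c(mean(range(hd$items$x)), mean(range(hd$items$y)))
  reach <- sqrt((hd$items$x - ctr[1])^2 + (hd$items$y - ctr[2])^2) + r
  expect_true(all(reach <= 2 * 175))  # diameter of the sub-region
})

test_that("rendering is deterministic and maps contrast to luminance", {
  sp <- single_circle_spec(30)
  a <- render_display(sp)
  b <- render_display(sp)
  expect_identical(a, b)

  # unit-contrast dark disc: pixel count within 3% of the analytic area
  dark <- sum(unclass(a) == 0)
  expect_equal(dark, pi * 15^2, tolerance = 0.03)

  # white item maps to luminance 1
  spw <- display_spec(tibble::tibble(shape = "circle", x = 384, y = 384,
                                     size = 30, contrast = 1))
  expect_equal(max(unclass(render_display(spw))), 1)

  # empty spec renders a uniform background
  sp0 <- display_spec(tibble::tibble(shape = character(), x = numeric(),
                                     y = numeric(), size = numeric()),
                      numerosity = 0)
  expect_true(all(unclass(render_display(sp0)) == 0.5))

  # an item outside the canvas is rejected
  expect_error(display_spec(tibble::tibble(shape = "circle", x = 5, y = 384,
                                           size = 30)),
               "beyond the canvas")
})

test_that("generalization series reproduce the quoted parameter ranges", {
  ser <- make_generalization_series("single_circle_diameters")
  expect_equal(nrow(ser), 240)
  expect_equal(ser$level, 1:240)
  expect_true(all(vapply(ser$spec, function(s) {
    s$items$x == 384 && s$items$y == 384
  }, logical(1))))

  pol <- make_generalization_series("polygons")
  expect_equal(pol$level, c(3:10, Inf))
  expect_true(all(vapply(pol$spec[1:8], function(s) s$items$size == 30,
                         logical(1))))

  st <- make_generalization_series("stars")
  expect_equal(st$level, 3:10)
  expect_true(all(vapply(st$spec, function(s) s$items$inner_radius == 10,
                         logical(1))))

  set.seed(9)
  num <- make_generalization_series("numerosity_1_to_175",
                                    numerosities = c(40, 175))
  for (i in seq_len(nrow(num))) {
    it <- num$spec[[i]]$items
    expect_true(all(it$size == 16))
    d <- as.matrix(dist(cbind(it$x, it$y)))
    diag(d) <- Inf
    if (nrow(it) > 1) expect_true(all(d - 16 >= 24 - 1e-4))
  }

  set.seed(10)
  spc <- make_generalization_series("seven_circle_spacing",
                                    area_diameters = c(50, 280, 528))
  for (i in seq_len(nrow(spc))) {
    it <- spc$spec[[i]]$items
    expect_equal(nrow(it), 7)
    D <- spc$level[i]
    d <- as.matrix(dist(cbind(it$x, it$y)))
    diag(d) <- Inf
    # centre-to-centre floor scales with the group area
    expect_true(all(d >= 16 * D / 50 - 1e-4))
  }
})

test_that("dot-pair displays have the quoted geometry and matched pixel mass", {
  counts <- vapply(c("dots_only", "bar", "rotated_bar", "illusory",
                     "rotated_illusory"), function(conn) {
    sum(item_pixel_mask(make_dot_pair_display(conn, 60)))
  }, numeric(1))

  # two 30-px discs
  expect_equal(unname(counts["dots_only"]), 2 * sum(item_pixel_mask(
    single_circle_spec(30))))
  # the bar adds separation x 4 px of mass, minus the tangent pixel it
  # shares with a dot
  expect_equal(unname(counts["bar"] - counts["dots_only"]), 60 * 4 - 1)
  # split-and-rotated controls carry exactly the same mass
  expect_identical(unname(counts["bar"]), unname(counts["rotated_bar"]))
  expect_identical(unname(counts["illusory"]),
                   unname(counts["rotated_illusory"]))
  # inducers carve into the dots (strictly less mass than the dots alone)
  expect_lt(counts["illusory"], counts["dots_only"])

  # inducer carving reaches exactly 10 px into each dot: carved depth along
  # the midline equals 10 on each side
  sp <- make_dot_pair_display("illusory", 60)
  img <- unclass(render_display(sp))
  row <- img[, 385]  # y = 384 midline (1-based column index)
  left_dot <- 325:355  # left dot spans x = 324..354 (centre 339, radius 15)
  carved <- which(row[left_dot] == 0.5)
  expect_equal(length(carved), 10)
  expect_equal(max(carved), length(left_dot))  # carve starts at the edge

  expect_error(make_dot_pair_display("bar", -3))
})
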