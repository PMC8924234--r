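test_that("the stimulus sequence has the block design structure", {
  sq <- numerosity_sequence()
  expect_equal(nrow(sq), 44)
  expect_equal(sum(sq$label == 20), 16)
  expect_equal(sq$label[1:14], rep(1:7, each = 2))
  expect_equal(sq$label[23:36], rep(7:1, each = 2))
  expect_equal(attr(sq, "tr_s"), 2.1)
})

test_that("build_sequence substitutes feature amplitudes per label", {
  sq <- numerosity_sequence()
  ident <- build_sequence(setNames(as.numeric(c(1:7, 20)),
                                   c(1:7, 20)), sq)
  expect_equal(ident$value, as.numeric(ident$label))

  lg <- build_sequence(setNames(log(c(1:7, 20)), c(1:7, 20)), sq)
  expect_equal(lg$value, log(lg$label))

  expect_error(build_sequence(c(`1` = 1), sq), "label")
})

test_that("the HRF kernel has the canonical shape and negligible truncation", {
  k <- hrf_kernel(tr_s = 0.5)
  t <- seq(0, 30, by = 0.5)
  expect_equal(max(k), 1, tolerance = 0.02)
  peak_t <- t[which.max(k)]
  expect_gte(peak_t, 4)
  expect_lte(peak_t, 7)
  # later undershoot dips negative
  expect_lt(min(k[t > 10]), 0)
  # truncation at 30 s loses under 1% of the L1 mass
  k60 <- hrf_kernel(tr_s = 0.5, duration_s = 60)
  expect_lt(sum(abs(k60[t > 30])) / sum(abs(k60)), 0.01)
  # TR-sampled kernel interleaves a denser sampling
  k21 <- hrf_kernel(tr_s = 2.1)
  k05 <- hrf_kernel(tr_s = 0.7)
  expect_equal(k21, k05[seq(1, length(k05), by = 3)], tolerance = 1e-12)
})

test_that("monotonic fits recover noiseless parameters and match a grid oracle", {
  sq <- numerosity_sequence()
  y <- simulate_voxel("monotonic_increasing", sq, beta = 2.5, baseline = 7)
  f <- fit_monotonic(y, sq)
  expect_equal(f$r2, 1, tolerance = 1e-9)
  expect_equal(f$beta, 2.5, tolerance = 1e-6)
  expect_equal(f$baseline, 7, tolerance = 1e-6)
  expect_equal(f$direction, 1)

  # closed-form GLM beats every point of a coarse brute-force lattice
  set.seed(23)
  yn <- y + rnorm(44, sd = 2)
  fn <- fit_monotonic(yn, sq)
  pred <- monotonic_prediction(sq, "log")
  sse <- function(b, b0) sum((yn - b0 - b * pred)^2)
  grid <- expand.grid(b = seq(0, 5, by = 0.1), b0 = seq(0, 14, by = 0.25))
  best_grid <- min(mapply(sse, grid$b, grid$b0))
  expect_lte(sse(fn$beta, fn$baseline), best_grid)

  expect_error(fit_monotonic(rep(3, 44), sq), "zero-variance")
})

test_that("beta is recovered without bias at moderate noise", {
  sq <- numerosity_sequence()
  clean <- simulate_voxel("monotonic_increasing", sq, beta = 1, baseline = 0)
  snr1_sd <- sd(clean)  # SNR 1: noise SD equals response SD
  set.seed(24)
  betas <- replicate(200, {
    fit_monotonic(clean + rnorm(44, sd = snr1_sd), sq)$beta
  })
  se <- sd(betas) / sqrt(length(betas))
  expect_lt(abs(mean(betas) - 1), 3 * se)
})

test_that("tuned fits recover parameters and pin at the boundary for monotonic input", {
  sq <- numerosity_sequence()
  y <- simulate_voxel("tuned", sq, mu = 3, sigma = 0.3, amplitude = 1.5,
                      baseline = 2)
  f <- fit_tuned(y, sq)
  mu_grid <- default_mu_grid()
  step <- max(diff(log(mu_grid)))
  expect_lt(abs(log(f$mu) - log(3)), step + 1e-9)
  expect_gt(f$r2, 0.999)

  # mu recovery error at SNR 1 stays below 0.5 log-units
  set.seed(25)
  snr1_sd <- sd(y)
  mus <- replicate(100, fit_tuned(y + rnorm(44, sd = snr1_sd), sq)$mu)
  expect_lt(sqrt(mean((log(mus) - log(3))^2)), 0.5)

  # a monotonically increasing voxel drives mu to the upper grid boundary
  ym <- simulate_voxel("monotonic_increasing", sq)
  fm <- fit_tuned(ym, sq)
  expect_equal(fm$mu, max(mu_grid), tolerance = 1e-9)

  expect_error(fit_tuned(y, sq, mu_grid = numeric()), "empty")
  expect_error(fit_tuned(y, sq, mu_grid = c(0.5, 3)), "1.05")
})

test_that("recovery error shrinks as noise vanishes", {
  sq <- numerosity_sequence()
  y <- simulate_voxel("tuned", sq, mu = 2.5, sigma = 0.4)
  set.seed(26)
  err <- vapply(c(1, 0.3, 0), function(ns) {
    median(replicate(40, {
      abs(log(fit_tuned(y + rnorm(44, sd = ns * sd(y)), sq)$mu) - log(2.5))
    }))
  }, numeric(1))
  expect_true(all(diff(err) <= 1e-12))
})

test_that("cross-validation freezes shape parameters and constrains the sign", {
  sq <- numerosity_sequence()
  y <- simulate_voxel("tuned", sq, mu = 4, sigma = 0.3)
  f <- fit_tuned(y, sq)
  # identical halves reproduce the fit
  cv <- cross_validate_fit(f, y)
  expect_equal(cv$r2_cv, cv$r2, tolerance = 1e-9)

  # an opposite-sign held-out response clamps beta and caps r2_cv at zero
  ym <- simulate_voxel("monotonic_increasing", sq, beta = 1)
  fm <- fit_monotonic(ym, sq)
  flipped <- simulate_voxel("monotonic_decreasing", sq, beta = 1)
  cvf <- cross_validate_fit(fm, flipped)
  expect_equal(cvf$beta_cv, 0)
  expect_lte(cvf$r2_cv, 1e-12)

  # with independent noise, cross-validated fits are worse on average
  set.seed(27)
  sd1 <- sd(y)
  drops <- replicate(60, {
    fa <- fit_tuned(y + rnorm(44, sd = sd1), sq)
    cb <- cross_validate_fit(fa, y + rnorm(44, sd = sd1))
    cb$r2 - cb$r2_cv
  })
  expect_gt(mean(drops), 0)
})

test_that("scaling choice follows summed variance explained with log ties", {
  sq <- numerosity_sequence()
  set.seed(28)
  pop <- replicate(30, simulate_voxel("monotonic_increasing", sq,
                                      noise_sd = 0.3), simplify = FALSE)
  fl <- dplyr::bind_rows(lapply(pop, fit_monotonic, seq = sq,
                                scaling = "log"))
  fn <- dplyr::bind_rows(lapply(pop, fit_monotonic, seq = sq,
                                scaling = "linear"))
  expect_equal(choose_scaling(fl, fn), "log")

  # linear-generated population prefers linear scaling
  lin_seq <- sq
  pop_lin <- replicate(30, {
    baseline <- 1
    clean <- baseline + 0.2 * monotonic_prediction(sq, "linear")
    clean + rnorm(44, sd = 0.3)
  }, simplify = FALSE)
  fl2 <- dplyr::bind_rows(lapply(pop_lin, fit_monotonic, seq = sq,
                                 scaling = "log"))
  fn2 <- dplyr::bind_rows(lapply(pop_lin, fit_monotonic, seq = sq,
                                 scaling = "linear"))
  expect_equal(choose_scaling(fl2, fn2), "linear")

  expect_equal(choose_scaling(fl, fl), "log")
})

test_that("pooled variance explained weights configurations by signal variance", {
  expect_equal(pool_configurations(c(0.5, 0.3), c(1, 1)), 0.4)
  # a configuration with tenfold variance dominates
  expect_equal(pool_configurations(c(0.9, 0.1), c(10, 1)),
               (0.9 * 10 + 0.1) / 11)

  # oracle: concatenated-residual computation on synthetic voxels
  sq <- numerosity_sequence()
  set.seed(29)
  r2s <- c(); tvars <- c(); res_all <- c(); y_all <- c()
  for (amp in c(1, 3)) {
    y <- amp * simulate_voxel("monotonic_increasing", sq) + rnorm(44)
    f <- fit_monotonic(y, sq)
    pred <- f$baseline + f$beta * monotonic_prediction(sq, "log")
    r2s <- c(r2s, f$r2)
    tvars <- c(tvars, sum((y - mean(y))^2))
    res_all <- c(res_all, y - pred)
    y_all <- c(y_all, y - mean(y))
  }
  pooled <- pool_configurations(r2s, tvars)
  direct <- 1 - sum(res_all^2) / sum(y_all^2)
  expect_equal(pooled, direct, tolerance = 1e-9)
})
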