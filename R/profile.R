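#' Bin voxel variance explained by pRF eccentricity
#'
#' @param fits Tibble with columns `eccentricity_deg` and `r2` (or the
#'   column named in `value`).
#' @param width Bin width, degrees.
#' @param max_ecc Upper limit of the binning range, degrees.
#' @param value Name of the value column to summarise.
#'
#' @return Tibble with `bin_center`, `mean_ve`, `sem_ve`, `n` (empty bins
#'   dropped).
#' @export
bin_by_eccentricity <- function(fits, width = 0.2, max_ecc = 5.5,
                                value = "r2") {
  stopifnot(all(fits$eccentricity_deg >= 0),
            all(fits$eccentricity_deg <= max_ecc))
  brk <- seq(0, by = width, length.out = ceiling(max_ecc / width - 1e-9) + 1)
  if (max(brk) < max_ecc) brk <- c(brk, max(brk) + width)
  fits |>
    dplyr::mutate(bin = cut(.data$eccentricity_deg, breaks = brk,
                            include.lowest = TRUE, labels = FALSE)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean_ve = mean(.data[[value]]),
                     sem_ve = sd(.data[[value]]) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(bin_center = brk[.data$bin] + width / 2) |>
    dplyr::select("bin_center", "mean_ve", "sem_ve", "n")
}

sigmoid_curve <- function(e, inflection, slope, max_asym, min_asym) {
  min_asym + (max_asym - min_asym) * (1 - stats::pnorm((e - inflection) / slope))
}

fit_sigmoid_once <- function(e, v) {
  rng <- range(v)
  starts <- list(
    c(inflection = 1.5, slope = 0.5, max_asym = max(v), min_asym = min(v)),
    c(inflection = 2.75, slope = 1, max_asym = rng[2], min_asym = rng[1]),
    c(inflection = 1, slope = 0.3, max_asym = rng[2], min_asym = 0),
    c(inflection = 4, slope = 0.8, max_asym = rng[2], min_asym = rng[1]),
    c(inflection = 0.5, slope = 1.5, max_asym = rng[2], min_asym = rng[1]))
  best <- NULL
  for (st in starts) {
    f <- tryCatch(
      minpack.lm::nlsLM(v ~ sigmoid_curve(e, inflection, slope, max_asym,
                                          min_asym),
                        start = as.list(st),
                        lower = c(0, 1e-3, -1, -1), upper = c(5.5, 10, 1, 1),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(err) NULL)
    if (!is.null(f)) {
      rss <- sum(stats::resid(f)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = f, rss = rss)
    }
  }
  if (is.null(best)) {
    # degenerate data (e.g. flat profiles) defeat the gradient-based
    # optimizer; a direct simplex search still returns the least-squares
    # solution
    sse <- function(p) {
      if (p[2] <= 0) return(1e12)
      sum((v - sigmoid_curve(e, p[1], p[2], p[3], p[4]))^2)
    }
    op <- optim(starts[[1]], sse, method = "Nelder-Mead",
                control = list(maxit = 2000))
    co <- setNames(op$par, c("inflection", "slope", "max_asym", "min_asym"))
    co[["inflection"]] <- min(max(co[["inflection"]], 0), 5.5)
  } else {
    co <- coef(best$fit)
  }
  if (!all(is.finite(co))) return(NULL)
  if (co[["max_asym"]] < co[["min_asym"]]) {
    # enforce the decreasing orientation of the parameterization
    co[c("max_asym", "min_asym")] <- co[c("min_asym", "max_asym")]
  }
  co
}

fit_quadratic_once <- function(e, v) {
  co <- coef(lm(v ~ e + I(e^2)))
  c(intercept = unname(co[1]), slope = unname(co[2]),
    quadratic = unname(co[3]))
}

#' Fit an eccentricity profile with bootstrap confidence intervals
#'
#' Fits the relationship between variance explained and pRF eccentricity
#' with either a four-parameter cumulative-Gaussian sigmoid (inflection,
#' slope, maximum asymptote at fixation, minimum asymptote at the far edge)
#' or a three-parameter quadratic.  The unbinned voxel data are resampled
#' `n_boot` times; each resample is binned (0.2 degree bins) and the curve
#' fit to the bin means.  The point estimate is the per-parameter median of
#' the bootstrap fits and the confidence envelope the 2.5/97.5 percentiles
#' of the fitted curves at each eccentricity.
#'
#' @param fits Unbinned tibble with `eccentricity_deg` and `r2`.
#' @param family `"sigmoid"` or `"quadratic"`.
#' @param n_boot Number of bootstrap resamples.
#' @param width,max_ecc Binning parameters.
#' @param value Value column name.
#' @param max_failure_frac Maximum tolerated fraction of non-convergent
#'   resamples (each is redrawn).
#'
#' @return An `eccentricity_profile_fit` list: `family`, `estimate` (named
#'   parameters), `boot` (tibble of resample parameters), `ci_curves`
#'   (tibble: eccentricity, lower, upper, median), `bins` (the observed bin
#'   series).
#' @export
fit_eccentricity_profile <- function(fits, family = c("sigmoid", "quadratic"),
                                     n_boot = 1000, width = 0.2,
                                     max_ecc = 5.5, value = "r2",
                                     max_failure_frac = 0.1) {
  family <- match.arg(family)
  bins <- bin_by_eccentricity(fits, width, max_ecc, value)
  if (family == "sigmoid" && nrow(bins) < 8) {
    stop("fit_eccentricity_profile: need >= 8 occupied bins for the sigmoid")
  }
  n <- nrow(fits)
  fit_one <- function(dat) {
    b <- bin_by_eccentricity(dat, width, max_ecc, value)
    if (family == "sigmoid") {
      fit_sigmoid_once(b$bin_center, b$mean_ve)
    } else {
      fit_quadratic_once(b$bin_center, b$mean_ve)
    }
  }
  boot <- vector("list", n_boot)
  failures <- 0
  max_failures <- ceiling(max_failure_frac * n_boot)
  i <- 1
  while (i <= n_boot) {
    res <- fit_one(fits[sample.int(n, n, replace = TRUE), ])
    if (is.null(res)) {
      failures <- failures + 1
      if (failures > max_failures) {
        stop("fit_eccentricity_profile: more than ",
             round(100 * max_failure_frac), "% of bootstrap resamples failed")
      }
      next
    }
    boot[[i]] <- res
    i <- i + 1
  }
  boot <- as_tibble(do.call(rbind, boot))
  estimate <- purrr::map_dbl(boot, median)
  ecc_grid <- seq(width / 2, max_ecc - width / 2, by = width)
  curves <- apply(boot, 1, function(p) eval_profile(family, p, ecc_grid))
  ci <- apply(curves, 1, quantile, probs = c(0.025, 0.5, 0.975))
  out <- list(family = family, estimate = estimate, boot = boot,
              ci_curves = tibble(eccentricity = ecc_grid,
                                 lower = ci[1, ], median = ci[2, ],
                                 upper = ci[3, ]),
              bins = bins, n_boot = n_boot, n_failures = failures)
  class(out) <- "eccentricity_profile_fit"
  out
}

eval_profile <- function(family, p, e) {
  if (family == "sigmoid") {
    sigmoid_curve(e, p[["inflection"]], p[["slope"]], p[["max_asym"]],
                  p[["min_asym"]])
  } else {
    p[["intercept"]] + p[["slope"]] * e + p[["quadratic"]] * e^2
  }
}

#' @export
print.eccentricity_profile_fit <- function(x, ...) {
  cat("<eccentricity_profile_fit> family:", x$family, "\n")
  print(round(x$estimate, 4))
  invisible(x)
}

#' @export
tidy.eccentricity_profile_fit <- function(x, ...) {
  est <- x$estimate
  qs <- purrr::map(names(est), function(nm) {
    quantile(x$boot[[nm]], c(0.025, 0.975))
  })
  tibble(term = names(est), estimate = unname(est),
         conf.low = purrr::map_dbl(qs, 1), conf.high = purrr::map_dbl(qs, 2))
}

#' @export
glance.eccentricity_profile_fit <- function(x, ...) {
  pred <- eval_profile(x$family, x$estimate, x$bins$bin_center)
  tibble(family = x$family,
         r.squared = cor(pred, x$bins$mean_ve)^2,
         n_bins = nrow(x$bins), n_boot = x$n_boot,
         n_failures = x$n_failures)
}

#' Choose between sigmoid and quadratic eccentricity profiles
#'
#' Selects the family whose fitted curve correlates best with the bin means.
#' Near-ties (within `tie_tol` of each other) resolve to the quadratic,
#' which makes the fewer structural assumptions.
#'
#' @param sigmoid_fit,quadratic_fit Fits from [fit_eccentricity_profile()].
#' @param tie_tol Correlation difference treated as a tie.
#'
#' @return `"sigmoid"` or `"quadratic"`.
#' @export
select_profile_family <- function(sigmoid_fit, quadratic_fit,
                                  tie_tol = 1e-6) {
  r_of <- function(f) {
    pred <- eval_profile(f$family, f$estimate, f$bins$bin_center)
    if (!all(is.finite(pred)) || sd(pred) < 1e-12) return(-Inf)
    cor(pred, f$bins$mean_ve)
  }
  rs <- r_of(sigmoid_fit)
  rq <- r_of(quadratic_fit)
  if (!is.finite(rs) && !is.finite(rq)) return("quadratic")
  if (rs > rq + tie_tol) "sigmoid" else "quadratic"
}
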