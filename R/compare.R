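#' Paired Wilcoxon signed-rank comparison of model fits
#'
#' Compares two models' cross-validated variance explained over paired
#' hemisphere (or recording-site) measurements with a two-sided Wilcoxon
#' signed-rank test, reporting the median paired difference, the normal
#' approximation Z statistic and the p-value, with Benjamini-Hochberg false
#' discovery rate correction across a declared family of comparisons.
#'
#' Voxel inclusion (no model explaining more than the threshold share of
#' variance) must be applied upstream on the fitting half of the data, never
#' on the evaluation half, to avoid circularity between voxel selection and
#' model comparison; see [apply_inclusion_rule()].
#'
#' @param ve_a,ve_b Paired variance-explained vectors (model A and B).
#' @param p_family Optional vector of p-values from the other comparisons in
#'   the same family; FDR correction is applied over `c(p, p_family)`.
#'
#' @return One-row tibble: `n`, `median_a`, `median_b`, `median_difference`,
#'   `statistic` (signed-rank V), `z`, `p_raw`, `p_fdr`.
#' @export
compare_models_wilcoxon <- function(ve_a, ve_b, p_family = numeric()) {
  stopifnot(length(ve_a) == length(ve_b))
  d <- ve_a - ve_b
  if (all(d == 0)) {
    p <- 1
    v <- 0
    z <- 0
  } else {
    wt <- wilcox.test(ve_a, ve_b, paired = TRUE, exact = length(d) <= 50,
                      correct = FALSE)
    p <- wt$p.value
    v <- unname(wt$statistic)
    z <- signed_rank_z(d)
  }
  p_adj <- p.adjust(c(p, p_family), method = "BH")[1]
  tibble(n = length(d),
         median_a = median(ve_a), median_b = median(ve_b),
         median_difference = median(d),
         statistic = v, z = z, p_raw = p, p_fdr = max(p_adj, p))
}

# signed Z from the normal approximation to the signed-rank statistic,
# with tie and zero corrections
signed_rank_z <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(0)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ev <- n * (n + 1) / 4
  ties <- table(r)
  sv <- sqrt(n * (n + 1) * (2 * n + 1) / 24 -
               sum(ties^3 - ties) / 48)
  if (sv == 0) return(0)
  (v - ev) / sv
}

#' Apply the voxel-inclusion rule on the fitting half
#'
#' Retains voxels for which at least one of the compared models explains
#' more than `threshold` of the response variance *before* cross-validation
#' (i.e. on the data the models were fit on).
#'
#' @param fits Tibble with `voxel_id`, `model` and `r2` (fit-half variance
#'   explained).
#' @param threshold Variance-explained threshold (default 0.2).
#'
#' @return Vector of retained `voxel_id`s.
#' @export
apply_inclusion_rule <- function(fits, threshold = 0.2) {
  fits |>
    dplyr::group_by(.data$voxel_id) |>
    dplyr::summarise(best = max(.data$r2), .groups = "drop") |>
    dplyr::filter(.data$best > threshold) |>
    dplyr::pull("voxel_id")
}

#' Compare neural-network response lines against candidate functions
#'
#' Takes a set of monotonic response lines (response vs numerosity, e.g.
#' digitized from neural-network studies), normalizes them globally so the
#' mean response to the lowest numerosity is 0 and to the highest is 1
#' (preserving between-line offsets), and linearly scales each candidate
#' function (e.g. aggregate-Fourier-power-vs-numerosity, log(numerosity))
#' to best fit all data points.  Each line is correlated with each scaled
#' candidate; candidates are compared by paired t-tests on the per-line
#' correlation coefficients, and a quadratic (second-degree polynomial) is
#' fit to all points as a reference.
#'
#' @param lines Tibble with columns `line`, `numerosity`, `response`.
#' @param candidates Named list of functions of numerosity (each vectorized).
#'
#' @return List with `normalized` (the normalized lines), `scaled`
#'   (candidate values at the observed numerosities after least-squares
#'   scaling), `correlations` (line x candidate), `t_tests` (pairwise paired
#'   t-tests on correlation sets) and `quadratic` (coefficients of the
#'   quadratic fit to all points).
#' @export
compare_nn_lines <- function(lines,
                             candidates = list(log_numerosity = log)) {
  stopifnot(all(c("line", "numerosity", "response") %in% names(lines)))
  n_lo <- min(lines$numerosity)
  n_hi <- max(lines$numerosity)
  m_lo <- mean(lines$response[lines$numerosity == n_lo])
  m_hi <- mean(lines$response[lines$numerosity == n_hi])
  if (abs(m_hi - m_lo) < 1e-12) {
    stop("compare_nn_lines: degenerate normalization anchors")
  }
  lines$norm <- (lines$response - m_lo) / (m_hi - m_lo)
  # drop lines with no variation (correlation undefined)
  keep <- lines |>
    dplyr::group_by(.data$line) |>
    dplyr::summarise(s = sd(.data$norm), .groups = "drop")
  drop <- keep$line[keep$s < 1e-12]
  if (length(drop)) {
    warning("compare_nn_lines: excluding constant line(s) ",
            paste(drop, collapse = ", "))
    lines <- lines[!lines$line %in% drop, ]
  }
  scaled <- purrr::imap(candidates, function(f, nm) {
    x <- f(lines$numerosity)
    co <- coef(lm(lines$norm ~ x))
    co[1] + co[2] * x
  })
  cor_tbl <- purrr::imap(scaled, function(v, nm) {
    lines |>
      dplyr::mutate(cand = v) |>
      dplyr::group_by(.data$line) |>
      dplyr::summarise(r = cor(.data$norm, .data$cand), .groups = "drop") |>
      dplyr::mutate(candidate = nm)
  }) |> purrr::list_rbind()
  wide <- tidyr::pivot_wider(cor_tbl, names_from = "candidate",
                             values_from = "r")
  cand_names <- names(candidates)
  tt <- purrr::list_rbind(purrr::map(utils::combn(cand_names, 2,
                                                  simplify = FALSE),
    function(pr) {
      ht <- t.test(wide[[pr[1]]], wide[[pr[2]]], paired = TRUE)
      tibble(candidate_a = pr[1], candidate_b = pr[2],
             mean_r_a = mean(wide[[pr[1]]]), mean_r_b = mean(wide[[pr[2]]]),
             t = unname(ht$statistic), df = unname(ht$parameter),
             p = ht$p.value)
    }))
  quad <- coef(lm(norm ~ numerosity + I(numerosity^2), data = lines))
  list(normalized = lines, scaled = scaled, correlations = cor_tbl,
       t_tests = tt,
       quadratic = c(intercept = unname(quad[1]), linear = unname(quad[2]),
                     quadratic = unname(quad[3])))
}
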