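#' Weighted-bootstrap median and confidence interval
#'
#' Resamples the values with replacement, with probability proportional to
#' the weights (by default inverse regression RMSE, so better-fitted curves
#' count more), computes the median of each replicate, and reports the median
#' of the replicate medians with the 2.5/97.5 percentile interval.
#'
#' @param values Non-empty numeric vector.
#' @param weights Non-negative weights, same length (default equal).
#' @param B Number of bootstrap replicates (default 1e5).
#' @param seed Optional integer seed (local RNG).
#' @return A tibble with `median`, `ci_lo`, `ci_hi`.
#' @export
boot_median_ci <- function(values, weights = NULL, B = 1e5, seed = NULL) {
  n <- length(values)
  stopifnot(n >= 1, B >= 1)
  cw <- cum_weights(weights, n)
  meds <- with_seed(seed, .boot_median_cpp(as.double(values), cw,
                                           as.integer(B)))
  ci <- unname(quantile(meds, c(0.025, 0.975), type = 7))
  tibble::tibble(median = median(meds), ci_lo = ci[1], ci_hi = ci[2])
}

# two-sided exact binomial sign p for k successes of m trials under p = 1/2:
# 2 * min(P(X <= k), P(X >= k)), capped at 1
binom_sign_p <- function(k, m) {
  lo <- ifelse(m == 0, 1, pbinom(k, m, 0.5))
  up <- ifelse(m == 0, 1, pbinom(k - 1, m, 0.5, lower.tail = FALSE))
  pmin(1, 2 * pmin(lo, up))
}

#' Weighted sign test with bootstrap medians
#'
#' Tests whether a sample sits symmetrically around `null_value`. Values
#' tied with the null are dropped (the sign-test convention). With equal
#' weights the p-value is the classical two-sided exact binomial sign test.
#' With unequal weights, the weighted proportion of positive signs is
#' referred to a binomial null at Kish's effective sample size
#' \eqn{(\sum w)^2 / \sum w^2}, so down-weighted curves contribute
#' proportionally less evidence. The reported median and its 95% CI come
#' from the weighted bootstrap ([boot_median_ci()]).
#'
#' @param values Non-empty numeric vector.
#' @param null_value Hypothesised centre (0 for coefficients, 1 when testing
#'   a ratio such as a noise-scale multiplier).
#' @param weights Non-negative weights (default equal).
#' @param alpha Significance level (default 0.05).
#' @param B Bootstrap replicates (default 1e4).
#' @param seed Optional integer seed.
#' @return A tibble of class-free test output: `p.value`, `decision`
#'   (logical, reject at `alpha`), `median`, `ci_lo`, `ci_hi` (weighted
#'   bootstrap median CI), `n`, `direction` (sign of the median shift).
#' @export
sign_test <- function(values, null_value = 0, weights = NULL, alpha = 0.05,
                      B = 1e4, seed = NULL) {
  n <- length(values)
  stopifnot(n >= 1)
  w <- weights %||% rep(1, n)
  nz <- values != null_value
  p <- if (!any(nz)) 1 else {
    v <- values[nz]
    wz <- w[nz]
    if (all(wz == wz[1])) {
      binom_sign_p(sum(v > null_value), length(v))
    } else {
      n_eff <- sum(wz)^2 / sum(wz^2)
      k_eff <- round(n_eff * sum(wz[v > null_value]) / sum(wz))
      binom_sign_p(k_eff, round(n_eff))
    }
  }
  ci <- boot_median_ci(values, weights = w, B = B,
                       seed = derive_seed(seed %||% 0, 7))
  tibble::tibble(p.value = p, decision = p < alpha, median = ci$median,
                 ci_lo = ci$ci_lo, ci_hi = ci$ci_hi, n = n,
                 direction = sign(ci$median - null_value))
}

#' Weighted-bootstrap rank-sum test
#'
#' Two-sided Wilcoxon/Mann-Whitney comparison of two groups with a
#' weighted-bootstrap null: under the null hypothesis both groups share one
#' distribution, so each of the `B` replicates redraws both groups from the
#' pooled weighted sample and computes the Mann-Whitney U of the first; the
#' p-value is the proportion of replicates whose U deviates from the null
#' mean \eqn{n_a n_b / 2} at least as far as the observed U (with the +1
#' finite-sample correction). With equal weights this is a Monte-Carlo
#' permutation-style test and holds its nominal level. The corrected p
#' multiplies the raw p by `n_comparisons` (Bonferroni), capped at 1.
#'
#' @param values_a,values_b Non-empty numeric vectors.
#' @param weights_a,weights_b Optional non-negative weights.
#' @param alpha Significance level applied to the corrected p.
#' @param n_comparisons Bonferroni divisor (default 1).
#' @param B Bootstrap replicates (default 1e4).
#' @param seed Optional integer seed.
#' @return A tibble with `p.value`, `p.adjusted`, `decision`, `n_a`, `n_b`.
#' @export
ranksum_test <- function(values_a, values_b, weights_a = NULL,
                         weights_b = NULL, alpha = 0.05,
                         n_comparisons = 1, B = 1e4, seed = NULL) {
  na <- length(values_a)
  nb <- length(values_b)
  stopifnot(na >= 1, nb >= 1)
  pool <- as.double(c(values_a, values_b))
  cw <- cum_weights(c(weights_a %||% rep(1, na), weights_b %||% rep(1, nb)),
                    na + nb)
  u_obs <- .ranksum_u_cpp(as.double(values_a), as.double(values_b))
  mu <- na * nb / 2
  u_null <- with_seed(seed, .boot_ranksum_null_cpp(pool, cw, na, nb,
                                                   as.integer(B)))
  p <- (1 + sum(abs(u_null - mu) >= abs(u_obs - mu) - 1e-12)) / (B + 1)
  p_adj <- min(1, p * n_comparisons)
  tibble::tibble(p.value = p, p.adjusted = p_adj, decision = p_adj < alpha,
                 n_a = length(values_a), n_b = length(values_b))
}

# inverse-RMSE weights with the RMSE floored at its 1st percentile, so a
# near-perfect fit cannot dominate the resampling
inverse_rmse_weights <- function(rmse) {
  floor_val <- quantile(rmse, 0.01, type = 7)
  if (floor_val <= 0) floor_val <- min(rmse[rmse > 0], 1e-12)
  1 / pmax(rmse, floor_val)
}

#' Per-coordinate tests of a fitted parameter
#'
#' For one named parameter of a per-curve fit table, runs the weighted
#' bootstrap sign test against `null_value` within each EA coordinate, and
#' the weighted bootstrap rank-sum test of each non-control coordinate
#' against the control (gain 1, offset 0), Bonferroni-corrected by the
#' number of non-control coordinates compared. Resampling weights are
#' inverse regression RMSE (floored at the 1st percentile).
#'
#' @param fits A tibble with columns `gain`, `offset`, `rmse` and the
#'   parameter column (e.g. output of [fit_learning_curves()] with unnested
#'   coefficients, or [fit_dpxmrml_curves()]).
#' @param parameter Name of the parameter column to test.
#' @param null_value Sign-test null (default 0).
#' @param alpha Significance level (default 0.05).
#' @param B Bootstrap replicates (default 1e4).
#' @param seed Optional integer seed.
#' @return A tibble of class `"ea_table"`: one row per EA coordinate with the
#'   sign-test output, medians and CIs, plus `p.control` / `p.control.adj` /
#'   `vs_control` for the rank-sum comparison (NA for the control row, and
#'   marked unavailable when no control fits exist). Supports [autoplot()].
#' @export
parameter_table <- function(fits, parameter, null_value = 0, alpha = 0.05,
                            B = 1e4, seed = NULL) {
  stopifnot(parameter %in% names(fits), "rmse" %in% names(fits))
  fits <- fits[is.finite(fits[[parameter]]) & is.finite(fits$rmse), ]
  fits$`..w` <- inverse_rmse_weights(fits$rmse)
  coords <- dplyr::distinct(fits, .data$gain, .data$offset) |>
    dplyr::arrange(.data$offset, .data$gain)
  ctrl <- fits[fits$gain == 1 & fits$offset == 0, ]
  n_cmp <- sum(!(coords$gain == 1 & coords$offset == 0))
  rows <- purrr::pmap(coords, function(gain, offset) {
    grp <- fits[fits$gain == gain & fits$offset == offset, ]
    st <- sign_test(grp[[parameter]], null_value = null_value,
                    weights = grp$`..w`, alpha = alpha, B = B,
                    seed = derive_seed(seed %||% 0, gain * 10 + offset))
    is_ctrl <- gain == 1 && offset == 0
    if (!is_ctrl && nrow(ctrl) > 0) {
      rs <- ranksum_test(grp[[parameter]], ctrl[[parameter]],
                         weights_a = grp$`..w`, weights_b = ctrl$`..w`,
                         alpha = alpha, n_comparisons = max(1, n_cmp), B = B,
                         seed = derive_seed(seed %||% 0,
                                            100 + gain * 10 + offset))
      pc <- rs$p.value; pca <- rs$p.adjusted; vs <- rs$decision
    } else {
      pc <- NA_real_; pca <- NA_real_; vs <- NA
    }
    tibble::tibble(gain = gain, offset = offset, parameter = parameter,
                   n = st$n, median = st$median, ci_lo = st$ci_lo,
                   ci_hi = st$ci_hi, p.sign = st$p.value,
                   sign_decision = st$decision, direction = st$direction,
                   p.control = pc, p.control.adj = pca, vs_control = vs)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ea_table", class(out))
  out
}

#' Steady-state error tests per EA coordinate
#'
#' Applies each curve's fitted model to compute the deterministic
#' steady-state error at trial `n` (default 250) from the curve's own
#' first-exposure error, excludes divergent curves (logged), and sign-tests
#' the steady states against zero within each EA coordinate. Negative
#' steady states indicate overcompensation, positive undercompensation.
#'
#' @param fits Output of [fit_learning_curves()] (needs `fit`, `e0`, `rmse`,
#'   `gain`, `offset`).
#' @param n Trial index of the steady state (default 250).
#' @inheritParams parameter_table
#' @return An `"ea_table"` tibble as in [parameter_table()], with attribute
#'   `excluded` counting divergent curves dropped.
#' @export
steady_state_table <- function(fits, n = 250, alpha = 0.05, B = 1e4,
                               seed = NULL) {
  ss <- purrr::map2(fits$fit, fits$e0, function(f, e0)
    steady_state_error(f$structure_id, f$params, e0, n = n))
  fits$steady_state <- vapply(ss, as.double, double(1))
  div <- vapply(ss, function(v) isTRUE(attr(v, "divergent")), logical(1))
  out <- parameter_table(fits[!div, ], "steady_state", null_value = 0,
                         alpha = alpha, B = B, seed = seed)
  attr(out, "excluded") <- sum(div)
  out
}

#' Washout time-constant comparisons per EA coordinate
#'
#' Reports bootstrap medians and CIs of the washout decay time constants and
#' rank-sum comparisons of each coordinate against the control (Bonferroni
#' over the non-control coordinates present). Longer time constants indicate
#' slower decay of the acquired skill, i.e. stronger retention.
#'
#' @param washout_fits Output of [fit_washout_curves()] (needs `tau`, `gain`,
#'   `offset`; flagged/unidentifiable fits are dropped).
#' @inheritParams parameter_table
#' @return A tibble: one row per coordinate with `n`, `median`, `ci_lo`,
#'   `ci_hi` of tau and the rank-sum columns.
#' @export
washout_table <- function(washout_fits, alpha = 0.05, B = 1e4, seed = NULL) {
  wf <- washout_fits[!washout_fits$flagged & is.finite(washout_fits$tau), ]
  stopifnot(nrow(wf) > 0)
  coords <- dplyr::distinct(wf, .data$gain, .data$offset) |>
    dplyr::arrange(.data$offset, .data$gain)
  stopifnot(nrow(coords) >= 2)
  ctrl <- wf[wf$gain == 1 & wf$offset == 0, ]
  n_cmp <- sum(!(coords$gain == 1 & coords$offset == 0))
  rows <- purrr::pmap(coords, function(gain, offset) {
    grp <- wf[wf$gain == gain & wf$offset == offset, ]
    ci <- boot_median_ci(grp$tau, B = B,
                         seed = derive_seed(seed %||% 0, gain * 10 + offset))
    is_ctrl <- gain == 1 && offset == 0
    if (!is_ctrl && nrow(ctrl) > 0) {
      rs <- ranksum_test(grp$tau, ctrl$tau, alpha = alpha,
                         n_comparisons = max(1, n_cmp), B = B,
                         seed = derive_seed(seed %||% 0,
                                            100 + gain * 10 + offset))
      pc <- rs$p.value; pca <- rs$p.adjusted; vs <- rs$decision
    } else {
      pc <- NA_real_; pca <- NA_real_; vs <- NA
    }
    tibble::tibble(gain = gain, offset = offset, n = nrow(grp),
                   median = ci$median, ci_lo = ci$ci_lo, ci_hi = ci$ci_hi,
                   p.control = pc, p.control.adj = pca, vs_control = vs)
  })
  dplyr::bind_rows(rows)
}
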