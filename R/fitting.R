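#' Fitting configuration
#'
#' Controls the multi-start bounded least-squares optimiser used by all model
#' fits. The global-search strategy is seeded multi-start: `n_starts` starting
#' points are drawn uniformly within the coefficient bounds, discarded while
#' their objective is non-finite (divergent simulation), supplemented by the
#' zero vector, and each survivor is refined by box-bounded
#' Levenberg-Marquardt; the best objective wins. Starting points come from a
#' deterministic seeded stream, so increasing `n_starts` can only improve
#' (never worsen) the best objective at a fixed seed.
#'
#' @param n_starts Number of random starts (default 1000, the reference
#'   setting; tests and the pipeline's test profile use far fewer).
#' @param bounds Named list of per-coefficient `c(lower, upper)` bounds.
#'   Defaults: `a` in \[-5, 5\] cm/trial, `b`/`b1`…`b8` in \[-2, 2\], `c` in
#'   \[-1, 1\], `d` in \[-0.5, 0.5\], `Af`/`As` in \[-1, 1\], `Bf`/`Bs` in
#'   \[-2, 2\].
#' @param tol Relative convergence tolerance of each local solve.
#' @param seed Integer seed for the start stream (default 1).
#' @param sigma_divisor `"n"` (default) divides the residual standard
#'   deviation by the number of learning-curve trials when estimating the
#'   inter-trial noise scale; `"sqrt_n"` divides by its square root.
#' @return A list of class `"fit_control"`.
#' @export
fit_control <- function(n_starts = 1000, bounds = NULL, tol = 1e-10,
                        seed = 1, sigma_divisor = c("n", "sqrt_n")) {
  stopifnot(n_starts >= 1)
  default_bounds <- list(
    a = c(-5, 5), b = c(-2, 2), c = c(-1, 1), d = c(-0.5, 0.5),
    Af = c(-1, 1), As = c(-1, 1), Bf = c(-2, 2), Bs = c(-2, 2))
  for (k in paste0("b", 1:8)) default_bounds[[k]] <- c(-2, 2)
  if (!is.null(bounds)) default_bounds[names(bounds)] <- bounds
  stopifnot(all(vapply(default_bounds, function(b)
    length(b) == 2 && all(is.finite(b)) && b[1] < b[2], logical(1))))
  structure(list(n_starts = as.integer(n_starts), bounds = default_bounds,
                 tol = tol, seed = seed,
                 sigma_divisor = match.arg(sigma_divisor)),
            class = "fit_control")
}

# Shared multi-start bounded least-squares driver. residual_fn(par) returns
# the raw residual vector (non-finite on divergent simulations). Starting
# points are drawn uniformly within the bounds from a seeded stream and only
# kept when their objective is finite — random starts in divergent regions
# give the optimiser a flat infinite plateau and are wasted — plus the zero
# vector (always stable). Each start is refined by Levenberg-Marquardt with
# box bounds; divergent residuals during refinement are clamped to a large
# finite value so the solver is pushed back toward the stable region.
# Because start i consumes a fixed slice of the seeded stream, the start set
# is nested in n_starts: the best objective is monotone in it at fixed seed.
multi_start <- function(residual_fn, lower, upper, control) {
  p <- length(lower)
  obj <- function(par) {
    r <- residual_fn(par)
    if (!all(is.finite(r))) return(Inf)
    sum(r * r)
  }
  clamped <- function(par) {
    r <- residual_fn(par)
    r[!is.finite(r)] <- 1e6
    r
  }
  starts <- with_seed(control$seed, {
    out <- list(pmin(pmax(rep(0, p), lower), upper))
    tries <- 0L
    max_tries <- 50L * control$n_starts
    while (length(out) < control$n_starts + 1L && tries < max_tries) {
      s <- lower + runif(p) * (upper - lower)
      tries <- tries + 1L
      if (is.finite(obj(s))) out[[length(out) + 1L]] <- s
    }
    out
  })
  best <- NULL
  for (s in starts) {
    fit <- suppressWarnings(
      minpack.lm::nls.lm(s, lower = lower, upper = upper, fn = clamped,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = control$tol)))
    v <- obj(fit$par)
    if (is.null(best) || v < best$objective) {
      best <- list(par = fit$par, objective = v,
                   convergence = fit$info)
    }
  }
  best$starts_run <- length(starts)
  best
}

#' Goodness-of-fit statistics
#'
#' @param observed,predicted Numeric vectors of equal length (>= 2).
#' @param n_free_params Number of free drift coefficients `p` used by the
#'   model; the adjusted statistic is
#'   \eqn{R^2_{adj} = 1 - (1 - R^2)(n - 1)/(n - p - 1)}.
#' @return A tibble with `r.squared`, `adj.r.squared`, `rmse`, `sse` and a
#'   `zero_variance` flag (when the observations carry no variance the R^2
#'   statistics are undefined and returned as `NA`).
#' @export
goodness_of_fit <- function(observed, predicted, n_free_params) {
  n <- length(observed)
  stopifnot(n >= 2, length(predicted) == n)
  sse <- sum((observed - predicted)^2)
  sst <- sum((observed - mean(observed))^2)
  zero_var <- sst == 0
  r2 <- if (zero_var) NA_real_ else 1 - sse / sst
  r2adj <- if (zero_var) NA_real_ else
    1 - (1 - r2) * (n - 1) / (n - n_free_params - 1)
  tibble::tibble(r.squared = r2, adj.r.squared = r2adj,
                 rmse = sqrt(sse / n), sse = sse, zero_variance = zero_var)
}

#' Estimate the inter-trial noise scale from fit residuals
#'
#' The noise scale of the Wiener-type disturbance is taken as the standard
#' deviation of the deterministic-fit residuals normalised by the number of
#' learning-curve trials (the divisor is configurable; see [fit_control()]).
#'
#' @param residuals Numeric residuals at the observed trials.
#' @param n_curve_trials Number of trials in the learning curve (default 250).
#' @param divisor `"n"` or `"sqrt_n"`.
#' @return Estimated `sigma` (error units).
#' @export
estimate_sigma <- function(residuals, n_curve_trials = 250,
                           divisor = c("n", "sqrt_n")) {
  divisor <- match.arg(divisor)
  s <- if (length(residuals) < 2) 0 else sd(residuals)
  s / switch(divisor, n = n_curve_trials, sqrt_n = sqrt(n_curve_trials))
}

#' Fit a proxy-process model to one learning curve
#'
#' Least-squares estimation of a proxy-process structure from the no-vision
#' observations of a single learning curve. The objective deterministically
#' simulates the model (noise off) over all consecutive trials from the
#' first-exposure error `e0` — so the process bridges the vision-trial gaps —
#' and sums squared deviations at the observed no-vision trials. Optimisation
#' is seeded multi-start bounded least squares; divergent simulations receive
#' an infinite objective and are rejected. The noise scale `sigma` is
#' estimated afterwards from the residuals ([estimate_sigma()]).
#'
#' @param data A data frame with columns `trial` (0-based index within the
#'   learning phase) and `error` (signed, cm), one row per no-vision
#'   observation. Row order is irrelevant.
#' @param structure_id Model structure id (see [proxy_models()]).
#' @param e0 First-exposure error of the curve's movement direction. Defaults
#'   to the `error` at `trial == 0` when present.
#' @param n_trials Length of the learning phase; defaults to
#'   `max(data$trial)`.
#' @param control A [fit_control()] list.
#' @return An object of class `"proxy_fit"`: fitted coefficients, `sigma`,
#'   fit statistics, residuals, divergence and constant-data flags, and
#'   optimiser metadata. Supports [tidy()], [glance()] and [autoplot()].
#' @export
fit_proxy <- function(data, structure_id, e0 = NULL, n_trials = NULL,
                      control = fit_control()) {
  spec <- model_spec(structure_id)
  stopifnot(all(c("trial", "error") %in% names(data)))
  data <- dplyr::arrange(dplyr::as_tibble(data[c("trial", "error")]),
                         .data$trial)
  if (is.null(e0)) {
    i0 <- which(data$trial == 0)
    if (length(i0) == 0) {
      stop("e0 not supplied and no trial-0 observation present", call. = FALSE)
    }
    e0 <- data$error[i0[1]]
  }
  stopifnot(is.finite(e0))
  if (nrow(data) < spec$n_free_params + 1) {
    stop("need at least ", spec$n_free_params + 1, " observations to fit '",
         structure_id, "', got ", nrow(data), call. = FALSE)
  }
  n_trials <- as.integer(n_trials %||% max(data$trial))
  constant_data <- var(data$error) == 0
  lower <- vapply(spec$param_names, function(nm) control$bounds[[nm]][1],
                  double(1))
  upper <- vapply(spec$param_names, function(nm) control$bounds[[nm]][2],
                  double(1))
  obs_idx <- as.integer(data$trial)   # 0-based, matches simulated sequence
  obs <- as.double(data$error)
  resfn <- function(th) {
    sim <- .sim_proxy_cpp(spec$type, spec$order, th, e0, n_trials, 0,
                          numeric(0))
    obs - sim[obs_idx + 1L]
  }
  best <- multi_start(resfn, lower, upper, control)
  params <- as.list(best$par)
  names(params) <- spec$param_names
  sim <- simulate_proxy(structure_id, params, e0, n_trials, sigma = 0)
  pred <- sim$error[obs_idx + 1L]
  gof <- goodness_of_fit(obs, pred, spec$n_free_params)
  sigma <- estimate_sigma(obs - pred, n_curve_trials = n_trials + 1L,
                          divisor = control$sigma_divisor)
  structure(list(
    structure_id = structure_id, params = params, sigma = sigma, e0 = e0,
    n_trials = n_trials, sse = gof$sse, rmse = gof$rmse,
    r.squared = gof$r.squared, adj.r.squared = gof$adj.r.squared,
    residuals = tibble::tibble(trial = data$trial, observed = obs,
                               predicted = pred, residual = obs - pred),
    divergent = !all(is.finite(pred)) || any(abs(pred) > 1e8),
    constant_data = constant_data, zero_variance = gof$zero_variance,
    n_obs = nrow(data),
    optim = list(starts_run = best$starts_run, objective = best$objective,
                 convergence = best$convergence)),
    class = "proxy_fit")
}

#' Fit the multi-rate model to one learning curve
#'
#' Estimates the retention rates (`Af`, `As`) and learning rates (`Bf`, `Bs`)
#' of the dynamic-proxy multi-rate model from intermittent no-vision
#' observations, holding the embedded second-order proxy coefficients fixed
#' (typically taken from a prior [fit_proxy()] of structure `"2.1"`). The
#' deterministic model run (`dz = 0`, states starting at zero) supplies the
#' objective: squared prediction error summed over the observed trials. The
#' constraints \eqn{A_s > A_f} and \eqn{B_f > B_s} are enforced by the smooth
#' reparameterisation \eqn{A_s = A_f + r (1 - A_f)}, \eqn{B_f = B_s +
#' q (2 - B_s)} with \eqn{r, q \in (0, 1]}, which also keeps
#' \eqn{A_s \le 1}.
#'
#' @inheritParams fit_proxy
#' @param proxy_params Named list with `a`, `b1`, `b2` (and optionally
#'   `sigma`) of the embedded `"2.1"` process.
#' @return An object of class `"dpxmrml_fit"` with fields `params`
#'   (`Af`, `As`, `Bf`, `Bs`), fit statistics, residuals and optimiser
#'   metadata. Supports [tidy()], [glance()] and [autoplot()].
#' @export
fit_dpxmrml <- function(data, proxy_params, n_trials = NULL,
                        control = fit_control()) {
  stopifnot(all(c("trial", "error") %in% names(data)))
  data <- dplyr::arrange(dplyr::as_tibble(data[c("trial", "error")]),
                         .data$trial)
  n_trials <- as.integer(n_trials %||% (max(data$trial) + 1L))
  obs <- rep(0, n_trials)
  avail <- rep(FALSE, n_trials)
  obs[data$trial + 1L] <- data$error
  avail[data$trial + 1L] <- TRUE
  if (!avail[1]) {
    stop("the first trial must carry an observation (the embedded proxy ",
         "process needs a seed); include the trial-0 error", call. = FALSE)
  }
  th <- c(proxy_params$a %||% 0, proxy_params$b1 %||% 0,
          proxy_params$b2 %||% 0)
  bA <- control$bounds$Af
  bB <- control$bounds$Bs
  eps <- 1e-6
  unpack <- function(p) {
    Af <- p[1]; r <- p[2]; Bs <- p[3]; q <- p[4]
    list(Af = Af, As = Af + r * (1 - Af), Bs = Bs, Bf = Bs + q * (2 - Bs))
  }
  obs_avail <- obs[avail]
  resfn <- function(p) {
    pr <- unpack(p)
    run <- .run_dpxmrml_cpp(pr$Af, pr$As, pr$Bf, pr$Bs, th, 0, obs, avail,
                            numeric(0))
    obs_avail - run$yhat[avail]
  }
  # Af is kept strictly below 1 so that As = Af + r (1 - Af) can exceed it
  best <- multi_start(resfn, lower = c(bA[1], eps, bB[1], eps),
                      upper = c(min(bA[2], 1 - 1e-6), 1, bB[2], 1),
                      control = control)
  params <- unpack(best$par)[c("Af", "As", "Bf", "Bs")]
  run <- run_dpxmrml(params, proxy_params = list(a = th[1], b1 = th[2],
                                                 b2 = th[3], sigma = 0),
                     observed = obs, available = avail)
  pred <- run$y_hat[avail]
  observed <- obs[avail]
  gof <- goodness_of_fit(observed, pred, 4)
  structure(list(
    params = params, proxy_params = proxy_params, n_trials = n_trials,
    sse = gof$sse, rmse = gof$rmse, r.squared = gof$r.squared,
    adj.r.squared = gof$adj.r.squared,
    residuals = tibble::tibble(trial = which(avail) - 1L,
                               observed = observed, predicted = pred,
                               residual = observed - pred),
    n_obs = sum(avail),
    optim = list(starts_run = best$starts_run, objective = best$objective,
                 convergence = best$convergence)),
    class = "dpxmrml_fit")
}

#' Fit an exponential decay to washout error magnitudes
#'
#' Least-squares fit of \eqn{A e^{-n/\tau}} to the error magnitudes of a
#' washout phase (`n` counted from 0). The time constant \eqn{\tau} indexes
#' how quickly the acquired skill decays once normal feedback returns; it is
#' bounded in (0.1, 300\] trials and fits landing at the upper bound (or
#' degenerate all-zero data) are flagged as non-decaying/unidentifiable.
#'
#' @param data A data frame with columns `trial` (0-based washout index) and
#'   `magnitude` (>= 0), at least 3 rows.
#' @param control A [fit_control()] list.
#' @return An object of class `"washout_fit"` with `A` (cm), `tau` (trials),
#'   `sse` and a `flagged` logical. Supports [tidy()] and [glance()].
#' @export
fit_washout <- function(data, control = fit_control()) {
  stopifnot(all(c("trial", "magnitude") %in% names(data)))
  data <- dplyr::as_tibble(data[c("trial", "magnitude")])
  stopifnot(nrow(data) >= 3, all(data$magnitude >= 0))
  n <- as.double(data$trial)
  y <- as.double(data$magnitude)
  if (all(y == 0)) {
    return(structure(list(A = 0, tau = NA_real_, sse = 0, flagged = TRUE,
                          data = data), class = "washout_fit"))
  }
  tau_bounds <- c(0.1, 300)
  A_hi <- 2 * max(y)
  resfn <- function(p) y - p[1] * exp(-n / p[2])
  best <- multi_start(resfn, lower = c(0, tau_bounds[1]),
                      upper = c(A_hi, tau_bounds[2]), control = control)
  tau <- best$par[2]
  structure(list(A = best$par[1], tau = tau, sse = best$objective,
                 flagged = tau >= tau_bounds[2] * 0.999, data = data),
            class = "washout_fit")
}

#' Fit models to every learning curve of a trial table
#'
#' Convenience wrapper: splits a trial table (as produced by
#' [generate_dataset()] or [read_trial_table()]) into learning curves
#' (subject x task x direction), keeps the no-vision rows of the learning
#' phase, and fits each requested structure to each curve.
#'
#' @param data A trial table.
#' @param structures Character vector of structure ids (default `"2.1"`).
#' @param control A [fit_control()] list.
#' @return A tibble with one row per curve x structure: curve identifiers,
#'   EA coordinate, `structure_id`, the `proxy_fit` object in a `fit` list
#'   column, and unnested `sigma`, `sse`, `rmse`, `r.squared`,
#'   `adj.r.squared`, `divergent` plus the curve's `e0`.
#' @export
fit_learning_curves <- function(data, structures = "2.1",
                                control = fit_control()) {
  curves <- data |>
    dplyr::filter(.data$phase == "learning") |>
    dplyr::group_by(.data$subject, .data$task, .data$direction,
                    .data$gain, .data$offset) |>
    tidyr::nest() |>
    dplyr::ungroup()
  n_trials <- max(purrr::map_int(curves$data, ~ max(.x$trial))) + 1L
  out <- tidyr::expand_grid(curves, structure_id = structures)
  fits <- purrr::pmap(list(out$data, out$structure_id), function(d, sid) {
    obs <- d[d$no_vision, c("trial", "error")]
    fit_proxy(obs, sid, e0 = d$e0[1], n_trials = n_trials - 1L,
              control = control)
  })
  out$fit <- fits
  out$e0 <- purrr::map_dbl(out$data, ~ .x$e0[1])
  out$sigma <- purrr::map_dbl(fits, "sigma")
  out$sse <- purrr::map_dbl(fits, "sse")
  out$rmse <- purrr::map_dbl(fits, "rmse")
  out$r.squared <- purrr::map_dbl(fits, "r.squared")
  out$adj.r.squared <- purrr::map_dbl(fits, "adj.r.squared")
  out$divergent <- purrr::map_lgl(fits, "divergent")
  dplyr::select(out, -"data")
}

#' Fit the multi-rate model to every learning curve
#'
#' Runs [fit_dpxmrml()] per curve, fixing each curve's embedded second-order
#' proxy coefficients at the matching `"2.1"` fit from `proxy_fits`.
#'
#' @param data A trial table.
#' @param proxy_fits Output of [fit_learning_curves()] restricted to (or
#'   containing) structure `"2.1"`.
#' @param control A [fit_control()] list.
#' @return A tibble with one row per curve: identifiers, EA coordinate, the
#'   `dpxmrml_fit` in a `fit` list column, and unnested `Af`, `As`, `Bf`,
#'   `Bs`, `rmse`.
#' @export
fit_dpxmrml_curves <- function(data, proxy_fits, control = fit_control()) {
  proxy_fits <- dplyr::filter(proxy_fits, .data$structure_id == "2.1")
  stopifnot(nrow(proxy_fits) > 0)
  curves <- data |>
    dplyr::filter(.data$phase == "learning") |>
    dplyr::group_by(.data$subject, .data$task, .data$direction,
                    .data$gain, .data$offset) |>
    tidyr::nest() |>
    dplyr::ungroup()
  curves <- dplyr::inner_join(
    curves, dplyr::select(proxy_fits, "subject", "task", "direction",
                          proxy_fit = "fit"),
    by = c("subject", "task", "direction"))
  fits <- purrr::pmap(list(curves$data, curves$proxy_fit), function(d, pf) {
    obs <- d[d$no_vision | d$trial == 0L, c("trial", "error")]
    obs$error[obs$trial == 0L] <- d$e0[1]
    obs <- dplyr::distinct(obs, .data$trial, .keep_all = TRUE)
    fit_dpxmrml(obs, proxy_params = c(pf$params, list(sigma = pf$sigma)),
                n_trials = max(d$trial) + 1L, control = control)
  })
  curves$fit <- fits
  curves$Af <- purrr::map_dbl(fits, ~ .x$params$Af)
  curves$As <- purrr::map_dbl(fits, ~ .x$params$As)
  curves$Bf <- purrr::map_dbl(fits, ~ .x$params$Bf)
  curves$Bs <- purrr::map_dbl(fits, ~ .x$params$Bs)
  curves$rmse <- purrr::map_dbl(fits, "rmse")
  dplyr::select(curves, -"data", -"proxy_fit")
}

#' Fit washout decays for every curve of a trial table
#'
#' @param data A trial table containing washout-phase rows.
#' @param per `"curve"` fits one decay per subject x task x direction
#'   (default); `"subject"` first averages magnitudes across a subject's
#'   curves at each washout trial, then fits one decay per subject x
#'   EA coordinate.
#' @param control A [fit_control()] list.
#' @return A tibble with identifiers, EA coordinate, the `washout_fit` in a
#'   `fit` list column, and unnested `A`, `tau`, `flagged`.
#' @export
fit_washout_curves <- function(data, per = c("curve", "subject"),
                               control = fit_control()) {
  per <- match.arg(per)
  w <- data |>
    dplyr::filter(.data$phase == "washout") |>
    dplyr::mutate(magnitude = abs(.data$error))
  grouped <- if (per == "curve") {
    dplyr::group_by(w, .data$subject, .data$task, .data$direction,
                    .data$gain, .data$offset)
  } else {
    w |>
      dplyr::group_by(.data$subject, .data$gain, .data$offset,
                      .data$trial) |>
      dplyr::summarise(magnitude = mean(.data$magnitude), .groups = "drop") |>
      dplyr::group_by(.data$subject, .data$gain, .data$offset)
  }
  out <- grouped |> tidyr::nest() |> dplyr::ungroup()
  out$fit <- purrr::map(out$data,
                        ~ fit_washout(.x[c("trial", "magnitude")], control))
  out$A <- purrr::map_dbl(out$fit, "A")
  out$tau <- purrr::map_dbl(out$fit, "tau")
  out$flagged <- purrr::map_lgl(out$fit, "flagged")
  dplyr::select(out, -"data")
}
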