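#' The proxy-process model family
#'
#' Trial-by-trial evolution of the signed reach error is modelled as an
#' autoregressive update \deqn{e_{n+1} = e_n + f(e_n, \dots, e_{n-k+1}) +
#' \sigma\,dz,} where \eqn{f} is one of eleven drift structures and \eqn{dz}
#' is a standard-normal deviate (Wiener-type inter-trial noise). The family
#' spans four first-order structures — linear (`"1.1L"`, \eqn{f = b e}),
#' affine (`"1.1"`, \eqn{f = a + b e}), quadratic (`"1.2"`,
#' \eqn{f = a + (b + c e) e}) and cubic (`"1.3"`,
#' \eqn{f = a + (b + c e + d e^2) e}) — and the kth-order structures
#' `"2.1"` … `"8.1"` with \eqn{f = a + b_1 e_n + \dots + b_k e_{n-k+1}}.
#'
#' @return A tibble with one row per structure: `structure_id`, `order`
#'   (history depth \eqn{k}), `n_free_params` (drift coefficients, excluding
#'   `sigma`) and `param_names` (list column of coefficient names in the
#'   canonical order used throughout the package).
#' @examples
#' proxy_models()
#' @export
proxy_models <- function() {
  first_order <- tibble::tibble(
    structure_id = c("1.1L", "1.1", "1.2", "1.3"),
    order = 1L,
    n_free_params = 1:4,
    param_names = list("b", c("a", "b"), c("a", "b", "c"),
                       c("a", "b", "c", "d"))
  )
  k <- 2:8
  higher <- tibble::tibble(
    structure_id = paste0(k, ".1"),
    order = as.integer(k),
    n_free_params = as.integer(k + 1L),
    param_names = lapply(k, function(ki) c("a", paste0("b", seq_len(ki))))
  )
  dplyr::bind_rows(first_order, higher)
}

# canonical structure lookup, with the C++ type code
model_spec <- function(structure_id) {
  reg <- proxy_models()
  i <- match(structure_id, reg$structure_id)
  if (is.na(i)) {
    stop("unknown model structure '", structure_id, "'; see proxy_models()",
         call. = FALSE)
  }
  type <- match(structure_id, c("1.1L", "1.1", "1.2", "1.3")) - 1L
  if (is.na(type)) type <- 4L
  list(structure_id = structure_id, order = reg$order[i],
       n_free_params = reg$n_free_params[i],
       param_names = reg$param_names[[i]], type = type)
}

# named params (list or vector) -> canonical coefficient vector for a spec
theta_from_params <- function(spec, params) {
  params <- as.list(params)
  th <- vapply(spec$param_names, function(nm) {
    v <- params[[nm]]
    if (is.null(v)) 0 else as.double(v)
  }, double(1))
  names(th) <- spec$param_names
  th
}

#' Drift of a proxy-process model
#'
#' Evaluates the deterministic per-trial rate of change in error \eqn{f} for
#' one model structure at a given error history.
#'
#' @param structure_id One of the eleven ids in [proxy_models()].
#' @param params Named list or vector of drift coefficients (`a`, `b` or
#'   `b1`…`bk`, `c`, `d` as used by the structure; missing ones default to 0).
#' @param history Numeric vector of signed errors, most recent last; must be
#'   at least as long as the structure's order.
#' @return The drift \eqn{f} (error units per trial).
#' @examples
#' proxy_drift("1.1L", list(b = -0.5), history = 2)  # -1
#' @export
proxy_drift <- function(structure_id, params, history) {
  spec <- model_spec(structure_id)
  history <- as.double(history)
  stopifnot(all(is.finite(history)))
  if (length(history) < spec$order) {
    stop("history of length ", length(history), " is shorter than the ",
         "structure order ", spec$order, call. = FALSE)
  }
  th <- theta_from_params(spec, params)
  n <- length(history)
  e <- history[n]
  switch(as.character(spec$type),
    "0" = th[["b"]] * e,
    "1" = th[["a"]] + th[["b"]] * e,
    "2" = th[["a"]] + (th[["b"]] + th[["c"]] * e) * e,
    "3" = th[["a"]] + (th[["b"]] + th[["c"]] * e + th[["d"]] * e^2) * e,
    "4" = th[["a"]] + sum(th[-1] * history[n - seq_len(spec$order) + 1])
  )
}

#' Single stochastic update of the proxy process
#'
#' Applies one step of \eqn{e_{n+1} = e_n + f + \sigma\,dz}.
#'
#' @inheritParams proxy_drift
#' @param sigma Inter-trial noise scale (error units, >= 0).
#' @param noise A standard-normal deviate (0 for the deterministic step).
#' @return The next signed error.
#' @examples
#' proxy_step("1.1", list(a = 0, b = -0.5), history = 2)  # 1
#' @export
proxy_step <- function(structure_id, params, history, sigma = 0, noise = 0) {
  stopifnot(sigma >= 0)
  e <- history[length(history)]
  e + proxy_drift(structure_id, params, history) + sigma * noise
}

#' Forward-simulate a proxy-process learning curve
#'
#' Iterates the proxy-process update from an initial error `e0` for
#' `n_trials` transitions. The history of kth-order structures is seeded by
#' repeating `e0` (trials before the first are treated as equal to it). When
#' `sigma > 0` and noise is requested, one standard-normal deviate scaled by
#' `sigma` is added per transition; with `noise = NULL` and no seed the
#' simulation is fully deterministic.
#'
#' @inheritParams proxy_drift
#' @param e0 Initial (first-exposure) signed error, finite.
#' @param n_trials Number of transitions to simulate (>= 1).
#' @param sigma Inter-trial noise scale (error units, >= 0).
#' @param noise Optional numeric vector of `n_trials` standard-normal
#'   deviates, or `NULL`.
#' @param seed Optional integer; when given (and `noise` is `NULL`) the
#'   deviates are drawn locally from this seed, leaving the global RNG
#'   untouched.
#' @return A tibble with columns `trial` (0-based, `0:n_trials`) and `error`;
#'   row 1 is `e0`.
#' @examples
#' simulate_proxy("1.1L", list(b = -0.5), e0 = 8, n_trials = 3)
#' @export
simulate_proxy <- function(structure_id, params, e0, n_trials,
                           sigma = 0, noise = NULL, seed = NULL) {
  spec <- model_spec(structure_id)
  stopifnot(is.numeric(e0), length(e0) == 1L, is.finite(e0),
            n_trials >= 1, sigma >= 0)
  th <- theta_from_params(spec, params)
  if (is.null(noise) && sigma > 0 && !is.null(seed)) {
    noise <- with_seed(seed, rnorm(n_trials))
  }
  if (is.null(noise) || sigma == 0) noise <- numeric(0)
  stopifnot(length(noise) %in% c(0L, n_trials))
  e <- .sim_proxy_cpp(spec$type, spec$order, unname(th), e0,
                      as.integer(n_trials), sigma, as.double(noise))
  tibble::tibble(trial = 0:n_trials, error = e)
}

#' Model-implied steady-state error
#'
#' Deterministically iterates a proxy-process model (noise off) from `e0` and
#' returns the signed error at trial `n` — by default trial 250, the end of a
#' learning phase. Negative values indicate overcompensation, positive values
#' undercompensation. Divergent dynamics are not clipped; the returned value
#' carries a `divergent` attribute flagging `|value| > 10 |e0|`.
#'
#' @inheritParams simulate_proxy
#' @param n Trial index at which the steady state is read (default 250).
#' @return A double with attribute `divergent` (logical).
#' @examples
#' steady_state_error("1.1", list(a = 0.5, b = -0.25), e0 = 8)  # -a/b = 2
#' @export
steady_state_error <- function(structure_id, params, e0, n = 250) {
  sim <- simulate_proxy(structure_id, params, e0, n_trials = n, sigma = 0)
  value <- sim$error[n + 1L]
  attr(value, "divergent") <- !is.finite(value) || abs(value) > 10 * abs(e0)
  value
}

#' One update of the multi-rate motor learning model
#'
#' The dynamic-proxy multi-rate model tracks a fast and a slow internal state:
#' \deqn{x^f_{n+1} = A_f x^f_n + B_f \hat e_n, \quad
#'       x^s_{n+1} = A_s x^s_n + B_s \hat e_n,} with prediction
#' \eqn{\hat y = x^f + x^s}. Retention rates satisfy \eqn{A_s > A_f} and
#' learning rates \eqn{B_f > B_s}.
#'
#' @param params Named list with `Af`, `As`, `Bf`, `Bs`.
#' @param state Named list or vector with current states `xf`, `xs`.
#' @param e_hat Driving error estimate for this trial.
#' @return A list with the updated `xf`, `xs` and the updated-state
#'   prediction `yhat = xf + xs`.
#' @examples
#' dpxmrml_step(list(Af = -0.5, As = 0.9, Bf = 0.4, Bs = 0.1),
#'              state = list(xf = 0, xs = 0), e_hat = 1)
#' @export
dpxmrml_step <- function(params, state, e_hat) {
  state <- as.list(state)
  stopifnot(is.finite(state$xf), is.finite(state$xs), is.finite(e_hat))
  xf <- params$Af * state$xf + params$Bf * e_hat
  xs <- params$As * state$xs + params$Bs * e_hat
  list(xf = xf, xs = xs, yhat = xf + xs)
}

#' Run the multi-rate model over a trial sequence with missing observations
#'
#' Iterates the dynamic-proxy multi-rate model across a block of trials.
#' On trials where an observed error is available the states are driven by it
#' (\eqn{\hat e_n = e_n}); on the remaining trials \eqn{\hat e_n} is
#' forward-predicted by the embedded second-order proxy process
#' \eqn{\hat e_n = \hat e_{n-1} + a + b_1 \hat e_{n-1} + b_2 \hat e_{n-2} +
#' \sigma dz} from the two most recent estimates. States start at
#' \eqn{x^f_0 = x^s_0 = 0}; the prediction for trial `n` is the state sum
#' before updating with that trial.
#'
#' @param params Named list with `Af`, `As`, `Bf`, `Bs`.
#' @param proxy_params Named list with the embedded `"2.1"` coefficients
#'   `a`, `b1`, `b2` and optionally `sigma`.
#' @param observed Numeric vector of observed signed errors, one slot per
#'   trial (values on unavailable trials are ignored).
#' @param available Logical mask, `TRUE` where `observed` holds a real
#'   observation. The first trial must be available (the proxy needs a seed).
#' @param noise Optional standard-normal deviates (one per trial) applied on
#'   unavailable trials; `NULL` for the deterministic run (`dz = 0`).
#' @param seed Optional integer used to draw `noise` locally.
#' @return A tibble with columns `trial` (0-based), `observed`, `available`,
#'   `e_hat`, `y_hat`, `xf`, `xs` (states before the trial's update).
#' @export
run_dpxmrml <- function(params, proxy_params, observed, available,
                        noise = NULL, seed = NULL) {
  N <- length(observed)
  stopifnot(length(available) == N, N >= 1)
  if (!available[1]) {
    stop("first trial has no available observation; the embedded proxy ",
         "process cannot be seeded", call. = FALSE)
  }
  sigma <- proxy_params$sigma %||% 0
  th <- c(proxy_params$a %||% 0, proxy_params$b1 %||% 0,
          proxy_params$b2 %||% 0)
  if (is.null(noise) && sigma > 0 && !is.null(seed)) {
    noise <- with_seed(seed, rnorm(N))
  }
  if (is.null(noise) || sigma == 0) noise <- numeric(0)
  out <- .run_dpxmrml_cpp(params$Af, params$As, params$Bf, params$Bs,
                          th, sigma, as.double(observed),
                          as.logical(available), as.double(noise))
  tibble::tibble(trial = 0:(N - 1L), observed = as.double(observed),
                 available = as.logical(available),
                 e_hat = out$ehat, y_hat = out$yhat,
                 xf = out$xf[seq_len(N)], xs = out$xs[seq_len(N)])
}
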