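# shared fixtures, built in code

# fast fitting settings for tests
quick_control <- function(n_starts = 10, seed = 4) {
  fit_control(n_starts = n_starts, seed = seed)
}

# a small complete design used by pipeline-level tests
tiny_design <- function() {
  experiment_design(n_subjects = 3, n_control = 1, n_tasks = 1,
                    n_trials = 60, n_novision = 18, n_washout = 12,
                    n_directions = 2)
}

# one noisy second-order learning curve observed on a catch-trial schedule
make_curve_21 <- function(truth = list(a = 0, b1 = 0.4, b2 = -0.45),
                          e0 = 4, n_trials = 250, n_novision = 74,
                          sigma = 0, seed = 1) {
  sim <- simulate_proxy("2.1", truth, e0 = e0, n_trials = n_trials - 1L,
                        sigma = sigma, seed = seed)
  mask <- make_schedule(n_trials, n_novision, seed = seed + 1)
  list(obs = data.frame(trial = which(mask) - 1L,
                        error = sim$error[which(mask)]),
       e0 = e0, mask = mask, full = sim$error, truth = truth)
}

# independent R-loop reference for the multi-rate recursion (oracle used to
# cross-check the compiled path)
dpxmrml_reference <- function(params, proxy, obs, avail) {
  N <- length(obs)
  xf <- 0; xs <- 0
  ehat <- numeric(N); yhat <- numeric(N)
  for (n in seq_len(N)) {
    yhat[n] <- xf + xs
    if (avail[n]) {
      ehat[n] <- obs[n]
    } else {
      e1 <- ehat[n - 1]
      e2 <- if (n >= 3) ehat[n - 2] else e1
      ehat[n] <- e1 + proxy$a + proxy$b1 * e1 + proxy$b2 * e2
    }
    xf_new <- params$Af * xf + params$Bf * ehat[n]
    xs_new <- params$As * xs + params$Bs * ehat[n]
    xf <- xf_new; xs <- xs_new
  }
  list(yhat = yhat, ehat = ehat)
}

# brute-force maximum perpendicular distance of samples to the segment line
max_perp_deviation <- function(traj) {
  x0 <- attr(traj, "x0"); y0 <- attr(traj, "y0")
  x1 <- attr(traj, "x1"); y1 <- attr(traj, "y1")
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  max(abs((traj$x - x0) * (y0 - y1) + (traj$y - y0) * (x1 - x0)) / len)
}
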