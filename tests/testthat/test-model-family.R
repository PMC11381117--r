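test_that("registry lists the eleven structures with correct orders and sizes", {
  reg <- proxy_models()
  expect_equal(nrow(reg), 11L)
  expect_equal(reg$structure_id,
               c("1.1L", "1.1", "1.2", "1.3", paste0(2:8, ".1")))
  r21 <- reg[reg$structure_id == "2.1", ]
  expect_equal(r21$order, 2L)
  expect_equal(r21$param_names[[1]], c("a", "b1", "b2"))
  expect_equal(reg$n_free_params[reg$structure_id == "1.1L"], 1L)
  expect_equal(reg$n_free_params[reg$structure_id == "8.1"], 9L)
  expect_equal(reg$order[1:4], rep(1L, 4))
})

test_that("drift matches direct substitution for each structure class", {
  expect_equal(proxy_drift("1.1L", list(b = -0.5), 2), -1.0)
  expect_equal(proxy_drift("1.1", list(a = 0.1, b = -0.5), 2), -0.9)
  expect_equal(proxy_drift("1.2", list(a = 0.1, b = -0.3, c = 0.05), 2), -0.3)
  expect_equal(proxy_drift("1.3", list(a = 0.1, b = -0.3, c = 0.05, d = 0.01),
                           2), -0.22)
  # kth-order uses the most recent k errors, most recent first coefficient
  expect_equal(proxy_drift("2.1", list(a = 1, b1 = 2, b2 = 3),
                           history = c(10, 5)), 1 + 2 * 5 + 3 * 10)
  expect_equal(proxy_drift("2.1", list(a = 0, b1 = 0, b2 = 0), c(4, 7)), 0)
  expect_error(proxy_drift("3.1", list(a = 0), history = c(1, 2)),
               "shorter than")
})

test_that("proxy step adds drift and scaled noise to the current error", {
  expect_equal(proxy_step("1.1L", list(b = -0.5), history = 2), 1.0)
  expect_equal(proxy_step("2.1", list(a = 0, b1 = 0, b2 = 0),
                          history = c(3, 3)), 3)
  expect_equal(proxy_step("1.1L", list(b = 0), history = 2, sigma = 0.1,
                          noise = 1.5), 2.15)
  # Monte-Carlo: mean of many stochastic steps approaches e + drift
  set.seed(11)
  draws <- replicate(2000, proxy_step("1.1", list(a = 0, b = -0.5), 2,
                                      sigma = 0.1, noise = rnorm(1)))
  expect_lt(abs(mean(draws) - 1), 3 * 0.1 / sqrt(2000))
})

test_that("deterministic simulation matches hand iteration and closed forms", {
  expect_equal(simulate_proxy("1.1L", list(b = -0.5), 8, 3)$error,
               c(8, 4, 2, 1))
  # affine recursion closed form: e_n = (e0 + a/b)(1+b)^n - a/b
  a <- 0.3; b <- -0.2; e0 <- 5
  sim <- simulate_proxy("1.1", list(a = a, b = b), e0, 50)
  closed <- (e0 + a / b) * (1 + b)^(0:50) - a / b
  expect_equal(sim$error, closed, tolerance = 1e-12)
  expect_equal(simulate_proxy("2.1", list(a = 0, b1 = 0, b2 = 0), 3, 10)$error,
               rep(3, 11))
  expect_error(simulate_proxy("1.1", list(a = 0, b = 0), Inf, 5))
})

test_that("linear structure follows geometric decay to 1e-12 relative error", {
  for (b in c(-0.9, -0.5, -0.1, -0.02)) {
    sim <- simulate_proxy("1.1L", list(b = b), e0 = 6, n_trials = 250)
    expect_equal(sim$error, 6 * (1 + b)^(0:250), tolerance = 1e-12)
  }
})

test_that("steady-state error reaches the fixed point of stable dynamics", {
  s1 <- steady_state_error("1.1", list(a = 0.5, b = -0.25), e0 = 8)
  expect_equal(as.double(s1), -0.5 / -0.25, tolerance = 1e-9)
  expect_false(attr(s1, "divergent"))
  # second-order fixed point: 0 = a + (b1 + b2) e*
  s2 <- steady_state_error("2.1", list(a = -0.3, b1 = 0.1, b2 = -0.25),
                           e0 = 1)
  expect_equal(as.double(s2), -(-0.3) / (0.1 - 0.25), tolerance = 1e-6)
  s0 <- steady_state_error("2.1", list(a = 0, b1 = 0, b2 = 0), e0 = 2.5)
  expect_equal(as.double(s0), 2.5)
  # divergent dynamics are flagged, not clipped
  sdiv <- steady_state_error("1.1L", list(b = 0.2), e0 = 1, n = 50)
  expect_true(attr(sdiv, "divergent"))
  expect_true(is.finite(as.double(sdiv)))
})

test_that("second-order steady state matches -a/(b1+b2) for stable roots", {
  cases <- list(c(a = -0.2, b1 = 0.1, b2 = -0.4),
                c(a = 0.1, b1 = 0.3, b2 = -0.5),
                c(a = -0.05, b1 = 0.4, b2 = -0.45))
  for (p in cases) {
    roots <- polyroot(c(-p[["b2"]], -(1 + p[["b1"]]), 1))
    expect_true(all(Mod(roots) < 1))  # guard: the case is genuinely stable
    ss <- steady_state_error("2.1", as.list(p), e0 = 3)
    expect_equal(as.double(ss), -p[["a"]] / (p[["b1"]] + p[["b2"]]),
                 tolerance = 1e-6)
  }
})

test_that("multi-rate step applies retention and learning rates", {
  p <- list(Af = -0.5, As = 0.9, Bf = 0.4, Bs = 0.1)
  s <- dpxmrml_step(p, list(xf = 0, xs = 0), e_hat = 1)
  expect_equal(s$xf, 0.4)
  expect_equal(s$xs, 0.1)
  expect_equal(s$yhat, 0.5)
  s0 <- dpxmrml_step(p, list(xf = 0, xs = 0), e_hat = 0)
  expect_equal(unlist(s0), c(xf = 0, xs = 0, yhat = 0))
  # learning off: pure state decay
  decay <- dpxmrml_step(list(Af = -0.5, As = 0.9, Bf = 0, Bs = 0),
                        list(xf = 2, xs = 3), e_hat = 7)
  expect_equal(decay$xf, -1)
  expect_equal(decay$xs, 2.7)
})

test_that("multi-rate run matches an independent trial-by-trial reference", {
  p <- list(Af = -0.5, As = 0.9, Bf = 0.4, Bs = 0.1)
  proxy <- list(a = 0.05, b1 = 0.2, b2 = -0.3, sigma = 0)
  obs <- c(4, 0, 3, 0, 2.2, 0, 1.5, 0)
  avail <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  run <- run_dpxmrml(p, proxy, obs, avail)
  ref <- dpxmrml_reference(p, proxy, obs, avail)
  expect_equal(run$y_hat, ref$yhat, tolerance = 1e-14)
  expect_equal(run$e_hat, ref$ehat, tolerance = 1e-14)
})

test_that("fully observed runs ignore the embedded proxy coefficients", {
  p <- list(Af = -0.3, As = 0.95, Bf = 0.35, Bs = 0.05)
  obs <- c(5, 4, 3.2, 2.8, 2.1, 1.7)
  avail <- rep(TRUE, 6)
  r1 <- run_dpxmrml(p, list(a = 0, b1 = 0, b2 = 0), obs, avail)
  r2 <- run_dpxmrml(p, list(a = 2, b1 = -1, b2 = 0.7), obs, avail)
  expect_identical(r1$y_hat, r2$y_hat)
  expect_equal(r1$e_hat, obs)
})

test_that("identity proxy holds its estimate constant across gaps", {
  p <- list(Af = 0, As = 0, Bf = 0, Bs = 0)
  obs <- c(3, 0, 0, 0, 1)
  avail <- c(TRUE, FALSE, FALSE, FALSE, TRUE)
  run <- run_dpxmrml(p, list(a = 0, b1 = 0, b2 = 0), obs, avail)
  expect_equal(run$e_hat, c(3, 3, 3, 3, 1))
})

test_that("a run starting on an unavailable trial is rejected", {
  expect_error(run_dpxmrml(list(Af = 0, As = 0.5, Bf = 1, Bs = 0),
                           list(a = 0, b1 = 0, b2 = 0),
                           observed = c(0, 1), available = c(FALSE, TRUE)),
               "seed")
})

test_that("seeded stochastic simulations are bit-reproducible", {
  s1 <- simulate_proxy("2.1", list(a = 0, b1 = 0.4, b2 = -0.45), 4, 100,
                       sigma = 0.1, seed = 99)
  s2 <- simulate_proxy("2.1", list(a = 0, b1 = 0.4, b2 = -0.45), 4, 100,
                       sigma = 0.1, seed = 99)
  expect_identical(s1$error, s2$error)
  p <- list(Af = -0.4, As = 0.92, Bf = 0.4, Bs = 0.06)
  proxy <- list(a = 0, b1 = 0.4, b2 = -0.45, sigma = 0.1)
  avail <- rep(c(TRUE, FALSE), 25)
  r1 <- run_dpxmrml(p, proxy, rnorm(50), avail, seed = 5)
  r2 <- run_dpxmrml(p, proxy, r1$observed, avail, seed = 5)
  expect_identical(r1$e_hat, r2$e_hat)
})
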