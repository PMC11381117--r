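test_that("noiseless curves are recovered to high precision", {
  cur <- make_curve_21(truth = list(a = -0.2, b1 = 0.1, b2 = -0.4), e0 = 5,
                       sigma = 0, seed = 3)
  f <- fit_proxy(cur$obs, "2.1", e0 = cur$e0, n_trials = 249,
                 control = quick_control(n_starts = 15))
  expect_lt(abs(f$params$a - (-0.2)), 1e-3)
  expect_lt(abs(f$params$b1 - 0.1), 1e-3)
  expect_lt(abs(f$params$b2 - (-0.4)), 1e-3)
  expect_lt(f$sse, 1e-10)

  sim <- simulate_proxy("1.1L", list(b = -0.5), e0 = 8, n_trials = 249)
  mask <- make_schedule(250, 74, seed = 7)
  obs <- data.frame(trial = which(mask) - 1L, error = sim$error[which(mask)])
  f1 <- fit_proxy(obs, "1.1L", e0 = 8, n_trials = 249,
                  control = quick_control())
  expect_lt(abs(f1$params$b - (-0.5)), 1e-4)
})

test_that("constant observations with zero-coefficient truth fit exactly", {
  obs <- data.frame(trial = c(0, 3, 7, 12, 20), error = rep(2.5, 5))
  f <- fit_proxy(obs, "2.1", e0 = 2.5, n_trials = 20,
                 control = quick_control(n_starts = 5))
  expect_lt(f$sse, 1e-12)
  expect_true(f$constant_data)
  expect_true(f$zero_variance)
})

test_that("fits fail informatively with too few observations", {
  obs <- data.frame(trial = c(0, 2), error = c(3, 2))
  expect_error(fit_proxy(obs, "2.1", e0 = 3), "at least")
})

test_that("fit is invariant to observation row order", {
  cur <- make_curve_21(sigma = 0.08, seed = 21)
  f1 <- fit_proxy(cur$obs, "2.1", e0 = cur$e0, n_trials = 249,
                  control = quick_control(n_starts = 6))
  shuffled <- cur$obs[sample.int(nrow(cur$obs)), ]
  f2 <- fit_proxy(shuffled, "2.1", e0 = cur$e0, n_trials = 249,
                  control = quick_control(n_starts = 6))
  expect_identical(unlist(f1$params), unlist(f2$params))
})

test_that("more starts never worsen the best objective", {
  cur <- make_curve_21(sigma = 0.1, seed = 31)
  sse <- vapply(c(2, 6, 12), function(ns) {
    fit_proxy(cur$obs, "3.1", e0 = cur$e0, n_trials = 249,
              control = quick_control(n_starts = ns, seed = 9))$sse
  }, double(1))
  expect_true(all(diff(sse) <= 1e-12))
})

test_that("sigma estimation divides the residual spread by the trial count", {
  expect_equal(estimate_sigma(rep(0, 10), 250), 0)
  r <- c(1, -1, 1, -1)
  expect_equal(estimate_sigma(r, 250), sd(r) / 250)
  expect_equal(estimate_sigma(2 * r, 250), 2 * estimate_sigma(r, 250))
  expect_equal(estimate_sigma(r, 250, divisor = "sqrt_n"),
               sd(r) / sqrt(250))
})

test_that("goodness of fit follows the standard definitions", {
  obs <- c(1, 2, 3, 4)
  g <- goodness_of_fit(obs, obs, 2)
  expect_equal(g$r.squared, 1)
  expect_equal(g$rmse, 0)
  g0 <- goodness_of_fit(obs, rep(mean(obs), 4), 2)
  expect_equal(g0$r.squared, 0)
  pred <- c(1.1, 1.8, 3.2, 4.1)
  g2 <- goodness_of_fit(obs, pred, 2)
  sse <- sum((obs - pred)^2)
  sst <- sum((obs - mean(obs))^2)
  expect_equal(g2$sse, sse)
  expect_equal(g2$r.squared, 1 - sse / sst)
  expect_equal(g2$adj.r.squared, 1 - (1 - g2$r.squared) * 3 / 1)
  expect_equal(g2$rmse, sqrt(sse / 4))
  expect_lte(g2$adj.r.squared, g2$r.squared)
  gz <- goodness_of_fit(rep(2, 4), pred, 1)
  expect_true(gz$zero_variance)
  expect_true(is.na(gz$r.squared))
})

test_that("multi-rate rates are recovered from noiseless intermittent data", {
  truth <- list(Af = -0.5, As = 0.95, Bf = 0.4, Bs = -0.05)
  proxy <- list(a = 0, b1 = 0.4, b2 = -0.45)
  mask <- make_schedule(250, 74, seed = 9)
  mask[1] <- TRUE
  ref <- local({
    # generate observations from the model itself on the availability mask
    obs <- numeric(250)
    xf <- 0; xs <- 0; e1 <- 0; e2 <- 0
    for (n in 1:250) {
      yh <- xf + xs
      if (n == 1) {
        obs[n] <- 4; eh <- 4
      } else if (mask[n]) {
        obs[n] <- yh; eh <- yh
      } else {
        ep2 <- if (n >= 3) e2 else e1
        eh <- e1 + proxy$a + proxy$b1 * e1 + proxy$b2 * ep2
      }
      xfn <- truth$Af * xf + truth$Bf * eh
      xsn <- truth$As * xs + truth$Bs * eh
      xf <- xfn; xs <- xsn; e2 <- e1; e1 <- eh
    }
    obs
  })
  obs <- data.frame(trial = which(mask) - 1L, error = ref[mask])
  f <- fit_dpxmrml(obs, proxy_params = proxy, n_trials = 250,
                   control = quick_control(n_starts = 30, seed = 5))
  for (nm in names(truth)) {
    expect_lt(abs(f$params[[nm]] - truth[[nm]]) / abs(truth[[nm]]), 0.05)
  }
  expect_gt(f$params$As, f$params$Af)
  expect_gt(f$params$Bf, f$params$Bs)
})

test_that("multi-rate constraints hold for every returned fit", {
  set.seed(14)
  for (r in 1:3) {
    cur <- make_curve_21(sigma = 0.15, seed = 40 + r)
    obs <- cur$obs
    if (obs$trial[1] != 0) obs <- rbind(data.frame(trial = 0, error = cur$e0),
                                        obs)
    f <- fit_dpxmrml(obs, proxy_params = cur$truth, n_trials = 250,
                     control = quick_control(n_starts = 6, seed = r))
    expect_gt(f$params$As, f$params$Af)
    expect_gt(f$params$Bf, f$params$Bs)
  }
})

test_that("zero observations yield near-zero learning rates", {
  obs <- data.frame(trial = c(0, 2, 4, 7, 9, 12, 15, 19), error = rep(0, 8))
  f <- fit_dpxmrml(obs, proxy_params = list(a = 0, b1 = 0, b2 = 0),
                   n_trials = 20, control = quick_control(n_starts = 4))
  expect_lt(f$sse, 1e-12)
})

test_that("washout exponentials are recovered and scale correctly", {
  w <- data.frame(trial = 0:29, magnitude = 6 * exp(-(0:29) / 5))
  f <- fit_washout(w, control = quick_control(n_starts = 8))
  expect_equal(f$tau, 5, tolerance = 1e-6)
  expect_equal(f$A, 6, tolerance = 1e-6)
  expect_false(f$flagged)
  w2 <- w; w2$magnitude <- 2 * w2$magnitude
  f2 <- fit_washout(w2, control = quick_control(n_starts = 8))
  expect_equal(f2$A, 12, tolerance = 1e-5)
  expect_equal(f2$tau, 5, tolerance = 1e-5)
  z <- data.frame(trial = 0:9, magnitude = rep(0, 10))
  fz <- fit_washout(z)
  expect_equal(fz$A, 0)
  expect_true(fz$flagged)
  grow <- data.frame(trial = 0:9, magnitude = seq(1, 4, length.out = 10))
  fg <- fit_washout(grow, control = quick_control(n_starts = 8))
  expect_true(fg$flagged)
})

test_that("curve-level wrappers attach fits to every curve", {
  d <- generate_dataset(tiny_design(), seed = 8)
  fits <- fit_learning_curves(d, structures = c("1.1L", "2.1"),
                              control = quick_control(n_starts = 4))
  expect_equal(nrow(fits), 3 * 1 * 2 * 2)  # subjects x tasks x dirs x models
  expect_s3_class(fits$fit[[1]], "proxy_fit")
  expect_true(all(is.finite(fits$rmse)))
  dfits <- fit_dpxmrml_curves(d, fits, control = quick_control(n_starts = 4))
  expect_equal(nrow(dfits), 6)
  expect_true(all(dfits$As > dfits$Af))
  expect_true(all(dfits$Bf > dfits$Bs))
  wfits <- fit_washout_curves(d, control = quick_control(n_starts = 4))
  expect_equal(nrow(wfits), 6)
  expect_true(all(wfits$tau[!wfits$flagged] > 0))
})

test_that("tidy and glance summarise fitted objects", {
  cur <- make_curve_21(sigma = 0, seed = 2)
  f <- fit_proxy(cur$obs, "2.1", e0 = cur$e0, n_trials = 249,
                 control = quick_control(n_starts = 4))
  td <- tidy(f)
  expect_equal(td$term, c("a", "b1", "b2", "sigma"))
  gl <- glance(f)
  expect_equal(gl$structure_id, "2.1")
  expect_gte(gl$r.squared, gl$adj.r.squared)
  w <- fit_washout(data.frame(trial = 0:9, magnitude = 3 * exp(-(0:9) / 4)),
                   control = quick_control(n_starts = 4))
  expect_equal(tidy(w)$term, c("A", "tau"))
})
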