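test_that("bootstrap median CIs behave on degenerate and simple samples", {
  c1 <- boot_median_ci(rep(4.2, 6), B = 500, seed = 1)
  expect_equal(c1$median, 4.2)
  expect_equal(c1$ci_lo, 4.2)
  expect_equal(c1$ci_hi, 4.2)
  c2 <- boot_median_ci(1:9, B = 5000, seed = 2)
  expect_lt(abs(c2$median - 5), 1)
  expect_gte(c2$ci_lo, 1)
  expect_lte(c2$ci_hi, 9)
  expect_true(c2$ci_lo <= c2$median && c2$median <= c2$ci_hi)
  # one dominant weight pins the median to its value
  c3 <- boot_median_ci(c(1, 2, 100), weights = c(1e-9, 1e-9, 1), B = 500,
                       seed = 3)
  expect_equal(c3$median, 100)
})

test_that("bootstrap median CI width shrinks with sample size", {
  set.seed(6)
  widths <- vapply(c(10, 40, 160), function(n) {
    mean(replicate(8, {
      ci <- boot_median_ci(rnorm(n), B = 400, seed = sample.int(1e6, 1))
      ci$ci_hi - ci$ci_lo
    }))
  }, double(1))
  expect_true(all(diff(widths) < 0))
})

test_that("the sign test rejects one-sided samples and spares symmetric ones", {
  st <- sign_test(rep(0.5, 20) + (1:20) / 100, null_value = 0, B = 500,
                  seed = 1)
  expect_lt(st$p.value, 0.05)
  expect_true(st$decision)
  expect_equal(st$direction, 1)
  sym <- sign_test(c(-(1:10), 1:10), null_value = 0, B = 2000, seed = 2)
  expect_gt(sym$p.value, 0.05)
  one <- sign_test(3.2, null_value = 0, B = 200, seed = 3)
  expect_gte(one$p.value, 0.05)
  allnull <- sign_test(rep(1, 5), null_value = 1, B = 200, seed = 4)
  expect_equal(allnull$p.value, 1)
})

test_that("the sign test against one detects inflated ratio parameters", {
  st <- sign_test(runif(15, 1.2, 1.8), null_value = 1, B = 500, seed = 9)
  expect_true(st$decision)
  expect_equal(st$direction, 1)
})

test_that("the rank-sum test separates disjoint groups, is symmetric in them", {
  a <- seq(0, 1, length.out = 20)
  b <- seq(5, 6, length.out = 20)
  r1 <- ranksum_test(a, b, B = 500, seed = 1)
  expect_lt(r1$p.value, 0.01)
  r2 <- ranksum_test(b, a, B = 500, seed = 1)
  expect_equal(r1$p.value, r2$p.value, tolerance = 1e-12)
  same <- ranksum_test(a, a, B = 500, seed = 2)
  expect_gt(same$p.value, 0.05)
  # Bonferroni correction caps at 1 and never lowers p
  r3 <- ranksum_test(a, b + 0.2, n_comparisons = 11, B = 500, seed = 3)
  expect_gte(r3$p.adjusted, r3$p.value)
  expect_lte(r3$p.adjusted, 1)
})

test_that("bootstrap tests are bit-reproducible at a fixed seed", {
  x <- c(0.3, -0.2, 0.8, 1.1, -0.5, 0.4)
  y <- c(0.1, 0.7, -0.3, 0.9)
  expect_identical(sign_test(x, B = 300, seed = 11),
                   sign_test(x, B = 300, seed = 11))
  expect_identical(ranksum_test(x, y, B = 300, seed = 12),
                   ranksum_test(x, y, B = 300, seed = 12))
  expect_identical(boot_median_ci(x, B = 300, seed = 13),
                   boot_median_ci(x, B = 300, seed = 13))
})

test_that("parameter tables test each coordinate and compare to control", {
  set.seed(21)
  coords <- dplyr::bind_rows(
    tibble::tibble(gain = 1L, offset = 0L, b2 = rnorm(12, -0.4, 0.05)),
    tibble::tibble(gain = 2L, offset = 0L, b2 = rnorm(12, -0.4, 0.05)),
    tibble::tibble(gain = 0L, offset = 1L, b2 = rnorm(12, -0.1, 0.05)))
  coords$rmse <- runif(nrow(coords), 0.05, 0.2)
  tab <- parameter_table(coords, "b2", null_value = 0, B = 500, seed = 5)
  expect_equal(nrow(tab), 3L)
  expect_true(all(tab$sign_decision))          # all b2 medians negative
  expect_true(all(tab$direction == -1))
  ctrl_row <- tab[tab$gain == 1 & tab$offset == 0, ]
  expect_true(is.na(ctrl_row$p.control))
  same <- tab[tab$gain == 2, ]
  expect_false(same$vs_control)                # same distribution as control
  diff <- tab[tab$gain == 0, ]
  expect_true(diff$vs_control)                 # clearly separated from control
})

test_that("steady-state tables flag the fixed-point sign and drop divergence", {
  # fits with known fixed point: e* = -a/(b1+b2) = -(-0.3)/(-0.15) = -2 < 0
  cur <- make_curve_21(truth = list(a = -0.3, b1 = 0.1, b2 = -0.25), e0 = 3,
                       sigma = 0.01, seed = 2)
  f <- fit_proxy(cur$obs, "2.1", e0 = cur$e0, n_trials = 249,
                 control = quick_control(n_starts = 8))
  fits <- tibble::tibble(
    subject = 1:6, task = 1L, direction = 1L, gain = 1L, offset = 0L,
    structure_id = "2.1", fit = rep(list(f), 6), e0 = 3,
    rmse = rep(f$rmse, 6))
  tab <- steady_state_table(fits, B = 400, seed = 3)
  expect_true(tab$sign_decision)
  expect_equal(tab$direction, -1)
  expect_equal(attr(tab, "excluded"), 0L)
  # a divergent fit is excluded, not propagated
  fdiv <- f
  fdiv$params <- list(a = 0, b1 = 0.6, b2 = 0.6)
  fits2 <- fits
  fits2$fit[[1]] <- fdiv
  tab2 <- steady_state_table(fits2, B = 400, seed = 3)
  expect_equal(attr(tab2, "excluded"), 1L)
})

test_that("steady-state sign flips with the constant drift term", {
  pos <- steady_state_error("2.1", list(a = -0.3, b1 = 0.1, b2 = -0.25), 1)
  neg <- steady_state_error("2.1", list(a = 0.3, b1 = 0.1, b2 = -0.25), 1)
  expect_equal(as.double(pos), -as.double(neg), tolerance = 1e-9)
})

test_that("washout tables order time constants as the ground truth", {
  set.seed(31)
  wf <- dplyr::bind_rows(
    tibble::tibble(gain = 1L, offset = 0L, tau = rlnorm(8, log(4), 0.15)),
    tibble::tibble(gain = 3L, offset = 0L, tau = rlnorm(8, log(20), 0.15)),
    tibble::tibble(gain = 2L, offset = 0L, tau = rlnorm(8, log(4), 0.15)))
  wf$flagged <- FALSE
  tab <- washout_table(wf, B = 500, seed = 7)
  expect_equal(nrow(tab), 3L)
  med <- tab$median[order(tab$gain)]
  expect_gt(tab$median[tab$gain == 3], tab$median[tab$gain == 1])
  expect_true(tab$vs_control[tab$gain == 3])
  expect_false(tab$vs_control[tab$gain == 2])
})

test_that("type-I error of the bootstrap tests is near nominal", {
  # simulated nulls; alpha = 0.05
  set.seed(41)
  n_rep <- 120
  rej_sign <- mean(replicate(n_rep, {
    sign_test(rnorm(20), B = 400, seed = sample.int(1e6, 1))$decision
  }))
  rej_rs <- mean(replicate(n_rep, {
    ranksum_test(rnorm(15), rnorm(15), B = 400,
                 seed = sample.int(1e6, 1))$decision
  }))
  expect_gte(rej_sign, 0.05 / 4)
  expect_lte(rej_sign, 0.05 * 3)
  expect_gte(rej_rs, 0.05 / 4)
  expect_lte(rej_rs, 0.05 * 3)
})
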