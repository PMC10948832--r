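test_that("Wald ratio follows the delta-method closed form", {
  hp <- make_hp(beta_exp = 0.10, beta_out = 0.05,
                se_exp = 0.02, se_out = 0.01)
  est <- wald_ratio(hp)
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, 0.1)
  # null numerator gives the null ratio
  est0 <- wald_ratio(make_hp(0.10, 0, se_out = 0.01))
  expect_equal(est0$beta, 0)
  expect_equal(est0$or_point, 1)
  expect_error(wald_ratio(make_hp(0, 0.05)), "zero")
  # random instrument vs symbolic oracle
  set.seed(2)
  g <- rnorm(1, 0.2, 0.05); G <- rnorm(1, 0.1, 0.02); so <- runif(1, 0.01, 0.05)
  est2 <- wald_ratio(harmonized_pair(g, 0.01, G, so))
  expect_equal(est2$beta, G / g)
  expect_equal(est2$se, so / abs(g))
})

test_that("IVW equals the origin-constrained WLS oracle", {
  g <- c(0.1, 0.2, 0.3); G <- c(0.06, 0.10, 0.18); so <- rep(0.01, 3)
  hp <- harmonized_pair(g, rep(0.01, 3), G, so)
  est <- mr_ivw(hp, "fixed")
  oracle <- lm_wls_oracle(matrix(g, ncol = 1), G, 1 / so^2)
  expect_equal(est$beta, oracle$beta, tolerance = 1e-10)
  expect_equal(est$se, oracle$se_unscaled, tolerance = 1e-10)
  # multiplicative random effects inflates by max(1, sqrt(Q/(J-1)))
  est_re <- mr_ivw(hp)
  expect_equal(est_re$se,
               oracle$se_unscaled * max(1, sqrt(est$q / est$q_df)),
               tolerance = 1e-10)
})

test_that("homogeneous ratios give the common ratio and zero Q", {
  g <- c(0.1, 0.2, 0.4); hp <- harmonized_pair(g, rep(0.01, 3), 0.5 * g,
                                               rep(0.01, 3))
  est <- mr_ivw(hp)
  expect_equal(est$beta, 0.5)
  expect_equal(est$q, 0)
  expect_equal(est$q_p, 1)
  # single instrument falls back to the Wald ratio
  expect_message(est1 <- mr_ivw(subset_pair(hp, 1)), "Wald")
  expect_equal(est1$beta, wald_ratio(subset_pair(hp, 1))$beta)
})

test_that("rescaling the exposure rescales beta and preserves the z-score", {
  set.seed(8)
  hp <- draw_hp(25, theta = 0.4)
  est <- mr_ivw(hp)
  c0 <- 3.7
  hp2 <- hp
  hp2$beta_exp <- c0 * hp$beta_exp
  hp2$se_exp <- c0 * hp$se_exp
  est2 <- mr_ivw(hp2)
  expect_equal(est2$beta, est$beta / c0, tolerance = 1e-12)
  expect_equal(est2$beta / est2$se, est$beta / est$se, tolerance = 1e-12)
})

test_that("Egger regression matches the weighted-intercept oracle", {
  # exact fit: slope and intercept recovered, residual Q zero
  g <- c(0.1, 0.2, 0.3, 0.5)
  hp <- harmonized_pair(g, rep(0.01, 4), 0.02 + 0.5 * g, rep(0.01, 4))
  est <- mr_egger(hp)
  expect_equal(est$beta, 0.5, tolerance = 1e-12)
  expect_equal(est$egger_intercept, 0.02, tolerance = 1e-12)
  expect_equal(est$q, 0, tolerance = 1e-16)
  # noisy fixture vs lm oracle (orientation: all gamma already positive)
  set.seed(17)
  hp2 <- draw_hp(30, theta = 0.3, alpha = rnorm(30, 0, 0.02))
  hp2$beta_exp <- abs(hp2$beta_exp)
  est2 <- mr_egger(hp2)
  orc <- lm_wls_oracle(matrix(hp2$beta_exp, ncol = 1), hp2$beta_out,
                       1 / hp2$se_out^2, intercept = TRUE)
  infl <- max(1, orc$sigma)
  expect_equal(est2$egger_intercept, orc$beta[1], tolerance = 1e-10)
  expect_equal(est2$beta, orc$beta[2], tolerance = 1e-10)
  expect_equal(est2$egger_intercept_se, orc$se_unscaled[1] * infl,
               tolerance = 1e-10)
  expect_equal(est2$se, orc$se_unscaled[2] * infl, tolerance = 1e-10)
  expect_error(mr_egger(subset_pair(hp2, 1:2)), "at least 3")
})

test_that("Egger slope equals IVW when the fitted intercept is zero", {
  set.seed(19)
  hp <- draw_hp(20, theta = 0.4)
  hp$beta_exp <- abs(hp$beta_exp)   # uniform orientation
  a_hat <- mr_egger(hp)$egger_intercept
  hp0 <- hp
  hp0$beta_out <- hp$beta_out - a_hat   # shifts fitted intercept to 0
  est_e <- mr_egger(hp0)
  expect_equal(est_e$egger_intercept, 0, tolerance = 1e-12)
  expect_equal(est_e$beta, mr_ivw(hp0, "fixed")$beta, tolerance = 1e-10)
})

test_that("weighted median interpolates the weighted CDF at one half", {
  # equal weights, symmetric ratios
  hp <- harmonized_pair(c(1, 1, 1), rep(0.01, 3), c(0.1, 0.5, 0.9),
                        rep(0.01, 3))
  expect_equal(mr_weighted_median(hp, n_boot = 0)$beta, 0.5)
  # hand-computed CDF interpolation: weights .49/.02/.49 on ratios 0/1/2
  # cumulative midpoints are .245/.50/.755, so the 0.5 quantile sits at 1
  g <- c(1, 1, 1)
  w_target <- c(0.49, 0.02, 0.49)
  so <- sqrt(g^2 / w_target)
  hp2 <- harmonized_pair(g, rep(0.01, 3), c(0, 1, 2) * g, so)
  expect_equal(mr_weighted_median(hp2, n_boot = 0)$beta, 1)
  # equal weights at odd J equal the plain median of ratios
  set.seed(21)
  g3 <- rep(1, 9); r <- rnorm(9)
  hp3 <- harmonized_pair(g3, rep(0.01, 9), r, rep(1, 9))
  expect_equal(mr_weighted_median(hp3, n_boot = 0)$beta, median(r))
  # bootstrap SE is reproducible under a fixed seed
  hp4 <- draw_hp(15, theta = 0.2)
  e1 <- mr_weighted_median(hp4, n_boot = 200, seed = 9)
  e2 <- mr_weighted_median(hp4, n_boot = 200, seed = 9)
  expect_identical(e1$se, e2$se)
  expect_gt(e1$se, 0)
})

test_that("Cochran's Q matches its two-term hand expansion", {
  hp <- make_hp(beta_exp = c(0.1, 0.2), beta_out = c(0.07, 0.09),
                se_out = c(0.01, 0.02))
  beta <- 0.5
  q <- cochran_q(hp, beta)
  hand <- (0.07 - 0.5 * 0.1)^2 / 0.01^2 + (0.09 - 0.5 * 0.2)^2 / 0.02^2
  expect_equal(q$q, hand)
  expect_equal(q$q_df, 1L)
  # exact proportionality gives zero
  hp0 <- make_hp(beta_exp = c(0.1, 0.2), beta_out = c(0.05, 0.10))
  expect_equal(cochran_q(hp0, 0.5)$q, 0)
})

test_that("null Q follows its chi-square reference distribution", {
  set.seed(13)
  J <- 15; reps <- 500
  qs <- replicate(reps, {
    hp <- draw_hp(J, theta = 0.3)
    cochran_q(hp, mr_ivw(hp, "fixed")$beta)$q
  })
  ks <- suppressWarnings(ks.test(qs, "pchisq", df = J - 1))
  expect_lt(unname(ks$statistic), 0.08)
})

test_that("leave-one-out isolates influential instruments", {
  # homogeneous case: every omission gives the same estimate
  g <- seq(0.1, 0.5, 0.1)
  hp <- harmonized_pair(g, rep(0.01, 5), 0.5 * g, rep(0.01, 5))
  loo <- mr_leave_one_out(hp)
  expect_length(loo, 5L)
  expect_equal(vapply(loo, `[[`, numeric(1), "beta"),
               setNames(rep(0.5, 5), names(loo)), tolerance = 1e-12)
  # definition at J=3: each estimate equals IVW on the 2-variant subset
  hp3 <- subset_pair(draw_hp(3, theta = 0.2), 1:3)
  loo3 <- mr_leave_one_out(hp3)
  for (j in 1:3) {
    expect_equal(loo3[[j]]$beta,
                 mr_ivw(subset_pair(hp3, setdiff(1:3, j)))$beta)
  }
  # planted outlier: omitting it moves the estimate closest to truth
  set.seed(23)
  J <- 12
  gamma <- runif(J, 0.1, 0.3)
  Gamma <- 0.5 * gamma
  Gamma[4] <- Gamma[4] + 0.2
  hpo <- harmonized_pair(gamma, rep(0.01, J), Gamma, rep(0.01, J))
  loo_o <- mr_leave_one_out(hpo)
  errs <- abs(vapply(loo_o, `[[`, numeric(1), "beta") - 0.5)
  expect_equal(which.min(errs), 4L, ignore_attr = TRUE)
})

test_that("odds-ratio formatting exponentiates and rounds half-even", {
  hp <- make_hp(beta_exp = c(0.1, 0.2), beta_out = c(0, 0))
  est <- mr_ivw(hp)
  trip <- estimate_to_or(est)
  expect_equal(unname(trip["or"]), 1)
  est2 <- wald_ratio(make_hp(0.1, 0.05, se_out = 0.01))
  trip2 <- estimate_to_or(est2, decimals = 4)
  expect_equal(unname(trip2["or"]), round(exp(est2$beta), 4))
  # Wald CIs are log-symmetric: OR is the geometric mean of its bounds
  expect_equal(unname(trip2["or"]),
               round(sqrt(exp(est2$ci_low) * exp(est2$ci_high)), 4))
})
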