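test_that("posterior probabilities normalize and summation identities hold", {
  set.seed(41)
  ms <- draw_ms(50, theta = c(0.4, 0, 0.1, 0), corr = 0.3)
  res <- mr_bma(ms, prior_inclusion = 0.1)
  expect_equal(sum(res$models$pp), 1, tolerance = 1e-10)
  expect_true(all(res$mip >= 0 & res$mip <= 1))
  # MIP[k] = sum of PP over models containing k; MACE likewise
  K <- 4
  mip_chk <- numeric(K); mace_chk <- numeric(K)
  for (m in seq_along(res$subsets)) {
    S <- res$subsets[[m]]
    mip_chk[S] <- mip_chk[S] + res$models$pp[m]
    mace_chk[S] <- mace_chk[S] + res$models$pp[m] * res$model_effects[[m]]
  }
  expect_equal(unname(res$mip), mip_chk, tolerance = 1e-10)
  expect_equal(unname(res$mace), mace_chk, tolerance = 1e-10)
})

test_that("a single strong exposure takes essentially all posterior mass", {
  set.seed(43)
  ms <- draw_ms(20, theta = 0.5)
  res <- mr_bma(ms)
  # K = 1 enumerates the empty and the single-exposure model
  expect_equal(nrow(res$models), 2L)
  expect_equal(sum(res$models$pp), 1, tolerance = 1e-10)
  expect_gt(unname(res$mip), 0.95)
  expect_equal(res$models$model[res$models$pp > 0.5], ms$exposure_names)
})

test_that("conditional effects converge to least squares as g grows", {
  set.seed(47)
  ms <- draw_ms(40, theta = c(0.4, -0.2))
  res <- mr_bma(ms, g = 1e8)
  # the full model's conditional effects vs the standardized WLS oracle
  full <- which(res$models$size == 2)
  y <- ms$beta_out / ms$se_out
  X <- ms$beta_exp / ms$se_out
  ols <- drop(solve(crossprod(X), crossprod(X, y)))
  expect_equal(unname(res$model_effects[[full]]), unname(ols),
               tolerance = 1e-4)
})

test_that("strengthening the causal signal never lowers its inclusion
           probability", {
  set.seed(53)
  J <- 40
  G <- matrix(rnorm(J * 2, 0, 0.1), J, 2)
  se_out <- rep(0.05, J)
  noise <- rnorm(J, 0, 0.05)
  mips <- vapply(c(0.1, 0.25, 0.5, 1), function(scale) {
    y <- scale * G[, 1] * 0.5 + noise
    ms <- multi_exposure_set(G, matrix(0.01, J, 2), y, se_out)
    unname(mr_bma(ms)$mip[1])
  }, numeric(1))
  expect_true(all(diff(mips) >= -1e-12))
})

test_that("duplicated exposure columns are scored as impossible models", {
  set.seed(59)
  g <- rnorm(20, 0, 0.1)
  ms <- multi_exposure_set(cbind(g, g), matrix(0.01, 20, 2),
                           0.4 * g + rnorm(20, 0, 0.02), rep(0.05, 20))
  expect_warning(res <- mr_bma(ms), "singular")
  both <- which(res$models$size == 2)
  expect_equal(res$models$pp[both], 0)
  expect_equal(sum(res$models$pp), 1, tolerance = 1e-10)
})

test_that("inclusion probabilities calibrate under the prior predictive", {
  # when causal status and effects are drawn from the model's own prior,
  # the posterior inclusion probability must average to the prior
  set.seed(43)
  K <- 4; J <- 60; q <- 0.1; reps <- 400
  mips <- replicate(reps, {
    X <- matrix(rnorm(J * K), J, K)
    S <- which(runif(K) < q)
    y <- rnorm(J)
    if (length(S) > 0) {
      Xs <- X[, S, drop = FALSE]
      z <- rnorm(length(S))
      y <- y + drop(Xs %*% (sqrt(J) * backsolve(chol(crossprod(Xs)), z)))
    }
    ms <- multi_exposure_set(X, matrix(1, J, K), y, rep(1, J))
    mr_bma(ms, prior_inclusion = q, g = J)$mip
  })
  per_rep <- colMeans(matrix(mips, K))
  mc_se <- sd(per_rep) / sqrt(reps)
  expect_lt(abs(mean(per_rep) - q), 2 * mc_se)
})

test_that("influence diagnostics flag a planted high-leverage instrument", {
  set.seed(47)
  J <- 30
  g <- runif(J, 0.05, 0.2)
  y <- 0.5 * g + rnorm(J, 0, 0.01)
  # one instrument with huge exposure effect and discordant outcome effect
  g[11] <- 1.5; y[11] <- -0.4
  ms <- multi_exposure_set(matrix(g), matrix(0.01, J, 1), y, rep(0.02, J))
  res <- mr_bma(ms)
  diag1 <- bma_diagnostics(ms, res, pp_threshold = 0.0)
  expect_true("snp11" %in% diag1$flagged_snps)
  # exact fit: nothing flagged, all Cook distances zero
  ms0 <- multi_exposure_set(matrix(g), matrix(0.01, J, 1), 0.5 * g,
                            rep(0.02, J))
  res0 <- mr_bma(ms0)
  d0 <- bma_diagnostics(ms0, res0, pp_threshold = 0.0)
  expect_length(d0$flagged_snps, 0)
  expect_true(all(d0$table$cook_distance < 1e-16))
  # vacuous threshold: no model reaches PP 1 in a split posterior
  ms2 <- draw_ms(30, theta = c(0.3, 0))
  res2 <- mr_bma(ms2)
  expect_lt(max(res2$models$pp), 1)
  dv <- bma_diagnostics(ms2, res2, pp_threshold = 1.0)
  expect_equal(nrow(dv$table), 0L)
})

test_that("re-running without flagged instruments behaves like a subset", {
  set.seed(53)
  ms <- draw_ms(60, theta = c(0.5, 0))
  res <- mr_bma(ms)
  same <- bma_rerun_without(ms, character(0))
  expect_equal(same$result$mip, res$mip, tolerance = 1e-12)
  # removing a handful of ordinary instruments barely moves the MACE
  drop_ids <- ms$snp_ids[c(2, 9, 17)]
  sub <- bma_rerun_without(ms, drop_ids)
  expect_lt(max(abs(sub$result$mace - res$mace)), 0.1)
  expect_equal(sub$result$ranking[1], res$ranking[1])
  expect_error(bma_rerun_without(ms, ms$snp_ids[1:59]), "under-identified")
})

test_that("joint clumping pools exposures by their minimum p-value", {
  e1 <- make_ds(n = 2, snp = c("rs1", "rs2"), pval = c(1e-10, 1e-9))
  e2 <- make_ds(n = 2, snp = c("rs3", "rs4"), pval = c(1e-12, 1e-8),
                pos = c(5000L, 6000L))
  ld0 <- ld_matrix(diag(4), paste0("rs", 1:4))
  # disjoint independent sets: union preserved
  expect_setequal(joint_clump_for_bma(list(e1, e2), ld0),
                  paste0("rs", 1:4))
  # duplicated variant across exposures appears once
  e3 <- make_ds(n = 2, snp = c("rs1", "rs5"), pval = c(1e-6, 1e-7))
  got <- joint_clump_for_bma(list(e1, e3), ld_matrix(diag(3),
                                                     c("rs1", "rs2", "rs5")))
  expect_equal(sum(got == "rs1"), 1L)
  # correlated pair from different exposures: smaller min-p wins
  ld2 <- ld_matrix(matrix(c(1, 0.6, 0.6, 1), 2), c("rs1", "rs3"))
  e4 <- make_ds(n = 1, snp = "rs1", pval = 1e-9)
  e5 <- make_ds(n = 1, snp = "rs3", pval = 1e-12, pos = 1500L)
  got2 <- joint_clump_for_bma(list(e4, e5), ld2, r2_threshold = 0.1)
  expect_equal(got2, "rs3")
})
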