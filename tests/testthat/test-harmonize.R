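make_pair_ds <- function(exp_alleles, out_alleles, beta_out = -0.05,
                         eaf_exp = 0.2, eaf_out = 0.2) {
  exposure <- summary_dataset(data.frame(
    snp = "rs1", chr = "1", pos = 100L,
    effect_allele = exp_alleles[1], other_allele = exp_alleles[2],
    eaf = eaf_exp, beta = 0.10, se = 0.01, pval = 2 * pnorm(-10),
    stringsAsFactors = FALSE), trait_name = "exp")
  outcome <- summary_dataset(data.frame(
    snp = "rs1", chr = "1", pos = 100L,
    effect_allele = out_alleles[1], other_allele = out_alleles[2],
    eaf = eaf_out, beta = beta_out, se = 0.01,
    pval = 2 * pnorm(-abs(beta_out / 0.01)),
    stringsAsFactors = FALSE), trait_name = "out")
  list(exposure = exposure, outcome = outcome)
}

test_that("swapped alleles flip the outcome effect sign", {
  d <- make_pair_ds(c("A", "G"), c("G", "A"), beta_out = -0.05,
                    eaf_out = 0.8)
  hp <- harmonize_pair(d$exposure, d$outcome)
  expect_equal(hp$actions$action, "flipped")
  expect_equal(hp$beta_out, 0.05)
})

test_that("palindromic variants are dropped when frequency is uninformative", {
  d <- make_pair_ds(c("A", "T"), c("A", "T"), eaf_exp = 0.5, eaf_out = 0.5)
  expect_error(harmonize_pair(d$exposure, d$outcome),
               "no variants survive")
  # eaf missing on one side: also dropped
  d2 <- make_pair_ds(c("C", "G"), c("C", "G"), eaf_exp = 0.2)
  d2$outcome$eaf <- NA_real_
  expect_error(harmonize_pair(d2$exposure, d2$outcome),
               "no variants survive")
  # decisive frequencies keep and orient the variant
  d3 <- make_pair_ds(c("A", "T"), c("A", "T"), eaf_exp = 0.2,
                     eaf_out = 0.79, beta_out = 0.03)
  hp <- harmonize_pair(d3$exposure, d3$outcome)
  expect_equal(hp$actions$action, "kept")
  expect_equal(hp$beta_out, -0.03)   # frequencies on opposite sides: flip
})

test_that("complementary-strand pairs are corrected and kept", {
  d <- make_pair_ds(c("A", "G"), c("T", "C"), beta_out = -0.05,
                    eaf_exp = 0.20, eaf_out = 0.21)
  hp <- harmonize_pair(d$exposure, d$outcome)
  expect_equal(hp$actions$action, "strand_corrected")
  expect_equal(hp$beta_out, -0.05)   # sign unchanged
  # complement-map oracle: C->G etc. on the swapped orientation flips
  d2 <- make_pair_ds(c("A", "G"), c("C", "T"), beta_out = -0.05)
  hp2 <- harmonize_pair(d2$exposure, d2$outcome)
  expect_equal(hp2$beta_out, 0.05)
})

test_that("irreconcilable alleles and missing variants are logged", {
  exposure <- make_ds(n = 3)
  outcome <- make_ds(n = 2, snp = c("rs1", "rs2"))
  outcome$effect_allele[2] <- "C"; outcome$other_allele[2] <- "A"
  hp <- harmonize_pair(exposure, outcome)
  acts <- setNames(hp$actions$action, hp$actions$snp)
  expect_equal(unname(acts["rs1"]), "kept")
  expect_equal(unname(acts["rs2"]), "dropped_mismatch")
  expect_equal(unname(acts["rs3"]), "dropped_missing")
  # conservation: exactly one action per exposure variant
  expect_setequal(hp$actions$snp, exposure$snp)
})

test_that("harmonization is idempotent and flip-invariant downstream", {
  set.seed(7)
  n <- 40
  rec <- make_records(n = n, beta = rnorm(n, 0, 0.05),
                      se = rep(0.005, n),
                      ea = sample(c("A", "C"), n, TRUE), eaf = runif(n, 0.1, 0.4))
  rec$other_allele <- ifelse(rec$effect_allele == "A", "G", "T")
  rec$pval <- pmax(2 * pnorm(-abs(rec$beta / rec$se)), 1e-300)
  exposure <- summary_dataset(rec, trait_name = "exp")
  out_rec <- rec
  out_rec$beta <- 0.5 * rec$beta + rnorm(n, 0, 0.01)
  out_rec$se <- rep(0.01, n)
  out_rec$pval <- pmax(2 * pnorm(-abs(out_rec$beta / out_rec$se)), 1e-300)
  outcome <- summary_dataset(out_rec, trait_name = "out")

  hp <- harmonize_pair(exposure, outcome)
  base <- mr_ivw(hp)

  # randomly swap alleles on a subset of outcome rows (beta negated,
  # eaf complemented): every downstream estimate must be unchanged
  swap <- sample(n, 15)
  out2 <- out_rec
  out2$effect_allele[swap] <- rec$other_allele[swap]
  out2$other_allele[swap] <- rec$effect_allele[swap]
  out2$beta[swap] <- -out2$beta[swap]
  out2$eaf[swap] <- 1 - out2$eaf[swap]
  hp2 <- harmonize_pair(exposure, summary_dataset(out2, trait_name = "out"))
  expect_equal(mr_ivw(hp2)$beta, base$beta, tolerance = 1e-12)
  expect_equal(mr_egger(hp2)$beta, mr_egger(hp)$beta, tolerance = 1e-12)

  # idempotence: re-harmonizing the already-oriented pair changes nothing
  exp_h <- summary_dataset(data.frame(
    snp = hp$snp_ids, chr = "1", pos = seq_along(hp$snp_ids),
    effect_allele = rec$effect_allele[match(hp$snp_ids, rec$snp)],
    other_allele = rec$other_allele[match(hp$snp_ids, rec$snp)],
    eaf = hp$eaf_exp, beta = hp$beta_exp, se = hp$se_exp,
    pval = hp$pval_exp, stringsAsFactors = FALSE), trait_name = "exp")
  out_h <- summary_dataset(data.frame(
    snp = hp$snp_ids, chr = "1", pos = seq_along(hp$snp_ids),
    effect_allele = rec$effect_allele[match(hp$snp_ids, rec$snp)],
    other_allele = rec$other_allele[match(hp$snp_ids, rec$snp)],
    eaf = hp$eaf_exp, beta = hp$beta_out, se = hp$se_out,
    pval = pmax(2 * pnorm(-abs(hp$beta_out / hp$se_out)), 1e-300),
    stringsAsFactors = FALSE), trait_name = "out")
  hp3 <- harmonize_pair(exp_h, out_h)
  expect_equal(hp3$beta_out, hp$beta_out)
  expect_true(all(hp3$actions$action == "kept"))
})

test_that("multi-exposure harmonization aligns to the first exposure", {
  expect_error(harmonize_multi(list(make_ds(n = 3),
                                    make_ds(n = 3, snp = paste0("rx", 1:3))),
                               make_ds(n = 3, snp = paste0("ry", 1:3))),
               "no overlapping")
  # all aligned: matrix equals column-stacked inputs
  e1 <- make_ds(n = 6, beta = seq(0.01, 0.06, by = 0.01), trait_name = "e1")
  e2 <- make_ds(n = 6, beta = seq(0.02, 0.12, by = 0.02), trait_name = "e2")
  out <- make_ds(n = 6, beta = rep(0.01, 6), trait_name = "out")
  ms <- harmonize_multi(list(e1, e2), out)
  expect_equal(ms$beta_exp[match(e1$snp, ms$snp_ids), 1], e1$beta)
  expect_equal(ms$beta_exp[match(e2$snp, ms$snp_ids), 2], e2$beta)
  expect_equal(ms$exposure_names, c("e1", "e2"))
})

test_that("multi-exposure estimates are invariant to allele swaps", {
  set.seed(7)
  n <- 30
  base_rec <- function(beta, seed_swap = NULL) {
    r <- make_records(n = n, beta = beta, se = rep(0.01, n),
                      ea = "A", eaf = runif(n, 0.1, 0.45))
    r$other_allele <- "G"
    r$pval <- pmax(2 * pnorm(-abs(r$beta / r$se)), 1e-300)
    r
  }
  b1 <- rnorm(n, 0, 0.05); b2 <- rnorm(n, 0, 0.05); b3 <- rnorm(n, 0, 0.05)
  y <- 0.4 * b1 + 0 * b2 + 0.2 * b3 + rnorm(n, 0, 0.01)
  recs <- list(base_rec(b1), base_rec(b2), base_rec(b3))
  out_rec <- base_rec(y)
  ms0 <- harmonize_multi(lapply(recs, summary_dataset),
                         summary_dataset(out_rec))
  fit0 <- mvmr_ivw(ms0)
  # swap alleles in exposures 2,3 and the outcome on random subsets
  swapped <- lapply(seq_along(recs), function(k) {
    r <- recs[[k]]
    if (k == 1) return(r)
    s <- sample(n, 10)
    r$effect_allele[s] <- "G"; r$other_allele[s] <- "A"
    r$beta[s] <- -r$beta[s]; r$eaf[s] <- 1 - r$eaf[s]
    r
  })
  s <- sample(n, 12)
  out2 <- out_rec
  out2$effect_allele[s] <- "G"; out2$other_allele[s] <- "A"
  out2$beta[s] <- -out2$beta[s]; out2$eaf[s] <- 1 - out2$eaf[s]
  ms1 <- harmonize_multi(lapply(swapped, summary_dataset),
                         summary_dataset(out2))
  fit1 <- mvmr_ivw(ms1)
  expect_equal(unname(fit1$beta), unname(fit0$beta), tolerance = 1e-12)
})
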