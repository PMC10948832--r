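#' @title Summary-statistics simulation with known ground truth
#' @description Generates two-sample GWAS summary statistics — a panel of
#'   continuous aging-related exposures (telomere length plus epigenetic
#'   age-acceleration clocks) and binary disease outcomes — directly on the
#'   summary scale, with configurable causal effects, instrument strength,
#'   pleiotropy and block LD structure, so every pipeline stage can be
#'   validated against a recorded truth manifest.
#' @name synthetic_data
NULL

#' Define a simulation scenario
#'
#' @param theta true causal effects of the K exposures on the outcome
#'   (log-odds per exposure unit).
#' @param n_snp total simulated variants.
#' @param n_instruments truly associated variants: a scalar (instruments
#'   shared by all exposures, effect correlation from `exposure_corr`) or
#'   a length-K vector (per-exposure instrument blocks; each block's
#'   variants affect primarily that exposure).
#' @param gamma_dist SD of true instrument-exposure effects, recycled to
#'   length K.
#' @param prop_invalid fraction of instruments violating exclusion
#'   restriction (direct outcome effects).
#' @param alpha_mean,alpha_sd mean and SD of the direct (pleiotropic)
#'   outcome effects of invalid instruments; `alpha_mean != 0` gives
#'   directional pleiotropy, `alpha_mean = 0` balanced.
#' @param inside_violated if `TRUE` the pleiotropic effects are correlated
#'   with instrument strength (violating the InSIDE assumption).
#' @param n_exp exposure-GWAS sample sizes, recycled to length K.
#' @param n_out outcome-GWAS sample size.
#' @param case_fraction case proportion of the binary outcome.
#' @param ld_blocks integer vector of LD block sizes summing to `n_snp`
#'   (default all 1 = independent variants).
#' @param block_r2 within-block squared correlation (recycled over
#'   blocks).
#' @param exposure_corr K x K correlation of true instrument effects
#'   across exposures (default identity).
#' @param exposure_names labels for the K exposures.
#' @return a `sim_truth` list echoing every parameter.
#' @export
sim_truth <- function(theta = 0.4, n_snp = 200, n_instruments = 50,
                      gamma_dist = 0.03, prop_invalid = 0,
                      alpha_mean = 0, alpha_sd = 0,
                      inside_violated = FALSE,
                      n_exp = 472174, n_out = 301445,
                      case_fraction = 1493 / 301445,
                      ld_blocks = NULL, block_r2 = 0,
                      exposure_corr = NULL,
                      exposure_names = NULL) {
  K <- length(theta)
  gamma_dist <- rep_len(gamma_dist, K)
  n_exp <- rep_len(n_exp, K)
  if (is.null(exposure_names)) {
    exposure_names <- if (K == 1L) "exposure" else paste0("exposure", 1:K)
  }
  if (is.null(exposure_corr)) exposure_corr <- diag(K)
  exposure_corr <- as.matrix(exposure_corr)
  stopifnot(all(dim(exposure_corr) == K),
            max(abs(exposure_corr - t(exposure_corr))) < 1e-8,
            all(abs(diag(exposure_corr) - 1) < 1e-12))
  ev <- eigen(exposure_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("exposure_corr must be positive semi-definite",
                            call. = FALSE)
  if (is.null(ld_blocks)) ld_blocks <- rep(1L, n_snp)
  if (sum(ld_blocks) != n_snp) {
    stop("ld_blocks must sum to n_snp", call. = FALSE)
  }
  stopifnot(prop_invalid >= 0, prop_invalid <= 1,
            case_fraction > 0, case_fraction < 1)
  if (length(n_instruments) == 1L) {
    stopifnot(n_instruments <= n_snp)
  } else {
    stopifnot(length(n_instruments) == K, sum(n_instruments) <= n_snp)
  }
  structure(list(
    theta = stats::setNames(theta, exposure_names), n_snp = n_snp,
    n_instruments = n_instruments, gamma_dist = gamma_dist,
    prop_invalid = prop_invalid, alpha_mean = alpha_mean,
    alpha_sd = alpha_sd, inside_violated = inside_violated,
    n_exp = n_exp, n_out = n_out, case_fraction = case_fraction,
    ld_blocks = ld_blocks, block_r2 = rep_len(block_r2, length(ld_blocks)),
    exposure_corr = exposure_corr, exposure_names = exposure_names
  ), class = "sim_truth")
}

#' A study-scale default scenario
#'
#' Six exposures (telomere length and five epigenetic-clock measures) with
#' per-exposure instrument counts of 121, 4, 7, 22, 4 and 10, exposure
#' sample sizes of 472,174 for telomere length and about 34,450 for the
#' clocks, and a binary outcome of 1,493 cases in 301,445 participants —
#' magnitudes typical of current biobank-scale telomere and methylation
#' GWASs and of registry disease endpoints. Only the first exposure is
#' causal by default (`theta[1] = log(2)`).
#'
#' @param theta optional override of the 6 true causal effects.
#' @return a `sim_truth`.
#' @export
study_scale_truth <- function(theta = c(log(2), 0, 0, 0, 0, 0)) {
  sim_truth(
    theta = theta,
    n_snp = 400,
    n_instruments = c(121, 4, 7, 22, 4, 10),
    gamma_dist = c(0.03, 0.08, 0.08, 0.08, 0.08, 0.08),
    n_exp = c(472174, 34467, 34449, 34461, 34448, 34463),
    n_out = 301445, case_fraction = 1493 / 301445,
    exposure_names = c("telomere_length", "grimage_accel", "hannum_accel",
                       "intrinsic_eaa", "dnam_pai1", "phenoage_accel"))
}

# two-sided normal p floored at the smallest normalized double so extreme
# z-scores never underflow to an (invalid) exact zero
.p_from_z <- function(z) pmax(2 * stats::pnorm(-abs(z)), 2.3e-308)

# standard error of a per-allele effect on a standardized continuous trait
.se_continuous <- function(n, eaf) 1 / sqrt(n * 2 * eaf * (1 - eaf))
# log-odds scale standard error for a binary trait
.se_binary <- function(n, cf, eaf) {
  1 / sqrt(n * cf * (1 - cf) * 2 * eaf * (1 - eaf))
}

#' Simulate the exposure summary-statistics panel
#'
#' Draws true instrument effects with the configured spread and
#' cross-exposure correlation, observed effects as the truth plus normal
#' sampling noise at the analytic standard error
#' `1/sqrt(n 2 eaf (1-eaf))`, and reproducible alleles, positions and
#' allele frequencies (uniform on 0.05–0.95). Every true value is
#' recorded in the manifest; estimators never see it.
#'
#' @param truth a [sim_truth()].
#' @param seed integer seed.
#' @return list with `exposures` (list of K `summary_dataset`s) and
#'   `manifest` (data.frame of per-variant true effects and flags).
#' @export
simulate_exposure_panel <- function(truth, seed = 1) {
  stopifnot(inherits(truth, "sim_truth"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  K <- length(truth$theta); J <- truth$n_snp
  snp <- sprintf("rs%06d", seq_len(J))
  # one LD block = one locus; blocks laid out along chromosomes 1..22
  block_id <- rep(seq_along(truth$ld_blocks), truth$ld_blocks)
  chr <- as.character((block_id - 1L) %% 22L + 1L)
  # loci 200 kb apart along each chromosome, 1 kb spacing within a block
  block_on_chr <- (block_id - 1L) %/% 22L + 1L
  pos <- integer(J)
  for (b in unique(block_id)) {
    i <- which(block_id == b)
    pos[i] <- as.integer(2e5 * block_on_chr[i] + seq_along(i) * 1000L)
  }
  eaf <- stats::runif(J, 0.05, 0.95)
  pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                 c("C", "A"), c("G", "A"))
  pick <- sample.int(nrow(pairs), J, replace = TRUE)
  ea <- pairs[pick, 1L]; oa <- pairs[pick, 2L]

  gamma <- matrix(0, J, K)
  is_instrument <- rep(FALSE, J)
  primary_exposure <- rep(NA_integer_, J)
  if (length(truth$n_instruments) == 1L) {
    if (truth$n_instruments > 0) {
      idx <- seq_len(truth$n_instruments)
      is_instrument[idx] <- TRUE
      primary_exposure[idx] <- 0L   # shared
      L <- chol(truth$exposure_corr + diag(1e-10, K))
      Z <- matrix(stats::rnorm(length(idx) * K), ncol = K) %*% L
      gamma[idx, ] <- Z * matrix(truth$gamma_dist, length(idx), K,
                                 byrow = TRUE)
    }
  } else {
    off <- 0L
    for (k in seq_len(K)) {
      nk <- truth$n_instruments[k]
      if (nk == 0L) next
      idx <- off + seq_len(nk)
      off <- off + nk
      is_instrument[idx] <- TRUE
      primary_exposure[idx] <- k
      gamma[idx, k] <- stats::rnorm(nk, 0, truth$gamma_dist[k])
      # cross-exposure leakage proportional to the effect correlation
      for (k2 in seq_len(K)) {
        if (k2 == k) next
        rho <- truth$exposure_corr[k, k2]
        if (rho != 0) {
          gamma[idx, k2] <- rho * gamma[idx, k] *
            (truth$gamma_dist[k2] / truth$gamma_dist[k])
        }
      }
    }
  }
  se_exp <- outer(eaf, truth$n_exp,
                  function(f, n) 1 / sqrt(n * 2 * f * (1 - f)))
  gamma_hat <- gamma + matrix(stats::rnorm(J * K), J, K) * se_exp

  exposures <- vector("list", K)
  for (k in seq_len(K)) {
    z <- gamma_hat[, k] / se_exp[, k]
    exposures[[k]] <- summary_dataset(data.frame(
      snp = snp, chr = chr, pos = pos, effect_allele = ea,
      other_allele = oa, eaf = eaf, beta = gamma_hat[, k],
      se = se_exp[, k], pval = .p_from_z(z),
      n = truth$n_exp[k], stringsAsFactors = FALSE),
      trait_name = truth$exposure_names[k], trait_type = "continuous",
      unit_label = "per 1-SD")
  }
  names(exposures) <- truth$exposure_names
  manifest <- data.frame(snp = snp, chr = chr, pos = pos, eaf = eaf,
                         is_instrument = is_instrument,
                         primary_exposure = primary_exposure,
                         stringsAsFactors = FALSE)
  for (k in seq_len(K)) {
    manifest[[paste0("gamma_", truth$exposure_names[k])]] <- gamma[, k]
  }
  list(exposures = exposures, manifest = manifest, seed = seed)
}

#' Simulate the outcome summary statistics
#'
#' True outcome effects follow the linear causal model
#' `Gamma_j = sum_k theta_k gamma_jk + alpha_j`, with `alpha_j = 0` for
#' valid instruments and drawn from `Normal(alpha_mean, alpha_sd^2)` for
#' the invalid fraction (optionally correlated with instrument strength
#' when the InSIDE assumption is violated). Observed effects add normal
#' noise at the binary-trait standard error
#' `1/sqrt(n case_fraction (1-case_fraction) 2 eaf (1-eaf))`.
#'
#' @param truth the [sim_truth()] used for the exposure panel.
#' @param panel result of [simulate_exposure_panel()].
#' @param seed integer seed (independent of the panel's).
#' @return list with `outcome` (a binary-trait `summary_dataset`) and
#'   `manifest` (the panel manifest extended with `alpha`, `Gamma`,
#'   `is_valid`).
#' @export
simulate_outcome <- function(truth, panel, seed = 2) {
  stopifnot(inherits(truth, "sim_truth"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  man <- panel$manifest
  J <- nrow(man)
  K <- length(truth$theta)
  gcols <- paste0("gamma_", truth$exposure_names)
  gamma <- as.matrix(man[, gcols, drop = FALSE])
  alpha <- rep(0, J)
  inst <- which(man$is_instrument)
  n_invalid <- round(truth$prop_invalid * length(inst))
  invalid <- if (n_invalid > 0) sort(sample(inst, n_invalid)) else integer(0)
  if (length(invalid) > 0) {
    draw <- stats::rnorm(length(invalid), truth$alpha_mean, truth$alpha_sd)
    if (truth$inside_violated) {
      g1 <- gamma[invalid, 1L]
      draw <- draw + 0.5 * abs(g1) * truth$alpha_sd /
        max(truth$gamma_dist[1], 1e-12)
    }
    # directional pleiotropy acts on the allele that raises exposure 1,
    # so the direct effect carries that orientation
    s1 <- sign(gamma[invalid, 1L]); s1[s1 == 0] <- 1
    alpha[invalid] <- s1 * draw
  }
  Gamma <- drop(gamma %*% truth$theta) + alpha
  se_out <- .se_binary(truth$n_out, truth$case_fraction, man$eaf)
  Gamma_hat <- Gamma + stats::rnorm(J, 0, se_out)
  z <- Gamma_hat / se_out
  outcome <- summary_dataset(data.frame(
    snp = man$snp, chr = man$chr, pos = man$pos,
    effect_allele = panel$exposures[[1L]]$effect_allele,
    other_allele = panel$exposures[[1L]]$other_allele,
    eaf = man$eaf, beta = Gamma_hat, se = se_out,
    pval = .p_from_z(z), n = truth$n_out,
    stringsAsFactors = FALSE),
    trait_name = "outcome", trait_type = "binary",
    unit_label = "log-odds")
  man$alpha <- alpha
  man$Gamma <- Gamma
  man$is_valid <- man$is_instrument & alpha == 0
  list(outcome = outcome, manifest = man, seed = seed)
}

#' Simulate a block-diagonal LD matrix
#'
#' Within each block every pair of variants has the block's constant
#' squared correlation; across blocks r2 is zero.
#'
#' @param truth a [sim_truth()] with `ld_blocks` and `block_r2`.
#' @param snp_ids variant ids (default the panel's `rs` ids).
#' @return an [ld_matrix()].
#' @export
simulate_ld <- function(truth, snp_ids = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  J <- truth$n_snp
  if (is.null(snp_ids)) snp_ids <- sprintf("rs%06d", seq_len(J))
  stopifnot(length(snp_ids) == J)
  m <- matrix(0, J, J)
  off <- 0L
  for (b in seq_along(truth$ld_blocks)) {
    sz <- truth$ld_blocks[b]
    i <- off + seq_len(sz)
    m[i, i] <- truth$block_r2[b]
    off <- off + sz
  }
  diag(m) <- 1
  ld_matrix(m, snp_ids)
}

#' Simulate a complete two-sample MR study
#'
#' Convenience wrapper running [simulate_exposure_panel()],
#' [simulate_outcome()] and [simulate_ld()] under one seed.
#'
#' @param truth a [sim_truth()].
#' @param seed integer master seed (panel and outcome seeds derived).
#' @return list with `exposures`, `outcome`, `ld`, `manifest`, `truth`.
#' @export
simulate_mr_study <- function(truth, seed = 1) {
  panel <- simulate_exposure_panel(truth, seed = seed)
  out <- simulate_outcome(truth, panel, seed = seed + 1e6)
  ld <- simulate_ld(truth, snp_ids = panel$manifest$snp)
  list(exposures = panel$exposures, outcome = out$outcome, ld = ld,
       manifest = out$manifest, truth = truth, seed = seed)
}
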