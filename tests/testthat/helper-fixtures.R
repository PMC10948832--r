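# Fixture builders shared across the suite. All randomness is seeded by the
# caller; builders themselves are deterministic given their arguments.

# minimal well-formed summary data.frame
make_records <- function(n = 3, beta = NULL, se = NULL, pval = NULL,
                         snp = NULL, ea = "A", oa = "G", eaf = 0.3,
                         chr = "1", pos = NULL) {
  if (is.null(snp)) snp <- paste0("rs", seq_len(n))
  if (is.null(se)) se <- rep(0.01, n)
  if (is.null(beta)) {
    beta <- if (is.null(pval)) seq(0.01, by = 0.01, length.out = n) else
      se * qnorm(1 - pval / 2)   # keep beta/se consistent with pval
  }
  if (is.null(pval)) pval <- pmax(2 * pnorm(-abs(beta / se)), 1e-300)
  if (is.null(pos)) pos <- seq_len(n) * 1000L
  data.frame(snp = snp, chr = chr, pos = pos,
             effect_allele = ea, other_allele = oa, eaf = eaf,
             beta = beta, se = se, pval = pval, n = 1000,
             stringsAsFactors = FALSE)
}

make_ds <- function(..., trait_name = "trait") {
  suppressWarnings(summary_dataset(make_records(...),
                                   trait_name = trait_name))
}

# harmonized pair straight from effect vectors
make_hp <- function(beta_exp, beta_out, se_exp = NULL, se_out = NULL) {
  J <- length(beta_exp)
  if (is.null(se_exp)) se_exp <- rep(0.01, J)
  if (is.null(se_out)) se_out <- rep(0.01, J)
  harmonized_pair(beta_exp, se_exp, beta_out, se_out)
}

# one replicate of a simple two-sample design with J strong instruments;
# returns a harmonized_pair. alpha is a vector of direct effects (recycled).
draw_hp <- function(J, theta, gamma_sd = 0.1, se_exp = 0.01, se_out = 0.05,
                    alpha = 0) {
  gamma <- rnorm(J, 0, gamma_sd)
  alpha <- rep_len(alpha, J)
  gamma_hat <- gamma + rnorm(J, 0, se_exp)
  Gamma_hat <- theta * gamma + alpha + rnorm(J, 0, se_out)
  harmonized_pair(gamma_hat, rep(se_exp, J), Gamma_hat, rep(se_out, J))
}

# multi-exposure replicate with correlated true instrument effects
draw_ms <- function(J, theta, corr = 0.6, gamma_sd = 0.1, se_exp = 0.01,
                    se_out = 0.05) {
  K <- length(theta)
  R <- matrix(corr, K, K); diag(R) <- 1
  G <- matrix(rnorm(J * K), J, K) %*% chol(R) * gamma_sd
  Ghat <- G + matrix(rnorm(J * K, 0, se_exp), J, K)
  y <- drop(G %*% theta) + rnorm(J, 0, se_out)
  multi_exposure_set(Ghat, matrix(se_exp, J, K), y, rep(se_out, J))
}

# independent WLS oracle via lm(); returns list(beta, se_fixed, V)
lm_wls_oracle <- function(X, y, w, intercept = FALSE) {
  df <- data.frame(y = y, X)
  form <- if (intercept) y ~ . else y ~ . + 0
  fit <- lm(form, data = df, weights = w)
  sm <- summary(fit)
  sigma <- sm$sigma
  list(beta = unname(coef(fit)),
       se_unscaled = unname(sm$coefficients[, "Std. Error"]) / sigma,
       sigma = sigma)
}
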