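#' @title Bayesian model averaging over exposure subsets
#' @description Ranks candidate exposures by enumerating every non-empty
#'   exposure subset, scoring each with a Zellner g-prior marginal
#'   likelihood on the standardized origin-constrained linear model, and
#'   averaging: model posterior probabilities (PP), marginal inclusion
#'   probabilities (MIP) and model-averaged causal effects (MACE), with
#'   per-instrument influence diagnostics.
#' @name bma
NULL

# all subsets of 1..K (the first is the empty model) as integer vectors
.subsets <- function(K) {
  lapply(0:(2^K - 1L), function(m) {
    which(bitwAnd(m, bitwShiftL(1L, 0:(K - 1L))) != 0L)
  })
}

#' Enumerate exposure subsets under Bayesian model averaging
#'
#' Effects are standardized by the outcome standard errors
#' (`y_j = beta_out_j / se_out_j`, `x_jk = beta_exp_jk / se_out_j`); every
#' subset S of the K exposures — including the empty, all-noise model,
#' whose presence lets inclusion probabilities calibrate to the prior
#' under a global null — is scored by its g-prior marginal likelihood on
#' the origin-constrained regression of y on the columns in S, multiplied
#' by an independent-inclusion prior, and normalized into model posterior
#' probabilities. Per-exposure marginal inclusion
#' probabilities sum the PP of models containing the exposure; the
#' model-averaged causal effect sums PP-weighted conditional posterior
#' means.
#'
#' @param ms a `multi_exposure_set` with K <= 20 (exhaustive enumeration).
#' @param prior_inclusion prior inclusion probability of each exposure
#'   (default 0.1).
#' @param g g-prior scale (default `NULL` = number of instruments J, the
#'   unit-information prior).
#' @return an `mr_bma`: list with `models` (data.frame: model, size,
#'   log-score, prior, pp), `model_effects` (list of conditional effect
#'   vectors), `mip`, `mace`, `ranking`, and the configuration echo.
#' @export
mr_bma <- function(ms, prior_inclusion = 0.1, g = NULL) {
  stopifnot(inherits(ms, "multi_exposure_set"))
  K <- ncol(ms$beta_exp); J <- nrow(ms$beta_exp)
  if (K > 20L) stop("exhaustive enumeration limited to K <= 20",
                    call. = FALSE)
  if (is.null(g)) g <- J
  stopifnot(g > 0, prior_inclusion > 0, prior_inclusion < 1)
  y <- ms$beta_out / ms$se_out
  X <- ms$beta_exp / ms$se_out       # row-wise standardization
  yty <- sum(y^2)
  subsets <- .subsets(K)
  M <- length(subsets)
  log_score <- numeric(M)
  prior <- numeric(M)
  effects <- vector("list", M)
  shrink <- g / (1 + g)
  for (m in seq_len(M)) {
    S <- subsets[[m]]
    p <- length(S)
    prior[m] <- prior_inclusion^p * (1 - prior_inclusion)^(K - p)
    if (p == 0L) {
      # empty model: pure noise, no shrinkage term
      log_score[m] <- -J / 2 * log(yty)
      effects[[m]] <- numeric(0)
      next
    }
    Xs <- X[, S, drop = FALSE]
    XtX <- crossprod(Xs)
    ok <- tryCatch({ R <- chol(XtX); TRUE }, error = function(e) FALSE)
    if (!ok) {
      warning("singular design for model {",
              paste(ms$exposure_names[S], collapse = ","),
              "}; assigned posterior probability 0", call. = FALSE)
      log_score[m] <- -Inf
      effects[[m]] <- stats::setNames(rep(NA_real_, p),
                                      ms$exposure_names[S])
      next
    }
    Xty <- crossprod(Xs, y)
    bhat <- backsolve(R, forwardsolve(t(R), Xty))
    fit_ss <- sum(Xty * bhat)          # y'X (X'X)^-1 X'y
    rss_g <- yty - shrink * fit_ss
    log_score[m] <- -p / 2 * log1p(g) - J / 2 * log(rss_g)
    effects[[m]] <- stats::setNames(drop(shrink * bhat),
                                    ms$exposure_names[S])
  }
  lw <- log_score + log(prior)
  lw <- lw - max(lw[is.finite(lw)])
  pp <- ifelse(is.finite(lw), exp(lw), 0)
  pp <- pp / sum(pp)
  mip <- numeric(K); mace <- numeric(K)
  for (m in seq_len(M)) {
    S <- subsets[[m]]
    mip[S] <- mip[S] + pp[m]
    eff <- effects[[m]]
    if (!anyNA(eff)) mace[S] <- mace[S] + pp[m] * eff
  }
  names(mip) <- names(mace) <- ms$exposure_names
  model_label <- vapply(subsets, function(S) {
    if (length(S) == 0L) "(none)" else
      paste(ms$exposure_names[S], collapse = ",")
  }, character(1))
  models <- data.frame(model = model_label,
                       size = lengths(subsets),
                       log_score = log_score, prior = prior, pp = pp,
                       stringsAsFactors = FALSE)
  # deterministic report order: PP desc, then smaller model, then label
  ord <- order(-models$pp, models$size, models$model)
  structure(list(
    models = models[ord, , drop = FALSE],
    subsets = subsets[ord],
    model_effects = effects[ord],
    mip = mip, mace = mace,
    ranking = names(sort(mip, decreasing = TRUE)),
    prior_inclusion = prior_inclusion, g = g,
    exposure_names = ms$exposure_names, n_snp = J
  ), class = "mr_bma")
}

#' @export
print.mr_bma <- function(x, top = 10, ...) {
  cat(sprintf("Bayesian model averaging over %d exposure(s), %d model(s), %d instrument(s)\n",
              length(x$mip), nrow(x$models), x$n_snp))
  cat(sprintf("  prior inclusion %.3g, g = %.4g\n", x$prior_inclusion, x$g))
  cat("Top models by posterior probability:\n")
  tab <- utils::head(x$models[, c("model", "size", "pp")], top)
  tab$pp <- signif(tab$pp, 4)
  print(tab, row.names = FALSE)
  cat("Marginal inclusion probabilities (ranked):\n")
  print(signif(sort(x$mip, decreasing = TRUE), 4))
  cat("Model-averaged causal effects:\n")
  print(signif(x$mace, 4))
  invisible(x)
}

#' @export
coef.mr_bma <- function(object, ...) object$mace

#' @export
summary.mr_bma <- function(object, top = 10, ...) {
  structure(list(bma = object, top = top), class = "summary.mr_bma")
}

#' @export
print.summary.mr_bma <- function(x, ...) {
  print(x$bma, top = x$top)
  invisible(x)
}

#' Influence and outlier diagnostics for high-posterior models
#'
#' For every model with posterior probability at or above `pp_threshold`
#' the origin-constrained standardized regression is refit and each
#' instrument receives a Cook's distance (leverage-weighted squared
#' residual) and a heterogeneity (Q) contribution. Instruments are
#' flagged when Cook's distance exceeds the median of the
#' `F(p, J - p)` distribution or the Q contribution exceeds the
#' chi-square(1) quantile at level `0.05 / J` (Bonferroni).
#'
#' @param ms the `multi_exposure_set` the result was fit on.
#' @param result an `mr_bma` from [mr_bma()] on `ms`.
#' @param pp_threshold minimum model PP for inspection (default 0.02).
#' @return an `mr_bma_diagnostics`: list with `table` (model, snp,
#'   cook_distance, q_contribution, flagged), `flagged_snps` (union over
#'   inspected models), and thresholds used.
#' @export
bma_diagnostics <- function(ms, result, pp_threshold = 0.02) {
  stopifnot(inherits(ms, "multi_exposure_set"), inherits(result, "mr_bma"))
  y <- ms$beta_out / ms$se_out
  X <- ms$beta_exp / ms$se_out
  J <- length(y)
  q_cut <- stats::qchisq(1 - 0.05 / J, df = 1)
  rows <- list()
  flagged <- character(0)
  inspect <- which(result$models$pp >= pp_threshold)
  for (m in inspect) {
    S <- result$subsets[[m]]
    p <- length(S)
    if (p == 0L || J <= p) next
    Xs <- X[, S, drop = FALSE]
    XtXinv <- tryCatch(chol2inv(chol(crossprod(Xs))),
                       error = function(e) NULL)
    if (is.null(XtXinv)) next
    H <- Xs %*% XtXinv %*% t(Xs)
    h <- diag(H)
    bhat <- drop(XtXinv %*% crossprod(Xs, y))
    e <- y - drop(Xs %*% bhat)
    rss <- sum(e^2)
    # numerically exact fits have no influential points
    exact <- rss <= 1e-12 * max(sum(y^2), .Machine$double.eps)
    s2 <- rss / (J - p)
    cook <- if (!exact && s2 > 0) {
      (e^2 / (p * s2)) * (h / (1 - h)^2)
    } else rep(0, J)
    qc <- if (exact) rep(0, J) else e^2
    d_cut <- stats::qf(0.5, p, J - p)
    fl <- cook > d_cut | qc > q_cut
    rows[[length(rows) + 1L]] <- data.frame(
      model = result$models$model[m], snp = ms$snp_ids,
      cook_distance = cook, q_contribution = qc, flagged = fl,
      stringsAsFactors = FALSE)
    flagged <- union(flagged, ms$snp_ids[fl])
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(model = character(0), snp = character(0),
               cook_distance = numeric(0), q_contribution = numeric(0),
               flagged = logical(0), stringsAsFactors = FALSE)
  structure(list(table = tab, flagged_snps = flagged,
                 pp_threshold = pp_threshold, q_cut = q_cut),
            class = "mr_bma_diagnostics")
}

#' @export
print.mr_bma_diagnostics <- function(x, ...) {
  cat(sprintf("BMA influence diagnostics (models with PP >= %g)\n",
              x$pp_threshold))
  if (length(x$flagged_snps)) {
    cat("  flagged:", paste(x$flagged_snps, collapse = ", "), "\n")
  } else {
    cat("  no instruments flagged\n")
  }
  invisible(x)
}

#' Re-run model averaging without flagged instruments
#'
#' @param ms the original `multi_exposure_set`.
#' @param flagged instrument ids to exclude.
#' @param prior_inclusion,g passed to [mr_bma()].
#' @return list with `original_flagged` (the ids actually removed) and
#'   `result` (the `mr_bma` on the reduced set).
#' @export
bma_rerun_without <- function(ms, flagged, prior_inclusion = 0.1, g = NULL) {
  stopifnot(inherits(ms, "multi_exposure_set"))
  keep <- which(!(ms$snp_ids %in% flagged))
  K <- ncol(ms$beta_exp)
  if (length(keep) <= K) {
    stop("under-identified after removal: ", length(keep),
         " instrument(s) remain for K = ", K, call. = FALSE)
  }
  sub <- .subset_ms(ms, keep)
  list(original_flagged = setdiff(ms$snp_ids, sub$snp_ids),
       result = mr_bma(sub, prior_inclusion = prior_inclusion, g = g))
}

#' Joint LD clumping across several exposures
#'
#' Pools the instruments of all exposures, ranks each variant by its
#' minimum association p-value across exposures, and clumps greedily as
#' in [ld_clump()] — supplying the approximately independent instrument
#' union required by multivariable model averaging.
#'
#' @param exposures list of `summary_dataset` objects (already screened
#'   to instruments, K >= 2).
#' @param ld an [ld_matrix()].
#' @param r2_threshold,window_kb as in [ld_clump()].
#' @return character vector of retained variant ids.
#' @export
joint_clump_for_bma <- function(exposures, ld, r2_threshold = 0.001,
                                window_kb = 10000) {
  stopifnot(length(exposures) >= 2L)
  pool <- list()
  for (ds in exposures) {
    pool[[length(pool) + 1L]] <- data.frame(
      snp = ds$snp, chr = ds$chr, pos = ds$pos, pval = ds$pval,
      stringsAsFactors = FALSE)
  }
  pool <- do.call(rbind, pool)
  if (nrow(pool) == 0L) stop("empty instrument pool", call. = FALSE)
  # min p across exposures per variant
  agg <- stats::aggregate(pval ~ snp, data = pool, FUN = min)
  meta <- pool[!duplicated(pool$snp), c("snp", "chr", "pos")]
  agg <- merge(agg, meta, by = "snp")
  fake <- summary_dataset(data.frame(
    snp = agg$snp, chr = agg$chr, pos = agg$pos,
    effect_allele = "A", other_allele = "G",
    beta = 0, se = 1, pval = agg$pval, stringsAsFactors = FALSE),
    trait_name = "pooled", validate = FALSE)
  sel <- ld_clump(fake, ld, r2_threshold, window_kb)
  sel$kept
}
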