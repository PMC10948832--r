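#' @title Multivariable MR estimators
#' @description Joint direct effects of several exposures from shared
#'   instruments: multivariable IVW, Egger, and LASSO-based selection of
#'   valid instruments.
#' @name mvmr
NULL

.new_mvmr_estimate <- function(method, ms, beta, se, q, q_df,
                               extra = list()) {
  K <- length(beta)
  z <- beta / se
  est <- c(list(
    method = method,
    exposure_names = ms$exposure_names,
    outcome_name = ms$outcome_name,
    n_snp = length(ms$beta_out),
    beta = stats::setNames(beta, ms$exposure_names),
    se = stats::setNames(se, ms$exposure_names),
    ci_low = beta - stats::qnorm(0.975) * se,
    ci_high = beta + stats::qnorm(0.975) * se,
    pvalue = 2 * stats::pnorm(-abs(z)),
    q = q, q_df = q_df,
    q_p = if (is.na(q)) NA_real_ else
      stats::pchisq(q, q_df, lower.tail = FALSE)
  ), extra)
  class(est) <- "mvmr_estimate"
  est
}

#' @export
print.mvmr_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("Multivariable MR estimate (%s) -> %s, %d instrument(s)\n",
              x$method, x$outcome_name, x$n_snp))
  tab <- data.frame(
    beta = round(x$beta, digits), se = round(x$se, digits),
    or = round(exp(x$beta), digits),
    ci_low = round(exp(x$ci_low), digits),
    ci_high = round(exp(x$ci_high), digits),
    p = signif(x$pvalue, 3))
  rownames(tab) <- x$exposure_names
  print(tab)
  if (!is.na(x$q)) {
    cat(sprintf("  Q %.4g on %d df (p %.4g)\n", x$q, x$q_df, x$q_p))
  }
  if (!is.null(x$intercept)) {
    cat(sprintf("  intercept %.4g (SE %.4g, p %.4g)\n",
                x$intercept, x$intercept_se, x$intercept_p))
  }
  if (!is.null(x$valid_set)) {
    cat(sprintf("  valid set: %d of %d instrument(s)\n",
                length(x$valid_set), x$n_snp))
  }
  invisible(x)
}

#' @export
coef.mvmr_estimate <- function(object, ...) object$beta

#' @export
confint.mvmr_estimate <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- cbind(object$beta - z * object$se, object$beta + z * object$se)
  dimnames(m) <- list(object$exposure_names,
                      sprintf("%g %%", c((1 - level) / 2,
                                         1 - (1 - level) / 2) * 100))
  if (!missing(parm)) m <- m[parm, , drop = FALSE]
  m
}

# weighted least squares via normal equations; returns coefs and
# unscaled covariance (X'WX)^{-1}
.wls <- function(X, y, w) {
  XtWX <- crossprod(X, w * X)
  qrd <- qr(XtWX)
  if (qrd$rank < ncol(X)) {
    bad <- colnames(X)[qrd$pivot[-seq_len(qrd$rank)]]
    stop("collinear design: rank ", qrd$rank, " < ", ncol(X),
         if (length(bad)) paste0(" (check columns: ",
                                 paste(bad, collapse = ", "), ")") else "",
         call. = FALSE)
  }
  V <- chol2inv(chol(XtWX))
  b <- drop(V %*% crossprod(X, w * y))
  list(beta = b, V = V)
}

#' Multivariable IVW estimate
#'
#' Weighted least squares of the instrument-outcome effects on the J x K
#' matrix of instrument-exposure effects, no intercept, weights
#' `1/se_out^2`. Each coefficient is the direct effect of one exposure
#' adjusted for the others. Under the multiplicative random-effects model
#' standard errors are inflated by `max(1, sqrt(Q/(J-K)))`.
#'
#' @param ms a `multi_exposure_set` with J > K.
#' @param effects_model `"multiplicative_random"` (default) or `"fixed"`.
#' @return an `mvmr_estimate` with per-exposure effects, Wald CIs and
#'   conditional heterogeneity Q on `J - K` df.
#' @export
mvmr_ivw <- function(ms, effects_model = c("multiplicative_random",
                                           "fixed")) {
  stopifnot(inherits(ms, "multi_exposure_set"))
  effects_model <- match.arg(effects_model)
  X <- ms$beta_exp; y <- ms$beta_out; w <- 1 / ms$se_out^2
  colnames(X) <- ms$exposure_names
  J <- nrow(X); K <- ncol(X)
  if (J <= K) stop("under-identified: J must exceed K", call. = FALSE)
  fit <- .wls(X, y, w)
  q <- sum(w * (y - drop(X %*% fit$beta))^2)
  q_df <- J - K
  infl <- if (effects_model == "multiplicative_random") {
    max(1, sqrt(q / q_df))
  } else 1
  se <- sqrt(diag(fit$V)) * infl
  est <- .new_mvmr_estimate("mvmr_ivw", ms, fit$beta, se, q, q_df)
  est$conditional_f <- conditional_f(ms)
  est
}

#' Conditional instrument-strength diagnostic
#'
#' A simple per-exposure conditional F: each exposure's instrument effects
#' are regressed (weighted by `1/se_exp^2` for that exposure) on the other
#' exposures' effects, and the F statistic for the residual instrument
#' signal is reported. Values below 10 flag conditionally weak
#' instruments.
#'
#' @param ms a `multi_exposure_set`.
#' @return named numeric vector of per-exposure conditional F statistics.
#' @export
conditional_f <- function(ms) {
  stopifnot(inherits(ms, "multi_exposure_set"))
  K <- ncol(ms$beta_exp); J <- nrow(ms$beta_exp)
  if (K < 2L) {
    return(stats::setNames(mean((ms$beta_exp[, 1] / ms$se_exp[, 1])^2),
                           ms$exposure_names))
  }
  out <- vapply(seq_len(K), function(k) {
    yk <- ms$beta_exp[, k]
    Xk <- ms$beta_exp[, -k, drop = FALSE]
    wk <- 1 / ms$se_exp[, k]^2
    fit <- tryCatch(.wls(Xk, yk, wk), error = function(e) NULL)
    resid <- if (is.null(fit)) yk else yk - drop(Xk %*% fit$beta)
    # mean weighted squared residual signal per instrument
    sum(wk * resid^2) / J
  }, numeric(1))
  stats::setNames(out, ms$exposure_names)
}

#' Multivariable Egger estimate
#'
#' As [mvmr_ivw()] with a free intercept, after re-orienting every
#' instrument so its effect on the `orient_on` exposure is non-negative
#' (both exposure-effect rows and the outcome effect are negated
#' together). The intercept z-test is the directional-pleiotropy
#' diagnostic.
#'
#' @param ms a `multi_exposure_set` with J > K + 1.
#' @param orient_on index of the exposure used for orientation
#'   (default 1).
#' @param effects_model as in [mvmr_ivw()].
#' @return an `mvmr_estimate` with intercept fields.
#' @export
mvmr_egger <- function(ms, orient_on = 1L,
                       effects_model = c("multiplicative_random",
                                         "fixed")) {
  stopifnot(inherits(ms, "multi_exposure_set"))
  effects_model <- match.arg(effects_model)
  X <- ms$beta_exp; y <- ms$beta_out; w <- 1 / ms$se_out^2
  J <- nrow(X); K <- ncol(X)
  if (J <= K + 1L) stop("under-identified: J must exceed K + 1",
                        call. = FALSE)
  s <- sign(X[, orient_on]); s[s == 0] <- 1
  Xo <- X * s; yo <- y * s
  D <- cbind(intercept = 1, Xo)
  colnames(D) <- c("intercept", ms$exposure_names)
  fit <- .wls(D, yo, w)
  q <- sum(w * (yo - drop(D %*% fit$beta))^2)
  q_df <- J - K - 1L
  infl <- if (effects_model == "multiplicative_random") {
    max(1, sqrt(q / q_df))
  } else 1
  se_all <- sqrt(diag(fit$V)) * infl
  .new_mvmr_estimate(
    "mvmr_egger", ms, fit$beta[-1L], se_all[-1L], q, q_df,
    extra = list(intercept = fit$beta[1L], intercept_se = se_all[1L],
                 intercept_p = 2 * stats::pnorm(-abs(fit$beta[1L] /
                                                       se_all[1L])),
                 orient_on = orient_on))
}

# coordinate descent for WLS with per-instrument L1-penalized intercepts:
# minimize sum_j w_j (y_j - a_j - x_j' b)^2 + lambda * sum_j |a_j|
.lasso_intercepts <- function(X, y, w, lambda, tol = 1e-8, max_iter = 10000) {
  J <- nrow(X)
  a <- rep(0, J)
  b <- .wls(X, y, w)$beta
  soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)
  for (it in seq_len(max_iter)) {
    r <- y - drop(X %*% b)
    a_new <- soft(r, lambda / (2 * w))
    b_new <- .wls(X, y - a_new, w)$beta
    delta <- max(abs(a_new - a), abs(b_new - b))
    a <- a_new; b <- b_new
    if (delta < tol) break
  }
  list(alpha = a, beta = b)
}

#' Multivariable LASSO estimate
#'
#' Augments the multivariable IVW regression with one L1-penalized
#' intercept per instrument (exposure effects unpenalized); instruments
#' whose intercept is shrunk exactly to zero at a given penalty form a
#' candidate set of valid instruments. Along a descending penalty grid the
#' largest candidate set whose post-selection heterogeneity Q falls below
#' the 95th chi-square percentile (at `J_valid - K` df) is chosen, and the
#' reported effects are the post-selection [mvmr_ivw()] fit on that set.
#'
#' @param ms a `multi_exposure_set` with J > K + 1.
#' @param lambda_grid descending penalties; by default 50 log-spaced
#'   values from the smallest penalty zeroing every intercept down to
#'   1/1000 of it.
#' @param effects_model passed to the post-selection [mvmr_ivw()].
#' @return an `mvmr_estimate` with `valid_set` (ids retained) and
#'   `lambda` (the chosen penalty).
#' @export
mvmr_lasso <- function(ms, lambda_grid = NULL,
                       effects_model = c("multiplicative_random",
                                         "fixed")) {
  stopifnot(inherits(ms, "multi_exposure_set"))
  effects_model <- match.arg(effects_model)
  X <- ms$beta_exp; y <- ms$beta_out; w <- 1 / ms$se_out^2
  J <- nrow(X); K <- ncol(X)
  if (J <= K + 1L) stop("under-identified: J must exceed K + 1",
                        call. = FALSE)
  if (is.null(lambda_grid)) {
    b0 <- .wls(X, y, w)$beta
    r0 <- y - drop(X %*% b0)
    lambda_max <- max(2 * w * abs(r0)) * 1.0001
    lambda_grid <- exp(seq(log(lambda_max), log(lambda_max / 1000),
                           length.out = 50))
  }
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  best <- NULL
  for (lam in lambda_grid) {
    fit <- .lasso_intercepts(X, y, w, lam)
    valid <- which(fit$alpha == 0)
    if (length(valid) <= K) next
    q <- {
      sub <- .subset_ms(ms, valid)
      f <- .wls(sub$beta_exp, sub$beta_out, 1 / sub$se_out^2)
      sum((1 / sub$se_out^2) *
            (sub$beta_out - drop(sub$beta_exp %*% f$beta))^2)
    }
    ok <- q < stats::qchisq(0.95, length(valid) - K)
    if (ok && (is.null(best) || length(valid) > length(best$valid))) {
      best <- list(valid = valid, lambda = lam)
    }
  }
  if (is.null(best)) {
    stop("no penalty yields a valid instrument set with Q below the ",
         "chi-square 95th percentile", call. = FALSE)
  }
  sub <- .subset_ms(ms, best$valid)
  est <- mvmr_ivw(sub, effects_model)
  est$method <- "mvmr_lasso"
  est$valid_set <- ms$snp_ids[best$valid]
  est$lambda <- best$lambda
  est$n_snp <- length(ms$beta_out)
  est
}

.subset_ms <- function(ms, idx) {
  out <- ms
  out$snp_ids <- ms$snp_ids[idx]
  out$beta_exp <- ms$beta_exp[idx, , drop = FALSE]
  out$se_exp <- ms$se_exp[idx, , drop = FALSE]
  out$pval_exp <- ms$pval_exp[idx, , drop = FALSE]
  out$beta_out <- ms$beta_out[idx]
  out$se_out <- ms$se_out[idx]
  out
}
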