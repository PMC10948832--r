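#' @title Single-variable two-sample MR estimators
#' @description Wald ratio, inverse-variance weighted, Egger regression and
#'   weighted-median estimators with Cochran's Q heterogeneity and
#'   Egger-intercept pleiotropy diagnostics.
#' @name svmr
NULL

.new_mr_estimate <- function(method, n_snp, beta, se, q = NA_real_,
                             q_df = NA_real_, extra = list(),
                             exposure = "exposure", outcome = "outcome") {
  ci <- beta + c(-1, 1) * stats::qnorm(0.975) * se
  est <- c(list(
    method = method, n_snp = n_snp, beta = beta, se = se,
    ci_low = ci[1], ci_high = ci[2],
    pvalue = 2 * stats::pnorm(-abs(beta / se)),
    or_point = exp(beta), or_low = exp(ci[1]), or_high = exp(ci[2]),
    q = q, q_df = q_df,
    q_p = if (is.na(q)) NA_real_ else stats::pchisq(q, q_df, lower.tail = FALSE),
    exposure = exposure, outcome = outcome
  ), extra)
  class(est) <- "mr_estimate"
  est
}

#' @export
print.mr_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("MR estimate (%s), %s -> %s\n", x$method, x$exposure, x$outcome))
  cat(sprintf("  nSNP %d  beta %.*f (SE %.*f)  OR %.*f [%.*f-%.*f]  p %.4g\n",
              x$n_snp, digits, x$beta, digits, x$se, digits, x$or_point,
              digits, x$or_low, digits, x$or_high, x$pvalue))
  if (!is.na(x$q)) {
    cat(sprintf("  Cochran Q %.4g on %d df (p %.4g)\n", x$q, x$q_df, x$q_p))
  }
  if (!is.null(x$egger_intercept)) {
    cat(sprintf("  Egger intercept %.4g (SE %.4g, p %.4g)\n",
                x$egger_intercept, x$egger_intercept_se,
                x$egger_intercept_p))
  }
  invisible(x)
}

#' @export
coef.mr_estimate <- function(object, ...) {
  stats::setNames(object$beta, object$method)
}

#' @export
confint.mr_estimate <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- matrix(object$beta + c(-1, 1) * z * object$se, nrow = 1,
              dimnames = list(object$method,
                              sprintf("%g %%", c((1 - level) / 2,
                                                 1 - (1 - level) / 2) * 100)))
  m
}

#' @export
summary.mr_estimate <- function(object, ...) {
  structure(object, class = c("summary.mr_estimate", "mr_estimate"))
}

#' @export
print.summary.mr_estimate <- function(x, ...) {
  print.mr_estimate(x, ...)
  cat(sprintf("  z = %.4f, two-sided normal p = %.4g\n",
              x$beta / x$se, x$pvalue))
  invisible(x)
}

#' Wald ratio estimate from a single instrument
#'
#' The causal effect from one variant: `beta_out / beta_exp`, with the
#' first-order delta-method standard error `se_out / |beta_exp|`.
#'
#' @param hp a `harmonized_pair` with exactly one instrument.
#' @return an `mr_estimate` with `method = "wald"`.
#' @export
wald_ratio <- function(hp) {
  stopifnot(inherits(hp, "harmonized_pair"))
  if (length(hp$snp_ids) != 1L) {
    stop("wald_ratio requires exactly one instrument", call. = FALSE)
  }
  if (hp$beta_exp == 0) {
    stop("undefined ratio: instrument-exposure effect is zero",
         call. = FALSE)
  }
  .new_mr_estimate("wald", 1L,
                   beta = hp$beta_out / hp$beta_exp,
                   se = hp$se_out / abs(hp$beta_exp),
                   exposure = hp$exposure_name, outcome = hp$outcome_name)
}

#' Inverse-variance weighted estimate
#'
#' Weighted least squares of the instrument-outcome effects on the
#' instrument-exposure effects through the origin with weights
#' `1/se_out^2` — the classical combination of per-variant Wald ratios.
#' Under the multiplicative random-effects model the standard error is
#' inflated by `max(1, sqrt(Q/(J-1)))`.
#'
#' @param hp a `harmonized_pair` with at least 2 instruments (one
#'   instrument falls back to [wald_ratio()] with a message).
#' @param effects_model `"multiplicative_random"` (default) or `"fixed"`.
#' @return an `mr_estimate` with `method = "ivw_re"` or `"ivw_fe"`.
#' @export
mr_ivw <- function(hp, effects_model = c("multiplicative_random", "fixed")) {
  stopifnot(inherits(hp, "harmonized_pair"))
  effects_model <- match.arg(effects_model)
  J <- length(hp$snp_ids)
  if (J < 2L) {
    message("single instrument: returning Wald ratio")
    return(wald_ratio(hp))
  }
  g <- hp$beta_exp; G <- hp$beta_out; w <- 1 / hp$se_out^2
  beta <- sum(w * g * G) / sum(w * g^2)
  se_fixed <- sqrt(1 / sum(w * g^2))
  q <- sum(w * (G - beta * g)^2)
  q_df <- J - 1L
  se <- if (effects_model == "multiplicative_random") {
    se_fixed * max(1, sqrt(q / q_df))
  } else se_fixed
  .new_mr_estimate(
    if (effects_model == "fixed") "ivw_fe" else "ivw_re",
    J, beta, se, q = q, q_df = q_df,
    exposure = hp$exposure_name, outcome = hp$outcome_name)
}

#' Egger regression estimate
#'
#' Weighted regression of instrument-outcome effects on
#' instrument-exposure effects with a free intercept, after re-orienting
#' every instrument to a non-negative exposure effect. The slope is the
#' causal estimate; a non-zero intercept indicates directional horizontal
#' pleiotropy. Standard errors carry the multiplicative random-effects
#' inflation `max(1, sqrt(Q'/(J-2)))`.
#'
#' @param hp a `harmonized_pair` with at least 3 instruments.
#' @return an `mr_estimate` with `method = "egger"` and intercept fields.
#' @export
mr_egger <- function(hp) {
  stopifnot(inherits(hp, "harmonized_pair"))
  J <- length(hp$snp_ids)
  if (J < 3L) stop("Egger regression needs at least 3 instruments",
                   call. = FALSE)
  s <- sign(hp$beta_exp); s[s == 0] <- 1
  g <- s * hp$beta_exp; G <- s * hp$beta_out
  w <- 1 / hp$se_out^2
  # weighted normal equations for (intercept, slope)
  sw <- sum(w); swx <- sum(w * g); swx2 <- sum(w * g^2)
  swy <- sum(w * G); swxy <- sum(w * g * G)
  det <- sw * swx2 - swx^2
  if (det <= 0) stop("degenerate design in Egger regression", call. = FALSE)
  a <- (swx2 * swy - swx * swxy) / det
  b <- (sw * swxy - swx * swy) / det
  q <- sum(w * (G - a - b * g)^2)
  q_df <- J - 2L
  infl <- max(1, sqrt(q / q_df))
  se_b <- sqrt(sw / det) * infl
  se_a <- sqrt(swx2 / det) * infl
  .new_mr_estimate("egger", J, b, se_b, q = q, q_df = q_df,
                   extra = list(
                     egger_intercept = a, egger_intercept_se = se_a,
                     egger_intercept_p = 2 * stats::pnorm(-abs(a / se_a))),
                   exposure = hp$exposure_name, outcome = hp$outcome_name)
}

# Point estimate of the weighted median of Wald ratios: linear
# interpolation of the weighted empirical CDF (midpoint convention) at 0.5.
.weighted_median_point <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]; w <- weights[ord] / sum(weights)
  p <- cumsum(w) - w / 2
  if (p[1] >= 0.5) return(r[1])
  if (p[length(p)] <= 0.5) return(r[length(r)])
  stats::approx(p, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median estimate
#'
#' Orders the per-variant Wald ratios and takes the weighted median with
#' weights proportional to `beta_exp^2 / se_out^2`, interpolating the
#' weighted empirical CDF at one half. Consistent when at least half of
#' the weight comes from valid instruments. The standard error is a
#' parametric bootstrap: exposure and outcome effects are resampled from
#' their normal sampling distributions and the estimate recomputed.
#'
#' @param hp a `harmonized_pair` with at least 3 instruments.
#' @param n_boot bootstrap replicates for the SE (default 1000; 0 skips
#'   the bootstrap and returns `se = NA`).
#' @param seed integer seed for the bootstrap.
#' @return an `mr_estimate` with `method = "weighted_median"`.
#' @export
mr_weighted_median <- function(hp, n_boot = 1000, seed = 1) {
  stopifnot(inherits(hp, "harmonized_pair"))
  J <- length(hp$snp_ids)
  if (J < 3L) stop("weighted median needs at least 3 instruments",
                   call. = FALSE)
  ratios <- hp$beta_out / hp$beta_exp
  weights <- hp$beta_exp^2 / hp$se_out^2
  beta <- .weighted_median_point(ratios, weights)
  se <- NA_real_
  if (n_boot > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    bs <- vapply(seq_len(n_boot), function(b) {
      gb <- stats::rnorm(J, hp$beta_exp, hp$se_exp)
      Gb <- stats::rnorm(J, hp$beta_out, hp$se_out)
      .weighted_median_point(Gb / gb, gb^2 / hp$se_out^2)
    }, numeric(1))
    se <- stats::sd(bs)
  }
  est <- .new_mr_estimate("weighted_median", J, beta,
                          if (is.na(se)) 1 else se,
                          exposure = hp$exposure_name,
                          outcome = hp$outcome_name)
  if (is.na(se)) {
    est$se <- est$ci_low <- est$ci_high <- est$pvalue <- NA_real_
    est$or_low <- est$or_high <- NA_real_
  }
  est$n_boot <- n_boot
  est$seed <- seed
  est
}

#' Cochran's Q heterogeneity statistic
#'
#' Weighted residual heterogeneity of the instrument-outcome effects
#' around a fitted causal slope: `Q = sum(w_j (beta_out_j - beta *
#' beta_exp_j)^2)` with `w_j = 1/se_out_j^2`.
#'
#' @param hp a `harmonized_pair` with at least 2 instruments.
#' @param beta the causal estimate to evaluate residuals against.
#' @param q_df degrees of freedom (default `J - 1`, the IVW convention;
#'   use `J - 2` after Egger regression).
#' @return list with `q`, `q_df`, `q_p`.
#' @export
cochran_q <- function(hp, beta, q_df = length(hp$snp_ids) - 1L) {
  stopifnot(inherits(hp, "harmonized_pair"), length(hp$snp_ids) >= 2L)
  w <- 1 / hp$se_out^2
  q <- sum(w * (hp$beta_out - beta * hp$beta_exp)^2)
  list(q = q, q_df = q_df,
       q_p = stats::pchisq(q, q_df, lower.tail = FALSE))
}

#' Leave-one-out sensitivity estimates
#'
#' Recomputes the IVW estimate J times, omitting one instrument each time.
#'
#' @param hp a `harmonized_pair` with at least 3 instruments.
#' @param effects_model passed to [mr_ivw()].
#' @return named list of `mr_estimate` objects, one per omitted variant.
#' @export
mr_leave_one_out <- function(hp,
                             effects_model = c("multiplicative_random",
                                               "fixed")) {
  stopifnot(inherits(hp, "harmonized_pair"))
  effects_model <- match.arg(effects_model)
  J <- length(hp$snp_ids)
  if (J < 3L) stop("leave-one-out needs at least 3 instruments",
                   call. = FALSE)
  out <- lapply(seq_len(J), function(j) {
    mr_ivw(subset_pair(hp, setdiff(seq_len(J), j)), effects_model)
  })
  names(out) <- hp$snp_ids
  out
}

#' Format an estimate as an odds-ratio triple
#'
#' Exponentiates the effect and its Wald CI bounds and rounds half-even.
#' For Wald-type (log-symmetric) intervals the OR equals the geometric
#' mean of its CI bounds, a consistency property used to audit reported
#' results.
#'
#' @param est an `mr_estimate`.
#' @param decimals decimal places (default 4).
#' @return named numeric vector `or`, `or_low`, `or_high`, `pvalue`.
#' @export
estimate_to_or <- function(est, decimals = 4) {
  stopifnot(inherits(est, "mr_estimate"))
  c(or = round(exp(est$beta), decimals),
    or_low = round(exp(est$ci_low), decimals),
    or_high = round(exp(est$ci_high), decimals),
    pvalue = round(est$pvalue, decimals))
}
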