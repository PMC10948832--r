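#' @title Instrument selection
#' @description Significance screening, greedy LD clumping, instrument
#'   strength (F) statistics and simulation-based pleiotropic-outlier
#'   detection.
#' @name instruments
NULL

#' Genome-wide significance screen
#'
#' Retains variants with association p-value below the threshold — the
#' relevance requirement for instrumental variables.
#'
#' @param ds a `summary_dataset`.
#' @param p_threshold significance threshold (default 5e-8).
#' @return the filtered `summary_dataset`, input order preserved.
#' @export
significance_screen <- function(ds, p_threshold = 5e-8) {
  stopifnot(inherits(ds, "summary_dataset"))
  keep <- !is.na(ds$pval) & ds$pval < p_threshold
  if (!any(keep)) {
    stop("no variant reaches p < ", format(p_threshold),
         "; no instruments available", call. = FALSE)
  }
  out <- ds[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("trait_name", "trait_type", "unit_label", "drop_log")) {
    attr(out, a) <- attr(ds, a)
  }
  class(out) <- class(ds)
  out
}

#' Greedy LD clumping
#'
#' Selects approximately independent index variants: candidates are ranked
#' by p-value ascending (ties broken by chromosome, position, then id) and
#' accepted greedily when their squared correlation with every previously
#' accepted variant is below `r2_threshold`. LD is consulted only within
#' `window_kb` kilobases on the same chromosome; variants farther apart, on
#' different chromosomes, or with unknown position are compared on r2 alone
#' when both are present in `ld`. Candidates absent from `ld` are treated
#' as independent and logged (set `strict = TRUE` to drop them instead).
#'
#' @param ds a `summary_dataset` of candidate instruments.
#' @param ld an [ld_matrix()] covering the candidates (or a subset).
#' @param r2_threshold maximum pairwise r2 among kept variants
#'   (default 0.001).
#' @param window_kb physical window in kb within which LD applies
#'   (default 10000).
#' @param strict drop candidates missing from `ld` instead of assuming
#'   independence.
#' @return an `instrument_selection`: list with `kept` (ids in acceptance
#'   order), `removed` (data.frame `snp`, `stage`, `reason`), and
#'   `warnings`.
#' @export
ld_clump <- function(ds, ld = NULL, r2_threshold = 0.001, window_kb = 10000,
                     strict = FALSE) {
  stopifnot(inherits(ds, "summary_dataset"))
  in_ld <- if (is.null(ld)) rep(FALSE, nrow(ds)) else ds$snp %in% rownames(ld)
  warnings <- character(0)
  removed <- data.frame(snp = character(0), stage = character(0),
                        reason = character(0), stringsAsFactors = FALSE)
  cand <- ds
  if (any(!in_ld)) {
    if (strict) {
      removed <- rbind(removed, data.frame(
        snp = ds$snp[!in_ld], stage = "clump", reason = "absent_from_ld",
        stringsAsFactors = FALSE))
      cand <- ds[in_ld, , drop = FALSE]
      in_ld <- rep(TRUE, nrow(cand))
    } else {
      warnings <- sprintf(
        "%d candidate(s) absent from LD matrix assumed independent",
        sum(!in_ld))
    }
  }
  ord <- order(cand$pval, cand$chr, cand$pos, cand$snp)
  cand <- cand[ord, , drop = FALSE]
  in_ld <- (cand$snp %in% rownames(ld))
  kept <- character(0)
  kept_idx <- integer(0)
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    for (j in kept_idx) {
      chr_known <- !is.na(cand$chr[i]) && !is.na(cand$chr[j])
      if (chr_known && cand$chr[i] != cand$chr[j]) next
      within <- if (chr_known && !is.na(cand$pos[i]) && !is.na(cand$pos[j])) {
        abs(cand$pos[i] - cand$pos[j]) <= window_kb * 1000
      } else {
        # no physical coordinates: rely on the LD matrix alone
        TRUE
      }
      if (!within) next
      r2 <- if (in_ld[i] && in_ld[j]) ld[cand$snp[i], cand$snp[j]] else 0
      if (r2 >= r2_threshold) {
        ok <- FALSE
        removed <- rbind(removed, data.frame(
          snp = cand$snp[i], stage = "clump",
          reason = sprintf("r2=%.4g_with_%s", r2, cand$snp[j]),
          stringsAsFactors = FALSE))
        break
      }
    }
    if (ok) { kept <- c(kept, cand$snp[i]); kept_idx <- c(kept_idx, i) }
  }
  structure(list(kept = kept, removed = removed, warnings = warnings,
                 r2_threshold = r2_threshold, window_kb = window_kb),
            class = "instrument_selection")
}

#' @export
print.instrument_selection <- function(x, ...) {
  cat(sprintf("Instrument selection: %d kept, %d removed (r2 < %g)\n",
              length(x$kept), nrow(x$removed), x$r2_threshold))
  for (w in x$warnings) cat("  note:", w, "\n")
  invisible(x)
}

#' Instrument strength (F) statistics
#'
#' Per-instrument F approximated by the squared exposure z-score
#' `(beta_exp / se_exp)^2`; mean F below 10 conventionally signals weak
#' instruments.
#'
#' @param hp a `harmonized_pair`.
#' @return list with `per_snp_f` (named vector) and `mean_f`.
#' @export
f_statistics <- function(hp) {
  stopifnot(inherits(hp, "harmonized_pair"))
  f <- (hp$beta_exp / hp$se_exp)^2
  names(f) <- hp$snp_ids
  list(per_snp_f = f, mean_f = mean(f))
}

#' Simulation-based pleiotropic-outlier detection
#'
#' For each instrument j the leave-one-out IVW estimate is computed and the
#' weighted residual of j against it taken; the observed residual sum of
#' squares is compared against `n_sim` parametric simulations of the
#' outcome effects under the no-pleiotropy null to give a global
#' heterogeneity p-value, and each instrument's residual exceedance gives a
#' per-variant outlier p-value (Bonferroni-adjusted over J). Instruments
#' with adjusted p below `alpha` are flagged for removal.
#'
#' @param hp a `harmonized_pair` with at least 4 instruments.
#' @param n_sim number of null simulations (>= 100; default 1000).
#' @param alpha flagging level on the adjusted per-variant p (default 0.05).
#' @param seed integer seed making the report reproducible.
#' @return an `outlier_report`: list with `global_rss`, `global_p`,
#'   `outlier_p` (raw), `outlier_p_adj`, `flagged`, `n_sim`, `seed`.
#' @export
presso_outliers <- function(hp, n_sim = 1000, alpha = 0.05, seed = 1) {
  stopifnot(inherits(hp, "harmonized_pair"))
  J <- length(hp$snp_ids)
  if (J < 4L) stop("outlier detection needs at least 4 instruments",
                   call. = FALSE)
  if (n_sim < 100L) stop("n_sim must be at least 100", call. = FALSE)
  g <- hp$beta_exp; G <- hp$beta_out; so <- hp$se_out
  w <- 1 / so^2
  # leave-one-out IVW via running sums
  s_num <- sum(w * g * G); s_den <- sum(w * g^2)
  theta_loo <- (s_num - w * g * G) / (s_den - w * g^2)
  mu <- theta_loo * g                     # null expectation for each Gamma_j
  resid_obs <- G - mu
  rss_obs <- sum(w * resid_obs^2)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  # simulate Gamma* under the null; recompute LOO residual RSS per replicate
  Gs <- matrix(stats::rnorm(J * n_sim, mean = mu, sd = so), nrow = J)
  s_num_s <- colSums(w * g * Gs)
  theta_loo_s <- (matrix(s_num_s, J, n_sim, byrow = TRUE) - (w * g) * Gs) /
    (s_den - w * g^2)
  resid_s <- Gs - theta_loo_s * g
  rss_s <- colSums(w * resid_s^2)
  global_p <- (1 + sum(rss_s >= rss_obs)) / (n_sim + 1)

  wr2_obs <- w * resid_obs^2
  wr2_s <- w * resid_s^2
  outlier_p <- (1 + rowSums(wr2_s >= wr2_obs)) / (n_sim + 1)
  outlier_p_adj <- pmin(1, outlier_p * J)
  flagged <- hp$snp_ids[outlier_p_adj < alpha]
  names(outlier_p) <- names(outlier_p_adj) <- hp$snp_ids
  structure(list(global_rss = rss_obs, global_p = global_p,
                 outlier_p = outlier_p, outlier_p_adj = outlier_p_adj,
                 flagged = flagged, n_sim = n_sim, seed = seed),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("Pleiotropy outlier report: global RSS %.4g, global p %.4g\n",
              x$global_rss, x$global_p))
  if (length(x$flagged)) {
    cat("  flagged:", paste(x$flagged, collapse = ", "), "\n")
  } else {
    cat("  no instruments flagged\n")
  }
  invisible(x)
}

# Preserve the caller's RNG state around internally seeded procedures.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
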