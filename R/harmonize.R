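#' @title Allele harmonization
#' @description Orient exposure and outcome summary statistics to a shared
#'   effect allele per variant, resolving allele swaps, strand flips and
#'   palindromic ambiguity.
#' @name harmonize
NULL

.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

.is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
  (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

# Orient one outcome record onto the exposure allele pair.
# Returns list(action, flip): flip means negate outcome beta / complement eaf.
.orient_one <- function(e1, o1, e2, o2, eaf1, eaf2, window) {
  if (.is_palindromic(e1, o1)) {
    # alleles cannot distinguish strand; use allele frequency if decisive
    if (is.na(eaf1) || is.na(eaf2)) {
      return(list(action = "dropped_palindromic", flip = FALSE))
    }
    if (min(eaf1, 1 - eaf1) > window || min(eaf2, 1 - eaf2) > window) {
      return(list(action = "dropped_palindromic", flip = FALSE))
    }
    if (!((e2 == e1 && o2 == o1) || (e2 == o1 && o2 == e1))) {
      return(list(action = "dropped_mismatch", flip = FALSE))
    }
    same_side <- (eaf1 < 0.5) == (eaf2 < 0.5)
    return(list(action = "kept", flip = !same_side))
  }
  if (e2 == e1 && o2 == o1) return(list(action = "kept", flip = FALSE))
  if (e2 == o1 && o2 == e1) return(list(action = "flipped", flip = TRUE))
  ce2 <- .COMPLEMENT[[e2]]; co2 <- .COMPLEMENT[[o2]]
  if (ce2 == e1 && co2 == o1) {
    return(list(action = "strand_corrected", flip = FALSE))
  }
  if (ce2 == o1 && co2 == e1) {
    return(list(action = "strand_corrected", flip = TRUE))
  }
  list(action = "dropped_mismatch", flip = FALSE)
}

#' Harmonize an exposure/outcome pair of summary datasets
#'
#' For every variant shared between the two datasets the outcome association
#' is oriented onto the exposure's effect allele: identical allele pairs are
#' kept, swapped pairs flip the outcome beta (and complement its frequency),
#' complementary-strand pairs are strand-corrected first, and palindromic
#' variants (A/T, C/G) are resolved from allele frequencies when those are
#' decisive and dropped otherwise. Variants absent from the outcome are
#' dropped with action `dropped_missing`.
#'
#' @param exposure,outcome `summary_dataset` objects.
#' @param palindrome_eaf_window palindromic variants with
#'   `min(eaf, 1 - eaf)` above this value on either side are treated as
#'   unresolvable and dropped (default 0.42).
#' @return a `harmonized_pair`: list with `snp_ids`, `beta_exp`, `se_exp`,
#'   `pval_exp`, `eaf_exp`, `beta_out`, `se_out`, and an `actions`
#'   data.frame recording one action code per shared variant. Kept variants
#'   are ordered by exposure p-value ascending.
#' @export
harmonize_pair <- function(exposure, outcome, palindrome_eaf_window = 0.42) {
  stopifnot(inherits(exposure, "summary_dataset"),
            inherits(outcome, "summary_dataset"))
  shared <- intersect(exposure$snp, outcome$snp)
  if (length(shared) == 0L) {
    stop("no overlapping variants between exposure and outcome",
         call. = FALSE)
  }
  all_exp_snps <- exposure$snp
  ie <- match(all_exp_snps, exposure$snp)
  io <- match(all_exp_snps, outcome$snp)

  action <- character(length(all_exp_snps))
  flip <- logical(length(all_exp_snps))
  for (k in seq_along(all_exp_snps)) {
    if (is.na(io[k])) { action[k] <- "dropped_missing"; next }
    r <- .orient_one(exposure$effect_allele[ie[k]], exposure$other_allele[ie[k]],
                     outcome$effect_allele[io[k]], outcome$other_allele[io[k]],
                     exposure$eaf[ie[k]], outcome$eaf[io[k]],
                     palindrome_eaf_window)
    action[k] <- r$action
    flip[k] <- r$flip
  }
  kept <- !startsWith(action, "dropped")
  if (!any(kept)) {
    stop("no variants survive harmonization", call. = FALSE)
  }
  sgn <- ifelse(flip[kept], -1, 1)
  hp <- list(
    snp_ids  = all_exp_snps[kept],
    beta_exp = exposure$beta[ie[kept]],
    se_exp   = exposure$se[ie[kept]],
    pval_exp = exposure$pval[ie[kept]],
    eaf_exp  = exposure$eaf[ie[kept]],
    beta_out = sgn * outcome$beta[io[kept]],
    se_out   = outcome$se[io[kept]],
    actions  = data.frame(snp = all_exp_snps, action = action,
                          stringsAsFactors = FALSE),
    exposure_name = attr(exposure, "trait_name"),
    outcome_name  = attr(outcome, "trait_name")
  )
  ord <- order(hp$pval_exp, hp$snp_ids)
  for (f in c("snp_ids", "beta_exp", "se_exp", "pval_exp", "eaf_exp",
              "beta_out", "se_out")) {
    hp[[f]] <- hp[[f]][ord]
  }
  structure(hp, class = "harmonized_pair")
}

#' @export
print.harmonized_pair <- function(x, ...) {
  cat(sprintf("Harmonized pair: %s -> %s\n", x$exposure_name, x$outcome_name))
  tab <- table(x$actions$action)
  cat(sprintf("  %d instrument(s) kept; actions: %s\n", length(x$snp_ids),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Subset a harmonized pair by variant
#' @param hp a `harmonized_pair`.
#' @param keep logical, integer or character index of variants to retain.
#' @return a `harmonized_pair` restricted to the selected variants.
#' @export
subset_pair <- function(hp, keep) {
  stopifnot(inherits(hp, "harmonized_pair"))
  if (is.character(keep)) keep <- match(keep, hp$snp_ids)
  for (f in c("snp_ids", "beta_exp", "se_exp", "pval_exp", "eaf_exp",
              "beta_out", "se_out")) {
    hp[[f]] <- hp[[f]][keep]
  }
  hp
}

#' Assemble a multi-exposure instrument set
#'
#' Harmonizes `K >= 2` exposure datasets and one outcome dataset onto the
#' allele orientation of the first exposure, retaining only variants present
#' and orientable in every dataset, for multivariable MR and Bayesian model
#' averaging.
#'
#' @param exposures list of `summary_dataset` objects (K >= 2).
#' @param outcome a `summary_dataset`.
#' @param palindrome_eaf_window as in [harmonize_pair()].
#' @param snp_ids optional restriction to a pre-selected instrument list
#'   (e.g. from [joint_clump_for_bma()]).
#' @return a `multi_exposure_set`: list with `snp_ids` (J), `beta_exp` and
#'   `se_exp` (J x K matrices), `beta_out`, `se_out` (J vectors),
#'   `exposure_names`, and `pval_exp` (J x K).
#' @export
harmonize_multi <- function(exposures, outcome, palindrome_eaf_window = 0.42,
                            snp_ids = NULL) {
  K <- length(exposures)
  stopifnot(K >= 2L, inherits(outcome, "summary_dataset"))
  ref <- exposures[[1L]]
  # orient every dataset (other exposures and the outcome) onto exposure 1
  pairs <- vector("list", K)
  pairs[[1L]] <- NULL
  shared <- ref$snp
  if (!is.null(snp_ids)) shared <- intersect(shared, snp_ids)
  aligned <- list()
  for (k in 2:K) {
    hk <- harmonize_pair(ref, exposures[[k]], palindrome_eaf_window)
    aligned[[k]] <- hk
    shared <- intersect(shared, hk$snp_ids)
  }
  hout <- harmonize_pair(ref, outcome, palindrome_eaf_window)
  shared <- intersect(shared, hout$snp_ids)
  if (length(shared) < K + 1L) {
    stop("under-identified: only ", length(shared),
         " variant(s) survive joint harmonization (need > K = ", K, ")",
         call. = FALSE)
  }
  iref <- match(shared, ref$snp)
  J <- length(shared)
  beta_exp <- matrix(NA_real_, J, K)
  se_exp <- matrix(NA_real_, J, K)
  pval_exp <- matrix(NA_real_, J, K)
  beta_exp[, 1L] <- ref$beta[iref]
  se_exp[, 1L] <- ref$se[iref]
  pval_exp[, 1L] <- ref$pval[iref]
  for (k in 2:K) {
    ik <- match(shared, aligned[[k]]$snp_ids)
    beta_exp[, k] <- aligned[[k]]$beta_out[ik]
    se_exp[, k] <- aligned[[k]]$se_out[ik]
    pval_exp[, k] <- 2 * stats::pnorm(-abs(beta_exp[, k] / se_exp[, k]))
  }
  iout <- match(shared, hout$snp_ids)
  nm <- vapply(exposures, function(d) attr(d, "trait_name"), character(1))
  structure(list(
    snp_ids = shared,
    beta_exp = beta_exp, se_exp = se_exp, pval_exp = pval_exp,
    beta_out = hout$beta_out[iout], se_out = hout$se_out[iout],
    exposure_names = nm,
    outcome_name = attr(outcome, "trait_name")
  ), class = "multi_exposure_set")
}

#' Construct a multi-exposure set from matrices
#'
#' Low-level constructor for simulation and testing: wraps pre-aligned
#' effect matrices directly without allele bookkeeping.
#'
#' @param beta_exp J x K exposure-effect matrix.
#' @param se_exp J x K matrix of standard errors.
#' @param beta_out,se_out outcome effect vector and standard errors (J).
#' @param snp_ids,exposure_names identifiers (defaults generated).
#' @return a `multi_exposure_set`.
#' @export
multi_exposure_set <- function(beta_exp, se_exp, beta_out, se_out,
                               snp_ids = NULL, exposure_names = NULL) {
  beta_exp <- as.matrix(beta_exp); se_exp <- as.matrix(se_exp)
  J <- nrow(beta_exp); K <- ncol(beta_exp)
  stopifnot(all(dim(se_exp) == c(J, K)), length(beta_out) == J,
            length(se_out) == J, all(se_out > 0), all(se_exp > 0))
  if (J <= K) stop("under-identified: J must exceed K", call. = FALSE)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(J))
  if (is.null(exposure_names)) exposure_names <- paste0("exposure", seq_len(K))
  structure(list(
    snp_ids = snp_ids, beta_exp = beta_exp, se_exp = se_exp,
    pval_exp = 2 * stats::pnorm(-abs(beta_exp / se_exp)),
    beta_out = as.numeric(beta_out), se_out = as.numeric(se_out),
    exposure_names = exposure_names, outcome_name = "outcome"
  ), class = "multi_exposure_set")
}

#' @export
print.multi_exposure_set <- function(x, ...) {
  cat(sprintf("Multi-exposure instrument set: %d variant(s) x %d exposure(s) -> %s\n",
              length(x$snp_ids), length(x$exposure_names), x$outcome_name))
  cat("  exposures:", paste(x$exposure_names, collapse = ", "), "\n")
  invisible(x)
}

#' Construct a harmonized pair from vectors
#'
#' Low-level constructor for pre-aligned effect vectors (simulation,
#' testing, or externally harmonized data).
#'
#' @param beta_exp,se_exp instrument-exposure effects and standard errors.
#' @param beta_out,se_out instrument-outcome effects and standard errors.
#' @param snp_ids optional identifiers.
#' @return a `harmonized_pair`.
#' @export
harmonized_pair <- function(beta_exp, se_exp, beta_out, se_out,
                            snp_ids = NULL) {
  J <- length(beta_exp)
  stopifnot(length(se_exp) == J, length(beta_out) == J, length(se_out) == J,
            all(se_exp > 0), all(se_out > 0), J >= 1L)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(J))
  structure(list(
    snp_ids = snp_ids,
    beta_exp = as.numeric(beta_exp), se_exp = as.numeric(se_exp),
    pval_exp = 2 * stats::pnorm(-abs(beta_exp / se_exp)),
    eaf_exp = rep(NA_real_, J),
    beta_out = as.numeric(beta_out), se_out = as.numeric(se_out),
    actions = data.frame(snp = snp_ids, action = "kept",
                         stringsAsFactors = FALSE),
    exposure_name = "exposure", outcome_name = "outcome"
  ), class = "harmonized_pair")
}
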