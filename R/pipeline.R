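#' @title Study orchestration
#' @description The full study design: a single-variable MR screen of every
#'   exposure against every outcome, multivariable adjustment of the
#'   outcomes flagged by the screen, fixed-effect meta-analysis across
#'   cohorts, and report rendering with a complete audit trail.
#' @name pipeline
NULL

#' Read a study configuration
#'
#' Loads a YAML study configuration: exposure and outcome file paths with
#' labels, the LD matrix path, module thresholds, seed and output
#' directory. Unspecified thresholds take the package defaults.
#'
#' @param path YAML file path.
#' @return a `study_config` list.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  study_config(
    exposures = raw$exposures, outcomes = raw$outcomes,
    validation_outcomes = raw$validation_outcomes, ld = raw$ld,
    thresholds = raw$thresholds, seed = raw$seed %||% 1L,
    out_dir = raw$out_dir %||% "."
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a study configuration
#'
#' @param exposures named list/vector of exposure summary-statistics
#'   paths, or a named list of `summary_dataset` objects.
#' @param outcomes discovery outcomes, same form.
#' @param validation_outcomes optional validation-cohort outcomes.
#' @param ld LD matrix path or an `ld_matrix`.
#' @param thresholds named list overriding any of: `screen_p` (5e-8),
#'   `clump_r2` (0.001), `clump_kb` (10000), `palindrome_window` (0.42),
#'   `effects_model` ("multiplicative_random"), `n_sim` (1000), `n_boot`
#'   (1000), `outlier_alpha` (0.05), `prior_inclusion` (0.1), `g` (NULL =
#'   J), `pp_threshold` (0.02), `svmr_gate` (0.05).
#' @param seed integer seed.
#' @param out_dir output directory.
#' @return a `study_config`.
#' @export
study_config <- function(exposures, outcomes, validation_outcomes = NULL,
                         ld = NULL, thresholds = list(), seed = 1L,
                         out_dir = ".") {
  defaults <- list(screen_p = 5e-8, clump_r2 = 0.001, clump_kb = 10000,
                   palindrome_window = 0.42,
                   effects_model = "multiplicative_random",
                   n_sim = 1000, n_boot = 1000, outlier_alpha = 0.05,
                   prior_inclusion = 0.1, g = NULL, pp_threshold = 0.02,
                   svmr_gate = 0.05)
  if (length(thresholds)) {
    unknown <- setdiff(names(thresholds), names(defaults))
    if (length(unknown)) stop("unknown threshold(s): ",
                              paste(unknown, collapse = ", "),
                              call. = FALSE)
    defaults[names(thresholds)] <- thresholds
  }
  stopifnot(defaults$screen_p > 0, defaults$screen_p <= 1,
            defaults$clump_r2 >= 0, defaults$clump_r2 <= 1,
            defaults$svmr_gate > 0, defaults$svmr_gate <= 1)
  structure(list(exposures = exposures, outcomes = outcomes,
                 validation_outcomes = validation_outcomes, ld = ld,
                 thresholds = defaults, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "study_config")
}

.load_ds <- function(x, name, trait_type = "continuous") {
  if (inherits(x, "summary_dataset")) {
    attr(x, "trait_name") <- name   # config labels win over stored names
    return(x)
  }
  read_sumstats(x, trait_name = name, trait_type = trait_type)
}

.load_named_list <- function(lst, trait_type) {
  if (is.null(names(lst)) || any(names(lst) == "")) {
    names(lst) <- paste0(trait_type, seq_along(lst))
  }
  out <- lapply(names(lst), function(nm) {
    .load_ds(lst[[nm]], nm, trait_type)
  })
  names(out) <- names(lst)
  out
}

# one exposure x outcome analysis: screen, clump, harmonize, outliers,
# estimators. Returns list(rows = data.frame, log = data.frame) or an error
# condition caught by the caller.
.analyse_pair <- function(exp_ds, out_ds, ld, th, seed) {
  logs <- list()
  note <- function(snp, stage, reason) {
    logs[[length(logs) + 1L]] <<- data.frame(
      snp = snp, stage = stage, reason = reason, stringsAsFactors = FALSE)
  }
  inst <- significance_screen(exp_ds, th$screen_p)
  dropped <- setdiff(exp_ds$snp, inst$snp)
  if (length(dropped)) note(dropped, "screen", "above_threshold")
  sel <- ld_clump(inst, ld, th$clump_r2, th$clump_kb)
  if (nrow(sel$removed)) {
    logs[[length(logs) + 1L]] <- sel$removed
  }
  inst <- inst[inst$snp %in% sel$kept, , drop = FALSE]
  class(inst) <- class(exp_ds)
  hp <- harmonize_pair(inst, out_ds, th$palindrome_window)
  acts <- hp$actions
  dr <- acts[startsWith(acts$action, "dropped"), , drop = FALSE]
  if (nrow(dr)) note(dr$snp, "harmonize", dr$action)
  flagged <- character(0)
  if (length(hp$snp_ids) >= 4L) {
    rep <- presso_outliers(hp, n_sim = th$n_sim, alpha = th$outlier_alpha,
                           seed = seed)
    flagged <- rep$flagged
    if (length(flagged)) {
      note(flagged, "outlier", "pleiotropic_outlier")
      hp <- subset_pair(hp, setdiff(seq_along(hp$snp_ids),
                                    match(flagged, hp$snp_ids)))
    }
  }
  J <- length(hp$snp_ids)
  ests <- list()
  if (J == 1L) {
    ests$wald <- wald_ratio(hp)
  } else {
    ests$ivw <- mr_ivw(hp, th$effects_model)
    if (J >= 3L) {
      ests$egger <- mr_egger(hp)
      ests$weighted_median <- mr_weighted_median(hp, n_boot = th$n_boot,
                                                 seed = seed)
    }
  }
  fstat <- f_statistics(hp)
  rows <- do.call(rbind, lapply(ests, function(e) {
    data.frame(
      exposure = attr(exp_ds, "trait_name"),
      outcome = attr(out_ds, "trait_name"),
      method = e$method, nsnp = length(hp$snp_ids),
      beta = e$beta, se = e$se,
      or = exp(e$beta), or_lo95 = exp(e$ci_low), or_hi95 = exp(e$ci_high),
      pval = e$pvalue, q = e$q, q_df = e$q_df, q_pval = e$q_p,
      egger_intercept = e$egger_intercept %||% NA_real_,
      egger_intercept_p = e$egger_intercept_p %||% NA_real_,
      mean_f = fstat$mean_f,
      stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  log_df <- if (length(logs)) do.call(rbind, logs) else
    data.frame(snp = character(0), stage = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  list(rows = rows, log = log_df, used = hp$snp_ids)
}

#' Run the single-variable MR screen
#'
#' For every exposure x outcome pair: significance screening, LD
#' clumping, harmonization, pleiotropic-outlier removal and all
#' applicable estimators (IVW; Egger and weighted median when at least 3
#' instruments remain; Wald ratio when one). Per-pair failures are logged
#' and skipped so the screen always completes.
#'
#' @param cfg a [study_config()].
#' @param outcome_group `"outcomes"` (discovery, default) or
#'   `"validation_outcomes"`.
#' @return an `svmr_screen`: list with `table` (one row per pair and
#'   method, `significant` flag and BH-adjusted IVW p column), `audit`
#'   (per-variant exclusion log), `skipped` (failed pairs with message).
#' @export
run_svmr_screen <- function(cfg, outcome_group = c("outcomes",
                                                   "validation_outcomes")) {
  stopifnot(inherits(cfg, "study_config"))
  outcome_group <- match.arg(outcome_group)
  th <- cfg$thresholds
  exposures <- .load_named_list(cfg$exposures, "continuous")
  outs_raw <- cfg[[outcome_group]]
  if (is.null(outs_raw) || length(outs_raw) == 0L) {
    warning("no outcomes configured; returning empty table",
            call. = FALSE)
    return(structure(list(table = data.frame(), audit = data.frame(),
                          skipped = data.frame()),
                     class = "svmr_screen"))
  }
  outcomes <- .load_named_list(outs_raw, "binary")
  ld <- cfg$ld
  if (is.character(ld)) ld <- read_ld_matrix(ld)
  rows <- list(); audits <- list(); skipped <- list()
  for (en in names(exposures)) for (on in names(outcomes)) {
    res <- tryCatch(
      .analyse_pair(exposures[[en]], outcomes[[on]], ld, th, cfg$seed),
      error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        exposure = en, outcome = on, reason = conditionMessage(res),
        stringsAsFactors = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- res$rows
    if (nrow(res$log)) {
      a <- res$log
      a$exposure <- en; a$outcome <- on
      audits[[length(audits) + 1L]] <- a
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else data.frame()
  if (nrow(tab)) {
    ivw_like <- tab$method %in% c("ivw_re", "ivw_fe", "wald")
    tab$significant <- ivw_like & tab$pval < th$svmr_gate
    tab$pval_bh <- NA_real_
    tab$pval_bh[ivw_like] <- stats::p.adjust(tab$pval[ivw_like],
                                             method = "BH")
  }
  structure(list(
    table = tab,
    audit = if (length(audits)) do.call(rbind, audits) else
      data.frame(snp = character(0), stage = character(0),
                 reason = character(0), exposure = character(0),
                 outcome = character(0), stringsAsFactors = FALSE),
    skipped = if (length(skipped)) do.call(rbind, skipped) else
      data.frame(exposure = character(0), outcome = character(0),
                 reason = character(0), stringsAsFactors = FALSE)
  ), class = "svmr_screen")
}

#' @export
print.svmr_screen <- function(x, ...) {
  cat(sprintf("Single-variable MR screen: %d result row(s), %d skipped pair(s)\n",
              nrow(x$table), nrow(x$skipped)))
  if (nrow(x$table)) {
    sig <- x$table[which(x$table$significant), c("exposure", "outcome",
                                                 "method", "or", "pval")]
    if (nrow(sig)) {
      cat("Flagged (IVW p below gate):\n"); print(sig, row.names = FALSE)
    } else cat("No pair flagged.\n")
  }
  invisible(x)
}

#' Run the multivariable MR adjustment
#'
#' For every outcome flagged by the single-variable screen the K exposures
#' are jointly harmonized (instruments pooled, jointly clumped) and
#' multivariable IVW — plus Egger and LASSO on request — estimates the
#' direct effect of each exposure adjusted for the rest. Each exposure
#' receives an attenuation verdict comparing its single-variable and
#' multivariable significance.
#'
#' @param cfg a [study_config()].
#' @param screen the `svmr_screen` result; flagged outcomes are taken
#'   from its `significant` rows (or pass `flagged_outcomes` explicitly).
#' @param flagged_outcomes optional character vector of outcome labels.
#' @param methods subset of `c("ivw", "egger", "lasso")`.
#' @return an `mvmr_adjust`: list with `table` (per outcome x exposure x
#'   method), `estimates` (the `mvmr_estimate` objects), `skipped`.
#' @export
run_mvmr_adjust <- function(cfg, screen = NULL, flagged_outcomes = NULL,
                            methods = c("ivw", "egger", "lasso")) {
  stopifnot(inherits(cfg, "study_config"))
  methods <- match.arg(methods, several.ok = TRUE)
  th <- cfg$thresholds
  exposures <- .load_named_list(cfg$exposures, "continuous")
  K <- length(exposures)
  if (K < 2L) {
    stop("multivariable adjustment needs K >= 2 exposures; ",
         "use run_svmr_screen for a single exposure", call. = FALSE)
  }
  if (is.null(flagged_outcomes)) {
    stopifnot(inherits(screen, "svmr_screen"))
    flagged_outcomes <- unique(screen$table$outcome[
      which(screen$table$significant)])
  }
  if (length(flagged_outcomes) == 0L) {
    return(structure(list(table = data.frame(), estimates = list(),
                          skipped = data.frame()), class = "mvmr_adjust"))
  }
  outcomes <- .load_named_list(cfg$outcomes, "binary")
  ld <- cfg$ld
  if (is.character(ld)) ld <- read_ld_matrix(ld)
  # joint instrument pool: per-exposure screen, then joint clump
  screened <- lapply(exposures, function(d) {
    tryCatch(significance_screen(d, th$screen_p), error = function(e) NULL)
  })
  screened <- Filter(Negate(is.null), screened)
  if (length(screened) < 2L) {
    stop("fewer than two exposures have any instruments", call. = FALSE)
  }
  joint <- joint_clump_for_bma(screened, ld, th$clump_r2, th$clump_kb)
  rows <- list(); ests <- list(); skipped <- list()
  for (on in intersect(flagged_outcomes, names(outcomes))) {
    ms <- tryCatch(
      harmonize_multi(unname(exposures), outcomes[[on]],
                      th$palindrome_window, snp_ids = joint),
      error = function(e) e)
    if (inherits(ms, "error")) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        outcome = on, reason = conditionMessage(ms),
        stringsAsFactors = FALSE)
      next
    }
    fits <- list()
    if ("ivw" %in% methods) {
      fits$mvmr_ivw <- tryCatch(mvmr_ivw(ms, th$effects_model),
                                error = function(e) e)
    }
    if ("egger" %in% methods) {
      fits$mvmr_egger <- tryCatch(mvmr_egger(ms), error = function(e) e)
    }
    if ("lasso" %in% methods) {
      fits$mvmr_lasso <- tryCatch(mvmr_lasso(ms), error = function(e) e)
    }
    for (mn in names(fits)) {
      f <- fits[[mn]]
      if (inherits(f, "error")) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          outcome = on, reason = paste0(mn, ": ", conditionMessage(f)),
          stringsAsFactors = FALSE)
        next
      }
      ests[[paste(on, mn, sep = ".")]] <- f
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = on, method = mn, exposure = f$exposure_names,
        nsnp = f$n_snp, beta = unname(f$beta), se = unname(f$se),
        or = exp(unname(f$beta)), or_lo95 = exp(unname(f$ci_low)),
        or_hi95 = exp(unname(f$ci_high)), pval = unname(f$pvalue),
        stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else data.frame()
  if (nrow(tab) && !is.null(screen)) {
    # attenuation verdict against the single-variable screen
    sv <- screen$table[screen$table$method %in%
                         c("ivw_re", "ivw_fe", "wald"), ]
    key <- paste(tab$exposure, tab$outcome)
    svp <- sv$pval[match(key, paste(sv$exposure, sv$outcome))]
    tab$svmr_pval <- svp
    tab$verdict <- ifelse(
      is.na(svp), "not_screened",
      ifelse(svp < th$svmr_gate & tab$pval >= th$svmr_gate, "attenuated",
             ifelse(svp < th$svmr_gate & tab$pval < th$svmr_gate,
                    "robust",
                    ifelse(tab$pval < th$svmr_gate, "mvmr_only",
                           "null"))))
  }
  structure(list(table = tab, estimates = ests,
                 skipped = if (length(skipped)) do.call(rbind, skipped)
                 else data.frame(outcome = character(0),
                                 reason = character(0),
                                 stringsAsFactors = FALSE)),
            class = "mvmr_adjust")
}

#' @export
print.mvmr_adjust <- function(x, ...) {
  cat(sprintf("Multivariable MR adjustment: %d row(s), %d skipped\n",
              nrow(x$table), nrow(x$skipped)))
  if (nrow(x$table)) {
    print(utils::head(x$table[, c("outcome", "method", "exposure", "or",
                                  "pval", "verdict")], 12),
          row.names = FALSE)
  }
  invisible(x)
}

#' Fixed-effect meta-analysis of causal estimates
#'
#' Inverse-variance pooling of per-cohort MR estimates of the same
#' exposure-outcome effect: pooled beta is the precision-weighted mean,
#' pooled variance the reciprocal summed precision; cross-cohort
#' heterogeneity is reported as Cochran's Q on `k - 1` df.
#'
#' @param estimates list of `mr_estimate` objects (same orientation).
#' @return a `meta_estimate`: pooled `beta`, `se`, `ci_low`, `ci_high`,
#'   `pvalue`, `q`, `q_df`, `q_p`, `k`, and the per-cohort inputs.
#' @export
meta_fixed <- function(estimates) {
  stopifnot(length(estimates) >= 1L,
            all(vapply(estimates, inherits, logical(1), "mr_estimate")))
  b <- vapply(estimates, `[[`, numeric(1), "beta")
  s <- vapply(estimates, `[[`, numeric(1), "se")
  w <- 1 / s^2
  beta <- sum(w * b) / sum(w)
  se <- sqrt(1 / sum(w))
  k <- length(b)
  q <- sum(w * (b - beta)^2)
  q_df <- k - 1L
  structure(list(
    beta = beta, se = se,
    ci_low = beta - stats::qnorm(0.975) * se,
    ci_high = beta + stats::qnorm(0.975) * se,
    pvalue = 2 * stats::pnorm(-abs(beta / se)),
    q = q, q_df = q_df,
    q_p = if (q_df >= 1L) stats::pchisq(q, q_df, lower.tail = FALSE)
    else NA_real_,
    k = k, cohort_beta = b, cohort_se = s
  ), class = "meta_estimate")
}

#' @export
print.meta_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("Fixed-effect meta-analysis of %d cohort(s)\n", x$k))
  cat(sprintf("  beta %.*f (SE %.*f)  OR %.*f [%.*f-%.*f]  p %.4g\n",
              digits, x$beta, digits, x$se, digits, exp(x$beta),
              digits, exp(x$ci_low), digits, exp(x$ci_high), x$pvalue))
  if (x$q_df >= 1L) {
    cat(sprintf("  cross-cohort Q %.4g on %d df (p %.4g)\n",
                x$q, x$q_df, x$q_p))
  }
  invisible(x)
}

#' Render result tables and run metadata to disk
#'
#' Writes each table as TSV, a human-readable text report
#' (`exposure outcome method nSNP OR [CI] P`, all to 4 decimals) and a
#' run-metadata file recording configuration, seed and package version.
#'
#' @param tables named list of data.frames (e.g. `svmr`, `mvmr`).
#' @param out_dir output directory (created if absent).
#' @param cfg optional `study_config` echoed into the metadata file.
#' @return character vector of written file paths, invisibly.
#' @export
render_report <- function(tables, out_dir, cfg = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(.round_for_report(tab), p, sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
    written <- c(written, p)
  }
  txt <- file.path(out_dir, "report.txt")
  con <- file(txt, "w")
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    if (!nrow(tab) || !all(c("or", "or_lo95", "or_hi95", "pval") %in%
                           names(tab))) next
    writeLines(paste0("== ", nm, " =="), con)
    writeLines(sprintf(
      "%s\t%s\t%s\t%d\t%.4f\t[%.4f-%.4f]\t%.4g",
      tab$exposure %||% "", tab$outcome, tab$method, tab$nsnp,
      tab$or, tab$or_lo95, tab$or_hi95, tab$pval), con)
  }
  close(con)
  written <- c(written, txt)
  meta <- file.path(out_dir, "run_metadata.txt")
  lines <- c(
    paste0("package: mrkit ",
           as.character(utils::packageVersion("mrkit"))),
    paste0("seed: ", if (!is.null(cfg)) cfg$seed else "NA"))
  if (!is.null(cfg)) {
    th <- cfg$thresholds
    lines <- c(lines, vapply(names(th), function(k) {
      paste0(k, ": ", if (is.null(th[[k]])) "default" else
        as.character(th[[k]]))
    }, character(1)))
  }
  writeLines(lines, meta)
  written <- c(written, meta)
  invisible(written)
}

.round_for_report <- function(tab) {
  for (col in intersect(c("beta", "se", "or", "or_lo95", "or_hi95"),
                        names(tab))) {
    tab[[col]] <- round(tab[[col]], 4)
  }
  for (col in intersect(c("pval", "q", "q_pval", "egger_intercept",
                          "egger_intercept_p", "pval_bh", "svmr_pval",
                          "mean_f"), names(tab))) {
    tab[[col]] <- signif(tab[[col]], 6)
  }
  tab
}
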