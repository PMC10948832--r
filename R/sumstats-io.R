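#' @title GWAS summary-statistics input and output
#' @description Readers and writers for the tab-delimited summary-statistics
#'   dialect used throughout the package, plus LD matrix readers.
#' @name sumstats_io
NULL

# canonical column order of the summary-statistics dialect
.SUMSTATS_COLS <- c("snp", "chr", "pos", "effect_allele", "other_allele",
                    "eaf", "beta", "se", "pval", "n")
.REQUIRED_COLS <- c("snp", "effect_allele", "other_allele", "beta", "se", "pval")

#' Construct a summary dataset
#'
#' A `summary_dataset` is a validated data.frame of per-variant association
#' records for one trait, one row per variant, with the canonical columns
#' `snp chr pos effect_allele other_allele eaf beta se pval n`.
#'
#' @param records data.frame containing at least the required columns
#'   (`snp`, `effect_allele`, `other_allele`, `beta`, `se`, `pval`).
#' @param trait_name trait label.
#' @param trait_type `"continuous"` or `"binary"`; binary traits carry
#'   log-odds betas.
#' @param unit_label free-text unit (e.g. `"per 1-SD"`, `"per year"`).
#' @param validate drop rows violating field invariants (with a drop log)?
#' @return A `summary_dataset`: the canonical data.frame with attributes
#'   `trait_name`, `trait_type`, `unit_label` and `drop_log` (a data.frame
#'   of `snp`, `reason` for every excluded row).
#' @export
summary_dataset <- function(records, trait_name = "trait",
                            trait_type = c("continuous", "binary"),
                            unit_label = "per unit", validate = TRUE) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(.REQUIRED_COLS, names(records))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- data.frame(
    snp           = as.character(records$snp),
    chr           = if ("chr" %in% names(records)) as.character(records$chr) else NA_character_,
    pos           = if ("pos" %in% names(records)) as.integer(records$pos) else NA_integer_,
    effect_allele = toupper(as.character(records$effect_allele)),
    other_allele  = toupper(as.character(records$other_allele)),
    eaf           = if ("eaf" %in% names(records)) as.numeric(records$eaf) else NA_real_,
    beta          = as.numeric(records$beta),
    se            = as.numeric(records$se),
    pval          = as.numeric(records$pval),
    n             = if ("n" %in% names(records)) as.numeric(records$n) else NA_real_,
    stringsAsFactors = FALSE
  )
  drop_log <- data.frame(snp = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  if (validate) {
    reason <- rep(NA_character_, nrow(df))
    bases <- c("A", "C", "G", "T")
    bad <- function(cond, code) {
      cond[is.na(cond)] <- FALSE
      ifelse(is.na(reason) & cond, code, reason)
    }
    reason <- bad(is.na(df$snp) | df$snp == "", "missing_snp_id")
    reason <- bad(!(df$effect_allele %in% bases) | !(df$other_allele %in% bases),
                  "invalid_allele")
    reason <- bad(df$effect_allele == df$other_allele, "identical_alleles")
    reason <- bad(is.na(df$beta), "missing_beta")
    reason <- bad(is.na(df$se) | df$se <= 0, "nonpositive_se")
    reason <- bad(is.na(df$pval) | df$pval <= 0 | df$pval > 1, "invalid_pvalue")
    reason <- bad(!is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1), "invalid_eaf")
    reason <- bad(duplicated(df$snp), "duplicate_snp_id")
    keep <- is.na(reason)
    if (any(!keep)) {
      drop_log <- data.frame(snp = df$snp[!keep], reason = reason[!keep],
                             stringsAsFactors = FALSE)
    }
    df <- df[keep, , drop = FALSE]
    # consistency warning: p implied by |z| should match reported p within 2x
    z <- abs(df$beta / df$se)
    p_implied <- 2 * stats::pnorm(-z)
    chk <- !is.na(df$pval) & p_implied > 0 & df$pval > 0
    off <- chk & (df$pval / p_implied > 2 | p_implied / df$pval > 2)
    if (any(off)) {
      warning(sum(off), " row(s) have p-values inconsistent with |beta/se| ",
              "by more than a factor of 2", call. = FALSE)
    }
  }
  rownames(df) <- NULL
  structure(df,
            trait_name = trait_name, trait_type = trait_type,
            unit_label = unit_label, drop_log = drop_log,
            class = c("summary_dataset", "data.frame"))
}

#' @export
print.summary_dataset <- function(x, ...) {
  cat(sprintf("GWAS summary dataset: %s (%s, %s)\n",
              attr(x, "trait_name"), attr(x, "trait_type"),
              attr(x, "unit_label")))
  cat(sprintf("  %d variant(s); %d row(s) dropped at validation\n",
              nrow(x), nrow(attr(x, "drop_log"))))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Read GWAS summary statistics
#'
#' Reads a tab-delimited summary-statistics file with a header row into a
#' validated [summary_dataset()]. Columns may be renamed via `column_map`;
#' rows violating the field invariants are dropped with a reason code
#' recorded in the dataset's `drop_log` attribute.
#'
#' @param path path to a tab-separated file with header.
#' @param column_map optional named character vector or list mapping
#'   canonical names to the file's column names, e.g.
#'   `c(effect_allele = "EA", other_allele = "NEA")`.
#' @param trait_name,trait_type,unit_label passed to [summary_dataset()].
#' @return a `summary_dataset`.
#' @export
read_sumstats <- function(path, column_map = NULL, trait_name = NULL,
                          trait_type = c("continuous", "binary"),
                          unit_label = "per unit") {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "NA",
                          colClasses = "character", check.names = FALSE)
  if (!is.null(column_map)) {
    column_map <- unlist(column_map)
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(df)) {
        stop("column_map refers to absent column: ", src, call. = FALSE)
      }
      names(df)[names(df) == src] <- canon
    }
  }
  missing_cols <- setdiff(.REQUIRED_COLS, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (num in intersect(c("pos", "eaf", "beta", "se", "pval", "n"), names(df))) {
    df[[num]] <- suppressWarnings(as.numeric(df[[num]]))
  }
  if (is.null(trait_name)) {
    trait_name <- sub("\\.[^.]*$", "", basename(path))
  }
  ds <- summary_dataset(df, trait_name = trait_name, trait_type = trait_type,
                        unit_label = unit_label)
  if (nrow(ds) == 0L) {
    stop("no valid rows in ", path, call. = FALSE)
  }
  ds
}

#' Write GWAS summary statistics
#'
#' Writes a [summary_dataset()] in the canonical tab-separated dialect
#' (columns `snp chr pos effect_allele other_allele eaf beta se pval n`,
#' missing values as `NA`). `read_sumstats(write_sumstats(ds))` reproduces
#' `ds` field for field.
#'
#' @param ds a `summary_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(ds, path) {
  stopifnot(inherits(ds, "summary_dataset"))
  df <- as.data.frame(ds)[, .SUMSTATS_COLS, drop = FALSE]
  # fixed significant-digit formatting keeps output byte-stable and lossless
  for (num in c("eaf", "beta", "se", "pval", "n")) {
    df[[num]] <- ifelse(is.na(df[[num]]), "NA",
                        formatC(df[[num]], digits = 17, format = "g"))
  }
  df$pos <- ifelse(is.na(df$pos), "NA", format(df$pos, scientific = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
  invisible(path)
}

#' Construct an LD matrix object
#'
#' @param r2 square numeric matrix of squared correlations.
#' @param snp_ids variant identifiers (defaults to `rownames(r2)`).
#' @return an `ld_matrix`: the validated matrix with dimnames set.
#' @export
ld_matrix <- function(r2, snp_ids = rownames(r2)) {
  r2 <- as.matrix(r2)
  if (is.null(snp_ids)) stop("snp_ids required", call. = FALSE)
  if (nrow(r2) != ncol(r2) || nrow(r2) != length(snp_ids)) {
    stop("r2 must be square with one row per snp_id", call. = FALSE)
  }
  if (max(abs(r2 - t(r2))) > 1e-8) {
    stop("LD matrix is not symmetric (beyond 1e-8)", call. = FALSE)
  }
  r2 <- (r2 + t(r2)) / 2
  if (any(r2 < -1e-12) || any(r2 > 1 + 1e-12)) {
    stop("r2 values outside [0, 1]", call. = FALSE)
  }
  r2[r2 < 0] <- 0; r2[r2 > 1] <- 1
  diag(r2) <- 1
  dimnames(r2) <- list(snp_ids, snp_ids)
  structure(r2, class = c("ld_matrix", "matrix", "array"))
}

#' Read an LD (r-squared) matrix
#'
#' Square format: header row of SNP ids, first column of SNP ids, numeric
#' body. Long format: columns `snp_a snp_b r2`; pairs not listed default to
#' r2 = 0; `snp_ids` may extend the universe beyond the ids in the file.
#'
#' @param path file path.
#' @param format `"square"` or `"long"`.
#' @param snp_ids optional universe of ids for long format.
#' @return an [ld_matrix()].
#' @export
read_ld_matrix <- function(path, format = c("square", "long"),
                           snp_ids = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "square") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
    ids <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!identical(colnames(m), ids)) {
      stop("square LD file: header ids do not match first-column ids",
           call. = FALSE)
    }
    storage.mode(m) <- "double"
    ld_matrix(m, ids)
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    need <- c("snp_a", "snp_b", "r2")
    if (!all(need %in% names(df))) {
      stop("long LD file needs columns snp_a, snp_b, r2", call. = FALSE)
    }
    ids <- snp_ids
    if (is.null(ids)) ids <- unique(c(df$snp_a, df$snp_b))
    m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    ia <- match(as.character(df$snp_a), ids)
    ib <- match(as.character(df$snp_b), ids)
    if (anyNA(ia) || anyNA(ib)) {
      stop("long LD file contains ids outside snp_ids", call. = FALSE)
    }
    r2 <- as.numeric(df$r2)
    # both triangle entries set; duplicated conflicting pairs are fatal
    # via the symmetry check in ld_matrix()
    m[cbind(ia, ib)] <- r2
    m[cbind(ib, ia)] <- r2
    diag(m) <- 1
    ld_matrix(m, ids)
  }
}

#' Write an LD matrix in square format
#' @param ld an [ld_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  stopifnot(inherits(ld, "ld_matrix"))
  df <- data.frame(snp = rownames(ld), as.data.frame(unclass(ld)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop log of a summary dataset
#' @param ds a `summary_dataset`.
#' @return data.frame with columns `snp`, `reason`.
#' @export
drop_log <- function(ds) attr(ds, "drop_log")
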