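# Column contracts for the flat interchange tables.  Absent values are "."
# on disk and NA in memory.  mutated_copies / wildtype_copies are only
# meaningful in tissue mode (SGZ-style copy-number outputs consumed as input).
VARIANT_COLUMNS <- c(
  "sample_id", "gene", "alteration_type", "protein_change",
  "allele_fraction", "somatic_status", "ch_flag", "oncogenicity",
  "mutated_copies", "wildtype_copies"
)
VARIANT_REQUIRED <- c(
  "sample_id", "gene", "alteration_type", "protein_change",
  "allele_fraction", "somatic_status", "ch_flag", "oncogenicity"
)

ALTERATION_TYPES <- c("SNV", "indel", "CNA-amplification", "CNA-loss", "rearrangement")
SOMATIC_STATUSES <- c("somatic", "germline", "ambiguous")
ONCOGENICITIES   <- c("known", "likely", "VUS")
ASSAY_MODES      <- c("ctdna", "tissue")
CLONALITY_CATEGORIES <- c(
  "clonal_single", "subclonal_single",
  "clonal_multiple", "subclonal_multiple",
  "no_pik3ca", "unestimable"
)

CLINICAL_REQUIRED <- c("sample_id", "arm", "responder", "pfs_time", "pfs_event")

#' Default stratification-factor levels
#'
#' The declared finite level sets against which clinical-table stratification
#' columns are validated: visceral disease (yes/no), endocrine sensitivity
#' (sensitive/resistant) and geographic region.  Override by passing your own
#' named list of character vectors to [read_clinical_table()].
#'
#' @return Named list of character vectors.
#' @export
default_strata_levels <- function() {
  list(
    visceral_disease      = c("yes", "no"),
    endocrine_sensitivity = c("sensitive", "resistant"),
    region                = c("north_america", "europe", "asia_pacific", "other")
  )
}

read_tsv_dots <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, na.strings = ".",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = NA, comment.char = "")
}

write_tsv_dots <- function(df, path) {
  ok <- tryCatch({
    suppressWarnings(
      utils::write.table(df, path, sep = "\t", quote = FALSE, na = ".",
                         row.names = FALSE, col.names = TRUE))
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write to '", path, "': ", conditionMessage(ok))
  invisible(NULL)
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
}

as_flag <- function(x) {
  if (is.logical(x)) return(x)
  lx <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[lx %in% c("true", "t", "1", "yes")] <- TRUE
  out[lx %in% c("false", "f", "0", "no")] <- FALSE
  out
}

#' Validate a variant-call table
#'
#' Enforces the invariants of a variant call: allele fraction in \[0, 1\]
#' when present, enumerated alteration type / somatic status / oncogenicity,
#' and mutated/wild-type copy numbers that are either both present or both
#' absent with `mc >= 0`, `wc >= 0`, `mc + wc > 0`.  Errors carry row numbers.
#'
#' @param variants Data frame with the columns of a variant table.
#' @return The validated data frame (invisibly usable), with `ch_flag`
#'   coerced to logical and gene symbols trimmed.
#' @export
validate_variants <- function(variants) {
  check_columns(variants, VARIANT_REQUIRED, "variant table")
  variants$gene <- trimws(as.character(variants$gene))
  variants$sample_id <- trimws(as.character(variants$sample_id))
  variants$ch_flag <- as_flag(variants$ch_flag)
  variants$allele_fraction <- as.numeric(variants$allele_fraction)
  if (!"mutated_copies" %in% names(variants)) variants$mutated_copies <- NA_real_
  if (!"wildtype_copies" %in% names(variants)) variants$wildtype_copies <- NA_real_
  variants$mutated_copies <- as.numeric(variants$mutated_copies)
  variants$wildtype_copies <- as.numeric(variants$wildtype_copies)

  fail_rows <- function(bad, msg) {
    if (any(bad, na.rm = TRUE)) {
      stop(sprintf("%s (row %s)", msg,
                   paste(which(bad), collapse = ", ")), call. = FALSE)
    }
  }
  incomplete <- is.na(variants$sample_id) | variants$sample_id == "" |
    is.na(variants$gene) | variants$gene == ""
  fail_rows(incomplete, "missing sample_id or gene")
  af <- variants$allele_fraction
  fail_rows(!is.na(af) & (af < 0 | af > 1), "allele_fraction outside [0, 1]")
  fail_rows(!variants$alteration_type %in% ALTERATION_TYPES,
            "unknown alteration_type")
  fail_rows(!variants$somatic_status %in% SOMATIC_STATUSES,
            "unknown somatic_status")
  fail_rows(!variants$oncogenicity %in% ONCOGENICITIES, "unknown oncogenicity")
  fail_rows(is.na(variants$ch_flag), "ch_flag is not interpretable as logical")
  mc <- variants$mutated_copies; wc <- variants$wildtype_copies
  fail_rows(xor(is.na(mc), is.na(wc)),
            "mutated_copies and wildtype_copies must be both present or both absent")
  both <- !is.na(mc) & !is.na(wc)
  fail_rows(both & (mc < 0 | wc < 0 | mc + wc <= 0),
            "copy numbers must satisfy mc >= 0, wc >= 0, mc + wc > 0")
  variants
}

#' Read a variant-call table into sample profiles
#'
#' Reads a UTF-8 tab-delimited table (one row per called variant, "." for
#' absent values) and groups rows into per-sample profiles.  Required
#' columns: `sample_id`, `gene`, `alteration_type`, `protein_change`,
#' `allele_fraction`, `somatic_status`, `ch_flag`, `oncogenicity`; tissue
#' tables additionally carry `mutated_copies` and `wildtype_copies`.  An
#' optional `aneuploidy_tumor_fraction` column supplies a per-sample
#' aneuploidy-based tumor-fraction estimate that takes precedence over MSAF.
#'
#' @param path Path to the table.
#' @param assay_mode `"ctdna"` or `"tissue"`.
#' @return A `sample_profiles` object: list with `variants` (validated data
#'   frame), `assay_mode`, `sample_ids`, and `aneuploidy` (named numeric of
#'   supplied aneuploidy tumor fractions, possibly empty).
#' @export
read_variant_table <- function(path, assay_mode = c("ctdna", "tissue")) {
  assay_mode <- match.arg(assay_mode)
  df <- read_tsv_dots(path)
  sample_profiles(df, assay_mode = assay_mode)
}

#' Construct sample profiles from an in-memory variant table
#'
#' @param variants Data frame of variant calls (see [read_variant_table()]).
#' @param assay_mode `"ctdna"` or `"tissue"`.
#' @param aneuploidy Optional named numeric vector of aneuploidy-based tumor
#'   fractions in (0, 1]; overrides any `aneuploidy_tumor_fraction` column.
#' @return A `sample_profiles` object.
#' @export
sample_profiles <- function(variants, assay_mode = c("ctdna", "tissue"),
                            aneuploidy = NULL) {
  assay_mode <- match.arg(assay_mode)
  aneu_col <- NULL
  if ("aneuploidy_tumor_fraction" %in% names(variants)) {
    atf <- as.numeric(variants$aneuploidy_tumor_fraction)
    keep <- !is.na(atf)
    if (any(keep)) {
      aneu_col <- tapply(atf[keep], variants$sample_id[keep], function(v) v[1])
      aneu_col <- stats::setNames(as.numeric(aneu_col), names(aneu_col))
    }
    variants$aneuploidy_tumor_fraction <- NULL
  }
  variants <- validate_variants(variants)
  if (is.null(aneuploidy)) aneuploidy <- aneu_col
  if (is.null(aneuploidy)) aneuploidy <- stats::setNames(numeric(0), character(0))
  bad <- aneuploidy <= 0 | aneuploidy > 1
  if (any(bad)) {
    stop("aneuploidy tumor fraction outside (0, 1] for sample(s): ",
         paste(names(aneuploidy)[bad], collapse = ", "), call. = FALSE)
  }
  structure(
    list(
      variants   = variants,
      assay_mode = assay_mode,
      sample_ids = unique(variants$sample_id),
      aneuploidy = aneuploidy
    ),
    class = "sample_profiles"
  )
}

#' @export
print.sample_profiles <- function(x, ...) {
  cat("Sample profiles (", x$assay_mode, " mode): ",
      length(x$sample_ids), " sample(s), ",
      nrow(x$variants), " variant call(s)\n", sep = "")
  invisible(x)
}

#' Number of samples in a profile set
#' @param x A `sample_profiles` object.
#' @param ... Unused.
#' @export
length.sample_profiles <- function(x) length(x$sample_ids)

#' Read a per-patient clinical table
#'
#' Tab-delimited, one row per patient, "." for absent.  Required columns:
#' `sample_id`, `arm` (`control`/`experimental`), `responder` (logical or
#' absent), `pfs_time` (months, > 0), `pfs_event` (logical).  Any further
#' columns are treated as stratification factors and validated against the
#' declared level sets.
#'
#' @param path Path to the table.
#' @param strata_levels Named list of allowed levels per stratification
#'   factor; defaults to [default_strata_levels()].  Stratification columns
#'   absent from this list are rejected.
#' @return Data frame of class `clinical_records`, keyed by `sample_id`.
#' @export
read_clinical_table <- function(path, strata_levels = default_strata_levels()) {
  df <- read_tsv_dots(path)
  check_columns(df, CLINICAL_REQUIRED, "clinical table")
  df$sample_id <- trimws(as.character(df$sample_id))
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in clinical table: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$arm %in% c("control", "experimental"))) {
    stop("arm must be 'control' or 'experimental'", call. = FALSE)
  }
  df$responder <- as_flag(df$responder)
  df$pfs_time <- as.numeric(df$pfs_time)
  df$pfs_event <- as_flag(df$pfs_event)
  bad_t <- is.na(df$pfs_time) | df$pfs_time <= 0
  if (any(bad_t)) {
    stop("pfs_time must be a positive number (row ",
         paste(which(bad_t), collapse = ", "), ")", call. = FALSE)
  }
  strata_cols <- setdiff(names(df), CLINICAL_REQUIRED)
  for (s in strata_cols) {
    if (!s %in% names(strata_levels)) {
      stop("undeclared stratification factor: ", s, call. = FALSE)
    }
    lev <- df[[s]][!is.na(df[[s]])]
    bad <- !lev %in% strata_levels[[s]]
    if (any(bad)) {
      stop(sprintf("unknown level(s) for stratum '%s': %s", s,
                   paste(unique(lev[bad]), collapse = ", ")), call. = FALSE)
    }
  }
  class(df) <- c("clinical_records", "data.frame")
  attr(df, "strata_columns") <- strata_cols
  df
}

#' Write the sample-category table
#'
#' Emits one row per sample with its clonality category, derived tumor
#' fraction (and estimation method), and the per-variant clonal fractions of
#' the target-gene mutations encoded as `gene:protein_change:clonal_fraction`
#' triplets (semicolon-separated, fractions to 6 decimals).  The table
#' round-trips through [read_category_table()].
#'
#' @param fit A `clonality_fit` from [estimate_clonality()].
#' @param path Output path.
#' @export
write_category_table <- function(fit, path) {
  stopifnot(inherits(fit, "clonality_fit"))
  samp <- fit$samples
  calls <- fit$calls
  enc <- vapply(samp$sample_id, function(sid) {
    k <- calls$sample_id == sid & calls$target_gene
    if (!any(k)) return(".")
    paste(sprintf("%s:%s:%s", calls$gene[k], calls$protein_change[k],
                  ifelse(is.na(calls$clonal_fraction[k]), ".",
                         formatC(calls$clonal_fraction[k], digits = 6,
                                 format = "f"))),
          collapse = ";")
  }, character(1))
  out <- data.frame(
    sample_id = samp$sample_id,
    clonality_category = samp$clonality_category,
    tumor_fraction = ifelse(is.na(samp$tumor_fraction), NA,
                            round(samp$tumor_fraction, 6)),
    tumor_fraction_method = samp$tumor_fraction_method,
    target_clonal_fractions = enc,
    stringsAsFactors = FALSE
  )
  write_tsv_dots(out, path)
}

#' Read back a sample-category table
#'
#' Inverse of [write_category_table()].
#'
#' @param path Path written by [write_category_table()].
#' @return Data frame with `sample_id`, `clonality_category`,
#'   `tumor_fraction`, `tumor_fraction_method`, `target_clonal_fractions`.
#' @export
read_category_table <- function(path) {
  df <- read_tsv_dots(path)
  check_columns(df, c("sample_id", "clonality_category", "tumor_fraction"),
                "category table")
  if (!all(is.na(df$clonality_category) |
           df$clonality_category %in% CLONALITY_CATEGORIES)) {
    stop("unknown clonality category in table", call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  df$tumor_fraction <- as.numeric(df$tumor_fraction)
  df
}
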