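# Per-variant clonal fractions and sample-level clonality categories.
#
# The clonal fraction of a variant is its allele fraction divided by the
# sample's estimated tumor fraction — a proxy for the fraction of tumor
# cells carrying the variant.  Thresholds (inclusive) call a variant clonal
# at >= 0.25 in ctDNA mode and >= 0.50 in tissue mode; the ctDNA cutoff is
# where a heterozygous single-copy alteration is present in a majority of
# diploid tumor cells.

#' Default clonal-fraction thresholds by assay mode
#' @return Named numeric vector with elements `ctdna` and `tissue`.
#' @export
default_clonal_thresholds <- function() c(ctdna = 0.25, tissue = 0.50)

#' Clonal fraction of a variant
#'
#' Ratio of the variant allele fraction to the sample tumor fraction, capped
#' at `cap` (amplified alleles can push the raw ratio above 1).  The raw
#' ratio is returned in the `"raw"` attribute.
#'
#' @param af Allele fraction in \[0, 1\].
#' @param tumor_fraction Sample tumor fraction in (0, 1].
#' @param cap Upper bound (default 1).
#' @return Capped clonal fraction (vectorised).
#' @export
clonal_fraction <- function(af, tumor_fraction, cap = 1) {
  if (any(tumor_fraction <= 0, na.rm = TRUE)) {
    stop("tumor_fraction must be positive", call. = FALSE)
  }
  raw <- af / tumor_fraction
  out <- pmin(raw, cap)
  attr(out, "raw") <- raw
  out
}

#' Label a variant clonal or subclonal
#'
#' Inclusive thresholding of the clonal fraction: `>= 0.25` is clonal in
#' ctDNA mode, `>= 0.50` in tissue mode.  `NA` clonal fractions (tumor
#' fraction or allele fraction unavailable) yield `"unestimable"`.
#'
#' @param cf Clonal fraction(s).
#' @param assay_mode `"ctdna"` or `"tissue"`.
#' @param thresholds Named thresholds, see [default_clonal_thresholds()].
#' @return Character vector in `{"clonal", "subclonal", "unestimable"}`.
#' @export
label_variant <- function(cf, assay_mode = c("ctdna", "tissue"),
                          thresholds = default_clonal_thresholds()) {
  assay_mode <- match.arg(assay_mode)
  thr <- thresholds[[assay_mode]]
  ifelse(is.na(cf), "unestimable", ifelse(cf >= thr, "clonal", "subclonal"))
}

#' Clonality category from target-gene mutation labels
#'
#' The pure classification rule, applied to the clonal/subclonal labels of a
#' sample's pathogenic target-gene SNVs:
#' * 0 mutations: `no_pik3ca`;
#' * any label unestimable: `unestimable`;
#' * 1 mutation: `clonal_single` if clonal else `subclonal_single`;
#' * >= 2 mutations: `clonal_multiple` if at least two are clonal, else
#'   `subclonal_multiple` (at most one clonal).
#'
#' @param labels Character vector of labels in
#'   `{"clonal", "subclonal", "unestimable"}` (order irrelevant).
#' @return One clonality category string.
#' @export
categorize_labels <- function(labels) {
  n <- length(labels)
  if (n == 0L) return("no_pik3ca")
  if (any(labels == "unestimable")) return("unestimable")
  n_clonal <- sum(labels == "clonal")
  if (n == 1L) {
    if (n_clonal == 1L) "clonal_single" else "subclonal_single"
  } else {
    if (n_clonal >= 2L) "clonal_multiple" else "subclonal_multiple"
  }
}

#' Estimate clonality and categorise samples
#'
#' The central fitting step: for each sample, estimates the tumor fraction
#' ([ctdna_fraction()] in liquid mode, [tissue_tumor_fraction()] in tissue
#' mode), computes per-variant clonal fractions, labels variants clonal or
#' subclonal by the assay-mode threshold, and assigns the sample a clonality
#' category based on the multiplicity and clonality of its pathogenic
#' target-gene SNVs (oncogenicity `known` or `likely`; indels, copy-number
#' alterations and rearrangements in the target gene are reported but do not
#' count toward multiplicity).
#'
#' @param profiles A `sample_profiles` object from [read_variant_table()] /
#'   [sample_profiles()].
#' @param target_gene Gene whose mutation multiplicity and clonality define
#'   the category (default `"PIK3CA"`).
#' @param thresholds Clonal-fraction thresholds per assay mode.
#' @param cap Cap applied to tumor fractions and clonal fractions.
#' @param include_ambiguous Treat ambiguous somatic status as somatic in
#'   MSAF (default `FALSE`).
#' @param ch_genes CH-associated genes excluded from MSAF.
#' @return An object of class `clonality_fit` with components `samples`
#'   (one row per sample: tumor fraction, method, target-mutation counts,
#'   category), `calls` (one row per variant: clonal fraction, label,
#'   whether it counts toward the target multiplicity), `assay_mode`, and
#'   the configuration used.
#' @examples
#' v <- data.frame(
#'   sample_id = "S1", gene = c("PIK3CA", "PIK3CA", "TP53"),
#'   alteration_type = "SNV",
#'   protein_change = c("H1047R", "E545K", "R175H"),
#'   allele_fraction = c(0.12, 0.10, 0.13),
#'   somatic_status = "somatic", ch_flag = FALSE, oncogenicity = "known")
#' fit <- estimate_clonality(sample_profiles(v, "ctdna"))
#' fit$samples$clonality_category
#' @export
estimate_clonality <- function(profiles,
                               target_gene = "PIK3CA",
                               thresholds = default_clonal_thresholds(),
                               cap = 1,
                               include_ambiguous = FALSE,
                               ch_genes = default_ch_genes()) {
  stopifnot(inherits(profiles, "sample_profiles"))
  v <- profiles$variants
  mode <- profiles$assay_mode
  ids <- profiles$sample_ids

  calls <- v[, c("sample_id", "gene", "alteration_type", "protein_change",
                 "allele_fraction")]
  calls$clonal_fraction <- rep(NA_real_, nrow(v))
  calls$raw_clonal_fraction <- rep(NA_real_, nrow(v))
  calls$label <- rep(NA_character_, nrow(v))
  calls$target_gene <- v$gene == target_gene &
    v$alteration_type == "SNV" &
    v$oncogenicity %in% c("known", "likely")

  samples <- data.frame(
    sample_id = ids,
    tumor_fraction = rep(NA_real_, length(ids)),
    tumor_fraction_method = rep("none", length(ids)),
    n_target_mut = rep(0L, length(ids)),
    n_target_clonal = rep(0L, length(ids)),
    clonality_category = rep(NA_character_, length(ids)),
    stringsAsFactors = FALSE
  )

  for (i in seq_along(ids)) {
    sid <- ids[i]
    rows <- which(v$sample_id == sid)
    sv <- v[rows, , drop = FALSE]
    tf <- if (mode == "ctdna") {
      atf <- if (sid %in% names(profiles$aneuploidy))
        profiles$aneuploidy[[sid]] else NA_real_
      ctdna_fraction(sv, atf, include_ambiguous = include_ambiguous,
                     ch_genes = ch_genes)
    } else {
      suppressWarnings(tissue_tumor_fraction(sv, cap = cap))
    }
    samples$tumor_fraction[i] <- tf$value
    samples$tumor_fraction_method[i] <- tf$method

    if (!is.na(tf$value)) {
      has_af <- !is.na(sv$allele_fraction)
      cf <- clonal_fraction(sv$allele_fraction[has_af], tf$value, cap = cap)
      calls$clonal_fraction[rows[has_af]] <- as.numeric(cf)
      calls$raw_clonal_fraction[rows[has_af]] <- attr(cf, "raw")
    }
    calls$label[rows] <- label_variant(calls$clonal_fraction[rows], mode,
                                       thresholds)

    tg <- rows[calls$target_gene[rows]]
    lab <- calls$label[tg]
    samples$n_target_mut[i] <- length(tg)
    samples$n_target_clonal[i] <- sum(lab == "clonal")
    samples$clonality_category[i] <- categorize_labels(lab)
  }

  structure(
    list(samples = samples, calls = calls, assay_mode = mode,
         target_gene = target_gene, thresholds = thresholds, cap = cap,
         variants = v),
    class = "clonality_fit"
  )
}

#' Cohort flow counts by clonality category
#'
#' Tabulates samples per clonality category (fixed category order), overall
#' and, when arm assignments are supplied, per treatment arm, with the
#' number excluded as unestimable reported alongside.
#'
#' @param fit A `clonality_fit`.
#' @param arms Optional named character vector or `clinical_records` data
#'   frame mapping sample ids to arms.
#' @return Data frame of class `cohort_flow`: one row per category with
#'   counts (columns `n`, and `control` / `experimental` when arms are
#'   given); attribute `excluded` holds the unestimable count.
#' @export
cohort_flow <- function(fit, arms = NULL) {
  stopifnot(inherits(fit, "clonality_fit"))
  cat_f <- factor(fit$samples$clonality_category, levels = CLONALITY_CATEGORIES)
  out <- data.frame(category = CLONALITY_CATEGORIES,
                    n = as.integer(table(cat_f)),
                    stringsAsFactors = FALSE)
  if (!is.null(arms)) {
    if (is.data.frame(arms)) {
      arms <- stats::setNames(as.character(arms$arm), arms$sample_id)
    }
    a <- arms[fit$samples$sample_id]
    for (lev in c("control", "experimental")) {
      out[[lev]] <- as.integer(table(cat_f[!is.na(a) & a == lev]))
    }
  }
  attr(out, "excluded") <- out$n[out$category == "unestimable"]
  class(out) <- c("cohort_flow", "data.frame")
  out
}

#' @export
print.cohort_flow <- function(x, ...) {
  cat("Cohort flow (samples per clonality category):\n")
  print.data.frame(x, row.names = FALSE)
  cat("Excluded as unestimable:", attr(x, "excluded"), "\n")
  invisible(x)
}

#' @export
print.clonality_fit <- function(x, ...) {
  cat("Clonality fit (", x$assay_mode, " mode, target gene ", x$target_gene,
      ")\n", sep = "")
  cat("  samples:", nrow(x$samples), "  variant calls:", nrow(x$calls), "\n")
  tab <- table(factor(x$samples$clonality_category,
                      levels = CLONALITY_CATEGORIES))
  for (nm in names(tab)) if (tab[[nm]] > 0)
    cat(sprintf("  %-20s %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' @export
summary.clonality_fit <- function(object, ...) {
  flow <- cohort_flow(object)
  mult <- object$samples$clonality_category %in%
    c("clonal_multiple", "subclonal_multiple")
  res <- list(
    flow = flow,
    n_samples = nrow(object$samples),
    n_multiple = sum(mult),
    clonal_share_multiple = if (any(mult))
      mean(object$samples$clonality_category[mult] == "clonal_multiple")
    else NA_real_,
    median_tumor_fraction = stats::median(object$samples$tumor_fraction,
                                          na.rm = TRUE)
  )
  class(res) <- "summary.clonality_fit"
  res
}

#' @export
print.summary.clonality_fit <- function(x, ...) {
  print(x$flow)
  if (!is.na(x$clonal_share_multiple)) {
    cat(sprintf("Clonal share among multiple-mutation samples: %.1f%% (%d samples)\n",
                100 * x$clonal_share_multiple, x$n_multiple))
  }
  cat(sprintf("Median tumor fraction: %.3f\n", x$median_tumor_fraction))
  invisible(x)
}

#' @export
plot.clonality_fit <- function(x, ...) {
  tab <- table(factor(x$samples$clonality_category,
                      levels = CLONALITY_CATEGORIES))
  graphics::barplot(tab, las = 2, ylab = "samples",
                    main = "Clonality categories", ...)
  invisible(x)
}

#' @export
fitted.clonality_fit <- function(object, ...) {
  object$calls$clonal_fraction
}

#' @export
as.data.frame.clonality_fit <- function(x, ...) x$samples
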