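# Sample-level tumor-fraction estimation.
#
# Liquid mode: an externally supplied aneuploidy-based estimate takes
# precedence; otherwise the maximum somatic allele fraction (MSAF) — the
# highest AF among non-germline, non-clonal-hematopoiesis variants — stands
# in for the ctDNA fraction.  Tissue mode: per-variant tumor fractions from
# allele fraction and SGZ copy numbers, maximised over somatic variants.

#' Default clonal-hematopoiesis gene list
#'
#' Genes whose variants are excluded from MSAF in addition to rows already
#' flagged `ch_flag = TRUE`.  The canonical CH drivers are used as a default;
#' the set is configurable because panel-specific CH blocklists differ.
#'
#' @return Character vector of gene symbols.
#' @export
default_ch_genes <- function() c("DNMT3A", "TET2", "ASXL1")

tf_result <- function(value = NA_real_, method = "none", variant = NA_integer_) {
  structure(list(value = value, method = method, contributing_variant = variant),
            class = "tumor_fraction_result")
}

#' @export
print.tumor_fraction_result <- function(x, ...) {
  if (x$method == "none") {
    cat("Tumor fraction: not estimable\n")
  } else {
    cat(sprintf("Tumor fraction: %.4f (method: %s)\n", x$value, x$method))
  }
  invisible(x)
}

#' Maximum somatic allele fraction (MSAF)
#'
#' The highest variant allele fraction among non-germline variants after
#' excluding clonal-hematopoiesis-associated calls (the `ch_flag` column plus
#' a configurable CH gene list).  Ambiguous somatic/germline calls are
#' excluded by default, conservatively; set `include_ambiguous = TRUE` to
#' treat them as somatic.
#'
#' @param variants Data frame of variant calls (validated columns).
#' @param include_ambiguous Count `somatic_status == "ambiguous"` rows as
#'   eligible (default `FALSE`).
#' @param ch_genes Gene symbols excluded as CH-associated regardless of flag.
#' @return A `tumor_fraction_result`; `method = "msaf"` with the defining
#'   variant's row index, or `method = "none"` when no variant is eligible.
#' @export
msaf <- function(variants, include_ambiguous = FALSE,
                 ch_genes = default_ch_genes()) {
  status_ok <- variants$somatic_status == "somatic" |
    (include_ambiguous & variants$somatic_status == "ambiguous")
  # a zero allele fraction is no evidence of shed, so it cannot define MSAF
  eligible <- status_ok & !variants$ch_flag &
    !(variants$gene %in% ch_genes) & !is.na(variants$allele_fraction) &
    variants$allele_fraction > 0
  if (!any(eligible)) return(tf_result())
  idx <- which(eligible)
  best <- idx[which.max(variants$allele_fraction[idx])]
  tf_result(variants$allele_fraction[best], "msaf", best)
}

#' ctDNA tumor fraction for one sample
#'
#' A supplied aneuploidy-based tumor-fraction estimate takes precedence
#' (used when there is clear evidence of aneuploidy); otherwise falls back to
#' [msaf()] on the sample's variants.
#'
#' @param variants Data frame of the sample's variant calls.
#' @param aneuploidy_tf Aneuploidy-based tumor fraction in (0, 1], or `NA`.
#' @param ... Passed to [msaf()].
#' @return A `tumor_fraction_result`.
#' @export
ctdna_fraction <- function(variants, aneuploidy_tf = NA_real_, ...) {
  if (!is.na(aneuploidy_tf)) {
    if (aneuploidy_tf <= 0 || aneuploidy_tf > 1) {
      stop("aneuploidy tumor fraction must lie in (0, 1], got ",
           aneuploidy_tf, call. = FALSE)
    }
    return(tf_result(aneuploidy_tf, "aneuploidy"))
  }
  msaf(variants, ...)
}

#' Per-variant tumor fraction from allele fraction and copy numbers
#'
#' For a somatic variant with allele fraction `af`, mutated copies `mc` and
#' wild-type copies `wc` (copy-number model outputs), the implied tumor
#' fraction of the sample is
#' \deqn{\mathrm{TF} = \frac{2\,\mathrm{AF}}{mc - \mathrm{AF}(wc + mc - 2)}.}
#' For a heterozygous variant in a diploid region (`mc = wc = 1`) this
#' reduces to `2 * af`.
#'
#' @param af Allele fraction in (0, 1].
#' @param mc Mutated copies, > 0.
#' @param wc Wild-type copies, >= 0.
#' @return The tumor-fraction estimate (> 0; may exceed 1 for variants on
#'   amplified alleles — callers cap it).
#' @export
sgz_variant_tumor_fraction <- function(af, mc, wc) {
  if (any(af <= 0 | af > 1)) stop("af must lie in (0, 1]", call. = FALSE)
  if (any(mc <= 0)) stop("mc must be positive", call. = FALSE)
  if (any(wc < 0)) stop("wc must be nonnegative", call. = FALSE)
  denom <- mc - af * (wc + mc - 2)
  if (any(denom <= 0)) {
    bad <- which(denom <= 0)[1]
    stop(sprintf(
      "degenerate copy-number inputs: nonpositive denominator (af=%g, mc=%g, wc=%g)",
      af[bad], mc[bad], wc[bad]), call. = FALSE)
  }
  2 * af / denom
}

#' Tissue tumor fraction for one sample
#'
#' Maximum of the per-variant tumor fractions over all somatic variants with
#' usable allele fractions and copy numbers.  Raw estimates above `cap`
#' (variants on amplified alleles overestimate tumor fraction) are capped,
#' with a warning carrying the raw value.  Variants lacking mc/wc or with a
#' degenerate denominator are skipped; their count is recorded in the
#' `skipped` attribute.
#'
#' @param variants Data frame of the sample's variant calls.
#' @param cap Upper bound applied to the estimate (default 1).
#' @return A `tumor_fraction_result` with `method = "sgz_max"`, or
#'   `method = "none"` when no somatic variant is usable.
#' @export
tissue_tumor_fraction <- function(variants, cap = 1) {
  som <- which(variants$somatic_status == "somatic" &
                 !is.na(variants$allele_fraction) &
                 variants$allele_fraction > 0)
  est <- rep(NA_real_, length(som))
  skipped <- 0L
  for (i in seq_along(som)) {
    r <- som[i]
    mc <- variants$mutated_copies[r]; wc <- variants$wildtype_copies[r]
    if (is.na(mc) || is.na(wc)) { skipped <- skipped + 1L; next }
    v <- tryCatch(
      sgz_variant_tumor_fraction(variants$allele_fraction[r], mc, wc),
      error = function(e) NA_real_)
    if (is.na(v)) { skipped <- skipped + 1L; next }
    est[i] <- v
  }
  if (all(is.na(est))) {
    res <- tf_result()
  } else {
    best <- which.max(est)
    raw <- est[best]
    val <- raw
    if (raw > cap) {
      warning(sprintf("tumor fraction %.4f exceeds cap; capped to %.2f", raw, cap))
      val <- cap
    }
    res <- tf_result(val, "sgz_max", som[best])
    attr(res, "raw_value") <- raw
  }
  attr(res, "skipped") <- skipped
  res
}
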