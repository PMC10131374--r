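# Convenience VCF ingestion.  The flat tab-delimited table is the canonical
# interchange format (VCF has no natural slots for copy numbers or CH
# flags); this reader maps the conventional INFO keys onto it.

#' Read variant calls from a VCF file
#'
#' Maps per-record INFO keys onto the variant-table columns: `AF` (allele
#' fraction), `SOMATIC` (somatic/germline/ambiguous, default somatic),
#' `CH` (0/1 clonal-hematopoiesis flag), `ONC` (known/likely/VUS, default
#' VUS), `GENE`, `PCHANGE`, `TYPE` (alteration type, default SNV), and in
#' tissue mode `MC`/`WC` (mutated/wild-type copies).  Multi-sample VCFs are
#' not supported; the sample id is taken from the single genotype column
#' name, or from `sample_id` when the VCF has no genotype columns.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF.
#' @param assay_mode `"ctdna"` or `"tissue"`.
#' @param sample_id Fallback sample id when no genotype column is present.
#' @return A `sample_profiles` object, as from [read_variant_table()].
#' @export
read_variant_vcf <- function(path, assay_mode = c("ctdna", "tissue"),
                             sample_id = NULL) {
  assay_mode <- match.arg(assay_mode)
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("the vcfR package is required to read VCF input", call. = FALSE)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  n <- nrow(vcf@fix)
  if (n == 0) {
    return(sample_profiles(
      utils::read.table(text = "", col.names = VARIANT_COLUMNS,
                        colClasses = c(rep("character", 4), "numeric",
                                       "character", "logical", "character",
                                       "numeric", "numeric")),
      assay_mode))
  }
  info <- function(key) vcfR::extract.info(vcf, element = key)
  gt_samples <- colnames(vcf@gt)
  sid <- if (!is.null(gt_samples) && length(gt_samples) > 1) {
    if (length(gt_samples) > 2) {
      stop("multi-sample VCFs are not supported", call. = FALSE)
    }
    gt_samples[2]
  } else {
    if (is.null(sample_id)) stop("no genotype column; supply sample_id",
                                 call. = FALSE)
    sample_id
  }
  pick <- function(x, default) ifelse(is.na(x), default, x)
  df <- data.frame(
    sample_id = sid,
    gene = info("GENE"),
    alteration_type = pick(info("TYPE"), "SNV"),
    protein_change = pick(info("PCHANGE"), "."),
    allele_fraction = suppressWarnings(as.numeric(info("AF"))),
    somatic_status = pick(info("SOMATIC"), "somatic"),
    ch_flag = pick(info("CH"), "0") %in% c("1", "TRUE", "true"),
    oncogenicity = pick(info("ONC"), "VUS"),
    mutated_copies = suppressWarnings(as.numeric(info("MC"))),
    wildtype_copies = suppressWarnings(as.numeric(info("WC"))),
    stringsAsFactors = FALSE
  )
  if (anyNA(df$gene)) {
    stop("VCF INFO field GENE is required on every record", call. = FALSE)
  }
  sample_profiles(df, assay_mode)
}
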