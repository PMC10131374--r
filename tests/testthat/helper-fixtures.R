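# In-code fixtures shared across test files.

make_variants <- function(sample_id, gene, allele_fraction,
                          alteration_type = "SNV",
                          protein_change = NULL,
                          somatic_status = "somatic",
                          ch_flag = FALSE,
                          oncogenicity = "known",
                          mutated_copies = NA_real_,
                          wildtype_copies = NA_real_) {
  n <- max(length(sample_id), length(gene), length(allele_fraction))
  if (is.null(protein_change)) protein_change <- sprintf("V%d", seq_len(n))
  data.frame(
    sample_id = rep_len(sample_id, n),
    gene = rep_len(gene, n),
    alteration_type = rep_len(alteration_type, n),
    protein_change = rep_len(protein_change, n),
    allele_fraction = rep_len(allele_fraction, n),
    somatic_status = rep_len(somatic_status, n),
    ch_flag = rep_len(ch_flag, n),
    oncogenicity = rep_len(oncogenicity, n),
    mutated_copies = rep_len(mutated_copies, n),
    wildtype_copies = rep_len(wildtype_copies, n),
    stringsAsFactors = FALSE
  )
}

write_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = ".",
                     row.names = FALSE)
  path
}

make_clinical <- function(sample_id, arm = "experimental", responder = FALSE,
                          pfs_time = 6, pfs_event = TRUE,
                          visceral_disease = "yes",
                          endocrine_sensitivity = "sensitive",
                          region = "europe") {
  n <- length(sample_id)
  data.frame(
    sample_id = sample_id,
    arm = rep_len(arm, n), responder = rep_len(responder, n),
    pfs_time = rep_len(pfs_time, n), pfs_event = rep_len(pfs_event, n),
    visceral_disease = rep_len(visceral_disease, n),
    endocrine_sensitivity = rep_len(endocrine_sensitivity, n),
    region = rep_len(region, n),
    stringsAsFactors = FALSE
  )
}

# Independent two-sided Fisher oracle: enumerate every table with the
# observed margins and sum hypergeometric point probabilities not exceeding
# that of the observed table.
fisher_oracle <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  x <- lo:hi
  probs <- stats::dhyper(x, c1, n - c1, r1)
  p_obs <- stats::dhyper(m[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Independent truth-table oracle for the clonality category: decide from
# the multiset counts alone, as a lookup over (n, n_unestimable, n_clonal).
category_oracle <- function(labels) {
  n <- length(labels)
  nu <- sum(labels == "unestimable")
  nc <- sum(labels == "clonal")
  if (n == 0) return("no_pik3ca")
  if (nu > 0) return("unestimable")
  if (n == 1 && nc == 1) return("clonal_single")
  if (n == 1) return("subclonal_single")
  if (nc >= 2) return("clonal_multiple")
  "subclonal_multiple"
}

random_2x2 <- function(max_total = 200) {
  repeat {
    m <- matrix(sample.int(max_total %/% 2, 4, replace = TRUE) - 1L, 2, 2)
    if (sum(m) > 0 && sum(m) <= max_total &&
        all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}
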