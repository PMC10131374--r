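# Gene- and pathway-level co-alteration status and exact 2x2 comparisons
# between clonality groups.  A pathway is "altered" when at least one gene
# on its list carries a pathogenic alteration (base substitution, indel,
# copy-number alteration or rearrangement of known or likely oncogenic
# significance).  The target gene itself is removed from its own pathway by
# default — every sample in a target-mutant cohort would otherwise count as
# pathway-altered.

#' Default signaling-pathway gene lists
#'
#' RTK, PI3K, MAPK and p53 pathway memberships restricted to a ~70-gene
#' liquid-panel-like universe.  These defaults are an approximation intended
#' for simulation and reuse — panel-specific published lists should be
#' supplied via `pathway_config()` when reproducing a particular study.
#' PIK3CA is excluded from the PI3K pathway in the default configuration.
#'
#' @return A `pathway_config` list with elements `pathways` (named list of
#'   gene-symbol vectors) and `excluded_genes` (named list of symbols removed
#'   before analysis).
#' @export
default_pathways <- function() {
  pathway_config(
    pathways = list(
      RTK  = c("EGFR", "ERBB2", "ERBB3", "MET", "FGFR1", "FGFR2", "FGFR3",
               "IGF1R", "KIT", "PDGFRA", "ALK", "NTRK1", "RET"),
      PI3K = c("PIK3CA", "PTEN", "AKT1", "AKT2", "AKT3", "PIK3R1", "MTOR",
               "TSC1", "TSC2", "RICTOR", "STK11"),
      MAPK = c("KRAS", "NRAS", "HRAS", "BRAF", "RAF1", "MAP2K1", "MAP2K2",
               "NF1"),
      p53  = c("TP53", "MDM2", "MDM4", "CDKN2A", "ATM", "CHEK2")
    ),
    excluded_genes = list(PI3K = "PIK3CA")
  )
}

#' Construct a pathway configuration
#'
#' @param pathways Named list mapping pathway name to gene symbols.
#' @param excluded_genes Named list mapping pathway name to symbols removed
#'   before analysis (e.g. the cohort-defining gene).
#' @return A `pathway_config` object.
#' @export
pathway_config <- function(pathways, excluded_genes = list()) {
  stopifnot(is.list(pathways), length(names(pathways)) == length(pathways))
  structure(list(pathways = pathways, excluded_genes = excluded_genes),
            class = "pathway_config")
}

retained_genes <- function(config, pathway) {
  if (!pathway %in% names(config$pathways)) {
    stop("unknown pathway: ", pathway, call. = FALSE)
  }
  setdiff(config$pathways[[pathway]],
          config$excluded_genes[[pathway]])
}

#' Is a pathway altered in a sample?
#'
#' `TRUE` iff the sample carries at least one alteration of known or likely
#' oncogenic significance in a retained gene of the pathway.
#'
#' @param variants Data frame of the sample's variant calls.
#' @param pathway Pathway name present in `config`.
#' @param config A `pathway_config` (default [default_pathways()]).
#' @return Logical scalar.
#' @export
pathway_altered <- function(variants, pathway, config = default_pathways()) {
  genes <- retained_genes(config, pathway)
  any(variants$gene %in% genes &
        variants$oncogenicity %in% c("known", "likely"))
}

#' Sample-by-gene (or -pathway) alteration matrix
#'
#' Gene level: an integer matrix counting the distinct pathogenic alteration
#' types per gene per sample (0 = none, 1 = one type, >= 2 = multiple
#' alteration types in one gene).  Pathway level: a 0/1 matrix of pathway
#' alteration status per [pathway_altered()].
#'
#' @param profiles A `sample_profiles` object (or `clonality_fit`, whose
#'   variants are used).
#' @param level `"gene"` or `"pathway"`.
#' @param config Pathway configuration (pathway level only).
#' @return Integer matrix, rows = sample ids, columns = genes or pathways.
#' @export
alteration_matrix <- function(profiles, level = c("gene", "pathway"),
                              config = default_pathways()) {
  level <- match.arg(level)
  if (inherits(profiles, "clonality_fit")) {
    v <- profiles$variants
    ids <- profiles$samples$sample_id
  } else {
    v <- profiles$variants
    ids <- profiles$sample_ids
  }
  path <- v$oncogenicity %in% c("known", "likely")
  v <- v[path, , drop = FALSE]
  if (level == "gene") {
    genes <- sort(unique(v$gene))
    m <- matrix(0L, length(ids), length(genes),
                dimnames = list(ids, genes))
    if (nrow(v) > 0) {
      key <- paste(v$sample_id, v$gene, v$alteration_type, sep = "\r")
      v2 <- v[!duplicated(key), , drop = FALSE]
      tab <- table(factor(v2$sample_id, levels = ids),
                   factor(v2$gene, levels = genes))
      m[] <- as.integer(tab)
    }
    m
  } else {
    pws <- names(config$pathways)
    m <- matrix(0L, length(ids), length(pws), dimnames = list(ids, pws))
    for (p in pws) {
      genes <- retained_genes(config, p)
      hit <- unique(v$sample_id[v$gene %in% genes])
      m[ids %in% hit, p] <- 1L
    }
    m
  }
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by the point-probability rule: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table (within
#' relative tolerance 1e-7).  A table with an all-zero margin carries no
#' information and returns p = 1 with a warning.
#'
#' @param table 2x2 matrix (or length-4 vector, filled by row) of
#'   nonnegative integer counts.
#' @return The two-sided p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(table) {
  m <- if (is.matrix(table)) {
    matrix(as.numeric(table), 2, 2)
  } else {
    matrix(as.numeric(table), 2, 2, byrow = TRUE)
  }
  if (any(m < 0) || any(m != round(m))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    warning("degenerate 2x2 table (all-zero margin); p = 1")
    return(1)
  }
  stats::fisher.test(m)$p.value
}

#' Compare alteration rates between two sample groups
#'
#' For each column of an alteration matrix, builds the 2x2 table of
#' altered/unaltered by group and tests it with [fisher_exact_2x2()].
#' Columns altered in neither group are omitted (tile-plot semantics);
#' p-values are unadjusted by default, matching exploratory-analysis
#' convention, with optional Benjamini-Hochberg adjustment.
#'
#' @param matrix Alteration matrix from [alteration_matrix()].
#' @param group_a,group_b Disjoint character vectors of sample ids, all
#'   present among the matrix rows.
#' @param adjust Add a `p_adjusted` column (Benjamini-Hochberg).
#' @return Data frame of class `group_comparison`: one row per retained
#'   column with counts, proportions and the Fisher p-value.
#' @export
compare_groups <- function(matrix, group_a, group_b, adjust = FALSE) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  if (length(intersect(group_a, group_b)) > 0) {
    stop("groups must be disjoint", call. = FALSE)
  }
  missing <- setdiff(c(group_a, group_b), rownames(matrix))
  if (length(missing) > 0) {
    stop("sample id(s) not in matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  na <- length(group_a); nb <- length(group_b)
  rows <- lapply(colnames(matrix), function(col) {
    aa <- sum(matrix[group_a, col] > 0)
    ab <- sum(matrix[group_b, col] > 0)
    if (aa == 0 && ab == 0) return(NULL)
    p <- suppressWarnings(
      fisher_exact_2x2(matrix(c(aa, na - aa, ab, nb - ab), 2, 2)))
    data.frame(label = col,
               altered_a = aa, n_a = na, prop_a = aa / na,
               altered_b = ab, n_b = nb, prop_b = ab / nb,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(label = character(0), altered_a = integer(0),
                      n_a = integer(0), prop_a = numeric(0),
                      altered_b = integer(0), n_b = integer(0),
                      prop_b = numeric(0), p_value = numeric(0))
  }
  if (adjust) out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' @export
print.group_comparison <- function(x, digits = 4, ...) {
  cat("Alteration-rate comparison (Fisher's exact test, two-sided):\n")
  y <- as.data.frame(x)
  y$prop_a <- sprintf("%.1f%%", 100 * y$prop_a)
  y$prop_b <- sprintf("%.1f%%", 100 * y$prop_b)
  y$p_value <- signif(y$p_value, digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Pairwise pathway co-occurrence / mutual exclusivity
#'
#' For every pair of pathways, crosses their alteration status across
#' samples into a 2x2 table, tests it with [fisher_exact_2x2()] and reports
#' the odds ratio.  When any cell is zero the Haldane-Anscombe correction
#' (0.5 added to every cell) keeps the odds ratio finite; the `corrected`
#' column records when it was applied.
#'
#' @param pathway_matrix 0/1 matrix from
#'   `alteration_matrix(..., level = "pathway")`.
#' @param pathways Pathway names to cross (default: all columns).
#' @return Data frame with one row per unordered pair: joint counts,
#'   `odds_ratio`, `corrected`, `p_value`.
#' @export
pairwise_pathway_association <- function(pathway_matrix,
                                         pathways = colnames(pathway_matrix)) {
  if (length(pathways) < 2) stop("need at least two pathways", call. = FALSE)
  pairs <- utils::combn(pathways, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    p1 <- pairs[1, k]; p2 <- pairs[2, k]
    a1 <- pathway_matrix[, p1] > 0; a2 <- pathway_matrix[, p2] > 0
    tab <- c(both = sum(a1 & a2), only_a = sum(a1 & !a2),
             only_b = sum(!a1 & a2), neither = sum(!a1 & !a2))
    m <- matrix(tab, 2, 2, byrow = TRUE)
    p <- suppressWarnings(fisher_exact_2x2(m))
    corrected <- any(m == 0)
    mm <- if (corrected) m + 0.5 else m
    or <- (mm[1, 1] * mm[2, 2]) / (mm[1, 2] * mm[2, 1])
    data.frame(pathway_a = p1, pathway_b = p2,
               both = tab[["both"]], only_a = tab[["only_a"]],
               only_b = tab[["only_b"]], neither = tab[["neither"]],
               odds_ratio = or, corrected = corrected, p_value = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
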