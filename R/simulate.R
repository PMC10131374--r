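# Truth-labelled synthetic cohorts.
#
# The generator emulates the statistical structure the clonality analysis
# assumes: per-sample ctDNA shed drawn lognormally; truncal and subclonal
# target-gene mutations at assigned cancer-cell fractions (CCF); observed
# allele fractions from binomial read sampling at fixed depth under the
# heterozygous-diploid model AF = CCF * shed / 2; clonal-hematopoiesis and
# germline contaminants; pathway co-alterations at category-specific rates;
# and Bernoulli response / Weibull progression-free survival with
# category- and arm-specific parameters.  Detection is not modelled: every
# simulated variant row is emitted, possibly with observed AF = 0.

PIK3CA_HOTSPOTS <- c("H1047R", "E545K", "E542K", "H1047L", "E726K", "C420R",
                     "N345K", "Q546R", "M1043I", "G118D", "K111E", "R88Q")
PASSENGER_GENES <- c("GATA3", "MAP3K1", "CBFB", "NCOR1", "RUNX1", "SF3B1")
GERMLINE_GENES  <- c("APC", "MUTYH")

#' Simulation configuration
#'
#' Defaults describe a liquid-biopsy breast-cancer trial cohort: 339
#' samples, 2:1 experimental:control randomisation, ~20% of samples with
#' multiple target-gene mutations of which 71.2% are clonal, 91.1% clonal
#' among single-mutation samples, 5000x depth, lognormal shed with median
#' 8%, and pathway co-alteration / response / PFS parameters by clonality
#' category.  See the package vignette for the rationale behind each value.
#'
#' @param n_samples Number of samples.
#' @param seed Integer seed governing every draw (single RNG stream).
#' @param assay_mode `"ctdna"` or `"tissue"`.
#' @param depth Sequencing depth (reads) for binomial AF noise.
#' @param shed_meanlog,shed_sdlog Lognormal parameters of the ctDNA shed
#'   (tissue mode: tumor purity).
#' @param shed_range Truncation interval for the shed, within (0, 1].  A
#'   degenerate interval `c(0, 0)` produces sheds of exactly zero (no
#'   signal).
#' @param p_multiple Probability a sample carries >= 2 target mutations.
#' @param p_clonal_given_multiple,p_clonal_given_single Probability the
#'   sample's true category is clonal, by multiplicity.
#' @param p_one_clonal_given_subclonal_multiple Within true subclonal
#'   multiples, probability that exactly one mutation is clonal (the rest
#'   subclonal) rather than all subclonal.
#' @param p_third_mutation Probability a multiple-mutation sample carries a
#'   third target mutation.
#' @param ccf_clonal_range,ccf_subclonal_range CCF intervals for truly
#'   clonal / subclonal mutations.
#' @param ch_rate Per-sample probability of a clonal-hematopoiesis variant.
#' @param ch_af_range True AF interval for CH variants.
#' @param germline_rate Per-sample probability of a germline variant
#'   (true AF 0.5).
#' @param mean_extra_passengers Poisson mean of additional somatic
#'   passengers beyond the truncal anchor (CCF 1) that every sample carries.
#' @param pathway_rates Matrix (categories x pathways) of co-alteration
#'   probabilities; see [default_pathway_rates()].
#' @param pathway_config Pathway gene lists used to draw co-altered genes.
#' @param orr Matrix (categories x arms `control`/`experimental`) of
#'   response probabilities; see [default_orr_rates()].
#' @param median_pfs Matrix (categories x arms) of median PFS in months;
#'   see [default_median_pfs()].
#' @param weibull_shape Weibull shape of the PFS distribution.
#' @param censoring_rate Rate (per month) of independent exponential
#'   censoring.
#' @param p_experimental Randomisation probability to the experimental arm.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_samples = 339,
                              seed = 1L,
                              assay_mode = c("ctdna", "tissue"),
                              depth = 5000L,
                              shed_meanlog = log(0.08),
                              shed_sdlog = 1.0,
                              shed_range = c(1e-6, 1),
                              p_multiple = 66 / 337,
                              p_clonal_given_multiple = 0.712,
                              p_clonal_given_single = 247 / 271,
                              p_one_clonal_given_subclonal_multiple = 15 / 19,
                              p_third_mutation = 0.15,
                              ccf_clonal_range = c(0.6, 1),
                              ccf_subclonal_range = c(0.04, 0.20),
                              ch_rate = 0.25,
                              ch_af_range = c(0.002, 0.05),
                              germline_rate = 0.5,
                              mean_extra_passengers = 1,
                              pathway_rates = default_pathway_rates(),
                              pathway_config = default_pathways(),
                              orr = default_orr_rates(),
                              median_pfs = default_median_pfs(),
                              weibull_shape = 1.2,
                              censoring_rate = 0.03,
                              p_experimental = 2 / 3) {
  assay_mode <- match.arg(assay_mode)
  cfg <- as.list(environment())
  probs <- c(p_multiple, p_clonal_given_multiple, p_clonal_given_single,
             p_one_clonal_given_subclonal_multiple, p_third_mutation,
             ch_rate, germline_rate, p_experimental)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (depth <= 0) stop("depth must be positive")
  for (rg in list(ccf_clonal_range, ccf_subclonal_range)) {
    if (length(rg) != 2 || rg[1] > rg[2] || rg[1] < 0 || rg[2] > 1) {
      stop("ccf ranges must be nonempty intervals within [0, 1]")
    }
  }
  class(cfg) <- "simulation_config"
  cfg
}

sim_categories <- c("clonal_single", "subclonal_single",
                    "clonal_multiple", "subclonal_multiple")

#' Default category-specific pathway co-alteration rates
#'
#' Per-category probabilities that a sample carries at least one pathogenic
#' alteration in a pathway.  Multiple-mutation rates follow the reported
#' ctDNA cohort contrasts (RTK 19.1% clonal vs 47.4% subclonal; PI3K and
#' MAPK from the large tissue cohort); single-mutation and p53 rates, not
#' reported as contrasts, are set to plausible mid values.
#'
#' @return Numeric matrix, rows = clonality categories, columns = pathways.
#' @export
default_pathway_rates <- function() {
  m <- rbind(
    clonal_single      = c(RTK = 0.25, PI3K = 0.08, MAPK = 0.20, p53 = 0.45),
    subclonal_single   = c(RTK = 0.25, PI3K = 0.08, MAPK = 0.20, p53 = 0.45),
    clonal_multiple    = c(RTK = 0.191, PI3K = 0.061, MAPK = 0.240, p53 = 0.45),
    subclonal_multiple = c(RTK = 0.474, PI3K = 0.131, MAPK = 0.165, p53 = 0.45)
  )
  m
}

#' Default response rates by category and arm
#'
#' Observed trial response proportions: clonal multiples 2/18 (control) and
#' 12/29 (experimental); subclonal multiples 0/5 and 1/14; singles set to
#' the reported clonal/subclonal single rates.
#'
#' @return Numeric matrix, rows = categories, columns = arms.
#' @export
default_orr_rates <- function() {
  rbind(
    clonal_single      = c(control = 0.095, experimental = 0.17),
    subclonal_single   = c(control = 0.17,  experimental = 0.28),
    clonal_multiple    = c(control = 2 / 18, experimental = 12 / 29),
    subclonal_multiple = c(control = 0.0,   experimental = 1 / 14)
  )
}

#' Default median progression-free survival (months) by category and arm
#'
#' Multiples follow the reported medians (3.9/2.0 months control,
#' 7.6/5.1 months experimental for clonal/subclonal); singles use the
#' trial-level medians (5.4 control, 7.4 experimental).
#'
#' @return Numeric matrix, rows = categories, columns = arms.
#' @export
default_median_pfs <- function() {
  rbind(
    clonal_single      = c(control = 5.4, experimental = 7.4),
    subclonal_single   = c(control = 5.4, experimental = 7.4),
    clonal_multiple    = c(control = 3.9, experimental = 7.6),
    subclonal_multiple = c(control = 2.0, experimental = 5.1)
  )
}

runif_range <- function(n, range) stats::runif(n, range[1], range[2])

draw_shed <- function(cfg) {
  if (cfg$shed_range[2] <= 0) return(0)
  repeat {
    s <- stats::rlnorm(1, cfg$shed_meanlog, cfg$shed_sdlog)
    if (s >= cfg$shed_range[1] && s <= cfg$shed_range[2]) return(s)
  }
}

observe_af <- function(true_af, depth) {
  stats::rbinom(length(true_af), depth, pmin(true_af, 1)) / depth
}

#' Simulate a truth-labelled cohort
#'
#' Draws, per sample and in a fixed documented order from a single RNG
#' stream: ctDNA shed; true clonality category; target-gene mutation CCFs;
#' the truncal somatic passenger anchor (CCF 1) plus extra passengers;
#' clonal-hematopoiesis and germline contaminants; pathway co-alterations;
#' then arm, stratification factors, response and PFS.  Observed allele
#' fractions are binomial draws at the configured depth; copy-number
#' columns are 1/1 (heterozygous diploid) in tissue mode and absent in
#' ctDNA mode.
#'
#' @param config A [simulation_config()].
#' @param seed Optional integer overriding `config$seed`.
#' @return A `synthetic_cohort` list: `variants` (variant table data
#'   frame), `clinical` (clinical table data frame), `truth` (list of data
#'   frames `samples`, `variants`, `pathways`), and `config`.
#' @export
simulate_cohort <- function(config = simulation_config(), seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(seed)) config$seed <- seed
  set.seed(config$seed)
  tissue <- config$assay_mode == "tissue"
  mc_val <- if (tissue) 1 else NA_real_

  vrows <- list(); trows <- list(); crows <- list(); prows <- list()
  srows <- list()
  pw_names <- colnames(config$pathway_rates)

  add_variant <- function(sid, gene, type, pchg, true_af, status, ch, onc,
                          ccf = NA_real_, role = "other") {
    af_obs <- if (is.na(true_af)) NA_real_ else
      observe_af(true_af, config$depth)
    vrows[[length(vrows) + 1L]] <<- data.frame(
      sample_id = sid, gene = gene, alteration_type = type,
      protein_change = pchg, allele_fraction = af_obs,
      somatic_status = status, ch_flag = ch, oncogenicity = onc,
      mutated_copies = if (type == "SNV") mc_val else NA_real_,
      wildtype_copies = if (type == "SNV") mc_val else NA_real_,
      stringsAsFactors = FALSE)
    trows[[length(trows) + 1L]] <<- data.frame(
      sample_id = sid, gene = gene, protein_change = pchg,
      true_af = true_af, true_ccf = ccf, role = role,
      stringsAsFactors = FALSE)
  }

  for (i in seq_len(config$n_samples)) {
    sid <- sprintf("S%04d", i)
    shed <- draw_shed(config)

    multiple <- stats::runif(1) < config$p_multiple
    clonal <- stats::runif(1) <
      (if (multiple) config$p_clonal_given_multiple
       else config$p_clonal_given_single)
    category <- if (multiple) {
      if (clonal) "clonal_multiple" else "subclonal_multiple"
    } else {
      if (clonal) "clonal_single" else "subclonal_single"
    }

    n_mut <- if (!multiple) 1L else
      2L + (stats::runif(1) < config$p_third_mutation)
    labels <- switch(category,
      clonal_single = "clonal",
      subclonal_single = "subclonal",
      clonal_multiple = rep("clonal", n_mut),
      subclonal_multiple = {
        one_clonal <- stats::runif(1) <
          config$p_one_clonal_given_subclonal_multiple
        c(if (one_clonal) "clonal" else "subclonal",
          rep("subclonal", n_mut - 1L))
      })
    ccfs <- ifelse(labels == "clonal",
                   runif_range(n_mut, config$ccf_clonal_range),
                   runif_range(n_mut, config$ccf_subclonal_range))
    pchg <- sample(PIK3CA_HOTSPOTS, n_mut)
    for (k in seq_len(n_mut)) {
      add_variant(sid, "PIK3CA", "SNV", pchg[k], ccfs[k] * shed / 2,
                  "somatic", FALSE, "known", ccf = ccfs[k], role = "target")
    }

    # truncal somatic passenger anchoring MSAF at ~ shed / 2
    add_variant(sid, sample(PASSENGER_GENES, 1), "SNV",
                sprintf("P%d", sample.int(500, 1)), shed / 2,
                "somatic", FALSE, "VUS", ccf = 1, role = "passenger")
    n_extra <- stats::rpois(1, config$mean_extra_passengers)
    for (k in seq_len(n_extra)) {
      ccf <- stats::runif(1, 0.1, 1)
      add_variant(sid, sample(PASSENGER_GENES, 1), "SNV",
                  sprintf("P%d", sample.int(500, 1)), ccf * shed / 2,
                  "somatic", FALSE, "VUS", ccf = ccf, role = "passenger")
    }

    if (stats::runif(1) < config$ch_rate) {
      add_variant(sid, sample(default_ch_genes(), 1), "SNV",
                  sprintf("C%d", sample.int(500, 1)),
                  runif_range(1, config$ch_af_range),
                  "somatic", TRUE, "VUS", role = "ch")
    }
    if (stats::runif(1) < config$germline_rate) {
      add_variant(sid, sample(GERMLINE_GENES, 1), "SNV",
                  sprintf("G%d", sample.int(500, 1)), 0.5,
                  "germline", FALSE, "VUS", role = "germline")
    }

    pw_status <- stats::setNames(logical(length(pw_names)), pw_names)
    for (pw in pw_names) {
      if (stats::runif(1) < config$pathway_rates[category, pw]) {
        pw_status[pw] <- TRUE
        genes <- retained_genes(config$pathway_config, pw)
        g <- sample(genes, 1)
        is_snv <- stats::runif(1) < 0.8
        ccf <- stats::runif(1, 0.3, 1)
        add_variant(sid, g,
                    if (is_snv) "SNV" else "CNA-amplification",
                    if (is_snv) sprintf("A%d", sample.int(500, 1)) else "amp",
                    if (is_snv) ccf * shed / 2 else NA_real_,
                    "somatic", FALSE, "known", ccf = ccf, role = "pathway")
      }
    }
    prows[[length(prows) + 1L]] <- data.frame(
      sample_id = sid, t(as.integer(pw_status)), stringsAsFactors = FALSE)

    arm <- if (stats::runif(1) < config$p_experimental) "experimental"
           else "control"
    responder <- stats::runif(1) < config$orr[category, arm]
    med <- config$median_pfs[category, arm]
    scale <- med / log(2)^(1 / config$weibull_shape)
    t_event <- stats::rweibull(1, shape = config$weibull_shape, scale = scale)
    t_cens <- if (config$censoring_rate > 0)
      stats::rexp(1, config$censoring_rate) else Inf
    pfs_time <- max(min(t_event, t_cens), 1e-3)
    crows[[length(crows) + 1L]] <- data.frame(
      sample_id = sid, arm = arm, responder = responder,
      pfs_time = pfs_time, pfs_event = t_event <= t_cens,
      visceral_disease = sample(c("yes", "no"), 1),
      endocrine_sensitivity = sample(c("sensitive", "resistant"), 1),
      region = sample(c("north_america", "europe", "asia_pacific", "other"), 1),
      stringsAsFactors = FALSE)
    srows[[length(srows) + 1L]] <- data.frame(
      sample_id = sid, true_category = category, true_shed = shed,
      n_target_mut = n_mut, arm = arm,
      true_orr = config$orr[category, arm], true_median_pfs = med,
      stringsAsFactors = FALSE)
  }

  pathways_df <- do.call(rbind, prows)
  names(pathways_df) <- c("sample_id", pw_names)
  structure(
    list(
      variants = do.call(rbind, vrows),
      clinical = do.call(rbind, crows),
      truth = list(samples = do.call(rbind, srows),
                   variants = do.call(rbind, trows),
                   pathways = pathways_df),
      config = config
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$truth$samples), "samples,",
      nrow(x$variants), "variant rows (seed", x$config$seed, ")\n")
  print(table(x$truth$samples$true_category))
  invisible(x)
}

#' Score inferred categories and clonal fractions against simulation truth
#'
#' @param truth The `truth` component of a [simulate_cohort()] result.
#' @param fit A `clonality_fit` on the cohort's variant table (or a data
#'   frame with `sample_id` and `clonality_category`).
#' @return List: `confusion` (true x inferred contingency table), `accuracy`
#'   (overall, over samples with an inferable truth), `ccf_mae` (mean
#'   absolute error of the capped clonal fraction against true CCF for
#'   target-gene mutations), `n`.
#' @export
truth_scorecard <- function(truth, fit) {
  inferred <- if (inherits(fit, "clonality_fit")) fit$samples else fit
  ts <- truth$samples
  if (!setequal(ts$sample_id, inferred$sample_id)) {
    stop("sample ids of truth and inferred categories do not match",
         call. = FALSE)
  }
  m <- match(ts$sample_id, inferred$sample_id)
  inf_cat <- inferred$clonality_category[m]
  confusion <- table(truth = ts$true_category, inferred = inf_cat)
  accuracy <- mean(inf_cat == ts$true_category)
  ccf_mae <- NA_real_
  if (inherits(fit, "clonality_fit")) {
    tv <- truth$variants[truth$variants$role == "target", , drop = FALSE]
    calls <- fit$calls[fit$calls$target_gene, , drop = FALSE]
    key_t <- paste(tv$sample_id, tv$gene, tv$protein_change)
    key_c <- paste(calls$sample_id, calls$gene, calls$protein_change)
    mm <- match(key_t, key_c)
    est <- calls$clonal_fraction[mm]
    ok <- !is.na(est)
    if (any(ok)) ccf_mae <- mean(abs(est[ok] - tv$true_ccf[ok]))
  }
  list(confusion = confusion, accuracy = accuracy, ccf_mae = ccf_mae,
       n = nrow(ts))
}
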