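# End-to-end orchestration: simulate (or ingest) -> categorize -> compare
# co-alterations -> outcomes, with flat-file stage outputs and a manifest of
# digests so any run can be reproduced or any stage rerun in isolation.

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

load_run_config <- function(config) {
  if (inherits(config, "simulation_config")) return(config)
  if (is.character(config)) {
    ext <- tolower(tools::file_ext(config))
    lst <- if (ext %in% c("yml", "yaml")) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("yaml package required to read YAML configs", call. = FALSE)
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
    return(do.call(simulation_config, lst))
  }
  if (is.list(config)) return(do.call(simulation_config, config))
  stop("config must be a simulation_config, a list, or a JSON/YAML path",
       call. = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes all stages in order against a simulated cohort (or supplied
#' variant/clinical tables): clonality categorisation with cohort-flow
#' counts, gene- and pathway-level comparisons between clonal-multiple and
#' subclonal-multiple samples, pairwise pathway association, and
#' response/PFS analyses.  Every stage writes flat tab-delimited/JSON files
#' under `out_dir`; a `manifest.json` records the seed, package version,
#' config snapshot and MD5 digests of all outputs.
#'
#' @param config A [simulation_config()], a list of its arguments, or a
#'   path to a JSON/YAML file of them.
#' @param out_dir Output directory (created if needed).
#' @param variants_path,clinical_path Optional paths to existing tables;
#'   when given, the simulate stage is skipped (and with no clinical table
#'   the outcomes stage is skipped with a notice).
#' @param quiet Suppress stage log lines.
#' @return The manifest, invisibly, as a list.
#' @export
run_all <- function(config = simulation_config(), out_dir,
                    variants_path = NULL, clinical_path = NULL,
                    quiet = FALSE) {
  config <- load_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  outputs <- character(0)
  t0 <- Sys.time()
  out <- function(name) {
    p <- file.path(out_dir, name)
    outputs <<- c(outputs, p)
    p
  }

  truth <- NULL
  if (is.null(variants_path)) {
    stage("simulate", {
      say("[simulate] generating cohort (n = %d, seed = %d)",
          config$n_samples, config$seed)
      cohort <- simulate_cohort(config)
      write_tsv_dots(cohort$variants, out("variants.tsv"))
      write_tsv_dots(cohort$clinical, out("clinical.tsv"))
      write_tsv_dots(cohort$truth$samples, out("truth_samples.tsv"))
      write_tsv_dots(cohort$truth$variants, out("truth_variants.tsv"))
      truth <- cohort$truth
      variants_path <- file.path(out_dir, "variants.tsv")
      clinical_path <- file.path(out_dir, "clinical.tsv")
    })
  }

  fit <- NULL; flow <- NULL; clinical <- NULL
  stage("categorize", {
    profiles <- read_variant_table(variants_path, config$assay_mode)
    fit <- estimate_clonality(profiles)
    write_category_table(fit, out("categories.tsv"))
    arms <- NULL
    if (!is.null(clinical_path)) {
      clinical <- read_clinical_table(clinical_path)
      arms <- clinical
    }
    flow <- cohort_flow(fit, arms)
    write_tsv_dots(as.data.frame(flow), out("flow_counts.tsv"))
    jsonlite::write_json(
      list(counts = as.data.frame(flow),
           excluded = attr(flow, "excluded")),
      out("flow_counts.json"), auto_unbox = TRUE, digits = NA)
    say("[categorize] %d samples categorised (%d unestimable)",
        nrow(fit$samples), attr(flow, "excluded"))
  })

  stage("coalter", {
    cm <- fit$samples$sample_id[fit$samples$clonality_category ==
                                  "clonal_multiple"]
    sm <- fit$samples$sample_id[fit$samples$clonality_category ==
                                  "subclonal_multiple"]
    if (length(cm) > 0 && length(sm) > 0) {
      gm <- alteration_matrix(fit, "gene")
      pm <- alteration_matrix(fit, "pathway", config$pathway_config)
      write_tsv_dots(as.data.frame(
        compare_groups(gm, cm, sm)), out("gene_comparisons.tsv"))
      write_tsv_dots(as.data.frame(
        compare_groups(pm, cm, sm)), out("pathway_comparisons.tsv"))
      write_tsv_dots(pairwise_pathway_association(pm),
                     out("pathway_pairs.tsv"))
      say("[coalter] compared %d clonal-multiple vs %d subclonal-multiple",
          length(cm), length(sm))
    } else {
      say("[coalter] skipped: a multiple-mutation group is empty")
    }
  })

  if (is.null(clinical)) {
    say("[outcomes] skipped: no clinical table supplied")
  } else {
    stage("outcomes", {
      dat <- merge(fit$samples, clinical, by = "sample_id")
      orr_rows <- list(); surv_rows <- list()
      for (cat in intersect(c("clonal_multiple", "subclonal_multiple",
                              "clonal_single", "subclonal_single"),
                            unique(dat$clonality_category))) {
        for (a in c("all", "control", "experimental")) {
          sub <- dat[dat$clonality_category == cat &
                       (a == "all" | dat$arm == a), , drop = FALSE]
          sub <- sub[!is.na(sub$responder), , drop = FALSE]
          if (nrow(sub) == 0) next
          o <- orr_exact_ci(sum(sub$responder), nrow(sub))
          orr_rows[[length(orr_rows) + 1L]] <- data.frame(
            category = cat, arm = a, responders = o$responders,
            total = o$total, orr = o$orr, ci_low = o$ci_low,
            ci_high = o$ci_high)
        }
      }
      for (a in c("control", "experimental")) {
        g1 <- dat[dat$clonality_category == "clonal_multiple" &
                    dat$arm == a, ]
        g2 <- dat[dat$clonality_category == "subclonal_multiple" &
                    dat$arm == a, ]
        if (nrow(g1) == 0 || nrow(g2) == 0) next
        if (sum(g1$pfs_event) + sum(g2$pfs_event) == 0) next
        cmp <- suppressWarnings(compare_survival(g2$pfs_time, g2$pfs_event,
                                g1$pfs_time, g1$pfs_event,
                                labels = c("subclonal_multiple",
                                           "clonal_multiple")))
        surv_rows[[length(surv_rows) + 1L]] <- data.frame(
          arm = a, median_clonal = cmp$median_b,
          median_subclonal = cmp$median_a,
          hr_clonal_vs_subclonal = cmp$hazard_ratio,
          hr_ci_low = cmp$hr_ci[1], hr_ci_high = cmp$hr_ci[2],
          logrank_p = cmp$logrank_p)
      }
      p_orr <- NA_real_
      cmn <- dat$clonality_category == "clonal_multiple" & !is.na(dat$responder)
      smn <- dat$clonality_category == "subclonal_multiple" &
        !is.na(dat$responder)
      if (any(cmn) && any(smn)) {
        p_orr <- compare_orr(sum(dat$responder[cmn]), sum(cmn),
                             sum(dat$responder[smn]), sum(smn))
      }
      write_tsv_dots(do.call(rbind, orr_rows), out("orr.tsv"))
      if (length(surv_rows) > 0) {
        write_tsv_dots(do.call(rbind, surv_rows), out("survival.tsv"))
      }
      jsonlite::write_json(list(orr_p_multiple = p_orr),
                           out("orr_tests.json"), auto_unbox = TRUE,
                           digits = NA)
      say("[outcomes] ORR and PFS summaries written")
    })
  }

  if (!is.null(truth)) {
    stage("scorecard", {
      sc <- truth_scorecard(truth, fit)
      jsonlite::write_json(
        list(accuracy = sc$accuracy, ccf_mae = sc$ccf_mae, n = sc$n),
        out("scorecard.json"), auto_unbox = TRUE, digits = NA)
      say("[scorecard] category accuracy %.3f", sc$accuracy)
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("clonarch")),
    seed = config$seed,
    config = config[setdiff(names(config),
                            c("pathway_config", "pathway_rates", "orr",
                              "median_pfs"))],
    outputs = as.list(tools::md5sum(outputs)),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
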