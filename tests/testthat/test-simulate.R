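test_that("simulation is bit-reproducible under a fixed seed", {
  cfg <- simulation_config(n_samples = 40, seed = 17)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$variants, b$variants)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth, b$truth)
  # a different seed changes the draw
  c <- simulate_cohort(cfg, seed = 18)
  expect_false(identical(a$variants, c$variants))
})

test_that("a cohort with no tumor shed is unestimable throughout", {
  cfg <- simulation_config(n_samples = 15, seed = 4, shed_range = c(0, 0),
                           ch_rate = 0, germline_rate = 0)
  co <- simulate_cohort(cfg)
  expect_true(all(co$variants$allele_fraction == 0, na.rm = TRUE))
  fit <- estimate_clonality(sample_profiles(co$variants, "ctdna"))
  expect_true(all(fit$samples$clonality_category == "unestimable"))
})

test_that("config validation rejects infeasible settings", {
  expect_error(simulation_config(p_multiple = 1.4), "probabilities")
  expect_error(simulation_config(depth = 0), "depth")
  expect_error(simulation_config(ccf_clonal_range = c(0.9, 0.2)),
               "ccf ranges")
})

test_that("truth category proportions match the configured probabilities", {
  cfg <- simulation_config(n_samples = 5000, seed = 21, depth = 100,
                           ch_rate = 0, germline_rate = 0,
                           mean_extra_passengers = 0)
  co <- simulate_cohort(cfg)
  ts <- co$truth$samples
  p_mult <- mean(ts$n_target_mut >= 2)
  tol <- 3 * sqrt(cfg$p_multiple * (1 - cfg$p_multiple) / 5000)
  expect_lt(abs(p_mult - cfg$p_multiple), tol)
  mult <- ts$true_category %in% c("clonal_multiple", "subclonal_multiple")
  share <- mean(ts$true_category[mult] == "clonal_multiple")
  tol2 <- 3 * sqrt(0.712 * 0.288 / sum(mult))
  expect_lt(abs(share - cfg$p_clonal_given_multiple), tol2)
})

test_that("observed AFs follow the heterozygous shed model", {
  cfg <- simulation_config(n_samples = 150, seed = 9, depth = 200000L,
                           shed_range = c(0.3, 1))
  co <- simulate_cohort(cfg)
  tv <- co$truth$variants
  tgt <- tv[tv$role == "target", ]
  obs <- co$variants[paste(co$variants$sample_id, co$variants$protein_change) %in%
                       paste(tgt$sample_id, tgt$protein_change), ]
  m <- match(paste(obs$sample_id, obs$protein_change),
             paste(tgt$sample_id, tgt$protein_change))
  shed <- co$truth$samples$true_shed[match(obs$sample_id,
                                           co$truth$samples$sample_id)]
  ratio <- obs$allele_fraction / tgt$true_ccf[m]
  expect_lt(mean(abs(ratio - shed / 2)), 0.002)
  expect_true(all(co$variants$allele_fraction <= 1, na.rm = TRUE))
})

test_that("high CH allele fractions never leak into MSAF", {
  cfg <- simulation_config(n_samples = 60, seed = 12, ch_rate = 1,
                           ch_af_range = c(0.6, 0.9),
                           shed_range = c(0.05, 0.5))
  co <- simulate_cohort(cfg)
  fit <- estimate_clonality(sample_profiles(co$variants, "ctdna"))
  v <- co$variants
  for (i in seq_len(nrow(fit$samples))) {
    sid <- fit$samples$sample_id[i]
    som <- v$somatic_status == "somatic" & !v$ch_flag & v$sample_id == sid &
      !is.na(v$allele_fraction) & v$allele_fraction > 0
    if (!any(som)) next
    expect_equal(fit$samples$tumor_fraction[i], max(v$allele_fraction[som]))
  }
})

test_that("tissue mode emits copy numbers consistent with purity recovery", {
  cfg <- simulation_config(n_samples = 80, seed = 6, assay_mode = "tissue",
                           depth = 20000L, shed_range = c(0.2, 0.9),
                           ch_rate = 0, germline_rate = 0)
  co <- simulate_cohort(cfg)
  snv <- co$variants$alteration_type == "SNV"
  expect_true(all(co$variants$mutated_copies[snv] == 1))
  fit <- estimate_clonality(sample_profiles(co$variants, "tissue"))
  m <- match(fit$samples$sample_id, co$truth$samples$sample_id)
  err <- abs(fit$samples$tumor_fraction - co$truth$samples$true_shed[m])
  # max over per-variant 2*AF estimates recovers purity closely
  expect_lt(stats::median(err / co$truth$samples$true_shed[m]), 0.05)
})

test_that("scorecard measures accuracy, MAE and fails on id mismatch", {
  cfg <- simulation_config(n_samples = 100, seed = 14, shed_range = c(0.2, 1))
  co <- simulate_cohort(cfg)
  fit <- estimate_clonality(sample_profiles(co$variants, "ctdna"))
  sc <- truth_scorecard(co$truth, fit)
  expect_true(sc$accuracy >= 0 && sc$accuracy <= 1)
  expect_true(sc$ccf_mae >= 0)

  # identity: scoring the truth against itself is perfect
  ident <- data.frame(sample_id = co$truth$samples$sample_id,
                      clonality_category = co$truth$samples$true_category)
  expect_equal(truth_scorecard(co$truth, ident)$accuracy, 1)

  # permutation baseline: uniform random labels over the 4 categories
  set.seed(2)
  rand <- ident
  accs <- replicate(40, {
    rand$clonality_category <- sample(
      c("clonal_single", "subclonal_single", "clonal_multiple",
        "subclonal_multiple"), nrow(rand), replace = TRUE)
    truth_scorecard(co$truth, rand)$accuracy
  })
  expect_lt(abs(mean(accs) - 0.25), 3 * sd(accs) / sqrt(40) + 0.02)

  bad <- ident[-1, ]
  expect_error(truth_scorecard(co$truth, bad), "do not match")
})

test_that("category accuracy is nondecreasing in sequencing depth", {
  acc <- sapply(c(100L, 10000L), function(d) {
    cfg <- simulation_config(n_samples = 150, seed = 33, depth = d,
                             shed_range = c(0.02, 0.3))
    co <- simulate_cohort(cfg)
    fit <- estimate_clonality(sample_profiles(co$variants, "ctdna"))
    truth_scorecard(co$truth, fit)$accuracy
  })
  expect_gte(acc[2], acc[1])
})
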