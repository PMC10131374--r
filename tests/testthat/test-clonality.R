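test_that("clonal fraction is AF over tumor fraction, capped at 1", {
  expect_equal(clonal_fraction(0.08, 0.32), 0.25, ignore_attr = TRUE)
  expect_equal(clonal_fraction(0.02, 0.32), 0.0625, ignore_attr = TRUE)
  expect_equal(clonal_fraction(0.32, 0.32), 1, ignore_attr = TRUE)
  capped <- clonal_fraction(0.5, 0.25)
  expect_equal(as.numeric(capped), 1)
  expect_equal(attr(capped, "raw"), 2)
  expect_error(clonal_fraction(0.1, 0), "positive")
})

test_that("labels use inclusive assay-mode thresholds", {
  expect_equal(label_variant(0.25, "ctdna"), "clonal")
  expect_equal(label_variant(0.2499, "ctdna"), "subclonal")
  expect_equal(label_variant(0.50, "tissue"), "clonal")
  expect_equal(label_variant(0.4999, "tissue"), "subclonal")
  expect_equal(label_variant(NA_real_, "ctdna"), "unestimable")
})

test_that("category rule matches the truth-table oracle for all multisets <= 4", {
  labs <- c("clonal", "subclonal", "unestimable")
  for (n in 0:4) {
    if (n == 0) {
      expect_equal(categorize_labels(character(0)), "no_pik3ca")
      next
    }
    grid <- do.call(expand.grid,
                    c(rep(list(labs), n), stringsAsFactors = FALSE))
    for (i in seq_len(nrow(grid))) {
      ls <- unlist(grid[i, ], use.names = FALSE)
      expect_equal(categorize_labels(ls), category_oracle(ls))
      # invariance to ordering
      expect_equal(categorize_labels(rev(ls)), categorize_labels(ls))
    }
  }
})

test_that("worked category examples behave as specified", {
  # two clonal PIK3CA SNVs -> clonal_multiple
  v <- make_variants("S", c("PIK3CA", "PIK3CA", "ESR1"),
                     c(0.12, 0.10, 0.13),
                     oncogenicity = c("known", "known", "VUS"))
  fit <- estimate_clonality(sample_profiles(v, "ctdna"))
  expect_equal(fit$samples$clonality_category, "clonal_multiple")

  # one clonal, one subclonal -> subclonal_multiple
  v2 <- make_variants("S", c("PIK3CA", "PIK3CA", "ESR1"),
                      c(0.12, 0.02, 0.13),
                      oncogenicity = c("known", "likely", "VUS"))
  expect_equal(estimate_clonality(
    sample_profiles(v2, "ctdna"))$samples$clonality_category,
    "subclonal_multiple")

  # three with labels {clonal, clonal, subclonal} -> clonal_multiple
  v3 <- make_variants("S", c(rep("PIK3CA", 3), "ESR1"),
                      c(0.12, 0.11, 0.02, 0.13),
                      oncogenicity = c(rep("known", 3), "VUS"))
  expect_equal(estimate_clonality(
    sample_profiles(v3, "ctdna"))$samples$clonality_category,
    "clonal_multiple")

  # a PIK3CA amplification does not count toward multiplicity
  v4 <- make_variants("S", c("PIK3CA", "PIK3CA", "ESR1"),
                      c(0.12, NA, 0.13),
                      alteration_type = c("SNV", "CNA-amplification", "SNV"),
                      oncogenicity = c("known", "known", "VUS"))
  expect_equal(estimate_clonality(
    sample_profiles(v4, "ctdna"))$samples$clonality_category,
    "clonal_single")

  # VUS PIK3CA SNVs are not pathogenic target mutations
  v5 <- make_variants("S", c("PIK3CA", "ESR1"), c(0.12, 0.13),
                      oncogenicity = c("VUS", "VUS"))
  expect_equal(estimate_clonality(
    sample_profiles(v5, "ctdna"))$samples$clonality_category, "no_pik3ca")

  # tumor fraction underivable with a pathogenic PIK3CA SNV -> unestimable
  v6 <- make_variants("S", c("PIK3CA", "BRCA2"), c(0, 0.5),
                      somatic_status = c("somatic", "germline"))
  expect_equal(estimate_clonality(
    sample_profiles(v6, "ctdna"))$samples$clonality_category, "unestimable")
})

test_that("the MSAF-defining variant has clonal fraction exactly 1", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(2:6, 1)
    v <- make_variants("S", c("PIK3CA", paste0("G", seq_len(n - 1))),
                       runif(n, 0.01, 0.4))
    fit <- estimate_clonality(sample_profiles(v, "ctdna"))
    top <- which.max(v$allele_fraction)
    expect_identical(fit$calls$clonal_fraction[top], 1)
    expect_equal(fit$calls$label[top], "clonal")
  }
})

test_that("raising a variant's AF never flips its own label to subclonal", {
  set.seed(5)
  others <- make_variants("S", paste0("G", 1:3), c(0.05, 0.18, 0.30))
  afs <- seq(0.005, 0.6, by = 0.005)
  labels <- vapply(afs, function(a) {
    v <- rbind(make_variants("S", "PIK3CA", a), others)
    estimate_clonality(sample_profiles(v, "ctdna"))$calls$label[1]
  }, character(1))
  num <- ifelse(labels == "clonal", 1L, 0L)
  expect_true(all(diff(num) >= 0L))
})

test_that("categorisation is invariant to variant ordering", {
  set.seed(23)
  v <- make_variants("S", c("PIK3CA", "PIK3CA", "PIK3CA", "G1", "G2"),
                     c(0.21, 0.03, 0.02, 0.25, 0.01))
  ref <- estimate_clonality(sample_profiles(v, "ctdna"))
  for (i in 1:5) {
    perm <- sample(nrow(v))
    fit <- estimate_clonality(sample_profiles(v[perm, ], "ctdna"))
    expect_equal(fit$samples$clonality_category, ref$samples$clonality_category)
  }
})

test_that("cohort flow tabulates categories, arms and exclusions", {
  mk <- function(sid, afs, onc = "known") {
    make_variants(sid, rep("PIK3CA", length(afs)), afs, oncogenicity = onc)
  }
  v <- rbind(
    mk("M1", c(0.2, 0.18)), mk("M2", c(0.2, 0.19)),      # clonal multiple
    mk("M3", c(0.2, 0.002)),                             # subclonal multiple
    mk("C1", 0.2),                                       # clonal single
    make_variants("U1", c("PIK3CA", "B"), c(0, 0.5),
                  somatic_status = c("somatic", "germline"))  # unestimable
  )
  fit <- estimate_clonality(sample_profiles(v, "ctdna"))
  arms <- c(M1 = "experimental", M2 = "control", M3 = "experimental",
            C1 = "experimental", U1 = "control")
  flow <- cohort_flow(fit, arms)
  counts <- setNames(flow$n, flow$category)
  expect_equal(counts[["clonal_multiple"]], 2L)
  expect_equal(counts[["subclonal_multiple"]], 1L)
  expect_equal(counts[["clonal_single"]], 1L)
  expect_equal(counts[["unestimable"]], 1L)
  expect_equal(attr(flow, "excluded"), 1L)
  expect_equal(sum(flow$control) + sum(flow$experimental), sum(flow$n))

  empty <- estimate_clonality(sample_profiles(v[0, ], "ctdna"))
  flow0 <- cohort_flow(empty)
  expect_true(all(flow0$n == 0L))
})
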