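test_that("BH adjustment matches hand computation and a brute-force oracle", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  for (seed in 1:5) {
    p <- withr::with_seed(seed, runif(50)^2)
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_warning(q <- bh_fdr(c(0.01, NaN, 0.5)), "missing")
  expect_true(is.na(q[2]))
})

test_that("BH output is permutation-equivariant and never below the raw minimum", {
  p <- withr::with_seed(1, runif(30))
  q <- bh_fdr(p)
  perm <- withr::with_seed(2, sample(30))
  expect_equal(bh_fdr(p[perm]), q[perm])
  expect_gte(min(q), min(p))
})

test_that("dispersion estimates recover simulated truth", {
  eff <- setNames(rep(1e4, 12), sprintf("s%02d", 1:12))
  # Poisson data: true phi = 0
  pois <- withr::with_seed(1, {
    m <- matrix(rpois(500 * 12, 100), 500, 12)
    dimnames(m) <- list(sprintf("f%03d", 1:500), names(eff))
    m
  })
  d <- estimate_dispersions(pois, eff)
  expect_lte(median(d$phi_mom), 0.05)

  # NB with phi = 0.4 at mean 100
  nb <- rand_counts(500, 12, mu = 100, phi = 0.4, seed = 2)
  colnames(nb) <- names(eff)
  d2 <- estimate_dispersions(nb, eff)
  expect_gte(median(d2$phi_mom), 0.2)
  expect_lte(median(d2$phi_mom), 0.6)

  # constant counts: floored at phi_min
  const <- matrix(50L, 3, 12,
                  dimnames = list(c("a", "b", "c"), names(eff)))
  d3 <- estimate_dispersions(const, eff)
  expect_equal(d3$phi, rep(1e-4, 3))
})

test_that("identical contrast groups give zero fold change", {
  half <- rand_counts(30, 6, seed = 5)
  counts <- cbind(half, half)
  colnames(counts) <- sprintf("s%02d", 1:12)
  samples <- two_group_samples(6)
  design <- de_design("mRNA", "obese_vs_lean", ancestry = "both",
                      use_raw_p = TRUE)
  de <- nb_wald_test(counts, samples, design, unit_factors(counts))
  expect_equal(de$log2_fc, rep(0, nrow(de)), tolerance = 1e-8)
})

test_that("swapping contrast level labels negates fold changes, preserves p", {
  counts <- rand_counts(40, 12, seed = 6)
  samples <- two_group_samples(6)
  design <- de_design("mRNA", "obese_vs_lean", ancestry = "both",
                      use_raw_p = TRUE)
  de1 <- nb_wald_test(counts, samples, design, unit_factors(counts))
  swapped <- samples
  swapped$bmi_class <- ifelse(samples$bmi_class == "obese", "lean", "obese")
  de2 <- nb_wald_test(counts, swapped, design, unit_factors(counts))
  expect_equal(de1$log2_fc, -de2$log2_fc, tolerance = 1e-8)
  expect_equal(de1$p, de2$p, tolerance = 1e-8)
})

test_that("planted log2 fold changes are recovered by the Wald engine", {
  n_feat <- 200
  n_planted <- 30   # modest DE fraction so TMM can anchor on null features
  mu <- matrix(100, n_feat, 12)
  mu[, 7:12] <- mu[, 7:12] * ifelse(seq_len(n_feat) <= n_planted, 4, 1)
  counts <- withr::with_seed(8, {
    m <- matrix(rnbinom(length(mu), size = 1 / 0.2, mu = mu), n_feat, 12)
    dimnames(m) <- list(sprintf("f%03d", seq_len(n_feat)),
                        sprintf("s%02d", 1:12))
    m
  })
  samples <- two_group_samples(6)
  design <- de_design("mRNA", "obese_vs_lean", ancestry = "both")
  de <- nb_wald_test(counts, samples, design, tmm_factors(counts))
  planted_ids <- sprintf("f%03d", seq_len(n_planted))
  planted <- de$log2_fc[de$feature_id %in% planted_ids]
  expect_lt(abs(median(planted) - 2), 0.3)
  # the pooled moment dispersion estimate is inflated for DE features, so
  # single-contrast power is moderate; planted features still dominate calls
  expect_gt(mean(de$is_de[de$feature_id %in% planted_ids]), 0.5)
  expect_lt(mean(de$is_de[!de$feature_id %in% planted_ids]), 0.05)
})

test_that("paired tumor-vs-normal fits absorb patient baselines", {
  # strong per-patient offsets would swamp an unpaired test; the paired
  # model must still isolate the planted tumor effect
  n_feat <- 100; n_pat <- 6
  patient_mult <- withr::with_seed(10, exp(rnorm(n_pat, 0, 1)))
  mu <- matrix(50, n_feat, 2 * n_pat)
  for (p in seq_len(n_pat)) mu[, c(p, p + n_pat)] <- mu[, c(p, p + n_pat)] * patient_mult[p]
  mu[seq_len(15), seq_len(n_pat)] <- mu[seq_len(15), seq_len(n_pat)] * 4  # tumor cols
  counts <- withr::with_seed(11, {
    m <- matrix(rnbinom(length(mu), size = 1 / 0.1, mu = mu), n_feat, 2 * n_pat)
    dimnames(m) <- list(sprintf("f%03d", seq_len(n_feat)),
                        sprintf("s%02d", seq_len(2 * n_pat)))
    m
  })
  samples <- tibble::tibble(
    sample_id = colnames(counts),
    patient_id = rep(sprintf("p%d", seq_len(n_pat)), 2),
    ancestry = "EA", bmi_class = "obese",
    tissue = rep(c("tumor", "normal"), each = n_pat),
    assay = "miRNA")
  design <- de_design("miRNA", "tumor_vs_normal", ancestry = "EA",
                      bmi_class = "obese", pairing = "paired_by_patient")
  de <- nb_wald_test(counts, samples, design, tmm_factors(counts))
  planted_ids <- sprintf("f%03d", 1:15)
  planted <- de$log2_fc[de$feature_id %in% planted_ids]
  expect_lt(abs(median(planted) - 2), 0.4)
  expect_gt(mean(de$is_de[de$feature_id %in% planted_ids]), 0.7)
  expect_lt(mean(de$is_de[!de$feature_id %in% planted_ids]), 0.1)
})

test_that("Wald p-values track likelihood-ratio p-values on large-mean features", {
  samples <- two_group_samples(8)
  offset <- rep(log(1e4), 16)
  grp <- factor(samples$bmi_class, levels = c("lean", "obese"))
  ratios <- withr::with_seed(12, {
    vapply(1:20, function(i) {
      mu <- rep(500, 16) * ifelse(grp == "obese", 2^1.5, 1)
      y <- rnbinom(16, size = 1 / 0.05, mu = mu)
      X <- model.matrix(~ grp)
      wald <- stratomir:::nb_wald_single(y, X, offset - offset, 0.05, 2)
      lrt <- nb_lrt_oracle(y, grp, offset - offset, 0.05)
      -log10(wald$p) / -log10(lrt)
    }, numeric(1))
  })
  expect_true(all(ratios > 0.5 & ratios < 2))
})

test_that("run_study_contrasts produces the study's eight tables with correct strata", {
  study <- simulate_study(tiny_config())
  suppressWarnings(
    tabs <- run_study_contrasts(study$mirna_counts, study$mrna_counts,
                                study$samples))
  expect_setequal(names(tabs), c(
    "mirna_EA_both_tvn", "mirna_EA_obese_tvn", "mirna_EA_lean_tvn",
    "mirna_AA_both_tvn", "mirna_AA_obese_tvn", "mirna_AA_lean_tvn",
    "mrna_EA_ovl", "mrna_AA_ovl"))
  expect_equal(unique(tabs$mirna_EA_both_tvn$n_level1), 12)
  expect_equal(unique(tabs$mirna_EA_obese_tvn$n_level1), 6)
  expect_equal(unique(tabs$mrna_EA_ovl$n_level1), 6)
  # thresholds: miRNA rule is FDR + fold change, mRNA rule is raw p
  mi <- tabs$mirna_EA_obese_tvn
  expect_true(all(mi$fdr[mi$is_de] <= 0.05 & abs(mi$log2_fc[mi$is_de]) >= 1))
  mr <- tabs$mrna_EA_ovl
  expect_true(all(mr$p[mr$is_de] <= 0.05))
  expect_gt(sum(mr$is_de & mr$fdr > 0.05), 0)
})

test_that("stratum-specific planted miRNAs are called in their own stratum only", {
  study <- simulate_study(tiny_config(seed = 3))
  suppressWarnings(
    tabs <- run_study_contrasts(study$mirna_counts, NULL, study$samples))
  planted_ea <- study$truth$de_mirnas$mirna_id[
    study$truth$de_mirnas$stratum == "EA.obese"]
  ea_hits <- de_features(tabs$mirna_EA_obese_tvn)
  aa_hits <- de_features(tabs$mirna_AA_obese_tvn)
  expect_gte(mean(planted_ea %in% ea_hits), 0.7)
  expect_lte(mean(planted_ea %in% aa_hits), 0.2)
})
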