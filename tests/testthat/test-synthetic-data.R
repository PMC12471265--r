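test_that("identical config and seed give identical outputs", {
  a <- simulate_study(tiny_config(seed = 42))
  b <- simulate_study(tiny_config(seed = 42))
  expect_identical(a$mirna_counts, b$mirna_counts)
  expect_identical(a$mrna_counts, b$mrna_counts)
  expect_identical(a$predictions, b$predictions)
  expect_identical(a$truth, b$truth)
  c <- simulate_study(tiny_config(seed = 43))
  expect_false(identical(a$mirna_counts, c$mirna_counts))
})

test_that("generated study has the stated shape and valid components", {
  study <- simulate_study(tiny_config())
  cfg <- study$config
  expect_equal(ncol(study$mirna_counts), 8 * cfg$n_patients_per_cell)
  expect_equal(ncol(study$mrna_counts), 4 * cfg$n_patients_per_cell)
  expect_silent(validate_count_matrix(study$mirna_counts))
  expect_silent(validate_sample_table(study$samples, allow_unpaired = TRUE))
  expect_silent(validate_target_pairs(study$predictions))
  # every true pair is present in the emitted prediction table
  tkey <- paste(study$truth$true_pairs$mirna_id, study$truth$true_pairs$gene_id)
  pkey <- paste(study$predictions$mirna_id, study$predictions$gene_id)
  expect_true(all(tkey %in% pkey))
  # planted stratum sets are disjoint
  planted <- study$truth$de_mirnas
  expect_equal(anyDuplicated(planted$mirna_id), 0)
})

test_that("null features follow the configured NB dispersion (method of moments)", {
  cfg <- tiny_config(seed = 5)
  study <- simulate_study(cfg)
  planted <- study$truth$de_mirnas$mirna_id
  null_ids <- setdiff(rownames(study$mirna_counts), planted)
  lib <- study$truth$libsizes
  mult <- setNames(lib$multiplier, lib$sample_id)[colnames(study$mirna_counts)]
  norm <- sweep(study$mirna_counts[null_ids, ], 2, mult, "/")
  mu <- rowMeans(norm)
  s2 <- apply(norm, 1, var)
  keep <- mu >= 20
  phi_hat <- (s2[keep] - mu[keep]) / mu[keep]^2
  expect_gt(median(phi_hat), cfg$dispersion * 0.5)
  expect_lt(median(phi_hat), cfg$dispersion * 1.5)
})

test_that("a null configuration yields almost no DE calls (Monte Carlo)", {
  frac <- vapply(1:5, function(seed) {
    cfg <- tiny_config(
      seed = seed,
      n_de_mirnas = c(EA.obese = 0, EA.lean = 0, AA.obese = 0, AA.lean = 0),
      n_shared_mirnas = 0, n_true_targets = 0,
      n_de_genes = c(EA = 0, AA = 0))
    study <- simulate_study(cfg)
    suppressWarnings(
      tabs <- run_study_contrasts(study$mirna_counts, NULL, study$samples))
    mean(vapply(tabs, function(t) mean(t$is_de), numeric(1)))
  }, numeric(1))
  expect_lte(mean(frac), 0.10)
})

test_that("planted repression pairs carry negative Spearman correlation", {
  rhos <- unlist(lapply(1:5, function(seed) {
    study <- simulate_study(tiny_config(seed = seed))
    mi_cpm <- log2(sweep(study$mirna_counts, 2,
                         colSums(study$mirna_counts), "/") * 1e6 + 1)
    mr_cpm <- log2(sweep(study$mrna_counts, 2,
                         colSums(study$mrna_counts), "/") * 1e6 + 1)
    s <- study$samples
    vapply(seq_len(nrow(study$truth$true_pairs)), function(i) {
      pr <- study$truth$true_pairs[i, ]
      mr_s <- s[s$assay == "mRNA" & s$ancestry == pr$ancestry, ]
      mi_s <- s[s$assay == "miRNA" & s$tissue == "tumor" &
                  s$ancestry == pr$ancestry, ]
      mi_cols <- mi_s$sample_id[match(mr_s$patient_id, mi_s$patient_id)]
      cor(rank(mi_cpm[pr$mirna_id, mi_cols]),
          rank(mr_cpm[pr$gene_id, mr_s$sample_id]))
    }, numeric(1))
  }))
  expect_lt(mean(rhos), -0.3)
})

test_that("infeasible simulator configurations are rejected", {
  expect_error(sim_config(n_true_targets = 10000),
               class = "stratomir_config_error")
  expect_error(sim_config(mirna_effect = 0.5),
               class = "stratomir_config_error")
  expect_error(sim_config(repression_strength = 1),
               class = "stratomir_config_error")
})

test_that("the default Venn fixture realizes the signature-chain cardinalities", {
  fx <- make_venn_fixture(venn_spec(), seed = 1)
  expect_equal(lengths(fx[c("ea_obese", "ea_lean", "aa_obese", "aa_lean",
                            "ea_all", "aa_all")]),
               c(ea_obese = 116, ea_lean = 39, aa_obese = 72, aa_lean = 39,
                 ea_all = 124, aa_all = 109))
  expect_length(intersect(fx$ea_obese, fx$ea_lean), 24)
  expect_length(intersect(fx$aa_obese, fx$aa_lean), 19)
  expect_length(intersect(fx$ea_all, fx$aa_all), 61)
})

test_that("random feasible Venn specifications obey inclusion-exclusion exactly", {
  for (seed in 1:10) {
    r <- withr::with_seed(seed, as.list(sample(0:25, 12, replace = TRUE)))
    names(r) <- c("ea_ol", "ea_l", "aa_ol", "aa_l", "cross", "ea_sh",
                  "ea_rest", "aa_sh", "aa_rest", "sh_rest", "ea_all_r",
                  "aa_all_r")
    spec <- venn_spec(
      ea_obese = r$ea_ol + r$ea_sh + r$ea_rest + r$cross,
      ea_lean = r$ea_ol + r$ea_l, ea_obese_lean_overlap = r$ea_ol,
      aa_obese = r$aa_ol + r$aa_sh + r$aa_rest + r$cross,
      aa_lean = r$aa_ol + r$aa_l, aa_obese_lean_overlap = r$aa_ol,
      obese_unique_overlap = r$cross,
      ea_all = r$ea_sh + r$aa_sh + r$sh_rest + r$ea_all_r,
      aa_all = r$ea_sh + r$aa_sh + r$sh_rest + r$aa_all_r,
      shared = r$ea_sh + r$aa_sh + r$sh_rest,
      ea_only_shared_overlap = r$ea_sh, aa_only_shared_overlap = r$aa_sh)
    fx <- make_venn_fixture(spec, seed = seed)
    # brute-force set arithmetic on the emitted sets
    expect_length(setdiff(fx$ea_obese, fx$ea_lean), r$ea_sh + r$ea_rest + r$cross)
    expect_length(setdiff(fx$aa_obese, fx$aa_lean), r$aa_sh + r$aa_rest + r$cross)
    eau <- setdiff(fx$ea_obese, fx$ea_lean)
    aau <- setdiff(fx$aa_obese, fx$aa_lean)
    expect_length(intersect(eau, aau), r$cross)
    shared <- intersect(fx$ea_all, fx$aa_all)
    expect_length(shared, r$ea_sh + r$aa_sh + r$sh_rest)
    expect_length(setdiff(setdiff(eau, aau), shared), r$ea_rest)
    expect_length(setdiff(setdiff(aau, eau), shared), r$aa_rest)
    # inclusion-exclusion identity on each stratified pair
    expect_equal(length(union(fx$ea_obese, fx$ea_lean)),
                 length(fx$ea_obese) + length(fx$ea_lean) -
                   length(intersect(fx$ea_obese, fx$ea_lean)))
  }
})

test_that("infeasible Venn specifications name the violated region", {
  expect_error(make_venn_fixture(venn_spec(ea_obese = 10, ea_lean = 39,
                                           ea_obese_lean_overlap = 24)),
               "region", class = "stratomir_config_error")
})
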