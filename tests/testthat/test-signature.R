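test_that("obesity_specific reproduces the stratified unique counts", {
  fx <- make_venn_fixture()
  ea <- obesity_specific(fx$ea_obese, fx$ea_lean)
  expect_length(ea$obese_unique, 92)
  expect_length(ea$lean_unique, 15)
  aa <- obesity_specific(fx$aa_obese, fx$aa_lean)
  expect_length(aa$obese_unique, 53)
  expect_length(aa$lean_unique, 20)

  # disjoint inputs pass through unchanged
  d <- obesity_specific(c("a", "b"), c("c"))
  expect_equal(d, list(obese_unique = c("a", "b"), lean_unique = "c"))
})

test_that("ancestry_exclusive and shared_core behave as set algebra", {
  fx <- make_venn_fixture()
  ea_u <- obesity_specific(fx$ea_obese, fx$ea_lean)$obese_unique
  aa_u <- obesity_specific(fx$aa_obese, fx$aa_lean)$obese_unique
  excl <- ancestry_exclusive(ea_u, aa_u)
  expect_length(excl$ea_only, 79)
  expect_length(excl$aa_only, 40)

  same <- ancestry_exclusive(c("x", "y"), c("x", "y"))
  expect_length(same$ea_only, 0)
  expect_length(same$aa_only, 0)

  # inclusion-exclusion on random sets vs brute force
  for (seed in 1:5) {
    ab <- withr::with_seed(seed, list(
      a = sample(letters, 12), b = sample(letters, 9)))
    ex <- ancestry_exclusive(ab$a, ab$b)
    expect_equal(length(ex$ea_only) + length(intersect(ab$a, ab$b)),
                 length(ab$a))
  }

  expect_length(shared_core(fx$ea_all, fx$aa_all), 61)
  expect_length(shared_core(c("p"), c("q")), 0)
  expect_equal(sort(shared_core(c("a", "b"), c("a", "b", "c"))), c("a", "b"))
})

test_that("refine_signature subtracts the shared core", {
  fx <- make_venn_fixture()
  ea_u <- obesity_specific(fx$ea_obese, fx$ea_lean)$obese_unique
  aa_u <- obesity_specific(fx$aa_obese, fx$aa_lean)$obese_unique
  excl <- ancestry_exclusive(ea_u, aa_u)
  shared <- shared_core(fx$ea_all, fx$aa_all)
  expect_length(refine_signature(excl$ea_only, shared), 55)
  expect_length(refine_signature(excl$aa_only, shared), 33)
  expect_equal(refine_signature(c("m1", "m2"), character()), c("m1", "m2"))
})

test_that("the full signature pipeline reproduces the printed cardinality chain", {
  sig <- run_signature_pipeline(make_venn_fixture())
  sizes <- setNames(sig$cardinality$size, sig$cardinality$set)
  expect_equal(sizes[["ea_obese_unique"]], 92)
  expect_equal(sizes[["ea_lean_unique"]], 15)
  expect_equal(sizes[["aa_obese_unique"]], 53)
  expect_equal(sizes[["aa_lean_unique"]], 20)
  expect_equal(sizes[["ea_only_obese"]], 79)
  expect_equal(sizes[["aa_only_obese"]], 40)
  expect_equal(sizes[["shared_ea_aa_all"]], 61)
  expect_equal(sizes[["ea_refined"]], 55)
  expect_equal(sizes[["aa_refined"]], 33)
})

test_that("signature pipeline invariants hold and empty inputs give empty sets", {
  sig <- run_signature_pipeline(make_venn_fixture())
  s <- sig$sets
  expect_length(intersect(s$ea_refined, s$aa_refined), 0)
  expect_length(intersect(s$ea_refined, s$shared_ea_aa_all), 0)
  expect_length(intersect(s$aa_refined, s$shared_ea_aa_all), 0)
  expect_true(all(s$ea_refined %in% s$ea_obese_tvn))
  # every final member has exactly one provenance row
  expect_equal(anyDuplicated(sig$provenance$mirna_id), 0)
  expect_setequal(sig$provenance$mirna_id[sig$provenance$signature == "ea_refined"],
                  s$ea_refined)

  empty <- run_signature_pipeline(list(
    ea_obese = character(), ea_lean = character(),
    aa_obese = character(), aa_lean = character(),
    ea_all = character(), aa_all = character()))
  expect_true(all(empty$cardinality$size == 0))

  expect_error(run_signature_pipeline(list(ea_obese = "a")), "aa_lean")
})

test_that("pipeline output depends only on id-set membership", {
  fx <- make_venn_fixture()
  sig1 <- run_signature_pipeline(fx)
  shuffled <- lapply(fx, function(s) withr::with_seed(9, sample(s)))
  sig2 <- run_signature_pipeline(shuffled)
  expect_setequal(sig1$sets$ea_refined, sig2$sets$ea_refined)
  expect_setequal(sig1$sets$aa_refined, sig2$sets$aa_refined)
})

test_that("the alternative shared-core mode intersects stratified unions", {
  fx <- make_venn_fixture()
  sig <- run_signature_pipeline(fx, shared_mode = "union_stratified")
  expect_setequal(sig$sets$shared_ea_aa_all,
                  intersect(union(fx$ea_obese, fx$ea_lean),
                            union(fx$aa_obese, fx$aa_lean)))
})

test_that("optional normal-tissue background subtraction removes its members", {
  fx <- make_venn_fixture()
  bg <- fx$ea_obese[!fx$ea_obese %in% fx$ea_lean][1:5]
  sig <- run_signature_pipeline(fx, normal_background = bg)
  expect_length(intersect(sig$sets$ea_obese_unique, bg), 0)
  expect_lte(length(sig$sets$ea_refined), 55)
})

test_that("planted ancestry-specific miRNAs reach the refined signature", {
  recalls <- vapply(1:5, function(seed) {
    study <- simulate_study(tiny_config(seed = seed))
    suppressWarnings(
      tabs <- run_study_contrasts(study$mirna_counts, NULL, study$samples))
    sig <- run_signature_pipeline(list(
      ea_obese = tabs$mirna_EA_obese_tvn, ea_lean = tabs$mirna_EA_lean_tvn,
      aa_obese = tabs$mirna_AA_obese_tvn, aa_lean = tabs$mirna_AA_lean_tvn,
      ea_all = tabs$mirna_EA_both_tvn, aa_all = tabs$mirna_AA_both_tvn))
    planted <- study$truth$de_mirnas$mirna_id[
      study$truth$de_mirnas$stratum == "EA.obese"]
    mean(planted %in% sig$sets$ea_refined)
  }, numeric(1))
  expect_gte(mean(recalls), 0.7)
})
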