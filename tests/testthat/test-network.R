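test_that("Spearman rho is -1 for perfect antitone data with exact p 2/120 at n=5", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(10, 8, 5, 3, 1)
  res <- spearman_test(x, y)
  expect_equal(res$rho, -1)
  expect_equal(res$p, 2 / 120)
  expect_identical(res$method, "exact")
})

test_that("exact permutation p matches an independent enumeration oracle", {
  for (seed in 1:4) {
    v <- withr::with_seed(seed, list(x = rnorm(6), y = rnorm(6)))
    res <- spearman_test(v$x, v$y)
    expect_equal(res$p, spearman_oracle_exact(v$x, v$y), tolerance = 1e-12)
  }
  # with ties (midranks), conditioning on the observed tie pattern
  x <- c(1, 1, 2, 3, 4, 5)
  y <- c(2, 4, 4, 1, 5, 3)
  expect_equal(spearman_test(x, y)$p, spearman_oracle_exact(x, y),
               tolerance = 1e-12)
})

test_that("t-approximation is close to exact enumeration at n=8", {
  for (seed in 1:5) {
    v <- withr::with_seed(seed + 20, list(x = rnorm(8), y = rnorm(8)))
    exact <- spearman_test(v$x, v$y, exact_n = 10)
    approx <- spearman_test(v$x, v$y, exact_n = 4)
    expect_identical(approx$method, "t-approx")
    expect_equal(exact$rho, approx$rho)
    expect_lt(abs(exact$p - approx$p), 0.02)
  }
})

test_that("Spearman input contract is enforced", {
  expect_error(spearman_test(1:3, 3:1), "length")
  expect_error(spearman_test(rep(1, 5), 1:5),
               class = "stratomir_constant_error")
})

test_that("correlate_pairs tests only predicted signature-by-DE pairs", {
  # two strongly anticorrelated planted pairs, one absent from predictions
  n <- 12
  samples <- tibble::tibble(
    sample_id = c(sprintf("mi%02d", 1:n), sprintf("mr%02d", 1:n)),
    patient_id = rep(sprintf("p%02d", 1:n), 2),
    ancestry = "EA", bmi_class = rep(c("obese", "lean"), n),
    tissue = "tumor",
    assay = rep(c("miRNA", "mRNA"), each = n))
  base <- withr::with_seed(1, rnorm(n))
  mirna_expr <- rbind(m1 = base, m2 = rev(base), m3 = base + 0.1)
  colnames(mirna_expr) <- sprintf("mi%02d", 1:n)
  noise <- withr::with_seed(2, rnorm(n, sd = 0.2))
  mrna_expr <- rbind(g1 = -base + noise, g2 = -rev(base) + noise,
                     g3 = withr::with_seed(3, rnorm(n)))
  colnames(mrna_expr) <- sprintf("mr%02d", 1:n)
  predictions <- tibble::tibble(mirna_id = c("m1", "m3"),
                                gene_id = c("g1", "g3"))
  edges <- correlate_pairs(mirna_expr, mrna_expr, predictions,
                           de_mirnas = c("m1", "m2", "m3"),
                           de_genes = c("g1", "g2", "g3"),
                           samples = samples, ancestry = "EA")
  # (m2, g2) is perfectly anticorrelated but unpredicted: never tested
  expect_false("m2" %in% edges$mirna_id)
  expect_equal(attr(edges, "n_pairs_tested"), 2)
  expect_true(all(edges$p <= 0.05))
  expect_equal(edges$mirna_id, "m1")
  expect_equal(edges$n, 12)

  # empty signature: empty edge list
  none <- correlate_pairs(mirna_expr, mrna_expr, predictions,
                          de_mirnas = character(), de_genes = c("g1"),
                          samples = samples, ancestry = "EA")
  expect_equal(nrow(none), 0)
})

test_that("retained edges satisfy the inclusive alpha threshold", {
  study <- simulate_study(tiny_config(seed = 2))
  mi_f <- filter_low_counts(study$mirna_counts)
  mr_f <- filter_low_counts(study$mrna_counts)
  mi_e <- log2_normalize(mi_f, tmm_factors(mi_f))
  mr_e <- log2_normalize(mr_f, tmm_factors(mr_f))
  truth <- study$truth
  sig <- unique(truth$true_pairs$mirna_id[truth$true_pairs$ancestry == "EA"])
  genes <- unique(truth$true_pairs$gene_id[truth$true_pairs$ancestry == "EA"])
  edges <- correlate_pairs(mi_e, mr_e, study$predictions, sig, genes,
                           study$samples, "EA")
  expect_true(all(edges$p <= 0.05))
  expect_true(all(paste(edges$mirna_id, edges$gene_id) %in%
                    paste(study$predictions$mirna_id, study$predictions$gene_id)))
  expect_lt(mean(edges$rho), 0)
})

test_that("edge classification follows the fold-change sign rule", {
  edges <- tibble::tibble(
    mirna_id = c("up_mir", "down_mir", "up_mir", "down_mir"),
    gene_id = c("down_gene", "up_gene", "up_gene", "down_gene"),
    rho = c(-0.8, -0.7, 0.9, -0.6),
    p = rep(0.01, 4), n = rep(12L, 4))
  mirna_de <- tibble::tibble(feature_id = c("up_mir", "down_mir"),
                             log2_fc = c(1.5, -1.5))
  gene_de <- tibble::tibble(feature_id = c("up_gene", "down_gene"),
                            log2_fc = c(2, -2))
  cl <- classify_edges(edges, mirna_de, gene_de)
  expect_equal(cl$regulation_class,
               c("direct", "indirect", "positive_unclassified",
                 "positive_unclassified"))
  # classes partition the edges
  expect_true(all(cl$regulation_class %in%
                    c("direct", "indirect", "positive_unclassified")))
  expect_error(
    classify_edges(edges, mirna_de[1, ], gene_de), "down_mir")
})

test_that("the bundled example networks classify as published-style direct/indirect", {
  ea <- example_network("EA")
  cl <- classify_edges(ea$edges, ea$mirna_de, ea$gene_de)
  hey2 <- cl[cl$mirna_id == "miR-181b-5p" & cl$gene_id == "HEY2", ]
  expect_equal(hey2$regulation_class, "direct")
  rab10 <- cl[cl$mirna_id == "miR-204-5p" & cl$gene_id == "RAB10", ]
  expect_equal(rab10$regulation_class, "indirect")
  expect_true(all(cl$regulation_class[cl$rho > 0] == "positive_unclassified"))
})

test_that("network summary counts match brute-force tallies", {
  ea <- example_network("EA")
  cl <- classify_edges(ea$edges, ea$mirna_de, ea$gene_de)
  s <- network_summary(cl)
  expect_equal(s$n_edges, nrow(cl))
  expect_equal(s$n_inverse, sum(cl$rho < 0))
  expect_equal(s$n_mirnas, length(unique(cl$mirna_id)))
  expect_equal(s$n_genes, length(unique(cl$gene_id)))
  for (node in unique(cl$mirna_id)) {
    expect_equal(s$degree$degree[s$degree$node == node],
                 sum(cl$mirna_id == node))
  }
  e0 <- network_summary(cl[0, ])
  expect_equal(e0$n_edges, 0)
  expect_equal(e0$n_genes, 0)
})
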