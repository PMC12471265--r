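# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately re-derive results by a different route than the
# package implementation.

# random NB count matrix with dimnames
rand_counts <- function(nf, ns, mu = 100, phi = 0.2, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnbinom(nf * ns, size = 1 / phi, mu = mu), nf, ns)
  })
  rownames(m) <- sprintf("f%03d", seq_len(nf))
  colnames(m) <- sprintf("s%02d", seq_len(ns))
  storage.mode(m) <- "integer"
  m
}

# small, fast study configuration for unit-level pipeline tests
tiny_config <- function(seed = 1, ...) {
  defaults <- list(
    n_patients_per_cell = 6, n_mirnas = 150, n_genes = 400,
    n_de_mirnas = c(EA.obese = 8, EA.lean = 5, AA.obese = 7, AA.lean = 5),
    n_shared_mirnas = 5,
    n_de_genes = c(EA = 25, AA = 25),
    n_true_targets = 12,
    n_random_genesets = 6, geneset_size = 25,
    seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# BH step-up computed the long way: sort, scale by m/i, cumulative minimum
# from the largest p, cap at 1, restore input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- ps * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# hypergeometric upper tail by exhaustive enumeration of all C(N, n) draws
hyper_oracle <- function(k, K, n, N) {
  universe <- seq_len(N)
  special <- seq_len(K)
  draws <- utils::combn(N, n)
  hits <- apply(draws, 2, function(d) sum(d %in% special))
  mean(hits >= k)
}

# exact two-sided Spearman p by full enumeration in lexicographic order --
# a different permutation generator than the package's recursive builder.
next_lex_perm <- function(p) {
  n <- length(p)
  i <- n - 1L
  while (i >= 1L && p[i] >= p[i + 1L]) i <- i - 1L
  if (i < 1L) return(NULL)
  j <- n
  while (p[j] <= p[i]) j <- j - 1L
  tmp <- p[i]; p[i] <- p[j]; p[j] <- tmp
  c(p[seq_len(i)], rev(p[(i + 1L):n]))
}

spearman_oracle_exact <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  obs <- abs(cor(rx, ry))
  perm <- seq_along(rx)
  count <- 0L; total <- 0L
  while (!is.null(perm)) {
    total <- total + 1L
    if (abs(cor(rx[perm], ry)) >= obs - 1e-12) count <- count + 1L
    perm <- next_lex_perm(perm)
  }
  count / total
}

# likelihood-ratio NB p-value oracle for comparison with the Wald test
nb_lrt_oracle <- function(y, grp, offset, phi) {
  fam <- MASS::negative.binomial(theta = 1 / phi)
  full <- glm(y ~ grp + offset(offset), family = fam)
  null <- glm(y ~ 1 + offset(offset), family = fam)
  dev <- null$deviance - full$deviance
  pchisq(dev, df = 1, lower.tail = FALSE)
}

# a minimal unpaired two-group mRNA sample table for engine-level tests
two_group_samples <- function(n_per_group = 6, ancestry = "EA") {
  tibble::tibble(
    sample_id = sprintf("s%02d", seq_len(2 * n_per_group)),
    patient_id = sprintf("p%02d", seq_len(2 * n_per_group)),
    ancestry = ancestry,
    bmi_class = rep(c("lean", "obese"), each = n_per_group),
    tissue = "tumor",
    assay = "mRNA")
}

unit_factors <- function(counts) {
  tibble::tibble(sample_id = colnames(counts),
                 library_size = colSums(counts),
                 tmm_factor = 1,
                 effective_size = colSums(counts))
}
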