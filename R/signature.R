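#' Obesity-specific differential miRNAs within one ancestry
#'
#' Splits an ancestry's tumor-vs-normal DE lists into the miRNAs unique to
#' the obese stratum and those unique to the lean stratum (plain set
#' differences; miRNAs differentially expressed in both strata are dropped
#' from both outputs).
#'
#' @param de_obese,de_lean Character vectors (or `de_table`s) of DE miRNAs
#'   from the obese- and lean-stratum tumor-vs-normal contrasts of the same
#'   ancestry.
#' @return A list with `obese_unique` and `lean_unique` character vectors.
#' @export
obesity_specific <- function(de_obese, de_lean) {
  a <- de_features(de_obese)
  b <- de_features(de_lean)
  list(obese_unique = setdiff(a, b), lean_unique = setdiff(b, a))
}

#' Ancestry-exclusive obesity-associated miRNAs
#'
#' Given the obese-unique lists of both ancestries, returns the miRNAs seen
#' only in the EA list and only in the AA list.
#'
#' @param ea_obese_unique,aa_obese_unique Character vectors from
#'   [obesity_specific()] of each ancestry.
#' @return A list with `ea_only` and `aa_only`.
#' @export
ancestry_exclusive <- function(ea_obese_unique, aa_obese_unique) {
  a <- de_features(ea_obese_unique)
  b <- de_features(aa_obese_unique)
  list(ea_only = setdiff(a, b), aa_only = setdiff(b, a))
}

#' Shared tumor core across ancestries
#'
#' The miRNAs differentially expressed between tumor and adjacent-normal
#' tissue in both ancestries regardless of BMI class - shared tumor biology
#' to be subtracted from obesity-specific signatures.
#'
#' @param de_ea_all,de_aa_all The all-patients tumor-vs-normal DE lists per
#'   ancestry.
#' @return Character vector (intersection).
#' @export
shared_core <- function(de_ea_all, de_aa_all) {
  intersect(de_features(de_ea_all), de_features(de_aa_all))
}

#' Refine an ancestry-exclusive signature
#'
#' Removes the shared tumor core from an ancestry-exclusive obesity list,
#' yielding the final signature of miRNAs exclusively associated with tumors
#' of obese patients of that ancestry.
#'
#' @param ancestry_only Character vector from [ancestry_exclusive()].
#' @param shared Character vector from [shared_core()].
#' @return Character vector (`ancestry_only` minus `shared`).
#' @export
refine_signature <- function(ancestry_only, shared) {
  setdiff(de_features(ancestry_only), de_features(shared))
}

#' Run the multistep signature-subtraction pipeline
#'
#' Executes the full distillation of six tumor-vs-normal DE miRNA lists into
#' ancestry-specific, obesity-exclusive signatures:
#' per ancestry, obese-unique = obese \\ lean; across ancestries,
#' EA-only = EA-obese-unique \\ AA-obese-unique (and vice versa); the shared
#' core = EA-all intersected with AA-all is then subtracted from each
#' ancestry-exclusive list. Membership is by exact miRNA id string (arm
#' suffixes such as -5p/-3p are never collapsed); the result is a pure
#' function of the input id sets. An optional normal-tissue background list
#' is subtracted from each ancestry's obese-unique set before the
#' cross-ancestry stage.
#'
#' @param de_tables Named list with elements `ea_obese`, `ea_lean`,
#'   `aa_obese`, `aa_lean`, `ea_all`, `aa_all`, each a `de_table` or a
#'   character vector of DE miRNA ids.
#' @param normal_background Optional character vector (or `de_table`) of
#'   miRNAs differentially expressed in adjacent-normal tissue, subtracted
#'   as background; default NULL (stage off).
#' @param shared_mode How the shared core is computed:
#'   `"all_contrasts"` (default) intersects the all-patients
#'   tumor-vs-normal lists; `"union_stratified"` intersects the per-ancestry
#'   unions of the obese- and lean-stratum lists instead.
#' @return A `signature_sets` object: a list of all named stage sets, a
#'   `cardinality` tibble (set, size, parents) and a `provenance` tibble
#'   tracing every final member through its chain.
#' @export
run_signature_pipeline <- function(de_tables, normal_background = NULL,
                                   shared_mode = c("all_contrasts",
                                                   "union_stratified")) {
  shared_mode <- match.arg(shared_mode)
  needed <- c("ea_obese", "ea_lean", "aa_obese", "aa_lean", "ea_all", "aa_all")
  missing <- setdiff(needed, names(de_tables))
  if (length(missing) > 0) {
    stopf("missing DE table(s): %s", paste(missing, collapse = ", "))
  }
  ids <- lapply(de_tables[needed], de_features)

  ea_split <- obesity_specific(ids$ea_obese, ids$ea_lean)
  aa_split <- obesity_specific(ids$aa_obese, ids$aa_lean)
  ea_obese_unique <- ea_split$obese_unique
  aa_obese_unique <- aa_split$obese_unique
  if (!is.null(normal_background)) {
    bg <- de_features(normal_background)
    ea_obese_unique <- setdiff(ea_obese_unique, bg)
    aa_obese_unique <- setdiff(aa_obese_unique, bg)
  }
  excl <- ancestry_exclusive(ea_obese_unique, aa_obese_unique)
  shared <- if (shared_mode == "all_contrasts") {
    shared_core(ids$ea_all, ids$aa_all)
  } else {
    shared_core(union(ids$ea_obese, ids$ea_lean),
                union(ids$aa_obese, ids$aa_lean))
  }
  ea_refined <- refine_signature(excl$ea_only, shared)
  aa_refined <- refine_signature(excl$aa_only, shared)

  sets <- list(
    ea_all_tvn = ids$ea_all, aa_all_tvn = ids$aa_all,
    ea_obese_tvn = ids$ea_obese, ea_lean_tvn = ids$ea_lean,
    aa_obese_tvn = ids$aa_obese, aa_lean_tvn = ids$aa_lean,
    ea_obese_unique = ea_obese_unique, ea_lean_unique = ea_split$lean_unique,
    aa_obese_unique = aa_obese_unique, aa_lean_unique = aa_split$lean_unique,
    ea_only_obese = excl$ea_only, aa_only_obese = excl$aa_only,
    shared_ea_aa_all = shared,
    ea_refined = ea_refined, aa_refined = aa_refined
  )
  parents <- list(
    ea_all_tvn = character(), aa_all_tvn = character(),
    ea_obese_tvn = character(), ea_lean_tvn = character(),
    aa_obese_tvn = character(), aa_lean_tvn = character(),
    ea_obese_unique = c("ea_obese_tvn", "ea_lean_tvn"),
    ea_lean_unique = c("ea_lean_tvn", "ea_obese_tvn"),
    aa_obese_unique = c("aa_obese_tvn", "aa_lean_tvn"),
    aa_lean_unique = c("aa_lean_tvn", "aa_obese_tvn"),
    ea_only_obese = c("ea_obese_unique", "aa_obese_unique"),
    aa_only_obese = c("aa_obese_unique", "ea_obese_unique"),
    shared_ea_aa_all = c("ea_all_tvn", "aa_all_tvn"),
    ea_refined = c("ea_only_obese", "shared_ea_aa_all"),
    aa_refined = c("aa_only_obese", "shared_ea_aa_all")
  )
  # structural invariants of the subtraction chain
  stopifnot(
    length(intersect(sets$ea_only_obese, sets$aa_only_obese)) == 0,
    length(intersect(sets$ea_refined, sets$shared_ea_aa_all)) == 0,
    length(intersect(sets$aa_refined, sets$shared_ea_aa_all)) == 0,
    length(intersect(sets$ea_refined, sets$aa_refined)) == 0,
    all(sets$ea_refined %in% sets$ea_obese_tvn),
    all(sets$aa_refined %in% sets$aa_obese_tvn)
  )
  provenance <- dplyr::bind_rows(
    tibble::tibble(
      mirna_id = sets$ea_refined, signature = "ea_refined",
      chain = "ea_obese_tvn > ea_obese_unique > ea_only_obese > ea_refined"),
    tibble::tibble(
      mirna_id = sets$aa_refined, signature = "aa_refined",
      chain = "aa_obese_tvn > aa_obese_unique > aa_only_obese > aa_refined")
  )
  cardinality <- tibble::tibble(
    set = names(sets),
    size = unname(vapply(sets, length, integer(1))),
    parents = unname(vapply(parents[names(sets)], paste, character(1),
                            collapse = ","))
  )
  structure(list(sets = sets, cardinality = cardinality,
                 provenance = provenance),
            class = "signature_sets")
}

#' @export
print.signature_sets <- function(x, ...) {
  cat("Obesity-exclusive miRNA signature sets\n")
  print(x$cardinality, n = nrow(x$cardinality))
  invisible(x)
}

#' @export
tidy.signature_sets <- function(x, ...) x$cardinality

#' @export
glance.signature_sets <- function(x, ...) {
  tibble::tibble(
    ea_refined = length(x$sets$ea_refined),
    aa_refined = length(x$sets$aa_refined),
    shared_core = length(x$sets$shared_ea_aa_all)
  )
}
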