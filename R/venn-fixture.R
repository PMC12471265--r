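#' Specify Venn cardinalities for a set-arithmetic fixture
#'
#' Describes the six tumor-vs-normal DE miRNA lists of a stratified study
#' purely by their sizes and the intersections that drive the signature
#' subtraction chain. The default values are the headline cardinalities of
#' the study design this package models (EA obese/lean 116/39 overlapping in
#' 24; AA 72/39 overlapping in 19; 13 obese-unique miRNAs shared across
#' ancestries; all-patient lists 124/109 with a shared core of 61 that meets
#' the EA- and AA-exclusive lists in 24 and 7 members respectively), which
#' chain to 92/15, 53/20, 79/40 and refined signatures of 55 and 33.
#'
#' @param ea_obese,ea_lean,ea_obese_lean_overlap EA stratum list sizes and
#'   their intersection.
#' @param aa_obese,aa_lean,aa_obese_lean_overlap AA stratum equivalents.
#' @param obese_unique_overlap Size of the intersection of the two
#'   obese-unique lists.
#' @param ea_all,aa_all,shared All-patients list sizes and their
#'   intersection (the shared core).
#' @param ea_only_shared_overlap,aa_only_shared_overlap How many members of
#'   each ancestry-exclusive list fall in the shared core.
#' @return A `venn_spec` list.
#' @export
venn_spec <- function(ea_obese = 116, ea_lean = 39, ea_obese_lean_overlap = 24,
                      aa_obese = 72, aa_lean = 39, aa_obese_lean_overlap = 19,
                      obese_unique_overlap = 13,
                      ea_all = 124, aa_all = 109, shared = 61,
                      ea_only_shared_overlap = 24,
                      aa_only_shared_overlap = 7) {
  structure(as.list(environment()), class = "venn_spec")
}

#' Realize a Venn specification as concrete miRNA id sets
#'
#' Builds six synthetic DE lists whose sizes and intersections match the
#' specification exactly, by allocating disjoint blocks of fresh ids to each
#' region of the diagram (inclusion-exclusion region counting). An
#' infeasible specification (any region with negative implied size) is
#' rejected with the violated region named.
#'
#' @param spec A [venn_spec()].
#' @param seed Integer seed controlling id labeling.
#' @return A named list of character vectors: `ea_obese`, `ea_lean`,
#'   `aa_obese`, `aa_lean`, `ea_all`, `aa_all` - directly consumable by
#'   [run_signature_pipeline()].
#' @export
make_venn_fixture <- function(spec = venn_spec(), seed = 1) {
  stopifnot(inherits(spec, "venn_spec"))
  regions <- with(spec, {
    eau <- ea_obese - ea_obese_lean_overlap
    aau <- aa_obese - aa_obese_lean_overlap
    list(
      ea_obese_lean = ea_obese_lean_overlap,
      ea_lean_only = ea_lean - ea_obese_lean_overlap,
      aa_obese_lean = aa_obese_lean_overlap,
      aa_lean_only = aa_lean - aa_obese_lean_overlap,
      cross_obese_unique = obese_unique_overlap,
      ea_only_in_shared = ea_only_shared_overlap,
      ea_only_rest = (eau - obese_unique_overlap) - ea_only_shared_overlap,
      aa_only_in_shared = aa_only_shared_overlap,
      aa_only_rest = (aau - obese_unique_overlap) - aa_only_shared_overlap,
      shared_rest = shared - ea_only_shared_overlap - aa_only_shared_overlap,
      ea_all_rest = ea_all - shared,
      aa_all_rest = aa_all - shared
    )
  })
  bad <- names(regions)[vapply(regions, function(v) v < 0, logical(1))]
  if (length(bad) > 0) {
    stopf("infeasible Venn specification: region(s) %s have negative size",
          paste(bad, collapse = ", "), class = "stratomir_config_error")
  }
  total <- sum(unlist(regions))
  ids <- withr::with_seed(as.integer(seed), {
    sample(sprintf("venn-miR-%04d", seq_len(total)))
  })
  blocks <- list()
  offset <- 0
  for (nm in names(regions)) {
    blocks[[nm]] <- ids[offset + seq_len(regions[[nm]])]
    offset <- offset + regions[[nm]]
  }
  with(blocks, list(
    ea_obese = c(ea_only_in_shared, ea_only_rest, cross_obese_unique,
                 ea_obese_lean),
    ea_lean = c(ea_obese_lean, ea_lean_only),
    aa_obese = c(aa_only_in_shared, aa_only_rest, cross_obese_unique,
                 aa_obese_lean),
    aa_lean = c(aa_obese_lean, aa_lean_only),
    ea_all = c(ea_only_in_shared, aa_only_in_shared, shared_rest,
               ea_all_rest),
    aa_all = c(ea_only_in_shared, aa_only_in_shared, shared_rest,
               aa_all_rest)
  ))
}
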