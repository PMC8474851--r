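#' Merging-incompatibility of two genotype vectors
#'
#' Two SVs are merging-incompatible when at least one sample carries a
#' non-reference genotype for both: their summed genotype would be ambiguous
#' (the two calls are then distinct variants in that sample, not one variant
#' observed twice).
#'
#' @param v_i,v_j Integer genotype vectors of equal length, entries in
#'   `{0, 1, 2}`.
#' @return `TRUE` if some sample is non-reference in both vectors.
#' @export
#' @examples
#' is_merging_incompatible(c(1, 0, 0), c(0, 2, 0)) # FALSE
#' is_merging_incompatible(c(2, 1, 0), c(0, 0, 1)) # FALSE: disjoint carriers
is_merging_incompatible <- function(v_i, v_j) {
  if (length(v_i) != length(v_j)) {
    abort("genotype vectors must have equal length")
  }
  any(v_i != 0 & v_j != 0)
}

#' Merge a set of genotype rows by summation
#'
#' Merging a set of pairwise merging-compatible SVs is elementwise summation
#' of their genotype vectors; compatibility guarantees at most one selected
#' row is non-zero per sample, so every entry of the result stays in
#' `{0, 1, 2}`.
#'
#' @param genotypes Integer genotype matrix (rows = SVs).
#' @param rows Integer vector of row indices to merge (non-empty).
#' @return The merged genotype vector (length = number of samples).
#' @export
#' @examples
#' m <- rbind(c(2, 1, 0), c(0, 0, 1))
#' colnames(m) <- c("child", "father", "mother")
#' merge_genotypes(m, 1:2) # (2, 1, 1)
merge_genotypes <- function(genotypes, rows) {
  if (length(rows) == 0) abort("rows must be non-empty")
  sub <- genotypes[rows, , drop = FALSE]
  if (length(rows) > 1 && max(colSums(sub != 0L)) > 1) {
    abort("rows contain a merging-incompatible pair")
  }
  as.integer(colSums(sub))
}

#' Cannot-link relation over candidate SV pairs
#'
#' Marks every candidate pair whose genotype rows are merging-incompatible.
#' The relation is symmetric; it is stored sparsely as one row per unordered
#' candidate pair.
#'
#' @param genotypes Integer genotype matrix.
#' @param candidate_pairs A data frame with integer columns `i` and `j`
#'   (row indices, typically restricted to same-chromosome, same-type pairs).
#' @return The input pairs with a logical `cannot_link` column.
#' @export
build_cannot_link <- function(genotypes, candidate_pairs) {
  cp <- as_tibble(candidate_pairs)
  if (!all(c("i", "j") %in% names(cp))) {
    abort("candidate_pairs needs integer columns i and j")
  }
  cp$cannot_link <- vapply(seq_len(nrow(cp)), function(k) {
    is_merging_incompatible(genotypes[cp$i[k], ], genotypes[cp$j[k], ])
  }, TRUE)
  cp
}
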