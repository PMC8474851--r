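#' Mendelian consistency of trio genotype configurations
#'
#' A trio configuration `(child, parent1, parent2)` with diploid genotypes
#' coded 0/1/2 is Mendelian-consistent when the child's two alleles can be
#' drawn one from each parent: a child `0` needs both parents to carry a
#' reference allele (genotype 0 or 1), a child `2` needs both parents to
#' carry an alternative allele (1 or 2), and a child `1` needs one parent
#' with an alternative allele and the other with a reference allele under
#' some assignment. A configuration violating this is a Mendelian
#' inheritance error (MIE).
#'
#' @param u An integer vector `(child, parent1, parent2)` or a matrix with
#'   three columns (child first), entries in `{0, 1, 2}`.
#' @return A logical (vector), `TRUE` for consistent configurations.
#' @export
#' @examples
#' mendelian_consistent(c(2, 1, 1)) # TRUE
#' mendelian_consistent(c(2, 1, 0)) # FALSE: father carries no alt allele
mendelian_consistent <- function(u) {
  if (is.null(dim(u))) {
    stopifnot(length(u) == 3)
    u <- matrix(u, ncol = 3)
  }
  stopifnot(ncol(u) == 3)
  c_ <- u[, 1]; p <- u[, 2]; q <- u[, 3]
  (c_ == 0 & p <= 1 & q <= 1) |
    (c_ == 2 & p >= 1 & q >= 1) |
    (c_ == 1 & ((p >= 1 & q <= 1) | (p <= 1 & q >= 1)))
}

#' Is a trio genotype vector non-trivial?
#'
#' A trio vector is non-trivial when at least one of its three genotypes is
#' non-reference; only non-trivial vectors carry inheritance information.
#'
#' @param u A length-3 vector or 3-column matrix of genotypes in `{0, 1, 2}`.
#' @return Logical (vector).
#' @export
trio_nontrivial <- function(u) {
  if (is.null(dim(u))) u <- matrix(u, ncol = 3)
  rowSums(u != 0) > 0
}

#' All 27 trio configurations with their Mendelian status
#'
#' @return A tibble with columns `child`, `parent1`, `parent2`,
#'   `consistent`, `nontrivial` covering all of `{0, 1, 2}^3`.
#' @export
mendelian_rule_table <- function() {
  g <- expand.grid(parent2 = 0:2, parent1 = 0:2, child = 0:2)[, 3:1]
  tb <- as_tibble(g)
  m <- as.matrix(tb)
  tb$consistent <- mendelian_consistent(m)
  tb$nontrivial <- trio_nontrivial(m)
  tb
}

#' Enumerate trio-vector groups that merge into a Mendelian-consistent SV
#'
#' Enumerates every unordered pair and triplet of non-trivial trio genotype
#' vectors in `{0, 1, 2}^3` with pairwise disjoint support (no trio member is
#' non-reference in two of them, i.e. the vectors are pairwise
#' merging-compatible within the trio) whose elementwise sum is a
#' Mendelian-consistent configuration. These are the genotype patterns a
#' decomposed SV can leave in a trio; there are 26 such pairs and 7 triplets.
#' No larger group exists: with only three trio members, a fourth non-trivial
#' vector always collides with one of the first three.
#'
#' @return A list of class `sv_mergeable_patterns` with elements `pairs`
#'   (list of 2 x 3 integer matrices, one row per member vector, child column
#'   first) and `triplets` (list of 3 x 3 matrices).
#' @export
mergeable_patterns <- function() {
  g <- as.matrix(expand.grid(0:2, 0:2, 0:2))[, 3:1]
  colnames(g) <- c("child", "parent1", "parent2")
  nt <- g[rowSums(g != 0) > 0, , drop = FALSE]
  n <- nrow(nt)
  pairs <- list()
  for (a in seq_len(n - 1)) {
    for (b in seq((a + 1), n)) {
      if (any(nt[a, ] != 0 & nt[b, ] != 0)) next
      if (mendelian_consistent(nt[a, ] + nt[b, ])) {
        pairs[[length(pairs) + 1L]] <- nt[c(a, b), , drop = FALSE]
      }
    }
  }
  triplets <- list()
  for (a in seq_len(n - 2)) {
    for (b in seq((a + 1), n - 1)) {
      if (any(nt[a, ] != 0 & nt[b, ] != 0)) next
      for (d in seq((b + 1), n)) {
        if (any(nt[a, ] != 0 & nt[d, ] != 0)) next
        if (any(nt[b, ] != 0 & nt[d, ] != 0)) next
        if (mendelian_consistent(nt[a, ] + nt[b, ] + nt[d, ])) {
          triplets[[length(triplets) + 1L]] <- nt[c(a, b, d), , drop = FALSE]
        }
      }
    }
  }
  structure(list(pairs = pairs, triplets = triplets),
            class = "sv_mergeable_patterns")
}

#' @export
print.sv_mergeable_patterns <- function(x, ...) {
  cat("<sv_mergeable_patterns> ", length(x$pairs), " pairs, ",
      length(x$triplets), " triplets of non-trivial trio vectors\n", sep = "")
  invisible(x)
}
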