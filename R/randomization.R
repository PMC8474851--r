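#' Null model: shuffle genotype rows within each SV type
#'
#' Permutes the rows of the genotype matrix uniformly at random within each
#' SV-type stratum while leaving every record's coordinates untouched. This
#' destroys the association between genotypes and genomic position but
#' preserves, for any clustering of the coordinates, the cluster size
#' distribution and the per-type multiset of genotype rows -- the null in
#' which decomposed-SV patterns arise by chance alone.
#'
#' @param callset An [sv_callset()].
#' @param seed Integer seed.
#' @return A new `sv_callset` with permuted genotype rows.
#' @export
randomize_genotypes <- function(callset, seed = 1L) {
  stopifnot(inherits(callset, "sv_callset"))
  set.seed(seed)
  geno <- callset$genotypes
  for (ty in unique(callset$records$svtype)) {
    rows <- which(callset$records$svtype == ty)
    if (length(rows) > 1) {
      geno[rows, ] <- geno[rows[sample(length(rows))], , drop = FALSE]
    }
  }
  sv_callset(callset$records, geno)
}

#' An ensemble of randomized callsets
#'
#' @param callset An [sv_callset()].
#' @param n_replicates Number of randomized replicates (default 10).
#' @param seed Base seed; replicate k uses `seed + k`.
#' @return A list of `n_replicates` randomized callsets.
#' @export
random_ensemble <- function(callset, n_replicates = 10, seed = 1L) {
  if (n_replicates < 1) abort("n_replicates must be >= 1")
  map(seq_len(n_replicates), function(k) {
    randomize_genotypes(callset, seed = seed + k)
  })
}

#' Pointwise envelope of replicate curves
#'
#' Summarizes an ensemble of per-threshold statistic curves by their
#' pointwise minimum and maximum across replicates.
#'
#' @param df A data frame with columns `replicate`, `d_max` and `value`.
#' @return A tibble with one row per `d_max`: `min`, `max`, `n_replicates`.
#' @export
envelope <- function(df) {
  df <- as_tibble(df)
  if (!all(c("replicate", "d_max", "value") %in% names(df))) {
    abort("df needs columns replicate, d_max, value")
  }
  if (nrow(df) == 0) abort("empty ensemble")
  df %>%
    group_by(.data$d_max) %>%
    summarise(min = min(.data$value), max = max(.data$value),
              n_replicates = dplyr::n_distinct(.data$replicate),
              .groups = "drop")
}
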