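#' Per-trio fraction of SVs with a Mendelian inheritance error
#'
#' For one trio, the fraction of SVs whose (child, father, mother) genotype
#' configuration is non-trivial (at least one non-reference genotype, the
#' informative SVs) and inconsistent with Mendelian inheritance. All-reference
#' configurations carry no inheritance information and are excluded from the
#' denominator.
#'
#' @param callset An [sv_callset()].
#' @param trio Character vector `(child, father, mother)` of sample names.
#' @return A single fraction in `[0, 1]`; 0 (with a warning) when the trio
#'   has no informative SV.
#' @export
trio_f_mei <- function(callset, trio) {
  stopifnot(inherits(callset, "sv_callset"), length(trio) == 3)
  missing <- setdiff(trio, colnames(callset$genotypes))
  if (length(missing) > 0) {
    abort(paste0("unknown sample(s): ", paste(missing, collapse = ", ")))
  }
  U <- callset$genotypes[, trio, drop = FALSE]
  nt <- rowSums(U != 0L) > 0
  if (!any(nt)) {
    warn("trio has no informative SVs; f_MEI set to 0")
    return(0)
  }
  mie <- nt & !mendelian_consistent(U)
  sum(mie) / sum(nt)
}

#' Mendelian-error fraction for every trio of a pedigree
#'
#' @param callset An [sv_callset()].
#' @param pedigree An [sv_pedigree()].
#' @return A tibble with one row per trio: `family`, `child`, `f_mei`,
#'   `n_informative`, `n_mie`.
#' @export
f_mei <- function(callset, pedigree) {
  stopifnot(inherits(pedigree, "sv_pedigree"))
  trios <- pedigree$trios
  out <- map(seq_len(nrow(trios)), function(t) {
    cols <- c(trios$child[t], trios$father[t], trios$mother[t])
    U <- callset$genotypes[, cols, drop = FALSE]
    nt <- rowSums(U != 0L) > 0
    mie <- nt & !mendelian_consistent(U)
    tibble(family = trios$family[t], child = trios$child[t],
           f_mei = if (any(nt)) sum(mie) / sum(nt) else 0,
           n_informative = sum(nt), n_mie = sum(mie))
  })
  bind_rows(out)
}

#' Mendelian bookkeeping of merged clusters, per trio
#'
#' For every trio and every merged component (>= 2 members) of a clustering,
#' classifies the merge by the Mendelian status of its members' and its
#' merged trio genotype configuration:
#'
#' * `n_ic` counts merges where at least one member was a Mendelian
#'   inheritance error (MIE) and the merged configuration is non-trivial and
#'   Mendelian-consistent -- decomposed SVs correctly reassembled.
#' * `n_cc` counts merges with no member MIE whose merged configuration *is*
#'   an MIE -- errors created by merging.
#'
#' @param clustering An `sv_clustering` from [cluster_svs()].
#' @param pedigree An [sv_pedigree()].
#' @return A tibble with one row per trio: `family`, `child`, `n_ic`, `n_cc`.
#' @export
mendelian_merge_counts <- function(clustering, pedigree) {
  stopifnot(inherits(clustering, "sv_clustering"),
            inherits(pedigree, "sv_pedigree"))
  geno <- clustering$input$genotypes
  trios <- pedigree$trios
  merged_comps <- clustering$components[clustering$merged]
  out <- map(seq_len(nrow(trios)), function(t) {
    cols <- c(trios$child[t], trios$father[t], trios$mother[t])
    n_ic <- 0L; n_cc <- 0L
    for (comp in merged_comps) {
      U <- geno[comp, cols, drop = FALSE]
      nt <- rowSums(U != 0L) > 0
      member_mie <- nt & !mendelian_consistent(U)
      u_merged <- colSums(U)
      merged_nt <- any(u_merged != 0)
      merged_ok <- mendelian_consistent(u_merged)
      if (any(member_mie) && merged_nt && merged_ok) n_ic <- n_ic + 1L
      if (!any(member_mie) && merged_nt && !merged_ok) n_cc <- n_cc + 1L
    }
    tibble(family = trios$family[t], child = trios$child[t],
           n_ic = n_ic, n_cc = n_cc)
  })
  bind_rows(out)
}

#' Average a per-trio metric over a family's trios
#'
#' @param values Numeric vector of per-trio values (non-empty).
#' @return Their arithmetic mean.
#' @export
family_average <- function(values) {
  if (length(values) == 0) abort("no trios to average over")
  mean(values)
}

#' Proportion of shared alleles between two samples
#'
#' The simple allele-sharing kinship estimator: at each locus two diploid
#' genotypes g and h (coded 0/1/2 alternative-allele counts) share
#' `min(g, h) + min(2 - g, 2 - h)` of their two allele slots. The estimate is
#' the mean of (shared alleles)/2 over included loci. Loci monomorphic
#' across the whole cohort are excluded (they are uninformative for every
#' pair); loci where only the tested pair is reference-homozygous count as
#' full sharing.
#'
#' @param callset An [sv_callset()].
#' @param sample1,sample2 Sample names.
#' @return A value in `[0, 1]` (`NA` if no locus is polymorphic).
#' @export
sxy_kinship <- function(callset, sample1, sample2) {
  geno <- callset$genotypes
  missing <- setdiff(c(sample1, sample2), colnames(geno))
  if (length(missing) > 0) {
    abort(paste0("unknown sample(s): ", paste(missing, collapse = ", ")))
  }
  poly <- apply(geno, 1, function(r) length(unique(r)) > 1)
  if (!any(poly)) return(NA_real_)
  g <- geno[poly, sample1]
  h <- geno[poly, sample2]
  shared <- pmin(g, h) + pmin(2L - g, 2L - h)
  mean(shared / 2)
}

#' Allele-sharing estimates for a set of sample pairs
#'
#' @param callset An [sv_callset()].
#' @param pairs A data frame with columns `sample1`, `sample2` (for example
#'   `pedigree$kinship_pairs`).
#' @return `pairs` with an added `estimate` column.
#' @export
sxy_pairs <- function(callset, pairs) {
  pairs <- as_tibble(pairs)
  geno <- callset$genotypes
  poly <- apply(geno, 1, function(r) length(unique(r)) > 1)
  pairs$estimate <- vapply(seq_len(nrow(pairs)), function(k) {
    if (!any(poly)) return(NA_real_)
    g <- geno[poly, pairs$sample1[k]]
    h <- geno[poly, pairs$sample2[k]]
    mean((pmin(g, h) + pmin(2L - g, 2L - h)) / 2)
  }, 0)
  pairs
}

#' Separation error between kinship categories
#'
#' Given relatedness estimates for sample pairs grouped into kinship
#' categories by relationship coefficient r (ordered increasingly), a pair
#' is correctly placed when its estimate lies strictly above the maximum
#' estimate of the category below and strictly below the minimum estimate of
#' the category above (boundary categories face -Inf / +Inf). Per category,
#' `L` counts correctly placed pairs and the error rate is
#' `s = 1 - L / n_pairs`; the overall separation error is the mean of `s`
#' over categories. Categories with fewer than two pairs are skipped with a
#' warning.
#'
#' @param estimates A data frame with columns `r` (relationship coefficient)
#'   and `estimate` (one row per sample pair), e.g. from [sxy_pairs()] on
#'   `pedigree$kinship_pairs`.
#' @return A list with `by_category` (tibble: `r`, `n_pairs`, `L`, `s`) and
#'   `s_mean`.
#' @export
kinship_separation <- function(estimates) {
  est <- as_tibble(estimates)
  if (!all(c("r", "estimate") %in% names(est))) {
    abort("estimates needs columns r and estimate")
  }
  est <- est[!is.na(est$estimate), , drop = FALSE]
  rs <- sort(unique(est$r))
  by_cat <- map(seq_along(rs), function(i) {
    vals <- est$estimate[est$r == rs[i]]
    lower <- if (i > 1) max(est$estimate[est$r == rs[i - 1]]) else -Inf
    upper <- if (i < length(rs)) min(est$estimate[est$r == rs[i + 1]]) else Inf
    L <- sum(vals > lower & vals < upper)
    tibble(r = rs[i], n_pairs = length(vals), L = L,
           s = 1 - L / length(vals))
  })
  by_cat <- bind_rows(by_cat)
  small <- by_cat$n_pairs < 2
  if (any(small)) {
    warn(paste0("skipping ", sum(small),
                " kinship categor(y/ies) with < 2 pairs"))
  }
  kept <- by_cat[!small, , drop = FALSE]
  list(by_category = by_cat,
       s_mean = if (nrow(kept) > 0) mean(kept$s) else NA_real_)
}

#' Hardy-Weinberg equilibrium chi-square tests per SV
#'
#' For each SV polymorphic among the given samples, compares observed
#' genotype counts (n0, n1, n2) with the Hardy-Weinberg expectations
#' n*(p^2, 2pq, q^2) by a 1-degree-of-freedom Pearson chi-square test
#' without continuity correction, then applies a Bonferroni correction over
#' all tested SVs. Monomorphic SVs are untestable and excluded.
#'
#' @param callset An [sv_callset()].
#' @param samples Character vector of (unrelated) sample names to test on.
#' @return A tibble with one row per SV: `id`, `tested`, `n0`, `n1`, `n2`,
#'   `chi2`, `p`, `p_bonf`.
#' @export
hwe_test <- function(callset, samples) {
  if (length(samples) == 0) abort("empty sample set for HWE testing")
  missing <- setdiff(samples, colnames(callset$genotypes))
  if (length(missing) > 0) {
    abort(paste0("unknown sample(s): ", paste(missing, collapse = ", ")))
  }
  geno <- callset$genotypes[, samples, drop = FALSE]
  n0 <- rowSums(geno == 0L)
  n1 <- rowSums(geno == 1L)
  n2 <- rowSums(geno == 2L)
  n <- length(samples)
  q <- (2 * n2 + n1) / (2 * n) # alternative-allele frequency
  tested <- q > 0 & q < 1
  e0 <- n * (1 - q)^2; e1 <- n * 2 * q * (1 - q); e2 <- n * q^2
  chi2 <- ifelse(tested,
                 (n0 - e0)^2 / e0 + (n1 - e1)^2 / e1 + (n2 - e2)^2 / e2,
                 NA_real_)
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  p_bonf <- rep(NA_real_, length(p))
  p_bonf[tested] <- p.adjust(p[tested], method = "bonferroni")
  tibble(id = callset$records$id, tested = unname(tested),
         n0 = unname(n0), n1 = unname(n1), n2 = unname(n2),
         chi2 = unname(chi2), p = unname(p), p_bonf = unname(p_bonf))
}

#' Fraction of SVs in Hardy-Weinberg equilibrium
#'
#' The fraction of testable (polymorphic) SVs whose Bonferroni-corrected
#' chi-square p-value is `>= alpha`, i.e. that do not significantly deviate
#' from Hardy-Weinberg proportions among the given unrelated samples.
#'
#' @inheritParams hwe_test
#' @param alpha Significance level after correction (default 0.05).
#' @return A fraction in `[0, 1]` (`NA` when no SV is testable).
#' @export
hwe_fraction <- function(callset, samples, alpha = 0.05) {
  ht <- hwe_test(callset, samples)
  ht <- ht[ht$tested, , drop = FALSE]
  if (nrow(ht) == 0) return(NA_real_)
  mean(ht$p_bonf >= alpha)
}
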