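#' Quality metrics of one merged call set
#'
#' Computes the four dataset-quality measures for a clustering result:
#' per-family averages of the Mendelian-error fraction and of the
#' consistent-from-error / error-from-consistent merge counts, the
#' kinship-category separation error (allele-sharing estimator) per family,
#' and the cohort-level fraction of SVs in Hardy-Weinberg equilibrium over
#' the unrelated samples.
#'
#' @param clustering An `sv_clustering`.
#' @param pedigree An [sv_pedigree()].
#' @param alpha Significance level for the HWE test (after Bonferroni).
#' @return A long tibble with columns `metric`, `family` (`NA` for
#'   cohort-level metrics) and `value`. Metrics: `f_mei`, `n_ic`, `n_cc`,
#'   `s_mean` (per family), `f_hweq` (cohort).
#' @export
clustering_metrics <- function(clustering, pedigree, alpha = 0.05) {
  merged <- clustering$callset
  fm <- f_mei(merged, pedigree) %>%
    group_by(.data$family) %>%
    summarise(value = mean(.data$f_mei), .groups = "drop") %>%
    mutate(metric = "f_mei")
  mc <- mendelian_merge_counts(clustering, pedigree) %>%
    group_by(.data$family) %>%
    summarise(n_ic = mean(.data$n_ic), n_cc = mean(.data$n_cc),
              .groups = "drop") %>%
    tidyr::pivot_longer(c("n_ic", "n_cc"), names_to = "metric",
                        values_to = "value")
  fams <- unique(pedigree$trios$family)
  ks <- map(fams, function(fam) {
    kp <- pedigree$kinship_pairs
    kp <- kp[kp$family == fam, , drop = FALSE]
    if (nrow(kp) == 0) return(NULL)
    est <- sxy_pairs(merged, kp)
    sep <- suppressWarnings(kinship_separation(est))
    tibble(family = fam, metric = "s_mean", value = sep$s_mean)
  })
  unrel <- unrelated_samples(pedigree)
  hw <- if (length(unrel) > 0) {
    tibble(family = NA_character_, metric = "f_hweq",
           value = hwe_fraction(merged, unrel, alpha = alpha))
  } else NULL
  bind_rows(fm, mc, bind_rows(ks), hw) %>%
    select("metric", "family", "value")
}

#' Sweep clustering strategies over threshold grids
#'
#' Runs every combination of strategy, dissimilarity measure and grid
#' threshold, computing all quality metrics of the merged call set at each
#' point -- the full comparison design (strategies x measures x thresholds).
#'
#' @param callset An [sv_callset()].
#' @param pedigree An [sv_pedigree()].
#' @param strategies Subset of `c("trivial", "corrected", "constrained")`.
#' @param measures Subset of `c("d1", "d2")`.
#' @param grids Named list of threshold grids, e.g.
#'   `list(d1 = seq(0.05, 0.95, 0.05), d2 = seq(50, 1000, 50))`.
#' @param seed Seed for the constrained strategy's tie-breaks.
#' @param alpha HWE significance level.
#' @return A tibble of class `sv_sweep`: one row per (strategy, measure,
#'   d_max, metric, family) with the metric `value`.
#' @export
run_sweep <- function(callset, pedigree,
                      strategies = c("trivial", "corrected", "constrained"),
                      measures = c("d1", "d2"),
                      grids = list(d1 = seq(0.05, 0.95, by = 0.05),
                                   d2 = seq(50, 1000, by = 50)),
                      seed = 1L, alpha = 0.05) {
  strategies <- match.arg(strategies, several.ok = TRUE)
  measures <- match.arg(measures, several.ok = TRUE)
  out <- list()
  for (meas in measures) {
    grid <- grids[[meas]]
    if (is.null(grid)) abort(paste0("no grid supplied for measure ", meas))
    if (is.unsorted(grid, strictly = TRUE)) {
      abort("grid thresholds must be strictly increasing")
    }
    for (strat in strategies) {
      for (dm in grid) {
        cl <- cluster_svs(callset, strategy = strat, measure = meas,
                          d_max = dm, pedigree = pedigree, seed = seed)
        met <- clustering_metrics(cl, pedigree, alpha = alpha)
        met$strategy <- strat
        met$measure <- meas
        met$d_max <- dm
        out[[length(out) + 1L]] <- met
      }
    }
  }
  res <- bind_rows(out) %>%
    select("strategy", "measure", "d_max", "metric", "family", "value")
  class(res) <- c("sv_sweep", class(res))
  res
}

#' Best achieved value of each metric per clustering scenario
#'
#' Summarizes a sweep by the extreme each scenario attains over its grid:
#' the minimum Mendelian-error fraction and kinship-separation error, and
#' the maximum consistent-from-error merge count and Hardy-Weinberg
#' fraction.
#'
#' @param sweep An `sv_sweep` from [run_sweep()].
#' @return A tibble with one row per (strategy, measure, metric, family):
#'   the `best` value and the `d_max` where it is attained (the smallest
#'   such threshold on ties).
#' @export
report_extremes <- function(sweep) {
  direction <- c(f_mei = "min", n_ic = "max", n_cc = "min",
                 s_mean = "min", f_hweq = "max")
  sweep %>%
    filter(.data$metric %in% names(direction), !is.na(.data$value)) %>%
    group_by(.data$strategy, .data$measure, .data$metric, .data$family) %>%
    summarise(best = if (direction[[.data$metric[1]]] == "min")
                min(.data$value) else max(.data$value),
              d_max = .data$d_max[which(.data$value == best)[1]],
              .groups = "drop")
}

#' Null-model metric curves from a randomized ensemble
#'
#' Applies the within-type row-shuffling null model ([randomize_genotypes()])
#' `n_replicates` times and recomputes the quality metrics on each replicate
#' across the threshold grid, using the corrected strategy by default (the
#' randomization is performed before the incompatibility correction).
#'
#' @inheritParams run_sweep
#' @param strategy Clustering strategy evaluated on the replicates.
#' @param measure Single dissimilarity measure.
#' @param grid Threshold grid for `measure`.
#' @param n_replicates Ensemble size (default 10).
#' @return A tibble: one row per (replicate, d_max, metric, family).
#' @export
run_null_ensemble <- function(callset, pedigree, measure = c("d1", "d2"),
                              grid, strategy = "corrected",
                              n_replicates = 10, seed = 1L, alpha = 0.05) {
  measure <- match.arg(measure)
  reps <- random_ensemble(callset, n_replicates = n_replicates, seed = seed)
  out <- list()
  for (k in seq_along(reps)) {
    sw <- run_sweep(reps[[k]], pedigree, strategies = strategy,
                    measures = measure, grids = setNames(list(grid), measure),
                    seed = seed, alpha = alpha)
    sw$replicate <- k
    out[[length(out) + 1L]] <- sw
  }
  res <- bind_rows(out)
  class(res) <- setdiff(class(res), "sv_sweep")
  res
}

#' Plot sweep curves
#'
#' One panel per metric (rows) and measure (columns, free x scales since d1
#' is unitless and d2 is in bp), curves colored by strategy; family-level
#' metrics drawn per family.
#'
#' @param object An `sv_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sv_sweep
#' @export
autoplot.sv_sweep <- function(object, ...) {
  df <- as_tibble(object)
  df$family[is.na(df$family)] <- "cohort"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d_max, y = .data$value,
                                   color = .data$strategy,
                                   linetype = .data$family)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_grid(metric ~ measure, scales = "free") +
    ggplot2::labs(x = "dissimilarity threshold d_max", y = NULL,
                  color = "strategy", linetype = "family") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.sv_sweep
#' @param sweep An `sv_sweep`.
#' @export
plot_sweep <- function(sweep, ...) autoplot.sv_sweep(sweep, ...)
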