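#' Cluster and merge a multi-sample SV call set
#'
#' Clusters SV records of the same chromosome and type whose pairwise
#' dissimilarity is at most `d_max`, then merges each cluster's genotype rows
#' by summation. Three strategies handle clusters containing
#' merging-incompatible pairs (two records both non-reference in some
#' sample):
#'
#' * `"trivial"`: a component containing any incompatible pair is left
#'   entirely unmerged (every member emitted as-is).
#' * `"corrected"`: such a component is re-split at the largest threshold
#'   `D < d_max` at which all sub-components are incompatibility-free; the
#'   sub-components are then merged. Candidate thresholds are the realized
#'   pairwise dissimilarities within the component (plus 0), since the
#'   sub-component structure only changes at those values.
#' * `"constrained"`: trio-informed constrained agglomerative clustering
#'   (see [cluster_constrained()]); requires `pedigree`.
#'
#' @param callset An [sv_callset()].
#' @param strategy `"trivial"`, `"corrected"` or `"constrained"`.
#' @param measure `"d1"` (overlap-based, threshold in `[0,1)`) or `"d2"`
#'   (breakpoint distance, threshold in bp).
#' @param d_max Dissimilarity threshold.
#' @param pedigree An [sv_pedigree()]; required for the constrained strategy.
#' @param seed Integer seed for the constrained strategy's random
#'   tie-breaks; ignored otherwise.
#' @return An object of class `sv_clustering`: a list with `components`
#'   (list of integer row-index vectors, the final partition), `merged`
#'   (logical per component: TRUE when >= 2 members were summed), the
#'   materialized output `callset` (see [materialize_clustering()]), the
#'   input callset as `input`, and the call parameters.
#' @export
cluster_svs <- function(callset, strategy = c("trivial", "corrected",
                                              "constrained"),
                        measure = c("d1", "d2"), d_max,
                        pedigree = NULL, seed = 1L) {
  strategy <- match.arg(strategy)
  measure <- match.arg(measure)
  stopifnot(inherits(callset, "sv_callset"))
  if (strategy == "constrained") {
    if (is.null(pedigree)) {
      abort("the constrained strategy requires a pedigree")
    }
    return(cluster_constrained(callset, pedigree, measure, d_max, seed))
  }
  records <- callset$records
  geno <- callset$genotypes
  edges <- candidate_pairs(records, measure, d_max)
  membership <- components_from_edges(nrow(records), edges)
  comps <- split(seq_len(nrow(records)), membership)

  final <- list()
  for (comp in comps) {
    if (length(comp) == 1 || component_compatible(geno, comp)) {
      final[[length(final) + 1L]] <- comp
    } else if (strategy == "trivial") {
      for (m in comp) final[[length(final) + 1L]] <- m
    } else {
      subs <- corrected_split(comp, geno, edges, d_max)
      for (s in subs) final[[length(final) + 1L]] <- s
    }
  }
  new_sv_clustering(callset, final, strategy, measure, d_max)
}

# TRUE when no merging-incompatible pair exists among the rows
component_compatible <- function(geno, rows) {
  if (length(rows) < 2) return(TRUE)
  max(colSums(geno[rows, , drop = FALSE] != 0L)) <= 1L
}

# Re-split one incompatible component at the maximal valid threshold D < d_max.
# Scans realized edge dissimilarities downward; a threshold below the minimum
# pairwise dissimilarity always works (all singletons), so a solution exists.
corrected_split <- function(comp, geno, edges, d_max) {
  within <- edges[edges$i %in% comp & edges$j %in% comp, , drop = FALSE]
  cand <- sort(unique(within$d[within$d < d_max]), decreasing = TRUE)
  for (D in c(cand, -1)) {
    sub_e <- within[within$d <= D, , drop = FALSE]
    # relabel to local indices
    loc <- match(c(sub_e$i, sub_e$j), comp)
    le <- tibble(i = loc[seq_len(nrow(sub_e))],
                 j = loc[seq_len(nrow(sub_e)) + nrow(sub_e)])
    memb <- components_from_edges(length(comp), le)
    subs <- split(comp, memb)
    ok <- all(vapply(subs, function(s) component_compatible(geno, s), TRUE))
    if (ok) return(unname(subs))
  }
  as.list(comp) # unreachable: singletons are always compatible
}

new_sv_clustering <- function(callset, components, strategy, measure, d_max,
                              groups = NULL, seed = NULL) {
  components <- unname(lapply(components, function(x)
    unname(sort(as.integer(x)))))
  # deterministic component order: by (chrom, start, id) of first member
  rec <- callset$records
  first <- vapply(components, function(m) {
    m[order(rec$chrom[m], rec$start[m], rec$id[m])][1]
  }, 0L)
  ord <- order(rec$chrom[first], rec$start[first], rec$id[first])
  components <- components[ord]
  obj <- structure(list(
    components = components,
    merged = lengths(components) >= 2L,
    input = callset,
    strategy = strategy, measure = measure, d_max = d_max,
    groups = groups, seed = seed), class = "sv_clustering")
  obj$callset <- materialize_clustering(obj)
  obj
}

#' Materialize a clustering as a merged call set
#'
#' Produces one output record per final component: the representative record
#' spans the min start to max end of its members, takes the
#' lexicographically smallest member ID, and lists all member IDs in a
#' `members` column; its genotype row is the sum of the member rows
#' (see [merge_genotypes()]).
#'
#' @param clustering An `sv_clustering`.
#' @return An [sv_callset()] whose records carry `members`, `n_members` and
#'   `merged` columns.
#' @export
materialize_clustering <- function(clustering) {
  rec <- clustering$input$records
  geno <- clustering$input$genotypes
  comps <- clustering$components
  rows <- map(comps, function(m) {
    r <- rec[m, , drop = FALSE]
    tibble(id = min(r$id), chrom = r$chrom[1],
           start = min(r$start), end = max(r$end),
           svtype = r$svtype[1],
           length = max(r$end) - min(r$start) + 1L,
           members = paste(sort(r$id), collapse = ","),
           n_members = length(m),
           merged = length(m) >= 2L)
  })
  out_rec <- bind_rows(rows)
  out_geno <- do.call(rbind, map(comps, function(m) merge_genotypes(geno, m)))
  colnames(out_geno) <- colnames(geno)
  sv_callset(out_rec, out_geno)
}

#' @export
print.sv_clustering <- function(x, ...) {
  cat("<sv_clustering> strategy=", x$strategy, " measure=", x$measure,
      " d_max=", x$d_max, "\n", sep = "")
  cat("  ", nrow(x$input$records), " input SVs -> ",
      length(x$components), " output SVs (",
      sum(x$merged), " merged components)\n", sep = "")
  invisible(x)
}

#' @method tidy sv_clustering
#' @export
tidy.sv_clustering <- function(x, ...) {
  rec <- x$input$records
  comp_of <- integer(nrow(rec))
  for (k in seq_along(x$components)) comp_of[x$components[[k]]] <- k
  rep_id <- vapply(x$components, function(m) min(rec$id[m]), "")
  tibble(id = rec$id, chrom = rec$chrom, start = rec$start, end = rec$end,
         svtype = rec$svtype, component = comp_of,
         component_id = rep_id[comp_of],
         merged = x$merged[comp_of])
}

#' @method glance sv_clustering
#' @export
glance.sv_clustering <- function(x, ...) {
  tibble(strategy = x$strategy, measure = x$measure, d_max = x$d_max,
         n_input = nrow(x$input$records),
         n_output = length(x$components),
         n_merged_components = sum(x$merged),
         n_groups = if (is.null(x$groups)) NA_integer_ else nrow(x$groups))
}
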