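#' Combinatorial search for decomposed-SV groups within trios
#'
#' Searches every parent-child trio for pairs and triplets of SV records
#' (same chromosome and type) whose trio-restricted genotype vectors are
#' non-trivial, pairwise merging-compatible, and sum to a
#' Mendelian-consistent configuration -- the signature a decomposed SV leaves
#' in a trio. Two further conditions must hold for a group to be emitted:
#' (1) the members are pairwise merging-compatible over *all* samples, not
#' just the trio; and (2) every member pair has dissimilarity `<= d_max`.
#' Only pairs and triplets exist: adding a fourth non-trivial trio vector to
#' a triplet always creates a merging-incompatible pair within the trio.
#'
#' @inheritParams cluster_svs
#' @param edges Optional precomputed [candidate_pairs()] result.
#' @return A tibble with one row per distinct member set: `members`
#'   (list-column of sorted row indices), `n_members`, `trios` (list-column
#'   of trio indices into `pedigree$trios` where the pattern was seen) and
#'   `n_trios`.
#' @export
find_sv_groups <- function(callset, pedigree, measure = c("d1", "d2"), d_max,
                           edges = NULL) {
  measure <- match.arg(measure)
  stopifnot(inherits(callset, "sv_callset"), inherits(pedigree, "sv_pedigree"))
  geno <- callset$genotypes
  records <- callset$records
  if (is.null(edges)) edges <- candidate_pairs(records, measure, d_max)
  trios <- pedigree$trios
  missing <- setdiff(unique(c(trios$child, trios$father, trios$mother)),
                     colnames(geno))
  if (length(missing) > 0) {
    abort(paste0("trio samples absent from callset: ",
                 paste(missing, collapse = ", ")))
  }
  # keep only edges whose endpoints are merging-compatible over all samples
  if (nrow(edges) > 0) {
    comp_ok <- vapply(seq_len(nrow(edges)), function(k) {
      !is_merging_incompatible(geno[edges$i[k], ], geno[edges$j[k], ])
    }, TRUE)
    cedges <- edges[comp_ok, , drop = FALSE]
  } else {
    cedges <- edges
  }

  found <- new.env(parent = emptyenv())
  note <- function(members, trio_idx) {
    key <- paste(members, collapse = ",")
    cur <- found[[key]]
    if (is.null(cur)) {
      found[[key]] <- list(members = members, trios = trio_idx)
    } else {
      found[[key]]$trios <- union(cur$trios, trio_idx)
    }
  }

  for (t in seq_len(nrow(trios))) {
    cols <- c(trios$child[t], trios$father[t], trios$mother[t])
    U <- geno[, cols, drop = FALSE]
    nt <- rowSums(U != 0L) > 0
    if (nrow(cedges) == 0) next
    te <- cedges[nt[cedges$i] & nt[cedges$j], , drop = FALSE]
    if (nrow(te) == 0) next
    # pairs
    sums <- U[te$i, , drop = FALSE] + U[te$j, , drop = FALSE]
    ok <- mendelian_consistent(sums)
    for (k in which(ok)) note(sort(c(te$i[k], te$j[k])), t)
    # triplets = triangles of the compatible within-threshold graph
    verts <- sort(unique(c(te$i, te$j)))
    g <- igraph::graph_from_edgelist(
      cbind(match(te$i, verts), match(te$j, verts)), directed = FALSE)
    tri <- igraph::triangles(g)
    if (length(tri) > 0) {
      tri <- matrix(verts[as.integer(tri)], ncol = 3, byrow = TRUE)
      for (k in seq_len(nrow(tri))) {
        m3 <- tri[k, ]
        u_sum <- U[m3[1], ] + U[m3[2], ] + U[m3[3], ]
        if (max(u_sum) <= 2 && mendelian_consistent(u_sum)) {
          note(sort(m3), t)
        }
      }
    }
  }
  keys <- ls(found)
  if (length(keys) == 0) {
    return(tibble(members = list(), n_members = integer(0),
                  trios = list(), n_trios = integer(0)))
  }
  tb <- tibble(
    members = map(keys, function(k) found[[k]]$members),
    trios = map(keys, function(k) sort(found[[k]]$trios)))
  tb$n_members <- lengths(tb$members)
  tb$n_trios <- lengths(tb$trios)
  # deterministic order: by first member, then size
  ord <- order(map_int(tb$members, 1), map_int(tb$members, ~ .x[length(.x)]),
               tb$n_members)
  tb[ord, c("members", "n_members", "trios", "n_trios")]
}

#' Reduce overlapping SV groups to a disjoint accepted set
#'
#' Groups found by [find_sv_groups()] may share SV records and are then
#' mutually exclusive (two groups sharing a record are merging-incompatible).
#' Groups are vertices of an intersection graph (edge = shared record); each
#' connected component is reduced greedily: repeatedly take the group
#' detected in the most trios (ties broken at random under `seed`), accept
#' it if it is merging-compatible with the groups already accepted in the
#' component *and* the running merged genotype vector stays
#' Mendelian-consistent (or trivial) in every trio, then drop it from the
#' queue.
#'
#' @param groups A [find_sv_groups()] result.
#' @inheritParams cluster_svs
#' @return A list with `accepted` (the accepted subset of `groups` with a
#'   `reduced_component` column) and `reduced_components` (list of integer
#'   vectors: the union of accepted member rows per intersection-graph
#'   component, the must-link sets for constrained clustering).
#' @export
reduce_sv_groups <- function(groups, callset, pedigree, seed = 1L) {
  stopifnot(inherits(callset, "sv_callset"), inherits(pedigree, "sv_pedigree"))
  geno <- callset$genotypes
  trios <- pedigree$trios
  n_g <- nrow(groups)
  if (n_g == 0) {
    return(list(accepted = groups, reduced_components = list()))
  }
  # intersection graph over groups
  g <- igraph::make_empty_graph(n = n_g, directed = FALSE)
  if (n_g > 1) {
    el <- list()
    for (a in seq_len(n_g - 1)) {
      for (b in seq(a + 1, n_g)) {
        if (length(intersect(groups$members[[a]], groups$members[[b]])) > 0) {
          el[[length(el) + 1L]] <- c(a, b)
        }
      }
    }
    if (length(el) > 0) g <- igraph::add_edges(g, unlist(el))
  }
  memb <- as.integer(igraph::components(g)$membership)

  set.seed(seed)
  trio_cols <- map(seq_len(nrow(trios)), function(t) {
    c(trios$child[t], trios$father[t], trios$mother[t])
  })
  accepted_idx <- integer(0)
  comp_of_accepted <- integer(0)
  reduced <- list()
  for (ci in sort(unique(memb))) {
    queue <- which(memb == ci)
    acc_rows <- integer(0)
    acc_support <- rep(FALSE, ncol(geno))
    acc_groups <- integer(0)
    while (length(queue) > 0) {
      best <- queue[groups$n_trios[queue] == max(groups$n_trios[queue])]
      pick <- if (length(best) > 1) sample(best, 1) else best
      queue <- setdiff(queue, pick)
      members <- groups$members[[pick]]
      sup <- colSums(geno[members, , drop = FALSE] != 0L) > 0
      if (any(sup & acc_support)) next # merging-incompatible with accepted
      merged <- colSums(geno[c(acc_rows, members), , drop = FALSE])
      ok <- TRUE
      for (cols in trio_cols) {
        u <- merged[cols]
        if (any(u != 0) && !mendelian_consistent(u)) { ok <- FALSE; break }
      }
      if (!ok) next
      acc_rows <- c(acc_rows, members)
      acc_support <- acc_support | sup
      acc_groups <- c(acc_groups, pick)
    }
    if (length(acc_groups) > 0) {
      reduced[[length(reduced) + 1L]] <- sort(acc_rows)
      accepted_idx <- c(accepted_idx, acc_groups)
      comp_of_accepted <- c(comp_of_accepted,
                            rep(length(reduced), length(acc_groups)))
    }
  }
  acc <- groups[accepted_idx, , drop = FALSE]
  acc$reduced_component <- comp_of_accepted
  list(accepted = acc, reduced_components = reduced)
}

#' Constrained agglomerative clustering of SVs
#'
#' The trio-informed clustering strategy. Reduced decomposed-SV groups
#' ([find_sv_groups()] then [reduce_sv_groups()]) are pre-linked as
#' must-link components; all remaining records start as singletons.
#' Candidate pairs (same chromosome and type, dissimilarity `<= d_max`) are
#' then processed in ascending dissimilarity order -- all pairs tied at the
#' current minimum before moving on -- and a pair's two components are
#' united only when the union would contain no merging-incompatible
#' (cannot-link) pair. Since every component is internally compatible, the
#' test reduces to disjointness of the two components' carrier supports.
#' Agglomeration stops when no cross-component pair at dissimilarity
#' `<= d_max` remains.
#'
#' @inheritParams cluster_svs
#' @return An `sv_clustering` (see [cluster_svs()]) whose `groups` element
#'   holds the accepted SV groups.
#' @export
cluster_constrained <- function(callset, pedigree, measure = c("d1", "d2"),
                                d_max, seed = 1L) {
  measure <- match.arg(measure)
  stopifnot(inherits(callset, "sv_callset"))
  records <- callset$records
  geno <- callset$genotypes
  n <- nrow(records)
  edges <- candidate_pairs(records, measure, d_max)
  groups <- find_sv_groups(callset, pedigree, measure, d_max, edges = edges)
  red <- reduce_sv_groups(groups, callset, pedigree, seed = seed)

  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  support <- geno != 0L # row = record; component support kept at root row
  link <- function(a, b) {
    ra <- find(a); rb <- find(b)
    parent[rb] <<- ra
    support[ra, ] <<- support[ra, ] | support[rb, ]
  }
  for (comp in red$reduced_components) {
    for (m in comp[-1]) link(comp[1], m)
  }
  if (nrow(edges) > 0) {
    # tie order within equal dissimilarity: genomic (chrom, start, id) rank
    rank_key <- order(records$chrom, records$start, records$id)
    pos_rank <- integer(n); pos_rank[rank_key] <- seq_len(n)
    ord <- order(edges$d, pmin(pos_rank[edges$i], pos_rank[edges$j]),
                 pmax(pos_rank[edges$i], pos_rank[edges$j]))
    for (k in ord) {
      a <- find(edges$i[k]); b <- find(edges$j[k])
      if (a == b) next
      if (any(support[a, ] & support[b, ])) next # cannot-link
      link(a, b)
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  comps <- split(seq_len(n), roots)
  new_sv_clustering(callset, comps, "constrained", measure, d_max,
                    groups = red$accepted, seed = seed)
}
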