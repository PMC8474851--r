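#' Dissimilarity measures between SV intervals
#'
#' Two measures are implemented, both defined only for SVs of the same type
#' on the same chromosome. `sv_d1()` is overlap-based:
#' `D1 = 1 - |g1 intersect g2| / max(|g1|, |g2|)`, so 0 for identical
#' intervals and 1 for disjoint ones. `sv_d2()` is breakpoint-based:
#' `D2 = max(|start1 - start2|, |end1 - end2|)` in bp, a metric on intervals.
#' Intervals are 1-based inclusive; overlap length is
#' `max(0, min(end1, end2) - max(start1, start2) + 1)`.
#'
#' @param a,b Data frames of SV records ([sv_callset()] record columns),
#'   paired row by row; both must have the same number of rows.
#' @return A numeric vector of dissimilarities (in `[0, 1]` for `sv_d1`,
#'   `>= 0` bp for `sv_d2`).
#' @export
#' @examples
#' a <- tibble::tibble(id = "a", chrom = "chr1", start = 101L, end = 200L,
#'                     svtype = "DEL")
#' b <- tibble::tibble(id = "b", chrom = "chr1", start = 151L, end = 250L,
#'                     svtype = "DEL")
#' sv_d1(a, b) # 0.5
#' sv_d2(a, b) # 50
sv_d1 <- function(a, b) {
  check_comparable(a, b)
  ov <- pmax(0, pmin(a$end, b$end) - pmax(a$start, b$start) + 1)
  len_a <- a$end - a$start + 1
  len_b <- b$end - b$start + 1
  1 - ov / pmax(len_a, len_b)
}

#' @rdname sv_d1
#' @export
sv_d2 <- function(a, b) {
  check_comparable(a, b)
  pmax(abs(a$start - b$start), abs(a$end - b$end))
}

check_comparable <- function(a, b) {
  if (nrow(a) != nrow(b)) abort("a and b must pair row by row")
  if (any(a$chrom != b$chrom)) {
    abort("dissimilarity is undefined across chromosomes")
  }
  if (any(a$svtype != b$svtype)) {
    abort("dissimilarity is undefined across SV types")
  }
  invisible(TRUE)
}

dissim_fun <- function(measure) {
  measure <- match.arg(measure, c("d1", "d2"))
  if (measure == "d1") sv_d1 else sv_d2
}

#' Candidate SV pairs within a dissimilarity threshold
#'
#' Finds all unordered pairs of records of the same chromosome and type with
#' dissimilarity `<= d_max`, using a sorted sweep over start positions so
#' that only nearby pairs are evaluated. For `d2`, a pair can only qualify
#' when its start positions differ by at most `d_max`; for `d1` (with
#' `d_max < 1`) the pair must overlap, so the partner's start must not exceed
#' the running maximum of earlier ends. The sweep therefore misses no
#' qualifying pair.
#'
#' @param records SV record tibble.
#' @param measure `"d1"` or `"d2"`.
#' @param d_max Dissimilarity threshold (in `[0, 1)` for d1; bp for d2).
#' @return A tibble with integer columns `i`, `j` (row indices into
#'   `records`, `i < j`) and numeric `d`.
#' @export
candidate_pairs <- function(records, measure = c("d1", "d2"), d_max) {
  measure <- match.arg(measure)
  if (measure == "d1" && d_max >= 1) {
    abort("d_max must be < 1 for the overlap measure (1 means disjoint)")
  }
  if (d_max < 0) abort("d_max must be non-negative")
  dfun <- dissim_fun(measure)
  out <- list()
  strata <- split(seq_len(nrow(records)),
                  paste(records$chrom, records$svtype, sep = "\r"))
  for (idx in strata) {
    idx <- idx[order(records$start[idx], records$end[idx], records$id[idx])]
    n <- length(idx)
    if (n < 2) next
    starts <- records$start[idx]
    ends <- records$end[idx]
    run_max_end <- cummax(ends)
    ii <- jj <- integer(0)
    for (a in seq_len(n - 1)) {
      for (b in seq(a + 1, n)) {
        near <- if (measure == "d2") {
          starts[b] - starts[a] <= d_max
        } else {
          starts[b] <= run_max_end[a]
        }
        if (!near) break
        ii <- c(ii, idx[a]); jj <- c(jj, idx[b])
      }
    }
    if (length(ii) == 0) next
    d <- dfun(records[ii, , drop = FALSE], records[jj, , drop = FALSE])
    keep <- d <= d_max
    if (any(keep)) {
      out[[length(out) + 1L]] <- tibble(i = pmin(ii[keep], jj[keep]),
                                        j = pmax(ii[keep], jj[keep]),
                                        d = d[keep])
    }
  }
  if (length(out) == 0) {
    return(tibble(i = integer(0), j = integer(0), d = numeric(0)))
  }
  bind_rows(out) %>% arrange(.data$i, .data$j)
}

#' Components of the dissimilarity threshold graph
#'
#' Builds the graph whose vertices are the SV records and whose edges join
#' pairs of the same chromosome and type with dissimilarity `<= d_max`, and
#' returns its connected components: the clusters assumed to represent a
#' single SV observed with different breakpoints.
#'
#' @inheritParams candidate_pairs
#' @param edges Optionally, a precomputed [candidate_pairs()] result.
#' @return An integer vector of component labels, one per record.
#' @export
threshold_components <- function(records, measure = c("d1", "d2"), d_max,
                                 edges = NULL) {
  measure <- match.arg(measure)
  if (is.null(edges)) edges <- candidate_pairs(records, measure, d_max)
  components_from_edges(nrow(records), edges)
}

components_from_edges <- function(n, edges) {
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(g, rbind(edges$i, edges$j))
  }
  as.integer(igraph::components(g)$membership)
}
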