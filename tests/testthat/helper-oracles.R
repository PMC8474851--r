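# Independent brute-force reference implementations used as oracles.
# These deliberately share no code with the package internals: plain loops,
# explicit allele enumeration, and a hand-rolled BFS instead of igraph.

# Mendelian consistency by explicit allele transmission: child genotype c is
# consistent iff one allele can come from each parent.
oracle_mendelian <- function(u) {
  alleles <- function(g) switch(g + 1L, 0L, c(0L, 1L), 1L)
  for (a in alleles(u[2])) {
    for (b in alleles(u[3])) {
      if (a + b == u[1]) return(TRUE)
    }
  }
  FALSE
}

oracle_d <- function(rec, i, j, measure) {
  if (rec$chrom[i] != rec$chrom[j] || rec$svtype[i] != rec$svtype[j]) {
    return(Inf)
  }
  if (measure == "d1") {
    ov <- max(0, min(rec$end[i], rec$end[j]) - max(rec$start[i], rec$start[j]) + 1)
    1 - ov / max(rec$end[i] - rec$start[i] + 1, rec$end[j] - rec$start[j] + 1)
  } else {
    max(abs(rec$start[i] - rec$start[j]), abs(rec$end[i] - rec$end[j]))
  }
}

oracle_dist_matrix <- function(rec, measure) {
  n <- nrow(rec)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        D[i, j] <- D[j, i] <- oracle_d(rec, i, j, measure)
      }
    }
  }
  D
}

# connected components of {D <= thr} by breadth-first search
oracle_components <- function(D, thr, vertices = seq_len(nrow(D))) {
  n <- length(vertices)
  seen <- rep(FALSE, n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s
    seen[s] <- TRUE
    comp <- integer(0)
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      for (w in seq_len(n)) {
        if (!seen[w] && D[vertices[v], vertices[w]] <= thr) {
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(vertices[comp])
  }
  comps
}

oracle_incompatible <- function(geno, rows) {
  if (length(rows) < 2) return(FALSE)
  for (a in seq_len(length(rows) - 1)) {
    for (b in seq(a + 1, length(rows))) {
      if (any(geno[rows[a], ] != 0 & geno[rows[b], ] != 0)) return(TRUE)
    }
  }
  FALSE
}

# reference trivial / corrected clustering: exhaustive threshold scan
oracle_cluster <- function(rec, geno, measure, d_max, strategy) {
  D <- oracle_dist_matrix(rec, measure)
  comps <- oracle_components(D, d_max)
  out <- list()
  for (comp in comps) {
    if (!oracle_incompatible(geno, comp)) {
      out[[length(out) + 1L]] <- comp
    } else if (strategy == "trivial") {
      for (m in comp) out[[length(out) + 1L]] <- m
    } else {
      vals <- D[comp, comp, drop = FALSE]
      vals <- vals[upper.tri(vals)]
      cand <- sort(unique(vals[is.finite(vals) & vals < d_max]),
                   decreasing = TRUE)
      done <- FALSE
      for (thr in c(cand, -1)) {
        subs <- oracle_components(D, thr, vertices = comp)
        if (!any(vapply(subs, function(s) oracle_incompatible(geno, s), TRUE))) {
          for (s in subs) out[[length(out) + 1L]] <- s
          done <- TRUE
          break
        }
      }
      stopifnot(done)
    }
  }
  out
}

# canonical form of a partition for comparison
canon_partition <- function(comps) {
  comps <- lapply(comps, function(x) sort(as.integer(x)))
  keys <- vapply(comps, function(x) paste(x, collapse = ","), "")
  comps[order(keys)]
}

# random clustering instance: clustered coordinates + random genotypes
random_instance <- function(seed, n_svs = 20, n_samples = 6) {
  set.seed(seed)
  svtype <- sample(c("DEL", "DUP"), n_svs, replace = TRUE, prob = c(0.7, 0.3))
  anchor <- cumsum(sample(c(50, 100, 500, 5000), n_svs, replace = TRUE))
  start <- anchor + sample(0:80, n_svs, replace = TRUE)
  len <- sample(60:400, n_svs, replace = TRUE)
  rec <- tibble::tibble(id = sprintf("r%03d", seq_len(n_svs)), chrom = "chr1",
                        start = as.integer(start),
                        end = as.integer(start + len - 1L), svtype = svtype)
  geno <- matrix(sample(0:2, n_svs * n_samples, replace = TRUE,
                        prob = c(0.75, 0.2, 0.05)), n_svs, n_samples)
  colnames(geno) <- paste0("s", seq_len(n_samples))
  svclust::sv_callset(rec, geno)
}
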