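#' Build a pedigree table for a simulated cohort
#'
#' Constructs one or more three-generation families plus unrelated
#' individuals. Each family has a grandparental founder couple, `n_gen2`
#' of their children (the eldest marries a founder spouse), and `n_gen3`
#' grandchildren from that marriage, giving parent-child (r = 0.5), sibling
#' (r = 0.5), grandparent-grandchild (r = 0.25) and avuncular (r = 0.25)
#' pairs, and r = 0 pairs through the married-in spouse.
#'
#' @param n_families Number of three-generation families.
#' @param n_gen2 Children of the grandparental couple per family (>= 1).
#' @param n_gen3 Grandchildren per family (>= 0).
#' @param n_unrelated Unrelated singleton individuals.
#' @return An [sv_pedigree()].
#' @export
simulate_pedigree <- function(n_families = 1, n_gen2 = 2, n_gen3 = 2,
                              n_unrelated = 20) {
  if (n_gen2 < 1) abort("each family needs at least one second-generation child")
  rows <- list()
  for (f in seq_len(n_families)) {
    fam <- paste0("FAM", f)
    gf <- paste0(fam, "_GF"); gm <- paste0(fam, "_GM")
    rows[[length(rows) + 1L]] <- tibble(
      family = fam, sample = c(gf, gm),
      father = NA_character_, mother = NA_character_)
    gen2 <- paste0(fam, "_P", seq_len(n_gen2))
    rows[[length(rows) + 1L]] <- tibble(
      family = fam, sample = gen2, father = gf, mother = gm)
    if (n_gen3 > 0) {
      sp <- paste0(fam, "_SP")
      rows[[length(rows) + 1L]] <- tibble(
        family = fam, sample = sp,
        father = NA_character_, mother = NA_character_)
      gen3 <- paste0(fam, "_C", seq_len(n_gen3))
      rows[[length(rows) + 1L]] <- tibble(
        family = fam, sample = gen3, father = gen2[1], mother = sp)
    }
  }
  if (n_unrelated > 0) {
    un <- paste0("U", seq_len(n_unrelated))
    rows[[length(rows) + 1L]] <- tibble(
      family = un, sample = un, father = NA_character_, mother = NA_character_)
  }
  sv_pedigree(bind_rows(rows))
}

signed_geom <- function(n, mean_abs) {
  # symmetric geometric-like bp offsets; mean absolute size ~ mean_abs
  s <- sample(c(-1L, 1L), n, replace = TRUE)
  s * rgeom(n, prob = 1 / (1 + mean_abs))
}

#' Simulate a pedigreed multi-sample SV call set with known ground truth
#'
#' Generates true SV loci (positions uniform on a synthetic chromosome,
#' lengths log-uniform, alternative-allele frequencies uniform), drops
#' founder genotypes under Hardy-Weinberg proportions and transmits alleles
#' down the pedigree by gene dropping (so the true matrix contains no
#' Mendelian errors), then emits a call set with two controlled error
#' processes that emulate breakpoint uncertainty:
#'
#' * with probability `p_decompose` a true SV with >= 2 carriers is
#'   *decomposed*: its carriers are split into 2 or 3 non-empty subsets
#'   (2 parts with odds 2:1) and one record is emitted per subset at
#'   breakpoints shifted by geometric offsets -- the decomposed-SV error
#'   pattern whose subsets partition the carriers;
#' * otherwise one record is emitted, its breakpoints jittered with
#'   probability `p_jitter`.
#'
#' @param n_svs Number of true SV loci.
#' @param pedigree An [sv_pedigree()] (e.g. from [simulate_pedigree()]).
#' @param sv_type_weights Named sampling weights over SV types.
#' @param length_range Log-uniform SV length range in bp (all > 50).
#' @param af_range Uniform range for the alternative-allele frequency.
#' @param p_decompose Per-SV probability of decomposition.
#' @param p_jitter Per-record probability of breakpoint jitter for
#'   non-decomposed records.
#' @param jitter_mean Mean absolute breakpoint offset in bp.
#' @param p_nearby Probability that a true SV is co-located with an earlier
#'   SV of the same type (breakpoints within `nearby_range` bp of the
#'   anchor's), emulating the clustered distinct variants found in SV
#'   hotspots; these are what make naive merging ambiguous.
#' @param nearby_range Maximum breakpoint offset (bp, uniform) of a
#'   co-located SV from its anchor.
#' @param chrom_length Length of the synthetic chromosome.
#' @param seed Integer seed; the simulation is reproducible given the seed.
#' @return A list with `callset` (the emitted [sv_callset()]), `pedigree`,
#'   and `truth`: a list with `map` (tibble record_id -> true_id),
#'   `true_callset` (one record per true SV) and the simulation parameters.
#' @export
simulate_sv_cohort <- function(n_svs = 500,
                               pedigree = simulate_pedigree(),
                               sv_type_weights = c(DEL = 0.5, DUP = 0.2,
                                                   INV = 0.15, INS = 0.15),
                               length_range = c(51, 1e5),
                               af_range = c(0.05, 0.5),
                               p_decompose = 0.2,
                               p_jitter = 0.1,
                               jitter_mean = 30,
                               p_nearby = 0.15,
                               nearby_range = 300,
                               chrom_length = 2.5e8,
                               seed = 1L) {
  stopifnot(inherits(pedigree, "sv_pedigree"))
  if (n_svs < 1) abort("n_svs must be >= 1")
  if (length_range[1] <= 50) abort("SV lengths must exceed 50 bp")
  set.seed(seed)
  samples <- pedigree$samples$sample
  m <- length(samples)

  lens <- as.integer(round(exp(runif(n_svs, log(length_range[1]),
                                     log(length_range[2])))))
  starts <- as.integer(floor(runif(n_svs, 1, chrom_length - max(lens))))
  types <- sample(names(sv_type_weights), n_svs, replace = TRUE,
                  prob = sv_type_weights)
  af <- runif(n_svs, af_range[1], af_range[2])
  ends <- starts + lens - 1L
  # SV-hotspot emulation: some SVs sit on top of an earlier SV of the same
  # type, so that distinct variants fall inside one another's merge window
  for (v in seq_len(n_svs)) {
    anchors <- which(types[seq_len(v - 1)] == types[v])
    if (length(anchors) == 0 || runif(1) >= p_nearby) next
    u <- anchors[sample(length(anchors), 1)]
    st <- max(1L, starts[u] + as.integer(round(runif(1, -nearby_range,
                                                     nearby_range))))
    en <- ends[u] + as.integer(round(runif(1, -nearby_range, nearby_range)))
    if (en - st + 1L <= 50L) en <- st + lens[u] - 1L
    starts[v] <- st; ends[v] <- en; lens[v] <- en - st + 1L
  }
  true_rec <- tibble(id = sprintf("sv%04d", seq_len(n_svs)),
                     chrom = "chr1", start = starts,
                     end = ends, svtype = types,
                     length = lens)

  # gene dropping: founders under HWE, children inherit one allele per parent
  ord <- pedigree_toposort(pedigree$samples)
  father <- setNames(pedigree$samples$father, pedigree$samples$sample)
  mother <- setNames(pedigree$samples$mother, pedigree$samples$sample)
  true_geno <- matrix(0L, n_svs, m, dimnames = list(true_rec$id, samples))
  for (s in ord) {
    fa <- father[[s]]; mo <- mother[[s]]
    if (is.na(fa) || is.na(mo)) {
      true_geno[, s] <- rbinom(n_svs, 2L, af)
    } else {
      true_geno[, s] <- rbinom(n_svs, 1L, true_geno[, fa] / 2) +
        rbinom(n_svs, 1L, true_geno[, mo] / 2)
    }
  }

  emit_rec <- list()
  emit_gt <- list()
  map_rows <- list()
  for (v in seq_len(n_svs)) {
    carriers <- which(true_geno[v, ] != 0L)
    decompose <- length(carriers) >= 2 && runif(1) < p_decompose
    if (decompose) {
      k <- if (length(carriers) >= 3 && runif(1) < 1 / 3) 3L else 2L
      part <- integer(length(carriers))
      part[sample(length(carriers), k)] <- seq_len(k) # one seed per subset
      rest <- part == 0L
      part[rest] <- sample(k, sum(rest), replace = TRUE)
      for (p in seq_len(k)) {
        row <- rep(0L, m)
        idx <- carriers[part == p]
        row[idx] <- true_geno[v, idx]
        off_s <- signed_geom(1, jitter_mean)
        off_e <- signed_geom(1, jitter_mean)
        st <- max(1L, true_rec$start[v] + off_s)
        en <- true_rec$end[v] + off_e
        if (en - st + 1L <= 50L) en <- st + true_rec$length[v] - 1L
        rid <- paste0(true_rec$id[v], "_p", p)
        emit_rec[[length(emit_rec) + 1L]] <- tibble(
          id = rid, chrom = "chr1", start = st, end = en,
          svtype = true_rec$svtype[v], length = en - st + 1L)
        emit_gt[[length(emit_gt) + 1L]] <- row
        map_rows[[length(map_rows) + 1L]] <- tibble(
          record_id = rid, true_id = true_rec$id[v], decomposed = TRUE)
      }
    } else {
      st <- true_rec$start[v]; en <- true_rec$end[v]
      if (runif(1) < p_jitter) {
        st <- max(1L, st + signed_geom(1, jitter_mean))
        en <- en + signed_geom(1, jitter_mean)
        if (en - st + 1L <= 50L) en <- st + true_rec$length[v] - 1L
      }
      emit_rec[[length(emit_rec) + 1L]] <- tibble(
        id = true_rec$id[v], chrom = "chr1", start = st, end = en,
        svtype = true_rec$svtype[v], length = en - st + 1L)
      emit_gt[[length(emit_gt) + 1L]] <- true_geno[v, ]
      map_rows[[length(map_rows) + 1L]] <- tibble(
        record_id = true_rec$id[v], true_id = true_rec$id[v],
        decomposed = FALSE)
    }
  }
  rec <- bind_rows(emit_rec)
  gt <- do.call(rbind, emit_gt)
  colnames(gt) <- samples
  ord_rec <- order(rec$chrom, rec$start, rec$id)
  callset <- sv_callset(rec[ord_rec, ], gt[ord_rec, , drop = FALSE])
  truth <- list(map = bind_rows(map_rows),
                true_callset = sv_callset(true_rec, true_geno),
                params = list(n_svs = n_svs, p_decompose = p_decompose,
                              p_jitter = p_jitter, jitter_mean = jitter_mean,
                              seed = seed))
  list(callset = callset, pedigree = pedigree, truth = truth)
}

#' Score how well a clustering reassembles decomposed SVs
#'
#' @param clustering An `sv_clustering` computed on a simulated callset.
#' @param truth The `truth` element of [simulate_sv_cohort()].
#' @return A tibble with `recall` (fraction of decomposed true SVs whose
#'   emitted records all ended up in a single merged component) and
#'   `precision` (fraction of merged components whose members all derive
#'   from one true SV; `NA` when nothing was merged).
#' @export
score_recovery <- function(clustering, truth) {
  stopifnot(inherits(clustering, "sv_clustering"))
  map_tb <- truth$map
  rec_ids <- clustering$input$records$id
  comp_of <- integer(length(rec_ids))
  for (k in seq_along(clustering$components)) {
    comp_of[clustering$components[[k]]] <- k
  }
  names(comp_of) <- rec_ids
  dec <- map_tb[map_tb$decomposed, , drop = FALSE]
  true_ids <- unique(dec$true_id)
  recall <- if (length(true_ids) == 0) NA_real_ else {
    mean(vapply(true_ids, function(tid) {
      members <- dec$record_id[dec$true_id == tid]
      length(unique(comp_of[members])) == 1
    }, TRUE))
  }
  merged_comps <- clustering$components[clustering$merged]
  precision <- if (length(merged_comps) == 0) NA_real_ else {
    true_of <- setNames(map_tb$true_id, map_tb$record_id)
    mean(vapply(merged_comps, function(mbrs) {
      length(unique(true_of[rec_ids[mbrs]])) == 1
    }, TRUE))
  }
  tibble(recall = recall, precision = precision,
         n_decomposed = length(true_ids),
         n_merged_components = length(merged_comps))
}
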