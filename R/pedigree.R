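#' Construct a pedigree object from a PED-style table
#'
#' @param ped A data frame with columns `family`, `sample`, `father`,
#'   `mother`, and optionally `sex` and `phenotype`. Founders (and married-in
#'   individuals) have `father`/`mother` equal to `"0"` or `NA`.
#'
#' @details A trio is any row where both parents are known. Relationship
#'   coefficients are computed by the standard recursive coancestry algorithm
#'   (r = 2 * kinship coefficient for outbred pairs) for every pair of samples
#'   within a family and reported for the coefficient classes
#'   `{0, 0.0625, 0.125, 0.25, 0.5}`; pairs at other coefficients are dropped
#'   with a warning. Individuals in single-member families are the cohort's
#'   unrelated set.
#'
#' @return An object of class `sv_pedigree`: a list with tibbles `samples`
#'   (sample, family, father, mother), `trios` (family, child, father,
#'   mother), and `kinship_pairs` (family, sample1, sample2, r).
#' @export
sv_pedigree <- function(ped) {
  ped <- as_tibble(ped)
  needed <- c("family", "sample", "father", "mother")
  if (!all(needed %in% names(ped))) {
    abort(paste0("pedigree table needs columns: ",
                 paste(needed, collapse = ", ")))
  }
  for (col in needed) ped[[col]] <- as.character(ped[[col]])
  ped$father[ped$father %in% c("0", "")] <- NA_character_
  ped$mother[ped$mother %in% c("0", "")] <- NA_character_
  if (anyDuplicated(ped$sample)) abort("duplicated sample identifiers")

  for (role in c("father", "mother")) {
    bad <- !is.na(ped[[role]]) & !(ped[[role]] %in% ped$sample)
    if (any(bad)) {
      abort(paste0(role, " '", ped[[role]][bad][1], "' of individual '",
                   ped$sample[bad][1], "' is absent from the pedigree"))
    }
  }
  ord <- pedigree_toposort(ped)

  trios <- ped %>%
    filter(!is.na(.data$father) & !is.na(.data$mother)) %>%
    select(family = "family", child = "sample",
           father = "father", mother = "mother")

  kinship_pairs <- pedigree_kinship_pairs(ped, ord)

  structure(list(samples = ped[, intersect(c(needed, "sex", "phenotype"),
                                           names(ped))],
                 trios = trios,
                 kinship_pairs = kinship_pairs),
            class = "sv_pedigree")
}

# founders-first order; errors on cycles
pedigree_toposort <- function(ped) {
  remaining <- ped$sample
  parents <- setNames(map2(ped$father, ped$mother, c), ped$sample)
  placed <- character(0)
  while (length(remaining) > 0) {
    ready <- vapply(remaining, function(s) {
      p <- parents[[s]]
      all(is.na(p) | p %in% placed)
    }, TRUE)
    if (!any(ready)) abort("cyclic pedigree: no founder-first ordering exists")
    placed <- c(placed, remaining[ready])
    remaining <- remaining[!ready]
  }
  placed
}

pedigree_kinship_pairs <- function(ped, ord) {
  allowed_r <- c(0, 0.0625, 0.125, 0.25, 0.5)
  fam_sizes <- table(ped$family)
  fams <- names(fam_sizes)[fam_sizes >= 2]
  out <- list()
  for (fam in fams) {
    ids <- ord[ord %in% ped$sample[ped$family == fam]]
    n <- length(ids)
    phi <- matrix(0, n, n, dimnames = list(ids, ids))
    father <- setNames(ped$father, ped$sample)
    mother <- setNames(ped$mother, ped$sample)
    par_phi <- function(p, j) {
      if (is.na(p) || !(p %in% ids)) 0 else phi[p, j]
    }
    for (a in seq_len(n)) {
      i <- ids[a]
      fi <- father[[i]]; mi <- mother[[i]]
      phi[i, i] <- 0.5 * (1 + if (!is.na(fi) && !is.na(mi) &&
                                  fi %in% ids && mi %in% ids)
                            phi[fi, mi] else 0)
      for (b in seq_len(a - 1)) {
        j <- ids[b]
        v <- 0.5 * (par_phi(fi, j) + par_phi(mi, j))
        phi[i, j] <- v
        phi[j, i] <- v
      }
    }
    pairs <- which(upper.tri(phi), arr.ind = TRUE)
    r <- 2 * phi[pairs]
    tb <- tibble(family = fam,
                 sample1 = ids[pairs[, 1]],
                 sample2 = ids[pairs[, 2]],
                 r = r)
    out[[fam]] <- tb
  }
  if (length(out) == 0) {
    return(tibble(family = character(0), sample1 = character(0),
                  sample2 = character(0), r = numeric(0)))
  }
  res <- bind_rows(out)
  snap <- vapply(res$r, function(x) {
    d <- abs(allowed_r - x)
    if (min(d) < 1e-9) allowed_r[which.min(d)] else NA_real_
  }, 0)
  if (anyNA(snap)) {
    warn(paste0(sum(is.na(snap)),
                " sample pairs at relationship coefficients outside ",
                "{0, 0.0625, 0.125, 0.25, 0.5} were dropped"))
  }
  res$r <- snap
  res[!is.na(res$r), , drop = FALSE]
}

#' Read a 6-column PED file
#'
#' @param path Path to a whitespace-delimited PED file with columns
#'   FamilyID, IndividualID, PaternalID, MaternalID, Sex, Phenotype.
#'   Parent identifiers of `0` mean unknown.
#' @return An [sv_pedigree()].
#' @export
read_pedigree <- function(path) {
  df <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("family", "sample", "father", "mother",
                                 "sex", "phenotype"),
                   colClasses = c(rep("character", 4), "integer", "integer"))
  sv_pedigree(df)
}

#' Write a pedigree as a 6-column PED file
#' @param pedigree An `sv_pedigree`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(pedigree, path) {
  stopifnot(inherits(pedigree, "sv_pedigree"))
  s <- pedigree$samples
  df <- data.frame(family = s$family, sample = s$sample,
                   father = ifelse(is.na(s$father), "0", s$father),
                   mother = ifelse(is.na(s$mother), "0", s$mother),
                   sex = if ("sex" %in% names(s)) s$sex else 0L,
                   phenotype = if ("phenotype" %in% names(s)) s$phenotype
                               else -9L)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.sv_pedigree <- function(x, ...) {
  cat("<sv_pedigree> ", nrow(x$samples), " samples, ",
      nrow(x$trios), " trios, ",
      length(unique(x$samples$family)), " families\n", sep = "")
  invisible(x)
}

#' @method tidy sv_pedigree
#' @export
tidy.sv_pedigree <- function(x, ...) x$samples

#' Samples outside any multi-member family
#'
#' @param pedigree An `sv_pedigree`.
#' @return Character vector of samples whose family has a single member --
#'   the cohort's unrelated individuals.
#' @export
unrelated_samples <- function(pedigree) {
  stopifnot(inherits(pedigree, "sv_pedigree"))
  fam_sizes <- table(pedigree$samples$family)
  singletons <- names(fam_sizes)[fam_sizes == 1]
  pedigree$samples$sample[pedigree$samples$family %in% singletons]
}
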