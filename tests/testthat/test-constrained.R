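# callsets here use samples child/father/mother (+ extras); trio_pedigree()
# provides the matching single-trio pedigree

test_that("the decomposed worked example is found as one group", {
  cs <- trio_callset(list(c(2L, 1L, 0L), c(0L, 0L, 1L)))
  ped <- trio_pedigree()
  g <- find_sv_groups(cs, ped, "d2", 150)
  expect_equal(nrow(g), 1)
  expect_equal(g$members[[1]], c(1L, 2L))
  expect_equal(g$n_trios, 1L)
})

test_that("a shared non-trio carrier vetoes the group (all-sample condition)", {
  cs <- trio_callset(list(c(2L, 1L, 0L), c(0L, 0L, 1L)),
                     extra_samples = 1,
                     extra_values = list(1L, 1L)) # x1 carries both records
  ped <- trio_pedigree(extra_samples = 1)
  g <- find_sv_groups(cs, ped, "d2", 150)
  expect_equal(nrow(g), 0)
})

test_that("distance above the threshold vetoes the group", {
  cs <- trio_callset(list(c(2L, 1L, 0L), c(0L, 0L, 1L)))
  cs$records$start[2] <- cs$records$start[1] + 500L
  cs$records$end[2] <- cs$records$end[1] + 500L
  ped <- trio_pedigree()
  g <- find_sv_groups(cs, ped, "d2", 150)
  expect_equal(nrow(g), 0)
})

test_that("triplet groups are found", {
  cs <- trio_callset(list(c(2L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L)))
  ped <- trio_pedigree()
  g <- find_sv_groups(cs, ped, "d2", 150)
  expect_true(any(vapply(g$members, length, 0L) == 3))
})

test_that("groups with no shared SV are both retained in reduction", {
  # two decomposed loci far apart: no cross-locus group can form
  geno <- rbind(c(2L, 1L, 0L), c(0L, 0L, 1L),
                c(1L, 0L, 0L), c(0L, 1L, 0L))
  colnames(geno) <- c("child", "father", "mother")
  rec <- del_records(c(1000, 1010, 90000, 90010),
                     c(1200, 1210, 90200, 90210))
  cs <- sv_callset(rec, geno)
  ped <- trio_pedigree()
  g <- find_sv_groups(cs, ped, "d2", 150)
  expect_equal(nrow(g), 2)
  red <- reduce_sv_groups(g, cs, ped, seed = 1)
  expect_length(red$reduced_components, 2)
  expect_equal(sort(unlist(red$reduced_components)), 1:4)
})

test_that("overlapping groups resolve to the one seen in more trios", {
  # two trios; rows 1+2 form a group in both, rows 2+3 only in the first
  ped_df <- tibble::tibble(
    family = "F1",
    sample = c("c1", "f1", "m1", "c2", "f2", "m2"),
    father = c("f1", NA, NA, "f2", NA, NA),
    mother = c("m1", NA, NA, "m2", NA, NA))
  ped <- sv_pedigree(ped_df)
  geno <- rbind(c(2L, 1L, 0L, 2L, 1L, 0L),  # MIE in both trios
                c(0L, 0L, 1L, 0L, 0L, 1L),  # completes it in both trios
                c(1L, 1L, 0L, 0L, 0L, 0L))  # pairs with row 2 in trio 1 only
  colnames(geno) <- ped_df$sample
  rec <- del_records(c(100, 120, 140), c(300, 320, 340))
  cs <- sv_callset(rec, geno)
  g <- find_sv_groups(cs, ped, "d2", 150)
  pair12 <- which(vapply(g$members, function(m) identical(m, c(1L, 2L)), TRUE))
  pair23 <- which(vapply(g$members, function(m) identical(m, c(2L, 3L)), TRUE))
  expect_length(pair12, 1)
  expect_length(pair23, 1)
  expect_equal(g$n_trios[pair12], 2L)
  expect_equal(g$n_trios[pair23], 1L)
  red <- reduce_sv_groups(g, cs, ped, seed = 3)
  expect_true(any(vapply(red$accepted$members, function(m)
    identical(m, c(1L, 2L)), TRUE)))
  expect_false(any(vapply(red$accepted$members, function(m)
    identical(m, c(2L, 3L)), TRUE)))
})

test_that("equal-trio-count ties retain exactly one group, fixed by seed", {
  # rows 1+2 and 2+3 are both groups in the single trio
  cs <- trio_callset(list(c(2L, 1L, 0L), c(0L, 0L, 1L), c(2L, 1L, 0L)))
  ped <- trio_pedigree()
  g <- find_sv_groups(cs, ped, "d2", 150)
  shared <- g[vapply(g$members, function(m) 2L %in% m, TRUE), ]
  expect_gte(nrow(shared), 2)
  red1 <- reduce_sv_groups(g, cs, ped, seed = 7)
  red2 <- reduce_sv_groups(g, cs, ped, seed = 7)
  expect_identical(red1$accepted$members, red2$accepted$members)
  # the two overlapping pair groups are mutually exclusive: one survives
  n_with_2 <- sum(vapply(red1$accepted$members, function(m) 2L %in% m, TRUE))
  expect_equal(n_with_2, 1L)
})

test_that("a pre-linked group attracts a compatible third record", {
  cs <- trio_callset(list(c(2L, 1L, 0L), c(0L, 0L, 1L), c(0L, 0L, 0L)),
                     extra_samples = 1,
                     extra_values = list(0L, 0L, 1L))
  ped <- trio_pedigree(extra_samples = 1)
  cl <- cluster_constrained(cs, ped, "d2", 150, seed = 1)
  expect_equal(length(cl$components), 1)
  expect_equal(cl$components[[1]], 1:3)
})

test_that("cannot-link dominates distance in agglomeration", {
  # rows 1,2 nearest but incompatible; row 3 farther and compatible with 1
  geno <- rbind(c(1L, 0L, 0L), c(1L, 0L, 0L), c(0L, 1L, 0L))
  colnames(geno) <- c("child", "father", "mother")
  rec <- del_records(c(100, 105, 160), c(300, 305, 360))
  cs <- sv_callset(rec, geno)
  ped <- trio_pedigree()
  cl <- cluster_constrained(cs, ped, "d2", 100, seed = 1)
  comps <- canon_partition(cl$components)
  # row 2 joins neither 1 nor 3 directly with 1: 1+3 or 2+3 merge, never 1+2
  expect_false(any(vapply(cl$components, function(m)
    all(c(1L, 2L) %in% m), TRUE)))
})

test_that("constrained output never contains a cannot-link pair", {
  ped <- trio_pedigree(extra_samples = 3)
  for (seed in 81:95) {
    cs0 <- random_instance(seed, n_svs = 25, n_samples = 6)
    geno <- cs0$genotypes
    colnames(geno) <- c("child", "father", "mother", paste0("x", 1:3))
    cs <- sv_callset(cs0$records, geno)
    cl <- cluster_constrained(cs, ped, "d2", 120, seed = seed)
    for (comp in cl$components) {
      expect_false(oracle_incompatible(cs$genotypes, comp))
    }
    # partition property
    expect_equal(sort(unlist(cl$components)), seq_len(nrow(cs$records)))
  }
})

test_that("constrained clustering is reproducible under a fixed seed", {
  ped <- trio_pedigree(extra_samples = 3)
  cs0 <- random_instance(99, n_svs = 30, n_samples = 6)
  geno <- cs0$genotypes
  colnames(geno) <- c("child", "father", "mother", paste0("x", 1:3))
  cs <- sv_callset(cs0$records, geno)
  a <- cluster_constrained(cs, ped, "d2", 120, seed = 5)
  b <- cluster_constrained(cs, ped, "d2", 120, seed = 5)
  expect_identical(a$components, b$components)
  expect_identical(a$callset$records, b$callset$records)
})

test_that("without groups or incompatibilities all strategies coincide", {
  geno <- rbind(c(0L, 0L, 0L, 1L), c(0L, 0L, 0L, 0L))
  geno[2, ] <- c(0L, 0L, 0L, 0L)
  colnames(geno) <- c("child", "father", "mother", "x1")
  cs <- sv_callset(del_records(c(100, 150), c(300, 350)), geno)
  ped <- trio_pedigree(extra_samples = 1)
  t_ <- cluster_svs(cs, "trivial", "d2", 100)
  c_ <- cluster_svs(cs, "corrected", "d2", 100)
  x_ <- cluster_svs(cs, "constrained", "d2", 100, pedigree = ped)
  expect_equal(canon_partition(t_$components), canon_partition(x_$components))
  expect_equal(canon_partition(c_$components), canon_partition(x_$components))
})
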