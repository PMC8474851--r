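test_that("f_MEI counts errors among informative trio configurations", {
  cs <- trio_callset(list(c(2L, 1L, 0L), c(0L, 0L, 1L)))
  expect_equal(trio_f_mei(cs, c("child", "father", "mother")), 1 / 2)

  all_ref <- trio_callset(list(c(0L, 0L, 0L), c(0L, 0L, 0L)))
  expect_warning(v <- trio_f_mei(all_ref, c("child", "father", "mother")),
                 "informative")
  expect_equal(v, 0)

  cs3 <- trio_callset(list(c(1L, 1L, 0L), c(2L, 2L, 2L), c(2L, 0L, 0L)))
  expect_equal(trio_f_mei(cs3, c("child", "father", "mother")), 1 / 3)

  expect_error(trio_f_mei(cs3, c("child", "father", "nobody")), "nobody")
})

test_that("f_MEI is invariant under row permutation", {
  set.seed(31)
  rows <- lapply(1:12, function(i) sample(0:2, 3, TRUE,
                                          prob = c(0.5, 0.3, 0.2)))
  cs <- trio_callset(rows)
  base <- trio_f_mei(cs, c("child", "father", "mother"))
  perm <- sample(12)
  cs_p <- sv_callset(cs$records, cs$genotypes[perm, , drop = FALSE])
  expect_equal(trio_f_mei(cs_p, c("child", "father", "mother")), base)
})

test_that("merged-cluster Mendelian bookkeeping distinguishes n_ic and n_cc", {
  ped <- trio_pedigree()
  # cluster 1: MIE member merging to consistent; cluster 2: consistent pair
  geno <- rbind(c(2L, 1L, 0L), c(0L, 0L, 1L),   # locus A, decomposed MIE
                c(0L, 1L, 0L), c(0L, 0L, 1L))   # locus B, both consistent
  colnames(geno) <- c("child", "father", "mother")
  rec <- del_records(c(1000, 1010, 90000, 90010),
                     c(1200, 1210, 90200, 90210))
  cl <- cluster_svs(sv_callset(rec, geno), "trivial", "d2", 100)
  mc <- mendelian_merge_counts(cl, ped)
  expect_equal(mc$n_ic, 1L)
  expect_equal(mc$n_cc, 0L)
})

test_that("an unmerged MIE contributes nothing to n_ic", {
  ped <- trio_pedigree()
  geno <- rbind(c(2L, 1L, 0L))
  colnames(geno) <- c("child", "father", "mother")
  cl <- cluster_svs(sv_callset(del_records(100, 300), geno),
                    "trivial", "d2", 100)
  mc <- mendelian_merge_counts(cl, ped)
  expect_equal(mc$n_ic, 0L)
})

test_that("n_ic never exceeds the number of merged components", {
  ped <- trio_pedigree(extra_samples = 3)
  for (seed in 101:105) {
    cs0 <- random_instance(seed, n_svs = 25, n_samples = 6)
    geno <- cs0$genotypes
    colnames(geno) <- c("child", "father", "mother", paste0("x", 1:3))
    cs <- sv_callset(cs0$records, geno)
    cl <- cluster_svs(cs, "corrected", "d2", 150)
    mc <- mendelian_merge_counts(cl, ped)
    expect_lte(mc$n_ic, sum(cl$merged))
  }
})

test_that("family_average is the plain mean and rejects empty input", {
  expect_equal(family_average(c(0.1, 0.3)), 0.2)
  expect_equal(family_average(5), 5)
  expect_error(family_average(numeric(0)), "no trios")
})

test_that("allele sharing matches hand-counted cases", {
  mk <- function(g, h, extra = NULL) {
    rows <- length(g)
    geno <- cbind(a = g, b = h)
    if (!is.null(extra)) geno <- cbind(geno, c = extra)
    storage.mode(geno) <- "integer"
    rec <- del_records(seq(1000, by = 10000, length.out = rows),
                       seq(1200, by = 10000, length.out = rows))
    sv_callset(rec, geno)
  }
  # identical non-monomorphic vectors share everything
  cs <- mk(c(0L, 1L, 2L), c(0L, 1L, 2L), extra = c(1L, 0L, 0L))
  expect_equal(sxy_kinship(cs, "a", "b"), 1)
  # opposite homozygotes share nothing
  cs2 <- mk(c(0L, 0L), c(2L, 2L))
  expect_equal(sxy_kinship(cs2, "a", "b"), 0)
  # het vs alt hom shares one allele slot of two
  cs3 <- mk(1L, 2L)
  expect_equal(sxy_kinship(cs3, "a", "b"), 0.5)
  expect_error(sxy_kinship(cs3, "a", "zz"), "zz")
})

test_that("cohort-monomorphic loci are excluded from allele sharing", {
  geno <- cbind(a = c(0L, 1L), b = c(0L, 1L), c = c(0L, 0L))
  rec <- del_records(c(1000, 90000), c(1200, 90200))
  cs <- sv_callset(rec, geno)
  # locus 1 is monomorphic (all 0): only locus 2 counts
  expect_equal(sxy_kinship(cs, "a", "b"), 1)
  expect_equal(sxy_kinship(cs, "a", "c"), 0.5)
})

test_that("kinship separation scores ordered and degenerate estimates", {
  perfect <- tibble::tibble(
    r = rep(c(0, 0.25, 0.5), each = 3),
    estimate = c(0.1, 0.12, 0.14, 0.3, 0.32, 0.34, 0.5, 0.52, 0.54))
  ks <- kinship_separation(perfect)
  expect_equal(ks$by_category$s, c(0, 0, 0))
  expect_equal(ks$s_mean, 0)

  tied <- perfect
  tied$estimate <- 0.4
  ks2 <- kinship_separation(tied)
  expect_equal(ks2$by_category$s, c(1, 1, 1))
  expect_equal(ks2$s_mean, 1)

  # one r=0.25 pair dips below the r=0 maximum: its delta is 0
  mixed <- perfect
  mixed$estimate[4] <- 0.05
  ks3 <- kinship_separation(mixed)
  expect_equal(ks3$by_category$L[ks3$by_category$r == 0.25], 2L)
})

test_that("small kinship categories are skipped with a warning", {
  est <- tibble::tibble(r = c(0, 0, 0.5), estimate = c(0.1, 0.2, 0.6))
  expect_warning(ks <- kinship_separation(est), "< 2 pairs")
  expect_equal(ks$s_mean, 0) # only the r=0 category remains
})

test_that("HWE chi-square matches closed forms", {
  mk_counts <- function(n0, n1, n2) {
    g <- c(rep(0L, n0), rep(1L, n1), rep(2L, n2))
    geno <- matrix(g, 1, dimnames = list(NULL, paste0("s", seq_along(g))))
    sv_callset(del_records(1000, 1200), geno)
  }
  ht <- hwe_test(mk_counts(25, 50, 25), paste0("s", 1:100))
  expect_equal(ht$chi2, 0)
  expect_equal(ht$p, 1)

  ht2 <- hwe_test(mk_counts(50, 0, 50), paste0("s", 1:100))
  expect_equal(ht2$chi2, 100) # n, the closed form with zero heterozygotes
  expect_lt(ht2$p_bonf, 1e-20)

  mono <- mk_counts(100, 0, 0)
  ht3 <- hwe_test(mono, paste0("s", 1:100))
  expect_false(ht3$tested)
  expect_true(is.na(hwe_fraction(mono, paste0("s", 1:100))))
  expect_error(hwe_test(mono, character(0)), "empty")
})

test_that("HWE fraction is calibrated under the null", {
  set.seed(77)
  m <- 200; n <- 100
  af <- runif(m, 0.1, 0.5)
  geno <- sapply(seq_len(n), function(s) rbinom(m, 2, af))
  colnames(geno) <- paste0("s", seq_len(n))
  rec <- del_records(seq(1e4, by = 1e5, length.out = m),
                     seq(1e4, by = 1e5, length.out = m) + 500)
  cs <- sv_callset(rec, geno)
  raw <- hwe_test(cs, paste0("s", 1:n))
  # before correction roughly alpha of the tests reject
  expect_lt(mean(raw$p[raw$tested] < 0.05), 0.15)
  expect_gte(hwe_fraction(cs, paste0("s", 1:n)), 0.99)
})
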