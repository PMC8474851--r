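two_sv_callset <- function(rows, starts = c(100, 150)) {
  geno <- do.call(rbind, rows)
  colnames(geno) <- paste0("s", seq_len(ncol(geno)))
  sv_callset(del_records(starts, starts + 200), geno)
}

test_that("a compatible near pair merges; an incompatible one does not", {
  ok <- two_sv_callset(list(c(1L, 0L), c(0L, 2L)))
  cl <- cluster_svs(ok, "trivial", "d2", 100)
  expect_equal(length(cl$components), 1)
  expect_true(cl$merged[1])
  expect_equal(unname(cl$callset$genotypes[1, ]), c(1L, 2L))

  bad <- two_sv_callset(list(c(1L, 0L), c(1L, 0L)))
  cl2 <- cluster_svs(bad, "trivial", "d2", 100)
  expect_equal(length(cl2$components), 2)
  expect_false(any(cl2$merged))
})

test_that("one incompatible pair unmerges a whole trivial component", {
  # three SVs pairwise within d_max; rows 1 and 3 share carrier s1
  geno <- rbind(c(1L, 0L, 0L), c(0L, 1L, 0L), c(1L, 0L, 0L))
  colnames(geno) <- paste0("s", 1:3)
  cs <- sv_callset(del_records(c(100, 130, 160), c(300, 330, 360)), geno)
  cl <- cluster_svs(cs, "trivial", "d2", 100)
  expect_equal(length(cl$components), 3)
  expect_false(any(cl$merged))
})

test_that("corrected strategy splits at the maximal incompatibility-free threshold", {
  # d(A,B)=10, d(B,C)=40, d(A,C)=50; A and C share a carrier
  geno <- rbind(c(1L, 0L), c(0L, 1L), c(1L, 0L))
  colnames(geno) <- c("s1", "s2")
  cs <- sv_callset(del_records(c(100, 110, 150), c(300, 310, 350)), geno)
  cl <- cluster_svs(cs, "corrected", "d2", 50)
  comps <- canon_partition(cl$components)
  expect_equal(comps, canon_partition(list(c(1, 2), 3)))
  expect_equal(sort(lengths(cl$components)), c(1, 2))
})

test_that("two incompatible SVs split into singletons under correction", {
  bad <- two_sv_callset(list(c(1L, 0L), c(2L, 0L)))
  cl <- cluster_svs(bad, "corrected", "d2", 100)
  expect_equal(length(cl$components), 2)
})

test_that("trivial and corrected agree when no incompatibility exists", {
  for (seed in 41:45) {
    cs <- random_instance(seed, n_svs = 15, n_samples = 40)
    # thin carriers so that incompatible pairs are absent
    geno <- cs$genotypes
    geno[, ] <- 0L
    for (i in seq_len(nrow(geno))) geno[i, ((i - 1) %% 40) + 1] <- 1L
    cs <- sv_callset(cs$records, geno)
    a <- cluster_svs(cs, "trivial", "d2", 120)
    b <- cluster_svs(cs, "corrected", "d2", 120)
    expect_equal(canon_partition(a$components), canon_partition(b$components))
  }
})

test_that("trivial and corrected match the brute-force reference", {
  for (seed in 1:60) {
    cs <- random_instance(seed, n_svs = sample(5:30, 1))
    for (spec in list(list("d2", 100), list("d1", 0.5))) {
      for (strat in c("trivial", "corrected")) {
        got <- cluster_svs(cs, strat, spec[[1]], spec[[2]])
        want <- oracle_cluster(cs$records, cs$genotypes, spec[[1]], spec[[2]],
                               strat)
        expect_equal(canon_partition(got$components), canon_partition(want),
                     info = paste(seed, strat, spec[[1]]))
      }
    }
  }
})

test_that("merged outputs conserve per-sample allele counts and stay coded", {
  for (seed in 61:70) {
    cs <- random_instance(seed, n_svs = 25)
    for (strat in c("trivial", "corrected")) {
      cl <- cluster_svs(cs, strat, "d2", 150)
      out <- cl$callset$genotypes
      expect_true(all(out %in% 0:2))
      expect_equal(colSums(out), colSums(cs$genotypes))
    }
  }
})

test_that("corrected sub-components refine the original component", {
  for (seed in 71:75) {
    cs <- random_instance(seed, n_svs = 25)
    memb <- threshold_components(cs$records, "d2", 150)
    cl <- cluster_svs(cs, "corrected", "d2", 150)
    for (comp in cl$components) {
      expect_equal(length(unique(memb[comp])), 1)
    }
  }
})

test_that("materialized representatives use the envelope and smallest ID", {
  geno <- rbind(c(1L, 0L), c(0L, 2L))
  colnames(geno) <- c("s1", "s2")
  rec <- del_records(c(100, 110), c(200, 210), ids = c("svB", "svA"))
  cl <- cluster_svs(sv_callset(rec, geno), "trivial", "d2", 50)
  out <- cl$callset$records
  expect_equal(out$start, 100L)
  expect_equal(out$end, 210L)
  expect_equal(out$id, "svA")
  expect_equal(out$members, "svA,svB")
})

test_that("a singleton component passes through unchanged", {
  geno <- matrix(1L, 1, 1, dimnames = list(NULL, "s1"))
  cs <- sv_callset(del_records(100, 300), geno)
  cl <- cluster_svs(cs, "trivial", "d2", 100)
  expect_equal(cl$callset$records$id, cs$records$id)
  expect_equal(cl$callset$records$start, cs$records$start)
  expect_false(cl$callset$records$merged)
})
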