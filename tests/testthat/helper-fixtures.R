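# Small fixtures shared across test files; everything is built in code.

# a trio-only callset: columns child, father, mother (+ optional extras)
trio_callset <- function(rows, extra_samples = 0, extra_values = NULL) {
  geno <- do.call(rbind, rows)
  if (extra_samples > 0) {
    ex <- if (is.null(extra_values)) {
      matrix(0L, nrow(geno), extra_samples)
    } else {
      do.call(rbind, extra_values)
    }
    geno <- cbind(geno, ex)
  }
  colnames(geno) <- c("child", "father", "mother",
                      if (extra_samples > 0) paste0("x", seq_len(extra_samples)))
  n <- nrow(geno)
  rec <- tibble::tibble(id = sprintf("sv%02d", seq_len(n)), chrom = "chr1",
                        start = 1000L + (seq_len(n) - 1L) * 10L,
                        end = 1200L + (seq_len(n) - 1L) * 10L,
                        svtype = "DEL")
  svclust::sv_callset(rec, geno)
}

# pedigree with one trio (child, father, mother) plus unrelated extras
trio_pedigree <- function(extra_samples = 0) {
  ped <- tibble::tibble(
    family = c("F1", "F1", "F1",
               if (extra_samples > 0) paste0("x", seq_len(extra_samples))),
    sample = c("child", "father", "mother",
               if (extra_samples > 0) paste0("x", seq_len(extra_samples))),
    father = c("father", NA, NA, rep(NA, extra_samples)),
    mother = c("mother", NA, NA, rep(NA, extra_samples)))
  svclust::sv_pedigree(ped)
}

# records helper: intervals on one chromosome, one type
del_records <- function(starts, ends, ids = NULL) {
  n <- length(starts)
  tibble::tibble(id = if (is.null(ids)) sprintf("sv%02d", seq_len(n)) else ids,
                 chrom = "chr1", start = as.integer(starts),
                 end = as.integer(ends), svtype = "DEL")
}

write_test_vcf <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "test.vcf")
  writeLines(lines, path)
  path
}

vcf_header <- function(samples) {
  c("##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"e\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"l\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}
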