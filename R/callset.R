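#' Bundle SV records with their genotype matrix
#'
#' An `sv_callset` pairs a table of structural-variant (SV) records with the
#' N x M genotype matrix the clustering algorithms act on. Rows of the matrix
#' correspond to records (in order), columns to samples. Genotypes are coded
#' 0 (reference homozygote), 1 (heterozygote), 2 (alternative homozygote).
#'
#' @param records A data frame with columns `id`, `chrom`, `start`, `end`,
#'   `svtype` and optionally `length`. Coordinates are 1-based inclusive;
#'   `end >= start`. For insertions the interval is the pseudo-interval
#'   `[start, start + length - 1]`.
#' @param genotypes An integer matrix with one row per record (same order),
#'   one column per sample, entries in `{0, 1, 2}`. Column names are sample
#'   identifiers.
#'
#' @return An object of class `sv_callset`: a list with elements `records`
#'   (a tibble) and `genotypes` (an integer matrix with rownames = record ids).
#' @export
#' @examples
#' recs <- tibble::tibble(id = "sv1", chrom = "chr1", start = 1000L,
#'                        end = 1200L, svtype = "DEL")
#' gt <- matrix(c(0L, 1L, 2L), nrow = 1,
#'              dimnames = list("sv1", c("s1", "s2", "s3")))
#' sv_callset(recs, gt)
sv_callset <- function(records, genotypes) {
  records <- as_tibble(records)
  needed <- c("id", "chrom", "start", "end", "svtype")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("records is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  records$id <- as.character(records$id)
  records$chrom <- as.character(records$chrom)
  records$start <- as.integer(records$start)
  records$end <- as.integer(records$end)
  records$svtype <- as.character(records$svtype)
  if (anyDuplicated(records$id)) abort("record ids must be unique")
  if (any(records$end < records$start)) abort("every record needs end >= start")
  if (!("length" %in% names(records))) {
    records$length <- records$end - records$start + 1L
  }
  records$length <- as.integer(records$length)
  if (any(records$length < 1L)) abort("record lengths must be >= 1")

  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (nrow(genotypes) != nrow(records)) {
    abort("genotypes must have one row per record")
  }
  if (is.null(colnames(genotypes))) {
    abort("genotypes must have sample identifiers as column names")
  }
  if (anyDuplicated(colnames(genotypes))) abort("sample names must be unique")
  if (nrow(genotypes) > 0 && !all(genotypes %in% 0:2)) {
    abort("genotype entries must all be in {0, 1, 2}")
  }
  rownames(genotypes) <- records$id
  structure(list(records = records, genotypes = genotypes),
            class = "sv_callset")
}

#' @export
print.sv_callset <- function(x, ...) {
  cat("<sv_callset> ", nrow(x$records), " SVs x ", ncol(x$genotypes),
      " samples\n", sep = "")
  types <- table(x$records$svtype)
  cat("  types:", paste(names(types), types, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @method tidy sv_callset
#' @export
tidy.sv_callset <- function(x, ...) x$records

#' @method glance sv_callset
#' @export
glance.sv_callset <- function(x, ...) {
  tibble(n_svs = nrow(x$records),
         n_samples = ncol(x$genotypes),
         n_carriers_mean = if (nrow(x$records) > 0)
           mean(rowSums(x$genotypes != 0L)) else NA_real_)
}

#' Extract the genotype matrix of a callset
#'
#' @param x An `sv_callset`.
#' @return The integer genotype matrix (rows = SVs, columns = samples).
#' @export
genotype_matrix <- function(x) {
  stopifnot(inherits(x, "sv_callset"))
  x$genotypes
}

#' Sample identifiers of a callset
#' @param x An `sv_callset`.
#' @return Character vector of sample names.
#' @export
callset_samples <- function(x) {
  stopifnot(inherits(x, "sv_callset"))
  colnames(x$genotypes)
}

gt_to_code <- function(gt) {
  # haploid-safe diploid GT string -> 0/1/2; NA for missing
  gt <- gsub("|", "/", gt, fixed = TRUE)
  out <- rep(NA_integer_, length(gt))
  out[gt %in% c("0/0", "0")] <- 0L
  out[gt %in% c("0/1", "1/0")] <- 1L
  out[gt %in% c("1/1", "1")] <- 2L
  out
}

info_field <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(info, regexec(pat, info))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
}

#' Read a structural-variant VCF into a callset
#'
#' Parses a (multi-sample) VCF of SV records, keeping records longer than
#' `min_length` base pairs. Genotypes are coded 0/1/2; missing genotypes
#' (`./.`) are coded 0 (reference) and counted in a warning, so that missing
#' data can never create spurious merging incompatibilities. Breakend (BND)
#' records and records carrying neither `INFO/END` nor `INFO/SVLEN` are
#' skipped and counted. Multi-allelic records are split into one biallelic
#' record per alternative allele.
#'
#' For insertions `END` typically equals `POS`; a pseudo-interval
#' `[POS, POS + |SVLEN| - 1]` is used so that overlap-based dissimilarity is
#' defined for every record.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param min_length Keep only records strictly longer than this many bp
#'   (default 50, the conventional lower bound for structural variants).
#' @return An [sv_callset()]. The attribute `"read_log"` records counts of
#'   missing genotypes, skipped BND records, skipped no-coordinate records and
#'   records removed by the length filter.
#' @export
read_sv_vcf <- function(path, min_length = 50) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) abort("VCF contains no records")
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt_raw)) abort("VCF has no GT field")
  samples <- colnames(gt_raw)

  svtype_raw <- info_field(fix$INFO, "SVTYPE")
  end_raw <- info_field(fix$INFO, "END")
  svlen_raw <- info_field(fix$INFO, "SVLEN")
  svtype <- vapply(strsplit(svtype_raw, ","), function(x)
    if (length(x)) x[1] else NA_character_, "")
  end_i <- suppressWarnings(as.integer(end_raw))
  svlen_i <- suppressWarnings(as.integer(vapply(
    strsplit(svlen_raw, ","), function(x)
      if (length(x)) x[1] else NA_character_, "")))
  pos <- as.integer(fix$POS)
  id <- fix$ID
  id[is.na(id) | id == "."] <- paste0("rec", which(is.na(id) | id == "."))

  n_bnd <- sum(svtype %in% "BND")
  keep <- !(svtype %in% "BND")
  no_coord <- is.na(end_i) & is.na(svlen_i)
  n_no_coord <- sum(no_coord & keep)
  keep <- keep & !no_coord

  # split multi-allelic records into biallelic ones
  alt_n <- lengths(strsplit(fix$ALT, ",", fixed = TRUE))
  alt_n[is.na(fix$ALT)] <- 1L
  rows <- list()
  gts <- list()
  n_missing <- 0L
  for (r in which(keep)) {
    for (k in seq_len(alt_n[r])) {
      kth <- function(raw) {
        parts <- strsplit(raw[r], ",", fixed = TRUE)[[1]]
        if (length(parts) >= k) parts[k] else parts[1]
      }
      st_k <- if (alt_n[r] > 1) kth(svtype_raw) else svtype[r]
      len_k <- if (alt_n[r] > 1)
        suppressWarnings(as.integer(kth(svlen_raw))) else svlen_i[r]
      end_k <- end_i[r]
      if (identical(st_k, "INS") || is.na(end_k) || end_k <= pos[r]) {
        if (!is.na(len_k)) end_k <- pos[r] + abs(len_k) - 1L
        if (is.na(end_k)) next
      }
      if (is.na(st_k)) st_k <- "UNK"
      gt_line <- gt_raw[r, , drop = TRUE]
      if (alt_n[r] > 1) {
        alle <- strsplit(gsub("|", "/", gt_line, fixed = TRUE), "/", fixed = TRUE)
        code <- vapply(alle, function(a) {
          if (any(a %in% c(".", NA))) return(NA_integer_)
          sum(a == as.character(k))
        }, 0L)
      } else {
        code <- gt_to_code(gt_line)
      }
      n_missing <- n_missing + sum(is.na(code))
      code[is.na(code)] <- 0L
      id_k <- if (alt_n[r] > 1) paste0(id[r], "_alt", k) else id[r]
      rows[[length(rows) + 1L]] <- tibble(
        id = id_k, chrom = fix$CHROM[r], start = pos[r], end = end_k,
        svtype = st_k,
        length = if (identical(st_k, "INS") && !is.na(len_k)) abs(len_k)
                 else end_k - pos[r] + 1L)
      gts[[length(gts) + 1L]] <- code
    }
  }
  if (length(rows) == 0) abort("no usable SV records in VCF")
  records <- bind_rows(rows)
  geno <- do.call(rbind, gts)
  colnames(geno) <- samples

  long <- records$length > min_length
  n_short <- sum(!long)
  records <- records[long, , drop = FALSE]
  geno <- geno[long, , drop = FALSE]
  if (nrow(records) == 0) {
    abort(paste0("all records removed by min_length = ", min_length))
  }
  if (n_missing > 0) {
    warn(paste0(n_missing, " missing genotypes coded as reference (0)"))
  }
  if (n_bnd > 0) inform(paste0("skipped ", n_bnd, " BND records"))
  if (n_no_coord > 0) {
    warn(paste0("skipped ", n_no_coord, " records with neither END nor SVLEN"))
  }
  out <- sv_callset(records, geno)
  attr(out, "read_log") <- list(missing_gt = n_missing, skipped_bnd = n_bnd,
                                skipped_no_coord = n_no_coord,
                                filtered_short = n_short)
  out
}

#' Write a callset as a multi-sample VCF
#'
#' Emits a minimal VCF 4.2 with `SVTYPE`, `END`, `SVLEN` (and, for merged
#' callsets, `MEMBERS`, `MERGED`, `STRATEGY`) INFO fields and `GT` genotypes.
#' Insertions are written with `SVLEN` only so that the pseudo-interval
#' convention round-trips through [read_sv_vcf()].
#'
#' @param x An `sv_callset` (optionally carrying `members`/`merged` record
#'   columns produced by clustering).
#' @param path Output file path.
#' @param strategy Optional strategy label stored in `INFO/STRATEGY`.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(x, path, strategy = NULL) {
  stopifnot(inherits(x, "sv_callset"))
  rec <- x$records
  geno <- x$genotypes
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=svclust",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length of the variant\">",
    "##INFO=<ID=MEMBERS,Number=.,Type=String,Description=\"IDs of merged member records\">",
    "##INFO=<ID=MERGED,Number=1,Type=Integer,Description=\"1 if record is a merge of >= 2 members\">",
    "##INFO=<ID=STRATEGY,Number=1,Type=String,Description=\"Clustering strategy that produced the record\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(geno)), collapse = "\t"))
  info <- paste0("SVTYPE=", rec$svtype,
                 ifelse(rec$svtype == "INS", "",
                        paste0(";END=", rec$end)),
                 ";SVLEN=", rec$length)
  if ("members" %in% names(rec)) {
    has <- !is.na(rec$members) & rec$members != ""
    info[has] <- paste0(info[has], ";MEMBERS=", rec$members[has])
  }
  if ("merged" %in% names(rec)) {
    info <- paste0(info, ";MERGED=", as.integer(rec$merged))
  }
  if (!is.null(strategy)) info <- paste0(info, ";STRATEGY=", strategy)
  gt_str <- matrix(c("0/0", "0/1", "1/1")[geno + 1L], nrow = nrow(geno))
  body <- paste(rec$chrom, rec$start, rec$id, "N", paste0("<", rec$svtype, ">"),
                ".", ".", info, "GT",
                apply(gt_str, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write the genotype matrix as TSV
#'
#' @param x An `sv_callset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(x, path) {
  stopifnot(inherits(x, "sv_callset"))
  df <- cbind(x$records[, c("id", "chrom", "start", "end", "svtype")],
              as.data.frame(x$genotypes))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
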