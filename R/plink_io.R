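# PLINK bed/bim/fam input and delimited phenotype/covariate tables.
# Only the SNP-major .bed layout (mode byte 0x01) is supported; dosage counts
# copies of the A1 allele (.bim column 5). Association results are
# sign-symmetric under an allele flip and p-values are invariant to it.

BED_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))

#' Read a PLINK .bim variant table
#'
#' @param path Path to a .bim file (6 whitespace-delimited columns:
#'   chromosome, id, genetic distance, bp position, allele 1, allele 2).
#' @return A data.frame with columns `chrom`, `id`, `cm`, `bp`, `a1`, `a2`,
#'   one row per variant, in file order. Positions are 1-based.
#' @export
read_bim <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), id = character(), cm = numeric(),
                      bp = integer(), a1 = character(), a2 = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 6L)) {
    bad <- which(nf != 6L)[1L]
    stop(sprintf("malformed .bim line %d: expected 6 columns, found %d",
                 bad, nf[bad]))
  }
  m <- matrix(unlist(fields), ncol = 6L, byrow = TRUE)
  bp <- suppressWarnings(as.integer(m[, 4L]))
  if (anyNA(bp) || any(bp < 1L)) {
    bad <- which(is.na(bp) | bp < 1L)[1L]
    stop(sprintf("malformed .bim line %d: bad bp position '%s'", bad, m[bad, 4L]))
  }
  if (any(!nzchar(m[, 2L]))) stop("empty variant id in .bim")
  data.frame(chrom = m[, 1L], id = m[, 2L],
             cm = suppressWarnings(as.numeric(m[, 3L])), bp = bp,
             a1 = m[, 5L], a2 = m[, 6L], stringsAsFactors = FALSE)
}

#' Read a PLINK .fam sample table
#'
#' @param path Path to a .fam file (first two columns: family id,
#'   individual id).
#' @return A data.frame with columns `fid` and `iid`; `(fid, iid)` pairs must
#'   be unique.
#' @export
read_fam <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    stop(sprintf("malformed .fam line %d: expected at least 2 columns",
                 which(nf < 2L)[1L]))
  }
  fid <- vapply(fields, `[[`, "", 1L)
  iid <- vapply(fields, `[[`, "", 2L)
  key <- paste(fid, iid, sep = ":")
  if (anyDuplicated(key)) stop("duplicate (fid, iid) pairs in .fam")
  data.frame(fid = fid, iid = iid, stringsAsFactors = FALSE)
}

# 256 x 4 lookup: byte value -> dosages of the 4 sample bit-pairs
# (low-to-high order). Codes: 00 -> 2, 01 -> NA (missing), 10 -> 1, 11 -> 0.
.bed_lookup <- local({
  tab <- matrix(NA_real_, nrow = 256L, ncol = 4L)
  code_map <- c(`0` = 2, `1` = NA_real_, `2` = 1, `3` = 0)
  for (byte in 0:255) {
    v <- byte
    for (k in 1:4) {
      tab[byte + 1L, k] <- code_map[[as.character(v %% 4L)]]
      v <- v %/% 4L
    }
  }
  tab
})

#' Read a block of genotypes from a PLINK .bed file
#'
#' Decodes the requested variants from a SNP-major .bed file without loading
#' the whole matrix; repeated reads of the same indices are identical.
#'
#' @param bed_path Path to the .bed file.
#' @param n_samples Number of samples (rows of the .fam file).
#' @param variant_indices 1-based indices into the .bim variant order.
#' @return A numeric matrix with `n_samples` rows (in .fam order) and one
#'   column per requested variant; entries are A1-allele dosages in
#'   \{0, 1, 2\} with `NA` for missing.
#' @export
read_genotype_block <- function(bed_path, n_samples, variant_indices) {
  stopifnot(file.exists(bed_path), n_samples >= 1L)
  variant_indices <- as.integer(variant_indices)
  bpv <- as.integer(ceiling(n_samples / 4))
  fsize <- file.size(bed_path)
  n_var_file <- (fsize - 3) / bpv
  if (length(variant_indices) &&
      (min(variant_indices) < 1L || max(variant_indices) > n_var_file)) {
    stop(sprintf("variant index out of range (file holds %d variants)",
                 as.integer(n_var_file)))
  }
  con <- file(bed_path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 3L)
  if (length(magic) != 3L || !identical(magic, BED_MAGIC)) {
    stop("not a SNP-major PLINK .bed file (bad magic/mode bytes)")
  }
  out <- matrix(NA_real_, nrow = n_samples, ncol = length(variant_indices))
  for (k in seq_along(variant_indices)) {
    seek(con, where = 3 + (variant_indices[k] - 1L) * bpv, origin = "start")
    bytes <- readBin(con, "raw", n = bpv)
    if (length(bytes) < bpv) stop("truncated .bed record")
    vals <- .bed_lookup[as.integer(bytes) + 1L, , drop = FALSE]
    out[, k] <- as.vector(t(vals))[seq_len(n_samples)]
  }
  out
}

#' Write genotypes to PLINK bed/bim/fam
#'
#' Inverse of [read_genotype_block()]; used by the fixture generator.
#'
#' @param dosage Numeric matrix, samples x variants, values in \{0, 1, 2, NA\}.
#' @param bim Data.frame as returned by [read_bim()] (one row per variant).
#' @param fam Data.frame with columns `fid`, `iid` (one row per sample).
#' @param out_prefix Output path prefix; writes `<prefix>.bed/.bim/.fam`.
#' @return `out_prefix`, invisibly.
#' @export
write_plink <- function(dosage, bim, fam, out_prefix) {
  stopifnot(is.matrix(dosage), nrow(bim) == ncol(dosage),
            nrow(fam) == nrow(dosage))
  n <- nrow(dosage)
  bpv <- as.integer(ceiling(n / 4))
  # dosage -> 2-bit code
  code_of <- function(d) {
    code <- integer(length(d))        # default 0 -> dosage 2
    code[is.na(d)] <- 1L
    code[!is.na(d) & d == 1] <- 2L
    code[!is.na(d) & d == 0] <- 3L
    code
  }
  con <- file(paste0(out_prefix, ".bed"), "wb")
  writeBin(BED_MAGIC, con)
  pow <- c(1L, 4L, 16L, 64L)
  for (j in seq_len(ncol(dosage))) {
    codes <- code_of(dosage[, j])
    length(codes) <- bpv * 4L          # pad with NA -> treat as 0 bits
    codes[is.na(codes)] <- 0L
    m <- matrix(codes, nrow = 4L)
    writeBin(as.raw(colSums(m * pow)), con)
  }
  close(con)
  write.table(bim[, c("chrom", "id", "cm", "bp", "a1", "a2")],
              paste0(out_prefix, ".bim"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  fam_out <- data.frame(fam$fid, fam$iid, 0L, 0L, 0L, -9L)
  write.table(fam_out, paste0(out_prefix, ".fam"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  invisible(out_prefix)
}

#' Read a delimited phenotype or covariate table aligned to .fam order
#'
#' The delimiter is auto-detected (tab, comma, or whitespace). Non-numeric
#' cells and the sentinel "NA" become missing. Samples are matched to the
#' .fam file by (FID, IID) when both columns are present, otherwise by IID;
#' table rows with no .fam match are dropped (a message reports the count)
#' and .fam samples absent from the table get all-missing rows.
#'
#' @param path Path to the delimited text file (header required).
#' @param fam Data.frame from [read_fam()] defining the sample order.
#' @param value_columns Optional character vector naming the columns to keep;
#'   default: all non-id columns.
#' @return A numeric matrix with `nrow(fam)` rows in .fam order, one column
#'   per value column.
#' @export
read_table_aligned <- function(path, fam, value_columns = NULL) {
  stopifnot(file.exists(path))
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  nm_upper <- toupper(names(tab))
  has_fid <- "FID" %in% nm_upper
  has_iid <- "IID" %in% nm_upper
  if (!has_iid) stop("table must contain an IID column")
  iid <- tab[[which(nm_upper == "IID")[1L]]]
  key <- if (has_fid) paste(tab[[which(nm_upper == "FID")[1L]]], iid, sep = ":")
         else iid
  fam_key <- if (has_fid) paste(fam$fid, fam$iid, sep = ":") else fam$iid
  idx <- match(fam_key, key)
  if (all(is.na(idx))) stop("no overlap between table samples and .fam samples")
  n_drop <- sum(!key %in% fam_key)
  if (n_drop > 0L) message(n_drop, " table row(s) not in .fam dropped")
  id_cols <- which(nm_upper %in% c("FID", "IID"))
  if (is.null(value_columns)) value_columns <- names(tab)[-id_cols]
  missing_cols <- setdiff(value_columns, names(tab))
  if (length(missing_cols)) {
    stop("columns not found: ", paste(missing_cols, collapse = ", "))
  }
  out <- matrix(NA_real_, nrow = nrow(fam), ncol = length(value_columns),
                dimnames = list(NULL, value_columns))
  for (j in seq_along(value_columns)) {
    v <- tab[[value_columns[j]]][idx]
    out[, j] <- suppressWarnings(as.numeric(v))
  }
  out
}
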