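#' Read a genotype panel
#'
#' Reads genotypes from PLINK binary files (`.bed`/`.bim`/`.fam`, v1.0
#' SNP-major) or from a headered CSV (rows = individuals, first column
#' `individual_id`, remaining columns one SNP each). Codes count copies of
#' PLINK allele 1; allele frequencies are computed from non-missing entries.
#' For the CSV dialect an optional tab-separated map file `<stem>.map`
#' (columns snp_id, chrom, pos) is read when present.
#'
#' @param path For `plink-bed`, the file stem (with or without `.bed`); for
#'   `csv`, the CSV file path.
#' @param format `"plink-bed"` or `"csv"`.
#' @return A [genotype_matrix()].
#' @seealso [write_genotypes()]
#' @export
read_genotypes <- function(path, format = c("plink-bed", "csv")) {
  format <- match.arg(format)
  if (format == "csv") read_genotypes_csv(path) else read_genotypes_bed(path)
}

#' Write a genotype panel
#'
#' Inverse of [read_genotypes()]; round-trips ids, map and codes exactly.
#' PLINK output uses alleles A (counted, allele 1) and B.
#'
#' @param geno A [genotype_matrix()].
#' @param path Output stem (plink-bed) or CSV path (csv).
#' @param format `"plink-bed"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path, format = c("plink-bed", "csv")) {
  check_genotype_matrix(geno)
  format <- match.arg(format)
  if (format == "csv") write_genotypes_csv(geno, path) else write_genotypes_bed(geno, path)
  invisible(path)
}

read_genotypes_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (names(tab)[1] != "individual_id") {
    abort("CSV genotype files must have `individual_id` as their first column.")
  }
  ids <- as.character(tab$individual_id)
  codes <- as.matrix(tab[, -1, drop = FALSE])
  bad <- which(!(is.na(codes) | codes == 0 | codes == 1 | codes == 2))
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(codes)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(codes)) + 1L
    abort(sprintf(
      "Invalid genotype code %s for individual '%s', SNP '%s' (must be 0/1/2/NA).",
      format(codes[bad[1]]), ids[i], colnames(codes)[j]
    ))
  }
  storage.mode(codes) <- "double"
  rownames(codes) <- ids
  map_path <- paste0(sub("\\.csv$", "", path), ".map")
  map <- NULL
  if (file.exists(map_path)) {
    map <- readr::read_tsv(map_path, show_col_types = FALSE, progress = FALSE)
  }
  genotype_matrix(codes, map)
}

write_genotypes_csv <- function(geno, path) {
  tab <- tibble(individual_id = geno$individual_ids)
  tab <- dplyr::bind_cols(tab, as_tibble(geno$codes, .name_repair = "minimal"))
  readr::write_csv(tab, path, progress = FALSE)
  readr::write_tsv(geno$map, paste0(sub("\\.csv$", "", path), ".map"), progress = FALSE)
}

# --- PLINK BED v1.0 (SNP-major) ------------------------------------------
# Two bits per genotype, samples packed four per byte from the low bits:
#   00 = two copies of allele 1, 10 = heterozygote, 11 = zero copies,
#   01 = missing. Codes count allele-1 copies.

plink_stem <- function(path) sub("\\.bed$", "", path)

read_genotypes_bed <- function(path) {
  stem <- plink_stem(path)
  bed <- paste0(stem, ".bed")
  bim <- paste0(stem, ".bim")
  fam <- paste0(stem, ".fam")
  for (f in c(bed, bim, fam)) {
    if (!file.exists(f)) abort(sprintf("File not found: %s", f))
  }
  bim_tab <- readr::read_tsv(
    bim,
    col_names = c("chrom", "snp_id", "cm", "pos", "a1", "a2"),
    show_col_types = FALSE, progress = FALSE
  )
  fam_tab <- readr::read_tsv(
    fam,
    col_names = c("fid", "iid", "pat", "mat", "sex", "pheno"),
    show_col_types = FALSE, progress = FALSE
  )
  n <- nrow(fam_tab)
  m <- nrow(bim_tab)
  bytes_per_snp <- ceiling(n / 4)
  raw <- readBin(bed, what = "raw", n = 3 + bytes_per_snp * m)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    abort(sprintf("%s is not a PLINK .bed file (bad magic bytes).", bed))
  }
  if (raw[3] != as.raw(0x01)) {
    abort("Only SNP-major (v1.0) .bed files are supported.")
  }
  if (length(raw) != 3 + bytes_per_snp * m) {
    abort(sprintf(
      ".bed size inconsistent with .bim/.fam dimensions (%d individuals x %d SNPs).",
      n, m
    ))
  }
  body <- as.integer(raw[-(1:3)])
  # n x 4*bytes_per_snp matrix of two-bit fields, one column block per SNP
  dim(body) <- c(bytes_per_snp, m)
  codes <- matrix(NA_real_, nrow = n, ncol = m)
  # decode the four sample slots of every byte
  lookup <- c(2, NA, 1, 0) # two-bit value 0,1,2,3 -> allele-1 count
  for (slot in 0:3) {
    vals <- (body %/% (4L^slot)) %% 4L
    rows <- seq.int(slot + 1L, by = 4L, length.out = bytes_per_snp)
    rows <- rows[rows <= n]
    if (length(rows)) {
      codes[rows, ] <- lookup[vals[seq_along(rows), , drop = FALSE] + 1L]
    }
  }
  rownames(codes) <- as.character(fam_tab$iid)
  colnames(codes) <- as.character(bim_tab$snp_id)
  genotype_matrix(
    codes,
    tibble(snp_id = as.character(bim_tab$snp_id), chrom = bim_tab$chrom, pos = bim_tab$pos)
  )
}

write_genotypes_bed <- function(geno, path) {
  stem <- plink_stem(path)
  n <- nrow(geno$codes)
  m <- ncol(geno$codes)
  bytes_per_snp <- ceiling(n / 4)
  # allele-1 count -> two-bit value
  two_bit <- matrix(1L, nrow = bytes_per_snp * 4L, ncol = m) # 1 = missing
  enc <- c(3L, 2L, 0L) # code 0,1,2
  obs <- !is.na(geno$codes)
  tb <- matrix(1L, nrow = n, ncol = m)
  tb[obs] <- enc[geno$codes[obs] + 1L]
  two_bit[seq_len(n), ] <- tb
  # pad slots beyond n encode as 0 (homozygous) per PLINK convention
  if (bytes_per_snp * 4L > n) two_bit[(n + 1L):(bytes_per_snp * 4L), ] <- 0L
  weights <- 4L^(0:3)
  dim(two_bit) <- c(4L, bytes_per_snp * m)
  bytes <- as.raw(colSums(two_bit * weights))
  con <- file(paste0(stem, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(bytes, con)
  bim <- tibble(
    chrom = geno$map$chrom, snp_id = geno$map$snp_id, cm = 0,
    pos = geno$map$pos, a1 = "A", a2 = "B"
  )
  readr::write_tsv(bim, paste0(stem, ".bim"), col_names = FALSE, progress = FALSE)
  fam <- tibble(
    fid = geno$individual_ids, iid = geno$individual_ids,
    pat = 0, mat = 0, sex = 0, pheno = -9
  )
  readr::write_tsv(fam, paste0(stem, ".fam"), col_names = FALSE, progress = FALSE)
}
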