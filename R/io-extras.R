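#' Write a SNP partition to disk
#'
#' Writes the prior and residual SNP id lists as plain-text files
#' (`<stem>_prior.txt`, `<stem>_residual.txt`, one id per line) plus a JSON
#' summary of the fraction and counts (`<stem>_summary.json`).
#'
#' @param part A `snp_partition` from [select_top_fraction()].
#' @param stem Output path stem.
#' @return `stem`, invisibly.
#' @export
write_partition <- function(part, stem) {
  if (!inherits(part, "snp_partition")) abort("`part` must be a snp_partition.")
  writeLines(part$prior_ids, paste0(stem, "_prior.txt"))
  writeLines(part$residual_ids, paste0(stem, "_residual.txt"))
  jsonlite::write_json(
    list(fraction = part$fraction, n_prior = part$n_prior,
         n_residual = part$n_residual),
    paste0(stem, "_summary.json"),
    auto_unbox = TRUE
  )
  invisible(stem)
}

#' Read a SNP partition written by [write_partition()]
#'
#' @param stem Path stem used when writing.
#' @return A `snp_partition`.
#' @export
read_partition <- function(stem) {
  summ <- jsonlite::read_json(paste0(stem, "_summary.json"))
  prior <- readLines(paste0(stem, "_prior.txt"))
  residual <- readLines(paste0(stem, "_residual.txt"))
  structure(
    list(
      fraction = summ$fraction,
      prior_ids = prior,
      residual_ids = residual,
      n_prior = length(prior),
      n_residual = length(residual)
    ),
    class = "snp_partition"
  )
}

#' Write a relationship matrix to disk
#'
#' Two formats: a headered, id-indexed CSV (first column `individual_id`),
#' and a compact binary layout (id header lines followed by the row-major
#' doubles) that round-trips bit-exactly.
#'
#' @param R A `relationship_matrix`.
#' @param path Output file.
#' @param format `"csv"` or `"binary"`.
#' @return `path`, invisibly.
#' @export
write_relationship_matrix <- function(R, path, format = c("csv", "binary")) {
  if (!inherits(R, "relationship_matrix")) abort("`R` must be a relationship_matrix.")
  format <- match.arg(format)
  if (format == "csv") {
    tab <- tibble(individual_id = R$individual_ids)
    tab <- dplyr::bind_cols(tab, as_tibble(R$values, .name_repair = "minimal"))
    readr::write_csv(tab, path, progress = FALSE)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    ids <- R$individual_ids
    writeBin(length(ids), con, size = 4L)
    writeBin(nchar(R$kind), con, size = 4L)
    writeBin(charToRaw(R$kind), con)
    for (id in ids) {
      writeBin(nchar(id), con, size = 4L)
      writeBin(charToRaw(id), con)
    }
    writeBin(as.numeric(c(R$scaling_denominator, R$ridge_added)), con)
    writeBin(as.numeric(base::t(R$values)), con) # row-major
  }
  invisible(path)
}

#' Read a relationship matrix written by [write_relationship_matrix()]
#'
#' @param path Input file.
#' @param format `"csv"` or `"binary"`.
#' @param kind Matrix kind for CSV input (the binary format stores it).
#' @return A `relationship_matrix`.
#' @export
read_relationship_matrix <- function(path, format = c("csv", "binary"),
                                     kind = "additive") {
  format <- match.arg(format)
  if (format == "csv") {
    tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    ids <- as.character(tab$individual_id)
    vals <- as.matrix(tab[, -1, drop = FALSE])
    dimnames(vals) <- list(ids, ids)
    relationship_matrix(vals, kind)
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    n <- readBin(con, integer(), size = 4L)
    kl <- readBin(con, integer(), size = 4L)
    kind <- rawToChar(readBin(con, raw(), kl))
    ids <- character(n)
    for (i in seq_len(n)) {
      il <- readBin(con, integer(), size = 4L)
      ids[i] <- rawToChar(readBin(con, raw(), il))
    }
    meta <- readBin(con, numeric(), 2L)
    vals <- matrix(readBin(con, numeric(), n * n), n, n, byrow = TRUE,
                   dimnames = list(ids, ids))
    relationship_matrix(vals, kind, scaling_denominator = meta[1],
                        ridge_added = meta[2])
  }
}
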