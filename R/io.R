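#' Read a features-by-samples matrix from TSV
#'
#' The expected layout matches typical per-protein count tables:
#' a header row of sample ids, first column feature ids, tab-separated,
#' decimal point ".".  `NA` is allowed only for non-count matrices.
#'
#' @param path path to a TSV file.
#' @param value_kind one of `"counts"`, `"transformed"`, `"log_intensity"`.
#' @return an [omics_matrix()].
#' @export
read_matrix <- function(path, value_kind = c("counts", "transformed", "log_intensity")) {
  value_kind <- match.arg(value_kind)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("matrix file needs a header and at least one row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  # tolerate an (empty or named) corner cell in the header
  n_samp <- length(fields[[2L]]) - 1L
  if (n_samp < 1L) stop("matrix file has no sample columns")
  sample_ids <- utils::tail(header, n_samp)
  body <- fields[-1L]
  ragged <- which(lengths(body) != n_samp + 1L)
  if (length(ragged))
    stop("ragged row at line ", ragged[1L] + 1L)
  feature_ids <- vapply(body, `[[`, character(1), 1L)
  raw <- unlist(lapply(body, `[`, -1L), use.names = FALSE)  # row-major
  num <- suppressWarnings(as.numeric(raw))
  bad <- is.na(num) & !(raw %in% c("NA", "na", ""))
  if (any(bad)) stop("non-numeric value in matrix body: ", raw[bad][1L])
  vals <- matrix(num, nrow = length(body), ncol = n_samp, byrow = TRUE)
  omics_matrix(vals, feature_ids, sample_ids, value_kind)
}

#' Write an omics matrix to TSV
#'
#' Inverse of [read_matrix()]; write-then-read round-trips are exact for
#' count matrices and exact-to-printed-precision (15 significant digits)
#' otherwise.
#'
#' @param x an `omics_matrix`.
#' @param path output path.
#' @export
write_matrix <- function(x, path) {
  stopifnot(inherits(x, "omics_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("feature_id", x$sample_ids), collapse = "\t"), con)
  body <- apply(x$values, 1L, function(v)
    paste(format(v, digits = 15, trim = TRUE, scientific = FALSE), collapse = "\t"))
  writeLines(paste(x$feature_ids, body, sep = "\t"), con)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated
#' `name<TAB>description<TAB>member1<TAB>member2...`.  Members are
#' de-duplicated within a set.
#'
#' @param path path to a GMT file.
#' @return a [gene_set_collection()].
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT line ", short[1L], " has fewer than 3 fields")
  nm <- vapply(fields, `[[`, character(1), 1L)
  desc <- vapply(fields, `[[`, character(1), 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  gene_set_collection(sets, desc)
}

#' Write gene sets to a GMT file
#' @param x a `gene_set_collection`.
#' @param path output path.
#' @export
write_gene_sets <- function(x, path) {
  stopifnot(inherits(x, "gene_set_collection"))
  lines <- vapply(names(x$sets), function(nm)
    paste(c(nm, x$description[[nm]], x$sets[[nm]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical sample table from CSV
#'
#' @param path path to a CSV file with header; requires a `sample_id`
#'   column, all other columns optional (see [sample_table()]).
#' @return a validated `sample_table`.
#' @export
read_clinical <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  sample_table(df)
}

#' Write a clinical sample table to CSV
#' @param x a `sample_table` (or plain data.frame).
#' @param path output path.
#' @export
write_clinical <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a protein-to-gene pair mapping from a two-column TSV
#'
#' @param path TSV with header `protein_id<TAB>gene_id`.
#' @return a [pair_map()].
#' @export
read_pair_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("protein_id", "gene_id") %in% names(df)))
    stop("pair map needs columns protein_id and gene_id")
  pair_map(df$protein_id, df$gene_id)
}

#' Write a protein-to-gene pair mapping
#' @param x a `pair_map`.
#' @param path output path.
#' @export
write_pair_map <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a plain-text annotation list (one id per line)
#' @param path text file; blank lines and `#` comments are skipped.
#' @return character vector of ids.
#' @export
read_id_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}
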