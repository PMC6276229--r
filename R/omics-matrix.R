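#' Construct an omics matrix
#'
#' The basic container used throughout the package: a numeric
#' features-by-samples matrix with unique feature and sample identifiers and
#' a tag describing what the values are.  Spectral-count matrices
#' (`value_kind = "counts"`) must hold non-negative integers and may not
#' contain missing values: absence of detection is coded 0, matching
#' spectral-count semantics.  Log-intensity and transformed matrices may
#' contain `NA`.
#'
#' @param values numeric matrix, features in rows, samples in columns.
#' @param feature_ids character vector of unique feature identifiers; taken
#'   from `rownames(values)` when missing.
#' @param sample_ids character vector of unique sample identifiers; taken
#'   from `colnames(values)` when missing.
#' @param value_kind one of `"counts"`, `"transformed"`, `"log_intensity"`.
#' @return an object of class `omics_matrix`: a list with elements
#'   `feature_ids`, `sample_ids`, `values` (dimnamed matrix) and
#'   `value_kind`.
#' @export
omics_matrix <- function(values, feature_ids = rownames(values),
                         sample_ids = colnames(values),
                         value_kind = c("counts", "transformed", "log_intensity")) {
  value_kind <- match.arg(value_kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != nrow(values))
    stop("row count does not match the number of feature ids")
  if (length(sample_ids) != ncol(values))
    stop("column count does not match the number of sample ids")
  if (anyDuplicated(feature_ids))
    stop("duplicated feature ids: ",
         paste(unique(feature_ids[duplicated(feature_ids)])[1:3], collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicated sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)])[1:3], collapse = ", "))
  if (value_kind == "counts") {
    if (anyNA(values))
      stop("counts matrices may not contain NA (undetected is 0)")
    if (any(values < 0))
      stop("counts must be non-negative")
    if (any(values != round(values)))
      stop("counts must be integers")
  }
  dimnames(values) <- list(feature_ids, sample_ids)
  structure(list(feature_ids = feature_ids, sample_ids = sample_ids,
                 values = values, value_kind = value_kind),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> %d features x %d samples [%s]\n",
              length(x$feature_ids), length(x$sample_ids), x$value_kind))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Subset an omics matrix by feature and/or sample ids
#'
#' @param x an `omics_matrix`.
#' @param features,samples character vectors of ids to keep (order
#'   respected); `NULL` keeps everything in the current order.
#' @return an `omics_matrix`.
#' @export
subset_omics <- function(x, features = NULL, samples = NULL) {
  stopifnot(inherits(x, "omics_matrix"))
  f <- if (is.null(features)) x$feature_ids else as.character(features)
  s <- if (is.null(samples)) x$sample_ids else as.character(samples)
  missing_f <- setdiff(f, x$feature_ids)
  if (length(missing_f))
    stop("unknown feature ids: ", paste(utils::head(missing_f, 3), collapse = ", "))
  missing_s <- setdiff(s, x$sample_ids)
  if (length(missing_s))
    stop("unknown sample ids: ", paste(utils::head(missing_s, 3), collapse = ", "))
  omics_matrix(x$values[f, s, drop = FALSE], f, s, x$value_kind)
}

#' Construct a protein-to-gene pair map
#'
#' @param protein_id,gene_id character vectors of equal length; each protein
#'   may map to at most one gene.
#' @return a `pair_map`: a data.frame with columns `protein_id`, `gene_id`.
#' @export
pair_map <- function(protein_id, gene_id) {
  protein_id <- as.character(protein_id)
  gene_id <- as.character(gene_id)
  if (length(protein_id) != length(gene_id))
    stop("protein_id and gene_id must have equal length")
  if (anyDuplicated(protein_id))
    stop("a protein maps to more than one gene: ",
         protein_id[duplicated(protein_id)][1])
  structure(data.frame(protein_id = protein_id, gene_id = gene_id,
                       stringsAsFactors = FALSE),
            class = c("pair_map", "data.frame"))
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (members are de-duplicated).
#' @param description named character vector of per-set descriptions
#'   (defaults to the set names).
#' @return a `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, description = NULL) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("every gene set must be named")
  if (anyDuplicated(names(sets)))
    stop("duplicated set names")
  sets <- lapply(sets, function(m) unique(as.character(m)))
  if (any(lengths(sets) == 0L)) stop("empty gene set not allowed")
  if (is.null(description)) {
    description <- stats::setNames(names(sets), names(sets))
  } else {
    description <- stats::setNames(as.character(description), names(sets))
  }
  structure(list(sets = sets, description = description),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets, sizes %d-%d\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' Construct/validate a sample (clinical) table
#'
#' Columns beyond the recognized ones are preserved as opaque covariates.
#' `surv_event` must be present (non-NA) wherever `surv_time` is, and each
#' `pair_id` may occur at most once per tissue type.
#'
#' @param df data.frame with at least a `sample_id` column; recognized
#'   optional columns: `tissue` ("tumor"/"normal"), `pair_id`, `subtype`
#'   ("luminalA","HER2","TN_basal","other"), `grade` (1-3), `er_status`
#'   ("pos"/"neg"), `race`, `surv_time` (months, positive), `surv_event`
#'   (0/1).
#' @return the validated data.frame with class `sample_table`.
#' @export
sample_table <- function(df) {
  if (!is.data.frame(df)) stop("`df` must be a data.frame")
  if (!"sample_id" %in% names(df)) stop("missing required column sample_id")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id")
  # CSV round-trips encode NA as the empty string
  for (nm in intersect(c("tissue", "subtype", "er_status", "race"),
                       names(df)))
    df[[nm]][!is.na(df[[nm]]) & df[[nm]] == ""] <- NA
  if ("tissue" %in% names(df)) {
    bad <- !is.na(df$tissue) & !df$tissue %in% c("tumor", "normal")
    if (any(bad)) stop("tissue must be 'tumor' or 'normal'")
    if ("pair_id" %in% names(df)) {
      ok <- !is.na(df$pair_id) & df$pair_id != ""
      key <- paste(df$pair_id[ok], df$tissue[ok])
      if (anyDuplicated(key))
        stop("a pair_id occurs more than once within a tissue type")
    }
  }
  if ("subtype" %in% names(df)) {
    bad <- !is.na(df$subtype) &
      !df$subtype %in% c("luminalA", "HER2", "TN_basal", "other")
    if (any(bad)) stop("unknown subtype value")
  }
  if ("grade" %in% names(df)) {
    df$grade <- suppressWarnings(as.integer(df$grade))
    if (any(!is.na(df$grade) & !df$grade %in% 1:3)) stop("grade must be 1-3")
  }
  if ("surv_time" %in% names(df)) {
    df$surv_time <- as.numeric(df$surv_time)
    if (any(!is.na(df$surv_time) & df$surv_time <= 0))
      stop("surv_time must be positive")
    if (!"surv_event" %in% names(df))
      stop("surv_time present without surv_event")
    df$surv_event <- as.integer(df$surv_event)
    if (any(!is.na(df$surv_time) & is.na(df$surv_event)))
      stop("surv_event missing for a sample with surv_time")
    if (any(!is.na(df$surv_event) & !df$surv_event %in% 0:1))
      stop("surv_event must be 0/1")
  } else if ("surv_event" %in% names(df)) {
    df$surv_event <- as.integer(df$surv_event)
  }
  class(df) <- c("sample_table", "data.frame")
  df
}
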