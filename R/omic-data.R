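#' Construct an omic matrix
#'
#' Wraps one omic's measurements as a features-by-samples numeric matrix with
#' validated identifiers. All values must be finite: impute or drop missing
#' entries upstream.
#'
#' @param values Numeric matrix, features in rows and samples in columns.
#' @param omic_id Short name for the omic (e.g. `"mrna"`, `"methylation"`).
#' @param feature_ids,sample_ids Optional identifier vectors; taken from
#'   `dimnames(values)` when `NULL`.
#' @param drop_constant Drop features with zero variance (they carry no
#'   similarity information).
#'
#' @return An object of class `omic_matrix`.
#' @export
omic_matrix <- function(values, omic_id, feature_ids = NULL, sample_ids = NULL,
                        drop_constant = TRUE) {
  values <- as.matrix(values)
  if (length(values) == 0L) {
    stop("omic '", omic_id, "': empty matrix", call. = FALSE)
  }
  if (!is.numeric(values)) {
    stop("omic '", omic_id, "': non-numeric values", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("omic '", omic_id, "': non-finite or missing values are not allowed",
         call. = FALSE)
  }
  feature_ids <- feature_ids %||% rownames(values) %||%
    paste0("f", seq_len(nrow(values)))
  sample_ids <- sample_ids %||% colnames(values) %||%
    stop("omic '", omic_id, "': sample ids are required", call. = FALSE)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) {
    stop("omic '", omic_id, "': duplicated sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  stopifnot(length(feature_ids) == nrow(values),
            length(sample_ids) == ncol(values))
  if (drop_constant) {
    keep <- apply(values, 1L, stats::sd) > 0
    values <- values[keep, , drop = FALSE]
    feature_ids <- feature_ids[keep]
  }
  dimnames(values) <- list(feature_ids, sample_ids)
  structure(
    list(omic_id = as.character(omic_id), values = values,
         feature_ids = as.character(feature_ids), sample_ids = sample_ids),
    class = "omic_matrix"
  )
}

#' @export
print.omic_matrix <- function(x, ...) {
  cat("<omic_matrix> ", x$omic_id, ": ", nrow(x$values), " features x ",
      ncol(x$values), " samples\n", sep = "")
  invisible(x)
}

#' Build the shared sample registry for a set of omics
#'
#' The registry fixes a global sample order (union of the per-omic sample ids,
#' first-seen order) and records, per omic, which of those samples were
#' measured. Samples absent from an omic keep zero-weight edges in that omic's
#' graph, so the omic does not influence their module assignment.
#'
#' @param omics List of [omic_matrix()] objects.
#' @return An object of class `sample_registry` with fields `sample_ids` and
#'   `membership` (named list of logical vectors over the global order).
#' @export
sample_registry <- function(omics) {
  stopifnot(length(omics) >= 1L)
  ids <- unique(unlist(lapply(omics, function(o) o$sample_ids)))
  membership <- lapply(omics, function(o) ids %in% o$sample_ids)
  names(membership) <- vapply(omics, function(o) o$omic_id, character(1))
  if (anyDuplicated(names(membership))) {
    stop("duplicated omic ids", call. = FALSE)
  }
  structure(list(sample_ids = ids, membership = membership),
            class = "sample_registry")
}

#' @export
print.sample_registry <- function(x, ...) {
  cat("<sample_registry> ", length(x$sample_ids), " samples, ",
      length(x$membership), " omic(s)\n", sep = "")
  for (o in names(x$membership)) {
    cat("  ", o, ": ", sum(x$membership[[o]]), " measured\n", sep = "")
  }
  invisible(x)
}

#' Load omic matrices from delimited files
#'
#' Each file is a delimited numeric matrix with a header row of sample ids and
#' a first column of feature ids (the common omics convention,
#' features x samples). Use `transpose = TRUE` for samples-in-rows files.
#'
#' @param paths Character vector of file paths (TSV or CSV, sniffed from the
#'   extension). Names, when present, become omic ids; otherwise file stems.
#' @param transpose Logical; set `TRUE` when rows are samples.
#' @param drop_constant Passed on to [omic_matrix()].
#'
#' @return A list with `omics` (list of [omic_matrix()]) and `registry`
#'   (the [sample_registry()] over their union).
#' @export
load_omics <- function(paths, transpose = FALSE, drop_constant = TRUE) {
  ids <- names(paths) %||% sub("\\.[^.]*$", "", basename(paths))
  omics <- purrr::map2(paths, ids, function(path, id) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    tb <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                            progress = FALSE, show_col_types = FALSE)
    if (ncol(tb) < 2L) stop("'", path, "': no data columns", call. = FALSE)
    row_ids <- as.character(tb[[1L]])
    mat <- as.matrix(tb[, -1L, drop = FALSE])
    if (!is.numeric(mat)) {
      bad <- colnames(tb[, -1L])[!vapply(tb[, -1L], is.numeric, logical(1))]
      stop("'", path, "': non-numeric column(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    rownames(mat) <- row_ids
    if (transpose) mat <- t(mat)
    omic_matrix(mat, omic_id = id, drop_constant = drop_constant)
  })
  names(omics) <- ids
  list(omics = omics, registry = sample_registry(omics))
}

#' Restrict a set of omics to a subset of samples
#'
#' @param omics List of [omic_matrix()] objects.
#' @param keep_ids Sample ids to keep (order preserved per omic).
#' @return List with subset `omics` (omics left without samples are dropped)
#'   and a rebuilt `registry`.
#' @export
subset_omics <- function(omics, keep_ids) {
  out <- lapply(omics, function(o) {
    keep <- o$sample_ids %in% keep_ids
    if (!any(keep)) return(NULL)
    omic_matrix(o$values[, keep, drop = FALSE], o$omic_id,
                feature_ids = o$feature_ids,
                sample_ids = o$sample_ids[keep], drop_constant = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) stop("no omic retains any sample", call. = FALSE)
  list(omics = out, registry = sample_registry(out))
}
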