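#' Expression matrix container
#'
#' A thin S3 wrapper around a features x samples numeric matrix plus a logical
#' detection matrix of the same shape (`TRUE` = the probe was called present
#' in that sample). All pipeline stages take and return this object; tabular
#' views are available through [expr_tbl()].
#'
#' @param values Numeric matrix, features in rows, samples in columns. Must
#'   carry unique row and column names (feature and sample identifiers).
#' @param detected Logical matrix of the same dimensions, or `NULL` for
#'   all-detected.
#' @param log2_scale Logical flag recording whether `values` are on the log2
#'   scale (set by [log2_transform()]).
#' @return An object of class `mir_expr`.
#' @examples
#' m <- matrix(2^rnorm(6, 5), 3, 2,
#'             dimnames = list(paste0("miR-", 1:3), c("s1", "s2")))
#' e <- mir_expr(m)
#' dim(e)
#' @export
mir_expr <- function(values, detected = NULL, log2_scale = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (features x samples).")
  }
  fid <- rownames(values)
  sid <- colnames(values)
  if (nrow(values) == 0L) fid <- character()
  if (ncol(values) == 0L) sid <- character()
  if (is.null(fid) || is.null(sid)) {
    abort("`values` must have feature row names and sample column names.")
  }
  dimnames(values) <- list(fid, sid)
  fid <- trimws(fid)
  sid <- trimws(sid)
  if (anyDuplicated(fid)) {
    abort(sprintf("Duplicate feature ID: '%s'.", fid[duplicated(fid)][1]))
  }
  if (anyDuplicated(sid)) {
    abort(sprintf("Duplicate sample ID: '%s'.", sid[duplicated(sid)][1]))
  }
  rownames(values) <- fid
  colnames(values) <- sid
  if (is.null(detected)) {
    detected <- matrix(TRUE, nrow(values), ncol(values), dimnames = dimnames(values))
  }
  if (!is.logical(detected) || !identical(dim(detected), dim(values))) {
    abort("`detected` must be a logical matrix with the same shape as `values`.")
  }
  dimnames(detected) <- dimnames(values)
  structure(
    list(values = values, detected = detected, log2_scale = isTRUE(log2_scale)),
    class = "mir_expr"
  )
}

#' @export
dim.mir_expr <- function(x) dim(x$values)

#' Feature and sample identifiers of an expression object
#' @param x A [mir_expr] object.
#' @return Character vector of IDs.
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname feature_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' @export
print.mir_expr <- function(x, ...) {
  cat(sprintf(
    "<mir_expr> %d features x %d samples (%s scale, %.1f%% detected)\n",
    nrow(x$values), ncol(x$values),
    if (x$log2_scale) "log2" else "raw",
    100 * mean(x$detected)
  ))
  invisible(x)
}

#' Subset an expression object
#'
#' @param x A [mir_expr] object.
#' @param features,samples Character, logical or integer index into rows /
#'   columns; `NULL` keeps everything.
#' @return A [mir_expr] object.
#' @export
expr_subset <- function(x, features = NULL, samples = NULL) {
  f <- features %||% seq_len(nrow(x$values))
  s <- samples %||% seq_len(ncol(x$values))
  mir_expr(x$values[f, s, drop = FALSE], x$detected[f, s, drop = FALSE],
           log2_scale = x$log2_scale)
}

#' Long tabular view of an expression object
#'
#' @param x A [mir_expr] object.
#' @return A tibble with columns `feature_id`, `sample_id`, `value`,
#'   `detected`; one row per cell, suitable for dplyr/ggplot2 work.
#' @export
expr_tbl <- function(x) {
  stopifnot(inherits(x, "mir_expr"))
  tibble(
    feature_id = rep(feature_ids(x), times = ncol(x$values)),
    sample_id = rep(sample_ids(x), each = nrow(x$values)),
    value = as.vector(x$values),
    detected = as.vector(x$detected)
  )
}

#' @export
as.matrix.mir_expr <- function(x, ...) x$values
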