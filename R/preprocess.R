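#' Quantile normalization
#'
#' Forces every sample (column) to share the same value distribution: each
#' column's order statistics are replaced by the across-sample mean of order
#' statistics, ties resolved by average rank. Delegates to
#' `limma::normalizeQuantiles(ties = TRUE)`.
#'
#' @param x A [mir_expr] object with at least 2 samples.
#' @return A [mir_expr] with identical column value multisets; detection
#'   flags untouched.
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "mir_expr"))
  if (ncol(x$values) < 2L) abort("Quantile normalization needs >= 2 samples.")
  qn <- limma::normalizeQuantiles(x$values, ties = TRUE)
  dimnames(qn) <- dimnames(x$values)
  mir_expr(qn, x$detected, log2_scale = x$log2_scale)
}

#' Log2 transform
#'
#' @param x A [mir_expr] object with positive values (or configure `offset`).
#' @param offset Non-negative constant added before taking logs (use 1 for
#'   intensity data containing zeros). Default 0.
#' @return A [mir_expr] on the log2 scale; detection flags untouched.
#' @export
log2_transform <- function(x, offset = 0) {
  stopifnot(inherits(x, "mir_expr"))
  assert_scalar_number(offset, "offset", min = 0)
  shifted <- x$values + offset
  if (any(shifted <= 0, na.rm = TRUE)) {
    bad <- which(shifted <= 0, arr.ind = TRUE)
    abort(sprintf(
      "Non-positive value(s) without a sufficient offset, e.g. feature '%s' sample '%s' (%g). %d cell(s) affected.",
      rownames(x$values)[bad[1, 1]], colnames(x$values)[bad[1, 2]],
      x$values[bad[1, , drop = FALSE]], nrow(bad)))
  }
  mir_expr(log2(shifted), x$detected, log2_scale = TRUE)
}

#' Detection-rate and expression-level feature filters
#'
#' Keeps a feature only if (1) it is detected in at least `detection_fraction`
#' of the samples and (2) the 3rd quartile (type-7) of its log2 values is not
#' below `q3_min`. The detection rule is applied first; the Q3 rule only to
#' its survivors, so the two removal sets are disjoint. Missing values in
#' surviving features are imputed by the feature median (with a message).
#'
#' @param x A log2-scale [mir_expr] with detection flags.
#' @param detection_fraction Minimum detected fraction (default 0.5).
#' @param q3_min Minimum allowed Q3 of log2 expression (default 3.5); a
#'   feature with Q3 exactly at the threshold is kept.
#' @return A list with `expr` (filtered [mir_expr]) and `report`, a tibble
#'   with one row per filter stage (`n_input`, `n_kept`, `removed` list
#'   column, thresholds).
#' @export
filter_features <- function(x, detection_fraction = 0.5, q3_min = 3.5) {
  stopifnot(inherits(x, "mir_expr"))
  assert_scalar_number(detection_fraction, "detection_fraction", min = 0, max = 1)
  assert_scalar_number(q3_min, "q3_min")
  if (!x$log2_scale) {
    warn("filter_features() expects log2-scale values; flag not set.")
  }
  det_frac <- rowMeans(x$detected)
  keep_det <- det_frac >= detection_fraction
  removed_det <- feature_ids(x)[!keep_det]

  x1 <- expr_subset(x, features = keep_det)
  q3 <- apply(x1$values, 1L, quantile, probs = 0.75, na.rm = TRUE, type = 7)
  keep_q3 <- q3 >= q3_min  # strictly-below rule: boundary features stay
  removed_q3 <- feature_ids(x1)[!keep_q3]
  out <- expr_subset(x1, features = keep_q3)

  if (nrow(out$values) == 0L) {
    warn("All features removed by the filters; returning an empty matrix.")
  } else if (anyNA(out$values)) {
    med <- apply(out$values, 1L, median, na.rm = TRUE)
    idx <- which(is.na(out$values), arr.ind = TRUE)
    out$values[idx] <- med[idx[, 1L]]
    inform(sprintf("Imputed %d missing value(s) by feature medians.", nrow(idx)))
  }
  report <- tibble(
    rule = c("detection", "q3"),
    threshold = c(detection_fraction, q3_min),
    n_input = c(nrow(x$values), nrow(x1$values)),
    n_kept = c(nrow(x1$values), nrow(out$values)),
    removed = list(removed_det, removed_q3)
  )
  list(expr = out, report = report)
}

#' Spearman sample-outlier detection
#'
#' Computes, for every sample, the mean Spearman correlation against all
#' other samples and flags those below `min_mean_rho`. The rule is applied
#' once (no re-computation after removal). Constant sample vectors are
#' assigned rho 0 against every partner, with a warning.
#'
#' @param x A [mir_expr] with at least 3 samples.
#' @param min_mean_rho Threshold on the mean pairwise Spearman rho
#'   (default 0.85).
#' @return A tibble with `sample_id`, `mean_rho`, `outlier`.
#' @export
detect_outlier_samples <- function(x, min_mean_rho = 0.85) {
  stopifnot(inherits(x, "mir_expr"))
  if (ncol(x$values) < 3L) abort("Outlier detection needs >= 3 samples.")
  assert_scalar_number(min_mean_rho, "min_mean_rho", min = -1, max = 1)
  v <- x$values
  const <- apply(v, 2L, function(col) sd(col, na.rm = TRUE) == 0 || all(is.na(col)))
  rho <- suppressWarnings(cor(v, method = "spearman", use = "pairwise.complete.obs"))
  if (any(const)) {
    warn(sprintf("Constant sample vector(s): %s; their correlations are set to 0.",
                 paste(colnames(v)[const], collapse = ", ")))
    rho[const, ] <- 0
    rho[, const] <- 0
  }
  diag(rho) <- NA
  mean_rho <- rowMeans(rho, na.rm = TRUE)
  tibble(sample_id = colnames(v), mean_rho = unname(mean_rho),
         outlier = unname(mean_rho < min_mean_rho))
}

#' Run the full preprocessing chain
#'
#' Quantile normalization, log2 transform (skipped when the input is already
#' on the log2 scale), detection filter, Q3 expression filter, and single-pass
#' Spearman outlier removal, in that order.
#'
#' @param x A [mir_expr] (raw intensities or log2 values).
#' @param detection_fraction,q3_min,min_mean_rho Stage thresholds; see
#'   [filter_features()] and [detect_outlier_samples()].
#' @param log2_offset Offset for the log2 step on raw data.
#' @return A list with `expr` (preprocessed [mir_expr]), `filter_report`, and
#'   `outlier_report`.
#' @export
preprocess_expression <- function(x, detection_fraction = 0.5, q3_min = 3.5,
                                  min_mean_rho = 0.85, log2_offset = 0) {
  x <- quantile_normalize(x)
  if (!x$log2_scale) x <- log2_transform(x, offset = log2_offset)
  filt <- filter_features(x, detection_fraction, q3_min)
  out <- filt$expr
  outliers <- detect_outlier_samples(out, min_mean_rho)
  if (any(outliers$outlier)) {
    out <- expr_subset(out, samples = !outliers$outlier)
  }
  list(expr = out, filter_report = filt$report, outlier_report = outliers)
}
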