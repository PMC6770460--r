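#' Principal component analysis of an expression matrix
#'
#' Samples are the observations, features the variables (features are
#' centered, optionally scaled). Built on `prcomp` (SVD). Loading signs are
#' normalized so that each component's largest-magnitude loading is positive,
#' removing the sign ambiguity of the decomposition.
#'
#' @param x A [mir_expr] object.
#' @param center,scale Passed to `prcomp` (defaults: centered, unscaled).
#' @return A `mir_pca` object with tibbles `scores` (sample_id, PC columns),
#'   `loadings` (feature_id, PC columns), and `variance` (component,
#'   proportion of variance, cumulative).
#' @export
run_pca <- function(x, center = TRUE, scale = FALSE) {
  stopifnot(inherits(x, "mir_expr"))
  if (ncol(x$values) < 2L) abort("PCA needs at least 2 samples.")
  if (scale) {
    zero_var <- apply(x$values, 1L, sd) == 0
    if (any(zero_var)) {
      abort(sprintf("Zero-variance feature(s) with scale=TRUE: %s.",
                    paste(head(feature_ids(x)[zero_var], 5), collapse = ", ")))
    }
  }
  p <- prcomp(t(x$values), center = center, scale. = scale)
  # sign convention: dominant loading positive per component
  flip <- apply(p$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  p$rotation <- sweep(p$rotation, 2L, flip, `*`)
  p$x <- sweep(p$x, 2L, flip, `*`)
  varfrac <- p$sdev^2 / sum(p$sdev^2)
  structure(list(
    scores = dplyr::bind_cols(tibble(sample_id = sample_ids(x)),
                              as_tibble(p$x)),
    loadings = dplyr::bind_cols(tibble(feature_id = feature_ids(x)),
                                as_tibble(p$rotation)),
    variance = tibble(component = seq_along(varfrac),
                      proportion = varfrac,
                      cumulative = cumsum(varfrac))
  ), class = "mir_pca")
}

#' @export
print.mir_pca <- function(x, ...) {
  cat(sprintf("<mir_pca> %d samples, %d components; PC1+PC2 = %.1f%% variance\n",
              nrow(x$scores), nrow(x$variance),
              100 * x$variance$cumulative[min(2L, nrow(x$variance))]))
  invisible(x)
}

#' Select features with high PCA loadings
#'
#' Returns the features whose loading magnitude on any of the selected
#' components exceeds the threshold, together with summary mean absolute
#' loadings for the selected set and for all features (for comparing the
#' informativeness of feature subsets).
#'
#' @param pca A `mir_pca` from [run_pca()].
#' @param components Integer vector of components to inspect (default 1:2).
#' @param threshold Loading-magnitude cutoff (default 0.1); must be >= 0.
#' @return A list with `features` (tibble feature_id, max_abs_loading),
#'   `mean_abs_selected`, and `mean_abs_all` (means of per-feature maximum
#'   absolute loadings over the chosen components).
#' @export
select_high_loading_features <- function(pca, components = 1:2, threshold = 0.1) {
  stopifnot(inherits(pca, "mir_pca"))
  if (threshold < 0) abort("`threshold` must be >= 0.")
  pcs <- paste0("PC", components)
  missing <- setdiff(pcs, names(pca$loadings))
  if (length(missing)) {
    abort(sprintf("Component(s) not present: %s.", paste(missing, collapse = ", ")))
  }
  lmat <- abs(as.matrix(pca$loadings[pcs]))
  max_abs <- apply(lmat, 1L, max)
  sel <- max_abs > threshold
  list(
    features = tibble(feature_id = pca$loadings$feature_id[sel],
                      max_abs_loading = max_abs[sel]) |>
      dplyr::arrange(dplyr::desc(.data$max_abs_loading)),
    mean_abs_selected = if (any(sel)) mean(max_abs[sel]) else NA_real_,
    mean_abs_all = mean(max_abs)
  )
}

#' Mean absolute loading of a feature set
#'
#' Convenience summary for contrasting e.g. up- and down-regulated feature
#' sets against the full feature population.
#'
#' @param pca A `mir_pca`.
#' @param features Character vector of feature IDs.
#' @param components Components over which the per-feature max |loading| is
#'   taken (default 1:2).
#' @return A single number.
#' @export
mean_abs_loading <- function(pca, features, components = 1:2) {
  stopifnot(inherits(pca, "mir_pca"))
  pcs <- paste0("PC", components)
  lmat <- abs(as.matrix(pca$loadings[pcs]))
  max_abs <- apply(lmat, 1L, max)
  idx <- match(features, pca$loadings$feature_id)
  if (anyNA(idx)) abort("Unknown feature ID(s) in `features`.")
  mean(max_abs[idx])
}

#' @rdname run_pca
#' @param object A `mir_pca` object (for `autoplot`).
#' @param annotation Optional annotation tibble joined by `sample_id`.
#' @param colour Optional annotation column name to colour samples by.
#' @param ... Unused.
#' @export
autoplot.mir_pca <- function(object, annotation = NULL, colour = NULL, ...) {
  df <- object$scores
  if (!is.null(annotation)) df <- dplyr::left_join(df, annotation, by = "sample_id")
  pv <- 100 * object$variance$proportion
  gg <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", pv[1]),
                  y = sprintf("PC2 (%.1f%%)", pv[2]))
  if (!is.null(colour)) {
    gg <- gg + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]), size = 2)
  } else {
    gg <- gg + ggplot2::geom_point(size = 2)
  }
  gg + ggplot2::theme_minimal()
}
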