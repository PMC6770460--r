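#' Z-score scaling per feature
#'
#' Standardizes every feature row to mean 0 and sample SD 1 (n - 1
#' denominator) across samples. Zero-variance features cannot be scaled and
#' are dropped with a warning.
#'
#' @param x A [mir_expr] with >= 2 samples.
#' @return A [mir_expr] of z-scores.
#' @export
zscore_by_feature <- function(x) {
  stopifnot(inherits(x, "mir_expr"))
  if (ncol(x$values) < 2L) abort("Z-scoring needs more than one sample.")
  sds <- apply(x$values, 1L, sd)
  if (any(sds == 0)) {
    warn(sprintf("Dropping %d zero-variance feature(s) before z-scaling.",
                 sum(sds == 0)))
    x <- expr_subset(x, features = sds > 0)
    sds <- sds[sds > 0]
  }
  z <- (x$values - rowMeans(x$values)) / sds
  mir_expr(z, x$detected, log2_scale = x$log2_scale)
}

#' Cluster temporal expression profiles
#'
#' Reduces each feature to its mean z-score per timepoint (a 4-vector over
#' E1, A1, E2, A2) and partitions the features into `k` wave-pattern clusters
#' with Lloyd k-means (Euclidean distance, `n_init` restarts under a fixed
#' seed) or, alternatively, hierarchical clustering with complete linkage
#' (`method = "hclust"`). Cluster labels are relabeled deterministically:
#' descending magnitude of the centroid's first peak (A1 - E1), positive
#' direction first on ties.
#'
#' @param xz A z-scored [mir_expr] (see [zscore_by_feature()]).
#' @param annotation Annotation tibble with `sample_id` and `timepoint`; all
#'   four timepoints must be present.
#' @param k Number of clusters (default 6).
#' @param seed Integer seed for the k-means restarts.
#' @param n_init Number of k-means restarts (default 50).
#' @param method `"kmeans"` (default) or `"hclust"`.
#' @param scale_profiles Standardize each feature's 4-point profile (mean 0,
#'   sd 1) before clustering (default `TRUE`). The wave clusters are shape
#'   families; without this, Euclidean distance partitions features by
#'   response amplitude rather than by temporal shape.
#' @return A `mir_clusters` object: `assignment` (tibble `feature_id`,
#'   `cluster`), `profiles` (per-feature mean z per timepoint), `centroids`
#'   (per-cluster mean profile), `sizes`, and `curves` (smoothed cubic
#'   B-spline centroid curves on a fine grid).
#' @export
cluster_profiles <- function(xz, annotation, k = 6, seed = 17, n_init = 50,
                             method = c("kmeans", "hclust"),
                             scale_profiles = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(xz, "mir_expr"))
  k <- assert_count(k, "k", min = 1L)
  if (k > nrow(xz$values)) abort("`k` exceeds the number of features.")
  ann <- annotation[match(sample_ids(xz), annotation$sample_id), , drop = FALSE]
  tps <- as.character(ann$timepoint)
  if (!all(TIMEPOINTS %in% tps)) {
    abort("All four timepoints (E1, A1, E2, A2) must be present.")
  }
  prof <- vapply(TIMEPOINTS, function(tp) {
    rowMeans(xz$values[, tps == tp, drop = FALSE])
  }, numeric(nrow(xz$values)))

  cl_input <- prof
  if (scale_profiles) {
    psd <- apply(prof, 1L, sd)
    psd[psd == 0] <- 1
    cl_input <- (prof - rowMeans(prof)) / psd
  }

  if (method == "kmeans") {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(derive_seed(seed, 2L))
    # Lloyd restarts occasionally produce an empty cluster and warn; those
    # restarts lose the within-SS competition, so the warning is noise
    km <- withCallingHandlers(
      kmeans(cl_input, centers = k, nstart = n_init,
             algorithm = "Lloyd", iter.max = 200),
      warning = function(w) {
        if (grepl("empty cluster", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    raw_lab <- km$cluster
    cents <- do.call(rbind, lapply(seq_len(k), function(cl) {
      colMeans(prof[raw_lab == cl, , drop = FALSE])
    }))
    colnames(cents) <- TIMEPOINTS
  } else {
    hc <- hclust(dist(cl_input), method = "complete")
    raw_lab <- cutree(hc, k = k)
    cents <- do.call(rbind, lapply(seq_len(k), function(cl) {
      colMeans(prof[raw_lab == cl, , drop = FALSE])
    }))
    colnames(cents) <- TIMEPOINTS
  }

  # deterministic relabeling: first-peak magnitude descending, ups before downs
  fp <- cents[, "A1"] - cents[, "E1"]
  ord <- order(-abs(fp), -sign(fp))
  relabel <- match(seq_len(k), ord)
  lab <- relabel[raw_lab]
  cents <- cents[ord, , drop = FALSE]
  rownames(cents) <- paste0("C", seq_len(k))

  grid <- seq(1, 4, length.out = 81)
  curves <- purrr::map_dfr(seq_len(k), function(cl) {
    dplyr::mutate(smooth_cluster_curve(cents[cl, ], grid = grid),
                  cluster = cl, .before = 1L)
  })

  structure(list(
    assignment = tibble(feature_id = feature_ids(xz), cluster = lab),
    profiles = dplyr::bind_cols(tibble(feature_id = feature_ids(xz),
                                       cluster = lab),
                                as_tibble(prof)),
    centroids = dplyr::bind_cols(tibble(cluster = seq_len(k)),
                                 as_tibble(cents)),
    sizes = tibble(cluster = seq_len(k), n = tabulate(lab, nbins = k)),
    curves = curves, k = k, method = method
  ), class = "mir_clusters")
}

#' @export
print.mir_clusters <- function(x, ...) {
  cat(sprintf("<mir_clusters> %d clusters (%s): sizes %s\n", x$k, x$method,
              paste(x$sizes$n, collapse = "/")))
  invisible(x)
}

#' Smoothed cubic B-spline curve through a 4-timepoint profile
#'
#' Least-squares fit of a degree-`degree` B-spline basis (no interior knots)
#' to the profile values at timepoint positions 1..4, evaluated on `grid`.
#' With four support points and a cubic basis the fit has four coefficients
#' and interpolates the points exactly.
#'
#' @param profile Numeric vector of length 4 (E1, A1, E2, A2 means).
#' @param degree Spline degree, at most `length(profile) - 1` (default 3).
#' @param grid Evaluation positions in `[1, 4]`.
#' @return A tibble with columns `t` and `value`.
#' @export
smooth_cluster_curve <- function(profile, degree = 3, grid = seq(1, 4, 0.05)) {
  profile <- as.numeric(profile)
  np <- length(profile)
  if (degree > np - 1L) {
    abort(sprintf("Spline degree %d needs more than %d support points.",
                  degree, np))
  }
  tt <- seq_len(np)
  basis <- splines::bs(tt, degree = degree,
                       df = degree + 1L, intercept = TRUE,
                       Boundary.knots = c(1, np))
  coefs <- qr.coef(qr(basis), profile)
  coefs[is.na(coefs)] <- 0
  pred_basis <- splines::bs(grid, degree = degree, df = degree + 1L,
                            intercept = TRUE, Boundary.knots = c(1, np))
  tibble(t = grid, value = as.numeric(pred_basis %*% coefs))
}

#' Cluster wave-pattern plot
#'
#' @param object A `mir_clusters` object.
#' @param ... Unused.
#' @return A ggplot of per-feature profiles (grey) with the smoothed cluster
#'   curve (black), faceted by cluster.
#' @export
autoplot.mir_clusters <- function(object, ...) {
  long <- tidyr::pivot_longer(object$profiles, dplyr::all_of(TIMEPOINTS),
                              names_to = "timepoint", values_to = "z")
  long$t <- match(long$timepoint, TIMEPOINTS)
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$z, group = .data$feature_id)) +
    ggplot2::geom_line(colour = "grey70", linewidth = 0.2) +
    ggplot2::geom_line(data = object$curves,
                       ggplot2::aes(.data$t, .data$value, group = NULL),
                       colour = "black", linewidth = 0.8) +
    ggplot2::facet_wrap(~cluster, labeller = ggplot2::label_both) +
    ggplot2::scale_x_continuous(breaks = 1:4, labels = TIMEPOINTS) +
    ggplot2::labs(x = NULL, y = "mean z-score") +
    ggplot2::theme_minimal()
}
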