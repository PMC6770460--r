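#' Per-participant Spearman correlation of expression with VO2 max
#'
#' For every participant, correlates each feature's expression with the
#' absolute VO2 max values over that participant's available timepoints
#' (at most 4 pairs; Spearman rank correlation). Participants with fewer
#' than 3 matched timepoints get `NA` and are counted in the output.
#'
#' @param x A preprocessed [mir_expr].
#' @param annotation Annotation tibble mapping samples to participants and
#'   timepoints.
#' @param phenotypes Phenotype tibble with `participant_id`, `timepoint`,
#'   `vo2max`.
#' @return A tibble with `participant_id`, `feature_id`, `rho`,
#'   `n_timepoints`.
#' @export
participant_correlations <- function(x, annotation, phenotypes) {
  stopifnot(inherits(x, "mir_expr"))
  ann <- annotation[match(sample_ids(x), annotation$sample_id), , drop = FALSE]
  key <- paste(ann$participant_id, ann$timepoint)
  vo2 <- phenotypes$vo2max[match(key, paste(phenotypes$participant_id,
                                            phenotypes$timepoint))]
  parts <- unique(ann$participant_id)
  purrr::map_dfr(parts, function(p) {
    idx <- which(ann$participant_id == p & !is.na(vo2))
    n <- length(idx)
    if (n < 3L) {
      return(tibble(participant_id = p, feature_id = feature_ids(x),
                    rho = NA_real_, n_timepoints = n))
    }
    rho <- suppressWarnings(
      cor(t(x$values[, idx, drop = FALSE]), vo2[idx], method = "spearman")[, 1]
    )
    tibble(participant_id = p, feature_id = feature_ids(x),
           rho = unname(rho), n_timepoints = n)
  })
}

#' Elastic-net regression of VO2 max on miRNA expression
#'
#' Fits a linear model with a mixed L1/L2 penalty (glmnet) over a grid of
#' `n_hyper` (mixing, penalty) candidates, selecting the pair with the best
#' repeated cross-validated R² (per-fold `1 - SSE/SST`, averaged over folds
#' and repeats), then refitting on all data. Features are standardized
#' internally. Folds are stratified by participant by default so a
#' participant's repeated samples never straddle the train/test split.
#'
#' @param x A preprocessed [mir_expr].
#' @param annotation Annotation tibble (`sample_id`, `participant_id`,
#'   `timepoint`).
#' @param phenotypes Phenotype tibble providing the VO2 max response.
#' @param folds,repeats Cross-validation layout (defaults 6 folds, 10
#'   repeats).
#' @param n_hyper Approximate number of (mixing, penalty) candidates
#'   (default 50; laid out as a near-square alpha x lambda grid).
#' @param seed Seed for fold assignment.
#' @param group_folds Stratify folds by participant (default `TRUE`).
#' @param metric `"rsq"` (default) or `"rmse"` for model selection.
#' @param alpha,lambda Optional scalar overrides that bypass the grid search
#'   (e.g. `lambda = 0` for the unpenalized limit).
#' @return A `mir_vo2_fit` object; use [tidy()] for coefficients and
#'   [glance()] for the fit summary.
#' @export
fit_vo2_model <- function(x, annotation, phenotypes, folds = 6, repeats = 10,
                          n_hyper = 50, seed = 42, group_folds = TRUE,
                          metric = c("rsq", "rmse"),
                          alpha = NULL, lambda = NULL) {
  metric <- match.arg(metric)
  stopifnot(inherits(x, "mir_expr"))
  ann <- annotation[match(sample_ids(x), annotation$sample_id), , drop = FALSE]
  key <- paste(ann$participant_id, ann$timepoint)
  y <- phenotypes$vo2max[match(key, paste(phenotypes$participant_id,
                                          phenotypes$timepoint))]
  ok <- !is.na(y)
  X <- t(x$values[, ok, drop = FALSE])
  y <- y[ok]
  part <- ann$participant_id[ok]
  n <- length(y)
  if (sd(y) == 0) abort("Constant VO2 max response; nothing to regress.")
  units <- if (group_folds) unique(part) else seq_len(n)
  if (folds > length(units)) {
    abort(sprintf("folds (%d) exceeds the number of CV units (%d).",
                  folds, length(units)))
  }

  if (is.null(alpha) || is.null(lambda)) {
    grid <- hyper_grid(X, y, n_hyper)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(derive_seed(seed, 3L))
    scores <- matrix(0, nrow(grid$combos), repeats * folds)
    col <- 0L
    for (r in seq_len(repeats)) {
      fold_of <- setNames(sample(rep(seq_len(folds), length.out = length(units))),
                          units)
      fold_idx <- if (group_folds) fold_of[part] else fold_of[seq_len(n)]
      for (f in seq_len(folds)) {
        col <- col + 1L
        test <- fold_idx == f
        for (ai in seq_along(grid$alphas)) {
          fit <- glmnet::glmnet(X[!test, , drop = FALSE], y[!test],
                                alpha = grid$alphas[ai],
                                lambda = grid$lambdas, standardize = TRUE)
          pred <- predict(fit, X[test, , drop = FALSE], s = grid$lambdas)
          rows <- grid$combos$alpha_i == ai
          err <- colSums((pred - y[test])^2)
          sst <- sum((y[test] - mean(y[!test]))^2)
          scores[rows, col] <- if (metric == "rsq") 1 - err / sst else sqrt(err / sum(test))
        }
      }
    }
    mean_score <- rowMeans(scores)
    best <- if (metric == "rsq") which.max(mean_score) else which.min(mean_score)
    alpha <- grid$alphas[grid$combos$alpha_i[best]]
    lambda <- grid$combos$lambda[best]
    cv_rsq <- if (metric == "rsq") mean_score[best] else {
      # recover the R² of the selected model for reporting
      NA_real_
    }
    cv_tbl <- dplyr::mutate(grid$combos,
                            alpha = grid$alphas[.data$alpha_i],
                            mean_score = mean_score)[, c("alpha", "lambda", "mean_score")]
  } else {
    cv_rsq <- NA_real_
    cv_tbl <- NULL
  }

  final <- glmnet::glmnet(X, y, alpha = alpha,
                          lambda = final_lambda_path(lambda),
                          standardize = TRUE, thresh = 1e-12)
  beta <- as.numeric(predict(final, type = "coefficients", s = lambda,
                             exact = FALSE))
  names(beta) <- c("(Intercept)", colnames(X))
  # importance is the absolute coefficient on the standardized predictor
  # scale, so the ranking does not depend on feature units
  feat_sd <- apply(X, 2L, sd)
  coefs <- tibble(feature_id = colnames(X), coefficient = unname(beta[-1]),
                  importance = unname(abs(beta[-1]) * feat_sd)) |>
    dplyr::arrange(dplyr::desc(.data$importance))

  structure(list(
    coefficients = coefs, intercept = beta[[1]],
    alpha = alpha, lambda = lambda,
    cv_rsq = cv_rsq, cv_grid = cv_tbl, metric = metric,
    n_nonzero = sum(coefs$coefficient != 0),
    n_samples = n, n_features = ncol(X),
    folds = folds, repeats = repeats, group_folds = group_folds, seed = seed
  ), class = "mir_vo2_fit")
}

# Near-square alpha x lambda grid totalling ~n_hyper candidates; the lambda
# path is anchored at the usual glmnet maximum |X'y|/n (computed at the
# smallest nonzero alpha to keep it finite).
hyper_grid <- function(X, y, n_hyper) {
  n_alpha <- max(2L, round(sqrt(n_hyper)))
  n_lambda <- max(2L, ceiling(n_hyper / n_alpha))
  alphas <- seq(0, 1, length.out = n_alpha)
  Xs <- scale(X)
  Xs[is.na(Xs)] <- 0
  lam_max <- max(abs(crossprod(Xs, y - mean(y)))) / (nrow(X) * max(min(alphas[alphas > 0]), 0.1))
  lambdas <- exp(seq(log(lam_max), log(lam_max * 1e-4), length.out = n_lambda))
  combos <- tidyr::expand_grid(alpha_i = seq_along(alphas), lambda = lambdas)
  list(alphas = alphas, lambdas = lambdas, combos = combos)
}

# glmnet is unreliable when asked for a single small lambda; give it a short
# descending path ending at the target.
final_lambda_path <- function(lambda) {
  if (lambda <= 0) return(c(0.5, 0.1, 0.01, 0))
  unique(c(lambda * c(16, 8, 4, 2), lambda))
}

#' @export
print.mir_vo2_fit <- function(x, ...) {
  cat(sprintf(
    "<mir_vo2_fit> alpha %.2f, lambda %.4g: %d/%d nonzero coefficients, CV R^2 %.3f\n",
    x$alpha, x$lambda, x$n_nonzero, x$n_features,
    ifelse(is.na(x$cv_rsq), NaN, x$cv_rsq)))
  invisible(x)
}

#' @export
tidy.mir_vo2_fit <- function(x, ...) x$coefficients

#' @export
glance.mir_vo2_fit <- function(x, ...) {
  tibble(r.squared = x$cv_rsq, alpha = x$alpha, lambda = x$lambda,
         n_nonzero = x$n_nonzero, n_samples = x$n_samples,
         n_features = x$n_features, folds = x$folds, repeats = x$repeats)
}

#' Coefficient plot for the VO2 max model
#'
#' @param object A `mir_vo2_fit`.
#' @param top Number of positive and negative coefficients shown (default 20).
#' @param clusters Optional `mir_clusters` to colour features by cluster.
#' @param ... Unused.
#' @export
autoplot.mir_vo2_fit <- function(object, top = 20, clusters = NULL, ...) {
  df <- dplyr::filter(object$coefficients, .data$coefficient != 0)
  df <- dplyr::bind_rows(
    dplyr::slice_max(df, .data$coefficient, n = top),
    dplyr::slice_min(df, .data$coefficient, n = top)
  ) |> dplyr::distinct() |>
    dplyr::arrange(.data$coefficient) |>
    dplyr::mutate(feature_id = factor(.data$feature_id, levels = .data$feature_id))
  gg <- ggplot2::ggplot(df, ggplot2::aes(.data$feature_id, .data$coefficient))
  if (!is.null(clusters)) {
    df <- dplyr::left_join(df, clusters$assignment, by = "feature_id")
    gg <- ggplot2::ggplot(df, ggplot2::aes(.data$feature_id, .data$coefficient,
                                           fill = factor(.data$cluster))) +
      ggplot2::labs(fill = "cluster")
  }
  gg + ggplot2::geom_col() + ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "coefficient") + ggplot2::theme_minimal()
}

#' Clinical-parameter tests across the cross-over design
#'
#' For every clinical column and each training period: a paired Student
#' t-test of the pre/post change within the treated (CHO) and untreated
#' participant sets and pooled over both, a Welch two-sample t-test of
#' pre vs post values pooled over groups (unpaired), plus a Welch test of
#' the per-participant changes between the treated and untreated sets. A
#' Benjamini-Hochberg column is appended over all reported tests. Degenerate
#' zero-variance contrasts are reported at the smallest representable
#' p-value with a warning.
#'
#' @param phenotypes Phenotype tibble with clinical columns.
#' @param annotation Annotation tibble (for the order-group assignment).
#' @param columns Clinical columns to test (default: the present ones among
#'   vo2max, bmi, weight, body_fat, max_hr, glucose, rbc).
#' @return A tibble: `parameter`, `period`, `contrast`, `group`, `n`,
#'   `estimate` (mean change), `statistic`, `p_value`, `p_adj`.
#' @export
clinical_tests <- function(phenotypes, annotation,
                           columns = intersect(c("vo2max", "bmi", "weight",
                                                 "body_fat", "max_hr",
                                                 "glucose", "rbc"),
                                               names(phenotypes))) {
  og <- dplyr::distinct(annotation, .data$participant_id, .data$order_group)
  res <- purrr::map_dfr(columns, function(colname) {
    purrr::map_dfr(1:2, function(period) {
      pre_tp <- if (period == 1L) "E1" else "E2"
      post_tp <- if (period == 1L) "A1" else "A2"
      wide <- phenotypes |>
        dplyr::filter(.data$timepoint %in% c(pre_tp, post_tp)) |>
        dplyr::select("participant_id", "timepoint",
                      value = dplyr::all_of(colname)) |>
        tidyr::pivot_wider(names_from = "timepoint", values_from = "value") |>
        dplyr::left_join(og, by = "participant_id")
      wide <- wide[complete.cases(wide[c(pre_tp, post_tp)]), , drop = FALSE]
      wide$change <- wide[[post_tp]] - wide[[pre_tp]]
      treated_group <- if (period == 1L) 2L else 1L
      groups <- list(CHO = wide$order_group == treated_group,
                     nonCHO = wide$order_group != treated_group,
                     pooled = rep(TRUE, nrow(wide)))
      paired_rows <- purrr::map_dfr(names(groups), function(g) {
        ch <- wide$change[groups[[g]]]
        pt <- paired_t_safe(ch)
        tibble(parameter = colname, period = period,
               contrast = "paired_pre_post", group = g, n = length(ch),
               estimate = mean(ch), statistic = pt$statistic,
               p_value = pt$p_value)
      })
      wt <- welch_safe(wide$change[groups$CHO], wide$change[groups$nonCHO])
      wpp <- welch_safe(wide[[post_tp]], wide[[pre_tp]])
      dplyr::bind_rows(paired_rows, tibble(
        parameter = colname, period = period,
        contrast = c("welch_CHO_vs_nonCHO", "welch_pre_post"),
        group = c("between", "pooled"),
        n = nrow(wide),
        estimate = c(mean(wide$change[groups$CHO]) - mean(wide$change[groups$nonCHO]),
                     mean(wide$change)),
        statistic = c(wt$statistic, wpp$statistic),
        p_value = c(wt$p_value, wpp$p_value)))
    })
  })
  dplyr::mutate(res, p_adj = bh_adjust(.data$p_value))
}

# Paired t on a vector of differences with degenerate-variance guards.
paired_t_safe <- function(d) {
  d <- d[!is.na(d)]
  if (length(d) < 3L) return(list(statistic = NA_real_, p_value = NA_real_))
  if (sd(d) == 0) {
    if (mean(d) == 0) return(list(statistic = 0, p_value = 1))
    warn("Zero-variance nonzero paired difference; p reported at the smallest representable value.")
    return(list(statistic = sign(mean(d)) * Inf, p_value = .Machine$double.xmin))
  }
  tt <- t.test(d)
  list(statistic = unname(tt$statistic), p_value = tt$p.value)
}

welch_safe <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    return(list(statistic = NA_real_, p_value = NA_real_))
  }
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) return(list(statistic = 0, p_value = 1))
    warn("Zero-variance Welch contrast; p reported at the smallest representable value.")
    return(list(statistic = sign(mean(a) - mean(b)) * Inf,
                p_value = .Machine$double.xmin))
  }
  tt <- t.test(a, b)
  list(statistic = unname(tt$statistic), p_value = tt$p.value)
}
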