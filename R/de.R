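#' The six pre/post comparison setups of the cross-over design
#'
#' Period 1 compares E1 vs A1, period 2 compares E2 vs A2; each period is
#' analyzed pooled over both order groups, restricted to the participants who
#' trained with the glucose supplement in that period (`CHO_*`), and
#' restricted to those who trained without it (`nonCHO_*`).
#'
#' @return A tibble with columns `setup`, `period`, `pre`, `post`, `subset`
#'   (`"all"`, `"treated"`, `"untreated"`).
#' @export
comparison_setups <- function() {
  tibble(
    setup = c("pooled_P1", "CHO_P1", "nonCHO_P1",
              "pooled_P2", "CHO_P2", "nonCHO_P2"),
    period = rep(1:2, each = 3),
    pre = rep(c("E1", "E2"), each = 3),
    post = rep(c("A1", "A2"), each = 3),
    subset = rep(c("all", "treated", "untreated"), 2)
  )
}

#' Pre/post differential expression for one comparison setup
#'
#' Per feature, compares post-training to pre-training samples of the setup's
#' period with a paired Student t-test across participants that have both
#' samples (default) or a Welch two-sample t-test (`paired = FALSE`).
#' `log2FC` is the post-mean minus pre-mean on the log2 scale. A feature is
#' called `up` when `log2FC >= fc_min` and `p < p_max`, `down` when
#' `log2FC <= -fc_min` and `p < p_max`, else `none`. Degenerate features with
#' a nonzero constant paired difference are reported at the smallest
#' representable p-value (with a message); all-zero differences give t = 0,
#' p = 1.
#'
#' @param x A preprocessed [mir_expr].
#' @param annotation Annotation tibble (from [read_annotation()] /
#'   [simulate_study()]).
#' @param setup One of the ids in [comparison_setups()], or a one-row subset
#'   of that tibble.
#' @param paired Paired by participant (default) or Welch unpaired.
#' @param fc_min Absolute log2 fold-change threshold (default 1).
#' @param p_max Unadjusted p-value threshold (default 0.05).
#' @return A `mir_de` object; its `table` is a tibble with `feature_id`,
#'   `log2fc`, `statistic`, `p_value`, `p_adj` (Benjamini-Hochberg),
#'   `direction`, plus `n_pairs`/`n_pre`/`n_post`.
#' @export
run_de <- function(x, annotation, setup = "pooled_P1", paired = TRUE,
                   fc_min = 1, p_max = 0.05) {
  stopifnot(inherits(x, "mir_expr"))
  if (is.character(setup)) {
    su <- comparison_setups()
    if (!setup %in% su$setup) {
      abort(sprintf("Unknown setup '%s'. Use one of: %s.", setup,
                    paste(su$setup, collapse = ", ")))
    }
    su <- su[su$setup == setup, ]
  } else {
    su <- as_tibble(setup)
  }
  ann <- annotation[match(sample_ids(x), annotation$sample_id), , drop = FALSE]
  if (anyNA(ann$sample_id)) {
    abort("Annotation must cover every expression sample (see align_samples()).")
  }
  keep <- switch(su$subset,
                 all = rep(TRUE, nrow(ann)),
                 treated = ann$treated_period &
                   ann$timepoint %in% c(su$pre, su$post),
                 untreated = !ann$treated_period &
                   ann$timepoint %in% c(su$pre, su$post))
  # for "treated"/"untreated" the period restriction is implied by timepoints;
  # for "all" restrict to the period's two timepoints
  keep <- keep & ann$timepoint %in% c(su$pre, su$post)
  ann <- ann[keep, , drop = FALSE]
  pre_ids <- ann$sample_id[ann$timepoint == su$pre]
  post_ids <- ann$sample_id[ann$timepoint == su$post]
  pre_part <- ann$participant_id[ann$timepoint == su$pre]
  post_part <- ann$participant_id[ann$timepoint == su$post]

  v <- x$values
  if (paired) {
    shared <- intersect(pre_part, post_part)
    if (length(shared) < 3L) {
      abort("Paired analysis needs >= 3 participants with both timepoints.")
    }
    pre_m <- v[, pre_ids[match(shared, pre_part)], drop = FALSE]
    post_m <- v[, post_ids[match(shared, post_part)], drop = FALSE]
    d <- post_m - pre_m
    nn <- ncol(d)
    mdiff <- rowMeans(d)
    sdd <- apply(d, 1L, sd)
    tstat <- mdiff / (sdd / sqrt(nn))
    p <- 2 * stats::pt(abs(tstat), df = nn - 1, lower.tail = FALSE)
    degen <- sdd == 0
    if (any(degen & mdiff != 0)) {
      inform(sprintf(
        "%d feature(s) with constant nonzero paired difference; p set to the smallest representable value.",
        sum(degen & mdiff != 0)))
      tstat[degen & mdiff != 0] <- sign(mdiff[degen & mdiff != 0]) * Inf
      p[degen & mdiff != 0] <- .Machine$double.xmin
    }
    tstat[degen & mdiff == 0] <- 0
    p[degen & mdiff == 0] <- 1
    log2fc <- rowMeans(post_m) - rowMeans(pre_m)
    n_pre <- n_post <- n_pairs <- nn
  } else {
    if (length(pre_ids) < 3L || length(post_ids) < 3L) {
      abort("Welch analysis needs >= 3 samples per timepoint.")
    }
    pre_m <- v[, pre_ids, drop = FALSE]
    post_m <- v[, post_ids, drop = FALSE]
    wt <- welch_rows(post_m, pre_m)
    tstat <- wt$statistic
    p <- wt$p_value
    log2fc <- rowMeans(post_m) - rowMeans(pre_m)
    n_pairs <- NA_integer_
    n_pre <- ncol(pre_m); n_post <- ncol(post_m)
  }

  tab <- tibble(
    feature_id = rownames(v),
    log2fc = unname(log2fc), statistic = unname(tstat), p_value = unname(p),
    p_adj = bh_adjust(p),
    direction = dplyr::case_when(
      is.na(p) ~ NA_character_,
      log2fc >= fc_min & p < p_max ~ "up",
      log2fc <= -fc_min & p < p_max ~ "down",
      TRUE ~ "none"
    ),
    n_pairs = n_pairs, n_pre = n_pre, n_post = n_post
  )
  structure(list(table = tab, setup = su$setup, paired = paired,
                 fc_min = fc_min, p_max = p_max),
            class = "mir_de")
}

# Row-wise Welch t-test from two matrices (features x samples).
welch_rows <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  va <- apply(a, 1L, var); vb <- apply(b, 1L, var)
  se2 <- va / na + vb / nb
  tstat <- (rowMeans(a) - rowMeans(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  zero <- se2 == 0
  if (any(zero)) {
    tstat[zero] <- ifelse(rowMeans(a)[zero] == rowMeans(b)[zero], 0, Inf)
    p[zero] <- ifelse(tstat[zero] == 0, 1, .Machine$double.xmin)
  }
  list(statistic = tstat, df = df, p_value = p)
}

#' @export
print.mir_de <- function(x, ...) {
  cnt <- table(factor(x$table$direction, c("up", "down", "none")))
  cat(sprintf("<mir_de> setup %s (%s): %d up, %d down of %d features\n",
              x$setup, if (x$paired) "paired t" else "Welch t",
              cnt[["up"]], cnt[["down"]], nrow(x$table)))
  invisible(x)
}

#' @export
tidy.mir_de <- function(x, ...) x$table

#' Run all six comparison setups
#'
#' @inheritParams run_de
#' @return A tibble binding the per-setup [run_de()] tables with a `setup`
#'   column.
#' @export
run_all_de <- function(x, annotation, paired = TRUE, fc_min = 1, p_max = 0.05) {
  su <- comparison_setups()
  purrr::map_dfr(su$setup, function(s) {
    dplyr::mutate(run_de(x, annotation, s, paired, fc_min, p_max)$table,
                  setup = s, .before = 1L)
  })
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (monotone in rank, capped at 1);
#' wraps `p.adjust(method = "BH")` after validating the input range.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA passed through).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

#' Fisher exact test on the overlap of two de-regulated feature sets
#'
#' Builds the 2x2 table `[[|A∩B|, |A\\B|], [|B\\A|, U - |A∪B|]]` over a
#' universe of `universe_size` features (default construction) and returns
#' the two-sided Fisher exact p-value. The alternative `"union"`
#' construction restricts the universe to `A ∪ B` (last cell 0), for
#' sensitivity analyses of how the table is framed.
#'
#' @param set_a,set_b Character vectors of feature IDs.
#' @param universe_size Total number of features tested; must be at least
#'   `|A ∪ B|`.
#' @param construction `"universe"` (default) or `"union"`.
#' @return A list with `table` (2x2 matrix) and `p_value`.
#' @export
fisher_set_difference <- function(set_a, set_b, universe_size,
                                  construction = c("universe", "union")) {
  construction <- match.arg(construction)
  set_a <- unique(set_a); set_b <- unique(set_b)
  both <- length(intersect(set_a, set_b))
  only_a <- length(setdiff(set_a, set_b))
  only_b <- length(setdiff(set_b, set_a))
  u <- length(union(set_a, set_b))
  if (universe_size < u) abort("`universe_size` is smaller than |A ∪ B|.")
  rest <- if (construction == "universe") universe_size - u else 0L
  tab <- matrix(c(both, only_a, only_b, rest), 2L, byrow = TRUE,
                dimnames = list(c("in_A", "not_A"), c("in_B", "not_B")))
  if (any(tab < 0)) abort("Negative cell in the contingency table.")
  list(table = tab, p_value = fisher.test(tab)$p.value)
}

#' Volcano plot of a differential-expression result
#'
#' @param object A `mir_de` object.
#' @param ... Unused.
#' @return A ggplot: log2 fold change vs -log10 unadjusted p, thresholds
#'   dashed, up/down features coloured.
#' @export
autoplot.mir_de <- function(object, ...) {
  df <- dplyr::mutate(object$table,
                      direction = factor(.data$direction, c("up", "down", "none")))
  ggplot2::ggplot(df, ggplot2::aes(.data$log2fc, -log10(.data$p_value),
                                   colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(object$p_max), linetype = 2) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * object$fc_min, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(up = "firebrick", down = "seagreen",
                                            none = "grey60")) +
    ggplot2::labs(title = object$setup, x = "log2 fold change",
                  y = "-log10 p (unadjusted)") +
    ggplot2::theme_minimal()
}
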