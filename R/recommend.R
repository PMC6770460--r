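#' Assign carbohydrate-recommendation groups from VO2 max trajectories
#'
#' For each participant, computes the VO2 max change in each training period
#' (`delta1 = VO2(A1) - VO2(E1)`, `delta2 = VO2(A2) - VO2(E2)`) and
#' recommends carbohydrate supplementation (`r = 1`) exactly when the change
#' in the participant's glucose-supplemented period strictly exceeds the
#' change in the non-supplemented period — a greater improvement, or a
#' smaller worsening, under treatment. Ties give `r = 0` with a tie flag
#' (no recommendation absent evidence of benefit). Participants missing any
#' of the four VO2 values are excluded and reported with a reason.
#'
#' @param phenotypes Phenotype tibble with `participant_id`, `timepoint`,
#'   `vo2max`.
#' @param annotation Annotation tibble carrying `participant_id` and
#'   `order_group` (2 = glucose in period 1, 1 = glucose in period 2).
#' @return A `mir_recommendation` object; `assignment` is a tibble with
#'   `participant_id`, `delta1`, `delta2`, `treated_period`,
#'   `delta_treated`, `delta_untreated`, `r`, `tie`; `excluded` lists
#'   participants left out with reasons.
#' @export
assign_recommendation_groups <- function(phenotypes, annotation) {
  og <- dplyr::distinct(annotation, .data$participant_id, .data$order_group)
  if (anyDuplicated(og$participant_id)) {
    abort("A participant appears with more than one order group.")
  }
  if (!all(og$order_group %in% c(1L, 2L))) abort("Unknown order group.")
  wide <- phenotypes |>
    dplyr::select("participant_id", "timepoint", "vo2max") |>
    tidyr::pivot_wider(names_from = "timepoint", values_from = "vo2max")
  for (tp in TIMEPOINTS) if (!tp %in% names(wide)) wide[[tp]] <- NA_real_
  wide <- dplyr::inner_join(og, wide, by = "participant_id")
  no_pheno <- setdiff(og$participant_id, wide$participant_id)

  complete <- complete.cases(wide[TIMEPOINTS])
  excluded <- dplyr::bind_rows(
    tibble(participant_id = no_pheno, reason = "no phenotype rows"),
    tibble(participant_id = wide$participant_id[!complete],
           reason = "missing VO2 max value(s)")
  )
  wide <- wide[complete, , drop = FALSE]
  asg <- wide |>
    dplyr::mutate(
      delta1 = .data$A1 - .data$E1,
      delta2 = .data$A2 - .data$E2,
      treated_period = ifelse(.data$order_group == 2L, 1L, 2L),
      delta_treated = ifelse(.data$treated_period == 1L, .data$delta1, .data$delta2),
      delta_untreated = ifelse(.data$treated_period == 1L, .data$delta2, .data$delta1),
      tie = .data$delta_treated == .data$delta_untreated,
      r = as.integer(.data$delta_treated > .data$delta_untreated)
    ) |>
    dplyr::select("participant_id", "order_group", "delta1", "delta2",
                  "treated_period", "delta_treated", "delta_untreated",
                  "r", "tie")
  structure(list(assignment = asg, excluded = excluded),
            class = "mir_recommendation")
}

#' @export
print.mir_recommendation <- function(x, ...) {
  cat(sprintf("<mir_recommendation> %d recommended, %d not (%d excluded)\n",
              sum(x$assignment$r == 1L), sum(x$assignment$r == 0L),
              nrow(x$excluded)))
  invisible(x)
}

#' @export
tidy.mir_recommendation <- function(x, ...) x$assignment

#' Evaluate a marker feature across recommendation groups
#'
#' Splits the samples into four cells — pre-training (E1 or E2) vs
#' post-training (A1 or A2), crossed with whether the sample's period was the
#' participant's glucose period (+Glucose) or not (−Glucose) — and, within
#' each cell, compares the marker's expression between the two recommendation
#' groups with a Welch two-sample t-test. Additionally reports, per
#' condition and group, the Spearman correlation between the participant's
#' marker log2 fold change in that period (post − pre on the log2 scale) and
#' the VO2 max change of the same period.
#'
#' @param x A preprocessed [mir_expr].
#' @param annotation Annotation tibble.
#' @param recommendation A `mir_recommendation` from
#'   [assign_recommendation_groups()].
#' @param feature_id Marker feature to evaluate.
#' @param phenotypes Optional phenotype tibble; required for the fold-change
#'   vs delta-VO2 correlations.
#' @return A `mir_marker_eval` object with `cells` (per timepoint class x
#'   condition x group: n, mean, sd), `tests` (four Welch p-values), and
#'   `correlations` (per condition x group Spearman rho), plus `samples`,
#'   the per-sample table the summaries are built from.
#' @export
evaluate_marker <- function(x, annotation, recommendation, feature_id,
                            phenotypes = NULL) {
  stopifnot(inherits(x, "mir_expr"), inherits(recommendation, "mir_recommendation"))
  if (!feature_id %in% feature_ids(x)) {
    abort(sprintf("Feature '%s' not present in the expression matrix.", feature_id))
  }
  asg <- recommendation$assignment
  ann <- annotation[match(sample_ids(x), annotation$sample_id), , drop = FALSE]
  df <- tibble(
    sample_id = ann$sample_id,
    participant_id = ann$participant_id,
    timepoint = as.character(ann$timepoint),
    timepoint_class = ifelse(ann$timepoint %in% c("E1", "E2"), "T1_pre", "T2_post"),
    condition = ifelse(ann$treated_period, "+Glucose", "-Glucose"),
    period = ifelse(ann$timepoint %in% c("E1", "A1"), 1L, 2L),
    value = x$values[feature_id, ]
  ) |>
    dplyr::inner_join(asg[c("participant_id", "r", "delta1", "delta2")],
                      by = "participant_id")

  cells <- df |>
    dplyr::group_by(.data$timepoint_class, .data$condition, group = .data$r) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sd = sd(.data$value), .groups = "drop")

  tests <- df |>
    dplyr::group_by(.data$timepoint_class, .data$condition) |>
    dplyr::group_modify(function(d, key) {
      a <- d$value[d$r == 1L]
      b <- d$value[d$r == 0L]
      if (length(a) < 2L || length(b) < 2L) {
        return(tibble(n1 = length(a), n0 = length(b),
                      statistic = NA_real_, p_value = NA_real_))
      }
      wt <- welch_safe(a, b)
      tibble(n1 = length(a), n0 = length(b),
             statistic = wt$statistic, p_value = wt$p_value)
    }) |>
    dplyr::ungroup()

  correlations <- NULL
  if (!is.null(phenotypes) || all(c("delta1", "delta2") %in% names(asg))) {
    fc <- df |>
      dplyr::select("participant_id", "condition", "period",
                    "timepoint_class", "value", "r") |>
      tidyr::pivot_wider(names_from = "timepoint_class", values_from = "value") |>
      dplyr::filter(!is.na(.data$T1_pre) & !is.na(.data$T2_post)) |>
      dplyr::mutate(log2fc = .data$T2_post - .data$T1_pre) |>
      dplyr::inner_join(asg[c("participant_id", "delta1", "delta2")],
                        by = "participant_id") |>
      dplyr::mutate(delta_vo2 = ifelse(.data$period == 1L, .data$delta1, .data$delta2))
    correlations <- fc |>
      dplyr::group_by(.data$condition, group = .data$r) |>
      dplyr::summarise(
        n = dplyr::n(),
        rho = ifelse(dplyr::n() >= 3,
                     suppressWarnings(cor(.data$log2fc, .data$delta_vo2,
                                          method = "spearman")),
                     NA_real_),
        .groups = "drop")
  }

  structure(list(feature_id = feature_id, cells = cells, tests = tests,
                 correlations = correlations, samples = df),
            class = "mir_marker_eval")
}

#' @export
print.mir_marker_eval <- function(x, ...) {
  cat(sprintf("<mir_marker_eval> %s\n", x$feature_id))
  print(x$tests)
  invisible(x)
}

#' Marker expression plot by recommendation group
#'
#' @param object A `mir_marker_eval`.
#' @param ... Unused.
#' @export
autoplot.mir_marker_eval <- function(object, ...) {
  df <- dplyr::mutate(object$samples,
                      group = factor(.data$r, c(1, 0), c("recommended", "not recommended")))
  ggplot2::ggplot(df, ggplot2::aes(.data$timepoint_class, .data$value,
                                   fill = .data$group)) +
    ggplot2::stat_summary(fun = mean, geom = "col",
                          position = ggplot2::position_dodge(0.9), alpha = 0.7) +
    ggplot2::geom_point(position = ggplot2::position_jitterdodge(0.1, 0, 0.9),
                        size = 0.8) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(title = object$feature_id, x = NULL, y = "log2 expression") +
    ggplot2::theme_minimal()
}

#' Screen all features for the marker expression pattern
#'
#' Systematizes a candidate-marker search: a feature is a candidate when the
#' recommendation groups differ significantly in post-training samples of the
#' no-treatment period (Welch p < `alpha`) while showing no significant
#' group difference in the other three cells (pre/no-treatment,
#' pre/treatment, post/treatment). Candidates are ranked by the
#' post-training no-treatment p-value.
#'
#' @param x A preprocessed [mir_expr].
#' @param annotation Annotation tibble.
#' @param recommendation A `mir_recommendation`.
#' @param alpha Significance threshold for the four cell tests (default
#'   0.05).
#' @return A tibble with one row per feature: the four cell p-values
#'   (`p_pre_noglc`, `p_post_noglc`, `p_pre_glc`, `p_post_glc`),
#'   `candidate`, and `rank` (NA for non-candidates).
#' @export
screen_markers <- function(x, annotation, recommendation, alpha = 0.05) {
  stopifnot(inherits(x, "mir_expr"), inherits(recommendation, "mir_recommendation"))
  assert_scalar_number(alpha, "alpha", min = 0, max = 1)
  asg <- recommendation$assignment
  ann <- annotation[match(sample_ids(x), annotation$sample_id), , drop = FALSE]
  r <- asg$r[match(ann$participant_id, asg$participant_id)]
  pre <- ann$timepoint %in% c("E1", "E2")
  glc <- ann$treated_period
  cells <- list(
    p_pre_noglc = pre & !glc, p_post_noglc = !pre & !glc,
    p_pre_glc = pre & glc, p_post_glc = !pre & glc
  )
  pmat <- vapply(cells, function(sel) {
    a_cols <- which(sel & r == 1L)
    b_cols <- which(sel & r == 0L)
    if (length(a_cols) < 2L || length(b_cols) < 2L) {
      return(rep(NA_real_, nrow(x$values)))
    }
    welch_rows(x$values[, a_cols, drop = FALSE],
               x$values[, b_cols, drop = FALSE])$p_value
  }, numeric(nrow(x$values)))

  out <- dplyr::bind_cols(tibble(feature_id = feature_ids(x)),
                          as_tibble(pmat)) |>
    dplyr::mutate(
      candidate = .data$p_post_noglc < alpha &
        .data$p_pre_noglc >= alpha &
        .data$p_pre_glc >= alpha &
        .data$p_post_glc >= alpha
    )
  out$candidate[is.na(out$candidate)] <- FALSE
  out |>
    dplyr::arrange(dplyr::desc(.data$candidate), .data$p_post_noglc) |>
    dplyr::mutate(rank = ifelse(.data$candidate, cumsum(.data$candidate), NA))
}
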