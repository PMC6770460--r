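#' Read an expression matrix from disk
#'
#' Supports two plain-text layouts: `"tsv"` (header row of sample IDs, first
#' column feature IDs, optional sibling file of detection flags) and
#' `"series_matrix"`, the GEO series-matrix text layout in which lines
#' starting with `!` carry metadata and the numeric table is fenced by
#' `!series_matrix_table_begin` / `!series_matrix_table_end` markers.
#'
#' @param path Path to the expression file.
#' @param dialect `"tsv"` or `"series_matrix"`.
#' @param detected_path Optional path to a TSV of logical detection flags with
#'   the same layout; when absent all probes are treated as detected.
#' @param log2_scale Whether the stored values are already log2 (default
#'   `FALSE` for raw intensities).
#' @return A [mir_expr] object; for the series-matrix dialect the captured
#'   `!` metadata lines are attached as attribute `"metadata"`.
#' @export
read_expression <- function(path, dialect = c("tsv", "series_matrix"),
                            detected_path = NULL, log2_scale = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("Expression file not found: '%s'.", path))
  meta <- character()
  lines <- readr::read_lines(path)
  if (dialect == "series_matrix") {
    meta <- lines[startsWith(lines, "!")]
    begin <- which(lines == "!series_matrix_table_begin")
    end <- which(lines == "!series_matrix_table_end")
    if (length(begin) != 1L || length(end) != 1L || end <= begin) {
      abort("Malformed series-matrix file: missing table begin/end markers.")
    }
    lines <- lines[(begin + 1L):(end - 1L)]
    lines <- gsub('"', "", lines, fixed = TRUE)
  }
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (any(widths != widths[1])) {
    bad <- which(widths != widths[1])[1]
    abort(sprintf("Ragged row in '%s' at line %d (%d fields, expected %d).",
                  path, bad, widths[bad], widths[1]))
  }
  header <- fields[[1]]
  body <- fields[-1]
  fid <- trimws(vapply(body, `[[`, "", 1L))
  if (anyDuplicated(fid)) {
    abort(sprintf("Duplicate feature ID in '%s': '%s'.",
                  path, fid[duplicated(fid)][1]))
  }
  vals <- do.call(rbind, lapply(body, function(f) {
    suppressWarnings(as.numeric(f[-1]))
  }))
  dimnames(vals) <- list(fid, trimws(header[-1]))
  detected <- NULL
  if (!is.null(detected_path)) {
    d <- read_expression(detected_path, dialect = "tsv")
    detected <- d$values[fid, colnames(vals), drop = FALSE] > 0
  } else if (anyNA(vals)) {
    # missing raw cells are treated as undetected; value imputation happens
    # only for features that survive filtering (see preprocess)
    detected <- !is.na(vals)
  }
  out <- mir_expr(vals, detected, log2_scale = log2_scale)
  if (length(meta)) attr(out, "metadata") <- meta
  out
}

#' Write an expression object as TSV
#'
#' Emits the value matrix (first column `feature_id`, header of sample IDs)
#' and, when any probe is flagged undetected, a sibling `*.detected.tsv` of
#' 0/1 flags with the same layout.
#'
#' @param x A [mir_expr] object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "mir_expr"))
  if (nrow(x$values) == 0L) abort("Refusing to write an empty expression matrix.")
  df <- as.data.frame(x$values, check.names = FALSE)
  df <- cbind(feature_id = rownames(x$values), df)
  readr::write_tsv(as_tibble(df), path)
  if (!all(x$detected)) {
    dd <- as.data.frame(x$detected * 1L, check.names = FALSE)
    dd <- cbind(feature_id = rownames(x$values), dd)
    readr::write_tsv(as_tibble(dd), detected_sibling(path))
  }
  invisible(path)
}

detected_sibling <- function(path) sub("(\\.tsv)?$", ".detected.tsv", path)

#' Read and validate a sample-annotation table
#'
#' Requires columns `sample_id`, `participant_id`, `timepoint` (one of E1, A1,
#' E2, A2), `order_group` (1 = glucose during the second training period, 2 =
#' glucose during the first), `chip`, `gender` (`f`/`m`); `rbc` is optional.
#' Two design flags are derived: `training_state` (`pre` for E1/E2, `post`
#' for A1/A2) and `treated_period` (`TRUE` when the sample falls in the
#' participant's glucose-supplemented period).
#'
#' @param path TSV path.
#' @return A tibble, one row per sample, with the derived flags appended.
#' @export
read_annotation <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE)
  validate_annotation(ann)
}

#' Validate an annotation data frame and derive design flags
#'
#' @param ann A data frame with the columns documented in [read_annotation()].
#' @return A validated tibble with `training_state` and `treated_period`.
#' @export
validate_annotation <- function(ann) {
  need <- c("sample_id", "participant_id", "timepoint", "order_group",
            "chip", "gender")
  missing <- setdiff(need, names(ann))
  if (length(missing)) {
    abort(sprintf("Annotation is missing column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  ann <- as_tibble(ann)
  bad_tp <- setdiff(unique(ann$timepoint), TIMEPOINTS)
  if (length(bad_tp)) {
    abort(sprintf("Unknown timepoint label(s): %s.", paste(bad_tp, collapse = ", ")))
  }
  if (!all(ann$order_group %in% c(1L, 2L))) {
    abort("`order_group` must be 1 or 2.")
  }
  if (!all(ann$gender %in% c("f", "m"))) {
    abort("`gender` must be 'f' or 'm'.")
  }
  if (anyDuplicated(ann$sample_id)) abort("Duplicate sample_id in annotation.")
  dplyr::mutate(
    ann,
    sample_id = trimws(.data$sample_id),
    participant_id = trimws(as.character(.data$participant_id)),
    timepoint = factor(.data$timepoint, levels = TIMEPOINTS),
    training_state = ifelse(.data$timepoint %in% c("E1", "E2"), "pre", "post"),
    period = ifelse(.data$timepoint %in% c("E1", "A1"), 1L, 2L),
    treated_period = (.data$order_group == 2L & .data$period == 1L) |
      (.data$order_group == 1L & .data$period == 2L)
  )
}

#' Read a phenotype table
#'
#' Requires `participant_id`, `timepoint`, `vo2max` (mL·min⁻¹·kg⁻¹); clinical
#' columns such as `bmi`, `weight`, `body_fat`, `max_hr`, `glucose`, `rbc`
#' are carried through when present.
#'
#' @param path TSV path.
#' @return A tibble with at most one row per participant x timepoint.
#' @export
read_phenotypes <- function(path) {
  ph <- readr::read_tsv(path, show_col_types = FALSE)
  validate_phenotypes(ph)
}

#' @rdname read_phenotypes
#' @param pheno A data frame to validate in place of a file.
#' @export
validate_phenotypes <- function(pheno) {
  need <- c("participant_id", "timepoint", "vo2max")
  missing <- setdiff(need, names(pheno))
  if (length(missing)) {
    abort(sprintf("Phenotype table is missing column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  pheno <- as_tibble(pheno)
  bad_tp <- setdiff(unique(pheno$timepoint), TIMEPOINTS)
  if (length(bad_tp)) {
    abort(sprintf("Unknown timepoint label(s): %s.", paste(bad_tp, collapse = ", ")))
  }
  if (anyDuplicated(pheno[c("participant_id", "timepoint")])) {
    abort("More than one phenotype row for a participant x timepoint.")
  }
  if (any(!is.na(pheno$vo2max) & pheno$vo2max <= 0)) {
    abort("`vo2max` must be positive where present.")
  }
  dplyr::mutate(pheno,
                participant_id = trimws(as.character(.data$participant_id)),
                timepoint = factor(.data$timepoint, levels = TIMEPOINTS))
}

#' Align an expression object with its annotation
#'
#' Samples present in the expression matrix but absent from the annotation are
#' dropped with a warning (they cannot enter any design-dependent stage);
#' annotation rows without an expression sample are ignored.
#'
#' @param x A [mir_expr] object.
#' @param ann Annotation tibble from [read_annotation()].
#' @return A list with elements `expr` and `annotation`, both restricted to
#'   the shared samples, annotation ordered as the expression columns.
#' @export
align_samples <- function(x, ann) {
  shared <- intersect(sample_ids(x), ann$sample_id)
  orphan <- setdiff(sample_ids(x), ann$sample_id)
  if (length(orphan)) {
    warn(sprintf("%d expression sample(s) missing from annotation, excluded: %s",
                 length(orphan), paste(head(orphan, 5), collapse = ", ")))
  }
  ann <- ann[match(shared, ann$sample_id), , drop = FALSE]
  list(expr = expr_subset(x, samples = shared), annotation = as_tibble(ann))
}
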