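#' Pipeline configuration
#'
#' Collects every stage threshold with its validated legal range, plus the
#' input source: either paths to expression/annotation/phenotype TSVs or a
#' `synthetic` block ([study_design()] + [effect_config()]). Thresholds
#' default to the pipeline's standard settings: detection fraction 0.5, Q3
#' minimum 3.5, outlier mean-rho 0.85, PVCA variance threshold 0.9, |log2FC|
#' >= 1, p < 0.05, 6 clusters, 6 CV folds x 10 repeats, 50 hyperparameter
#' candidates.
#'
#' @param expression,annotation,phenotypes Input TSV paths (ignored when
#'   `synthetic` is given).
#' @param synthetic Optional list with elements `design` and `effects`.
#' @param detection_fraction,q3_min,min_mean_rho,pvca_threshold,fc_min,p_max,k,folds,repeats,n_hyper
#'   Stage thresholds.
#' @param pvca_factors Annotation columns used as PVCA main effects.
#' @param paired Paired (default) or Welch differential expression.
#' @param seed Seed driving every stochastic stage.
#' @param out_dir Output directory for stage tables and the manifest.
#' @return A validated `mir_pipeline_config` list.
#' @export
pipeline_config <- function(expression = NULL, annotation = NULL,
                            phenotypes = NULL, synthetic = NULL,
                            detection_fraction = 0.5, q3_min = 3.5,
                            min_mean_rho = 0.85, pvca_threshold = 0.9,
                            fc_min = 1, p_max = 0.05, k = 6,
                            folds = 6, repeats = 10, n_hyper = 50,
                            pvca_factors = c("participant_id", "timepoint",
                                             "training_state", "chip",
                                             "gender", "order_group"),
                            paired = TRUE, seed = 1L, out_dir = NULL) {
  assert_scalar_number(detection_fraction, "detection_fraction", 0, 1)
  assert_scalar_number(q3_min, "q3_min", 0, Inf)
  assert_scalar_number(min_mean_rho, "min_mean_rho", -1, 1)
  assert_scalar_number(pvca_threshold, "pvca_threshold", 0, 1)
  assert_scalar_number(fc_min, "fc_min", 0, Inf)
  assert_scalar_number(p_max, "p_max", 0, 1)
  assert_count(k, "k", 1L)
  assert_count(folds, "folds", 2L)
  assert_count(repeats, "repeats", 1L)
  assert_count(n_hyper, "n_hyper", 2L)
  if (is.null(synthetic) &&
      (is.null(expression) || is.null(annotation) || is.null(phenotypes))) {
    abort("Provide either the three input paths or a `synthetic` block.")
  }
  structure(
    list(expression = expression, annotation = annotation,
         phenotypes = phenotypes, synthetic = synthetic,
         detection_fraction = detection_fraction, q3_min = q3_min,
         min_mean_rho = min_mean_rho, pvca_threshold = pvca_threshold,
         fc_min = fc_min, p_max = p_max, k = as.integer(k),
         folds = as.integer(folds), repeats = as.integer(repeats),
         n_hyper = as.integer(n_hyper), pvca_factors = pvca_factors,
         paired = isTRUE(paired), seed = as.integer(seed), out_dir = out_dir),
    class = "mir_pipeline_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' The YAML mirrors the [pipeline_config()] arguments; a `synthetic:` block
#' may carry `design:` and `effects:` sub-blocks whose entries override the
#' [study_design()] / [effect_config()] defaults.
#'
#' @param path YAML file path.
#' @return A `mir_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$synthetic)) {
    des <- do.call(study_design, raw$synthetic$design %||% list())
    eff <- do.call(effect_config, raw$synthetic$effects %||% list())
    raw$synthetic <- list(design = des, effects = eff)
  }
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Executes preprocess → PCA/PVCA → differential expression (all six
#' setups) → temporal clustering → VO2 max association → CHO recommendation
#' and marker screen, writing per-stage TSV/JSON outputs when `out_dir` is
#' set, and returns all stage results together with a manifest (package
#' version, seed, thresholds, stage log, input hashes). A failing stage
#' aborts with a stage-tagged error; stage outputs written up to that point
#' are renamed with a `.partial` suffix.
#'
#' @param config A `mir_pipeline_config`.
#' @return A `mir_pipeline_result` list: `preprocess`, `pca`, `pvca`, `de`,
#'   `clusters`, `correlations`, `vo2_fit`, `recommendation`, `marker_screen`,
#'   and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "mir_pipeline_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  log <- list()
  emit_tsv <- function(df, name) {
    if (is.null(out_dir)) return(invisible(NULL))
    p <- file.path(out_dir, name)
    readr::write_tsv(df, p)
    written <<- c(written, p)
  }
  stage <- function(name, expr) {
    res <- tryCatch(force(expr), error = function(e) {
      for (p in written) file.rename(p, paste0(p, ".partial"))
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
    log[[name]] <<- TRUE
    res
  }

  inputs <- stage("load", {
    if (!is.null(config$synthetic)) {
      st <- simulate_study(config$synthetic$design, config$synthetic$effects)
      list(expr = st$expr, annotation = st$annotation,
           phenotypes = st$phenotypes, truth = st$truth)
    } else {
      expr <- read_expression(config$expression,
                              detected_path = detected_path_if_exists(config$expression))
      ann <- read_annotation(config$annotation)
      al <- align_samples(expr, ann)
      list(expr = al$expr, annotation = al$annotation,
           phenotypes = read_phenotypes(config$phenotypes), truth = NULL)
    }
  })

  prep <- stage("preprocess", preprocess_expression(
    inputs$expr, config$detection_fraction, config$q3_min, config$min_mean_rho))
  ann <- inputs$annotation[inputs$annotation$sample_id %in% sample_ids(prep$expr), ]
  emit_tsv(prep$outlier_report, "outlier_report.tsv")

  pca <- stage("variance_decomposition", run_pca(prep$expr))
  pvca <- stage("pvca", run_pvca(prep$expr, ann,
                                 factors = intersect(config$pvca_factors, names(ann)),
                                 var_threshold = config$pvca_threshold))
  emit_tsv(pvca$proportions, "pvca.tsv")

  de <- stage("differential_expression", run_all_de(
    prep$expr, ann, paired = config$paired,
    fc_min = config$fc_min, p_max = config$p_max))
  emit_tsv(de, "differential_expression.tsv")

  clusters <- stage("temporal_clustering", cluster_profiles(
    zscore_by_feature(prep$expr), ann, k = config$k, seed = config$seed))
  emit_tsv(clusters$profiles, "clusters.tsv")

  correlations <- stage("phenotype_association", participant_correlations(
    prep$expr, ann, inputs$phenotypes))
  vo2 <- stage("vo2_model", fit_vo2_model(
    prep$expr, ann, inputs$phenotypes, folds = config$folds,
    repeats = config$repeats, n_hyper = config$n_hyper, seed = config$seed))
  emit_tsv(dplyr::left_join(tidy(vo2), clusters$assignment, by = "feature_id"),
           "vo2_coefficients.tsv")

  rec <- stage("cho_recommendation", assign_recommendation_groups(
    inputs$phenotypes, ann))
  screen <- stage("marker_screen", screen_markers(prep$expr, ann, rec))
  emit_tsv(tidy(rec), "recommendation.tsv")
  emit_tsv(screen, "marker_screen.tsv")

  manifest <- list(
    package_version = as.character(utils::packageVersion("crossmir")),
    seed = config$seed,
    thresholds = config[c("detection_fraction", "q3_min", "min_mean_rho",
                          "pvca_threshold", "fc_min", "p_max", "k", "folds",
                          "repeats", "n_hyper")],
    stages = names(log),
    n_features_in = nrow(inputs$expr$values),
    n_features_out = nrow(prep$expr$values),
    n_samples_out = ncol(prep$expr$values),
    input_hash = rlang::hash(inputs$expr$values),
    result_hash = rlang::hash(list(prep$expr$values, de$p_value,
                                   clusters$assignment$cluster,
                                   tidy(vo2)$coefficient,
                                   tidy(rec)$r))
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(preprocess = prep, pca = pca, pvca = pvca, de = de,
                 clusters = clusters, correlations = correlations,
                 vo2_fit = vo2, recommendation = rec, marker_screen = screen,
                 manifest = manifest, truth = inputs$truth),
            class = "mir_pipeline_result")
}

detected_path_if_exists <- function(path) {
  d <- detected_sibling(path)
  if (file.exists(d)) d else NULL
}

#' @export
print.mir_pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "<mir_pipeline_result> %d stages; %d -> %d features, %d samples; hash %s\n",
    length(m$stages), m$n_features_in, m$n_features_out, m$n_samples_out,
    substr(m$result_hash, 1, 8)))
  invisible(x)
}
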