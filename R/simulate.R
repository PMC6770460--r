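#' Simulate a cross-over miRNA training study with known ground truth
#'
#' Generates log2-scale expression, sample annotation, phenotypes, and a
#' ground-truth record for a two-period endurance-training cross-over. Each
#' expression cell is assembled as
#' `baseline + participant intercept + (1 + response) * gain * wave(timepoint)
#'  + chip + gender + marker + noise`,
#' where `wave` is the feature's cluster archetype, `response` a
#' participant-specific training-response amplitude, and the marker term an
#' extra post-training shift in CHO responders during their no-treatment
#' period. VO2 max trajectories rise over each training period, and the
#' treatment-period gain exceeds the no-treatment gain exactly for the latent
#' responder class.
#'
#' @param design A [study_design()].
#' @param effects An [effect_config()].
#' @return A `mir_study` list with elements `expr` ([mir_expr], log2 scale),
#'   `annotation`, `phenotypes` (tibbles), and `truth` (planted parameters:
#'   feature-to-cluster map, marker id, responder classes, per-participant
#'   VO2 deltas, expected period-1 log2 fold changes, and the effect
#'   configuration used).
#' @examples
#' st <- simulate_study(study_design(seed = 7))
#' st$expr
#' dplyr::count(st$annotation, order_group, timepoint)
#' @export
simulate_study <- function(design = study_design(), effects = effect_config()) {
  stopifnot(inherits(design, "study_design"), inherits(effects, "effect_config"))
  n_wave <- sum(effects$cluster_sizes)
  if (n_wave + 1L > design$n_features) {
    abort(sprintf(
      "Cluster sizes sum to %d but the design only has %d features.",
      n_wave, design$n_features))
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(design$seed, 1L))

  np <- design$n_participants
  participants <- sprintf("P%02d", seq_len(np))
  order_group <- rep(c(1L, 2L), design$group_sizes)
  gender <- unlist(lapply(1:2, function(g) {
    nf <- design$females_per_group[g]
    sample(rep(c("f", "m"), c(nf, design$group_sizes[g] - nf)))
  }))

  ann <- tidyr::expand_grid(participant_id = participants,
                            timepoint = TIMEPOINTS)
  ann$sample_id <- sprintf("S%02d", seq_len(nrow(ann)))
  ann$order_group <- order_group[match(ann$participant_id, participants)]
  ann$gender <- gender[match(ann$participant_id, participants)]
  ann$chip <- sprintf("chip%02d",
                      sample(rep(seq_len(design$n_chips), length.out = nrow(ann))))
  ns <- nrow(ann)

  # --- features -------------------------------------------------------------
  k <- length(effects$cluster_sizes)
  cluster_of <- rep(c(seq_len(k), NA_integer_),
                    c(effects$cluster_sizes, design$n_features - n_wave))
  fid <- sprintf("miR-sim-%04d", seq_len(design$n_features))
  marker_idx <- 1L  # first feature of cluster 1 doubles as the planted marker
  fid[marker_idx] <- "miR-532-5p"
  is_low <- is.na(cluster_of)
  # wide baseline spread across features, as on real arrays, so that samples
  # correlate strongly with each other (the study's mean Spearman rho >= 0.85)
  baseline <- ifelse(is_low, rnorm(design$n_features, 2, 0.8),
                     pmax(rnorm(design$n_features, 9, 4.5), 3.8))
  baseline[marker_idx] <- 6.3
  # right-skewed response amplitudes: most features respond mildly, a tail
  # reaches |log2FC| >= 1 after scaling by the population mean response
  gain <- rgamma(design$n_features, shape = 5, scale = 0.22)
  gain[marker_idx] <- 0.15  # the marker is only mildly training-responsive
  gender_feats <- seq_len(design$n_features) %in%
    sample(which(!is_low), size = max(1L, round(0.15 * design$n_features)))

  # --- participant-level latent terms --------------------------------------
  responder <- setNames(sample(c(TRUE, FALSE), np, replace = TRUE), participants)
  # bounded training-response heterogeneity around a sub-unit mean: the
  # person-by-training interaction then carries more variance than the
  # training main effect, without unbounded per-sample excursions
  # fixed uniform quantile spread, randomly permuted over participants: the
  # population mean and spread of the response are design constants of the
  # dataset rather than resampled, so every realization carries the same
  # overall training signal
  half_width <- sqrt(3) * effects$participant_response_sd
  spread <- 2 * (seq_len(np) - 0.5) / np - 1
  response_mult <- setNames(
    effects$response_mean + half_width * sample(spread), participants)
  part_intercept <- matrix(rnorm(design$n_features * np, 0, effects$participant_sd),
                           design$n_features, np, dimnames = list(fid, participants))
  part_intercept[marker_idx, ] <- 0.3 * part_intercept[marker_idx, ]
  chip_levels <- sort(unique(ann$chip))
  chip_eff <- matrix(rnorm(design$n_features * length(chip_levels), 0, effects$chip_sd),
                     design$n_features, length(chip_levels),
                     dimnames = list(fid, chip_levels))

  # --- assemble expression --------------------------------------------------
  tp_idx <- match(ann$timepoint, TIMEPOINTS)
  wave <- effects$cluster_archetypes
  vals <- matrix(0, design$n_features, ns, dimnames = list(fid, ann$sample_id))
  # design flags needed for the marker term
  period <- ifelse(ann$timepoint %in% c("E1", "A1"), 1L, 2L)
  treated <- (ann$order_group == 2L & period == 1L) |
    (ann$order_group == 1L & period == 2L)
  post <- ann$timepoint %in% c("A1", "A2")
  for (s in seq_len(ns)) {
    p <- ann$participant_id[s]
    w <- ifelse(is.na(cluster_of), 0, wave[cbind(cluster_of, tp_idx[s])])
    col <- baseline + part_intercept[, p] +
      response_mult[p] * gain * ifelse(is.na(w), 0, w) +
      chip_eff[, ann$chip[s]] +
      ifelse(gender_feats & ann$gender[s] == "m", effects$gender_effect, 0)
    if (post[s] && !treated[s] && responder[p]) {
      col[marker_idx] <- col[marker_idx] + effects$marker_effect
    }
    vals[, s] <- col
  }
  vals <- vals + matrix(rnorm(length(vals), 0, effects$noise_sd),
                        nrow(vals), ncol(vals))

  detected <- matrix(TRUE, design$n_features, ns, dimnames = dimnames(vals))
  if (any(is_low) && effects$detection_dropout > 0) {
    drop <- matrix(runif(sum(is_low) * ns) < effects$detection_dropout,
                   sum(is_low), ns)
    detected[is_low, ] <- !drop
  }

  # --- phenotypes -----------------------------------------------------------
  vo2_base <- setNames(rnorm(np, 35, 5), participants)
  gain_untreated <- setNames(rnorm(np, 2, 1), participants)
  bonus <- setNames(pmax(rnorm(np, 1.5, 0.5), 0.1), participants)
  gain_treated <- gain_untreated + ifelse(responder, bonus, -bonus)
  # order group 2 trains with glucose in period 1, group 1 in period 2
  treated_period <- setNames(ifelse(order_group == 2L, 1L, 2L), participants)
  delta1 <- ifelse(treated_period == 1L, gain_treated, gain_untreated)
  delta2 <- ifelse(treated_period == 2L, gain_treated, gain_untreated)

  pheno <- tidyr::expand_grid(participant_id = participants,
                              timepoint = TIMEPOINTS)
  pb <- vo2_base[pheno$participant_id]
  d1 <- delta1[pheno$participant_id]
  d2 <- delta2[pheno$participant_id]
  pheno$vo2max <- unname(dplyr::case_when(
    pheno$timepoint == "E1" ~ pb,
    pheno$timepoint == "A1" ~ pb + d1,
    pheno$timepoint == "E2" ~ pb,  # full wash-out back to baseline
    pheno$timepoint == "A2" ~ pb + d2
  ))
  if (effects$vo2_noise_sd > 0) {
    pheno$vo2max <- pheno$vo2max + rnorm(nrow(pheno), 0, effects$vo2_noise_sd)
  }
  post_ph <- pheno$timepoint %in% c("A1", "A2")
  weight_base <- setNames(rnorm(np, 75, 10), participants)
  height <- setNames(rnorm(np, 1.78, 0.08), participants)
  hr_base <- setNames(rnorm(np, 188, 8), participants)
  pheno$weight <- unname(weight_base[pheno$participant_id]) +
    rnorm(nrow(pheno), 0, 0.8) - ifelse(post_ph, 0.3, 0)
  pheno$bmi <- pheno$weight / unname(height[pheno$participant_id])^2
  pheno$body_fat <- pmax(rnorm(nrow(pheno), 22, 4) - ifelse(post_ph, 0.8, 0), 5)
  pheno$max_hr <- unname(hr_base[pheno$participant_id]) -
    ifelse(post_ph, effects$max_hr_effect, 0) + rnorm(nrow(pheno), 0, 3)
  pheno$glucose <- rnorm(nrow(pheno), 90, 6) + ifelse(post_ph, 2, 0)
  pheno$rbc <- pmax(rnorm(nrow(pheno), 4.9, 0.35) - ifelse(post_ph, 0.12, 0), 3.5)

  ann$rbc <- pheno$rbc[match(paste(ann$participant_id, ann$timepoint),
                             paste(pheno$participant_id, pheno$timepoint))]
  ann <- validate_annotation(ann[, c("sample_id", "participant_id", "timepoint",
                                     "order_group", "chip", "gender", "rbc")])

  expr <- mir_expr(vals, detected, log2_scale = TRUE)
  if (design$n_missing > 0) {
    keep <- sort(sample(ns, ns - design$n_missing))
    expr <- expr_subset(expr, samples = keep)
    ann <- ann[keep, , drop = FALSE]
  }

  truth <- list(
    feature_cluster = setNames(cluster_of, fid),
    low_expressed = setNames(is_low, fid),
    marker_id = fid[marker_idx],
    responder = responder,
    treated_period = treated_period,
    delta1 = delta1, delta2 = delta2,
    expected_log2fc_p1 = setNames(
      effects$response_mean * gain *
        ifelse(is.na(cluster_of), 0, wave[cbind(cluster_of, 2L)]), fid),
    variance_components = list(participant_sd = effects$participant_sd,
                               participant_response_sd = effects$participant_response_sd,
                               chip_sd = effects$chip_sd,
                               noise_sd = effects$noise_sd),
    seed = design$seed
  )

  structure(list(expr = expr, annotation = ann,
                 phenotypes = validate_phenotypes(pheno), truth = truth,
                 design = design, effects = effects),
            class = "mir_study")
}

#' @export
print.mir_study <- function(x, ...) {
  cat(sprintf("<mir_study> %d participants, %d samples, %d features (seed %d)\n",
              x$design$n_participants, ncol(x$expr$values),
              nrow(x$expr$values), x$design$seed))
  invisible(x)
}

# Save/restore the global RNG state so simulation never perturbs user code.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Write a simulated study to a directory of plain-text fixtures
#'
#' Emits `expression.tsv` (plus `expression.detected.tsv` when any probe is
#' undetected), `annotation.tsv`, `phenotypes.tsv`, and `truth.json`; the
#' tables round-trip exactly through [read_expression()], [read_annotation()]
#' and [read_phenotypes()].
#'
#' @param study A `mir_study` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_fixture <- function(study, dir) {
  stopifnot(inherits(study, "mir_study"))
  if (nrow(study$expr$values) == 0L) {
    abort("Refusing to write a study with an empty feature set.")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(sprintf("Cannot create directory '%s'.", dir))
  write_expression(study$expr, file.path(dir, "expression.tsv"))
  drop_derived <- c("training_state", "period", "treated_period")
  readr::write_tsv(study$annotation[setdiff(names(study$annotation), drop_derived)],
                   file.path(dir, "annotation.tsv"))
  readr::write_tsv(study$phenotypes, file.path(dir, "phenotypes.tsv"))
  truth <- study$truth
  truth$responder <- as.list(truth$responder)
  truth$feature_cluster <- as.list(truth$feature_cluster)
  truth$low_expressed <- as.list(truth$low_expressed)
  truth$expected_log2fc_p1 <- as.list(truth$expected_log2fc_p1)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
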