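#' Study design configuration for the synthetic generator
#'
#' Describes the randomized cross-over layout: two order-of-treatment groups
#' (group 1 receives the glucose supplement during the second eight-week
#' training period, group 2 during the first), four blood-draw timepoints
#' (E1/A1 flanking period 1, E2/A2 flanking period 2), and the microarray
#' chip count. Defaults mirror the emulated study: 23 untrained adults split
#' 13/10, with 6 f / 7 m in group 1 and 4 f / 6 m in group 2, 17 chips.
#'
#' @param n_participants Total participants.
#' @param group_sizes Length-2 integer vector, sizes of order groups 1 and 2;
#'   must sum to `n_participants`.
#' @param females_per_group Length-2 integer vector of female counts per
#'   group (remainder male).
#' @param n_features Number of array features to simulate.
#' @param n_chips Number of microarray chips samples are spread over.
#' @param n_missing Number of randomly dropped samples (emulates the few
#'   hybridizations that fail in practice).
#' @param seed Integer seed; identical seed and configs give bit-identical
#'   datasets.
#' @return A `study_design` list.
#' @export
study_design <- function(n_participants = 23,
                         group_sizes = c(13, 10),
                         females_per_group = c(6, 4),
                         n_features = 400,
                         n_chips = 17,
                         n_missing = 0,
                         seed = 1L) {
  n_participants <- assert_count(n_participants, "n_participants", min = 2L)
  if (length(group_sizes) != 2L || sum(group_sizes) != n_participants) {
    abort("`group_sizes` must be two counts summing to `n_participants`.")
  }
  if (length(females_per_group) != 2L || any(females_per_group > group_sizes) ||
      any(females_per_group < 0)) {
    abort("`females_per_group` must be two counts, each <= its group size.")
  }
  n_features <- assert_count(n_features, "n_features", min = 10L)
  n_chips <- assert_count(n_chips, "n_chips", min = 1L)
  n_missing <- assert_count(n_missing, "n_missing", min = 0L)
  structure(
    list(n_participants = n_participants,
         group_sizes = as.integer(group_sizes),
         females_per_group = as.integer(females_per_group),
         n_features = n_features, n_chips = n_chips,
         n_missing = n_missing, timepoints = TIMEPOINTS,
         seed = as.integer(seed)),
    class = "study_design"
  )
}

#' Effect-size configuration for the synthetic generator
#'
#' All expression effects are on the log2 scale (the scale the pipeline's
#' statistics operate on). Six signed wave archetypes over (E1, A1, E2, A2)
#' drive the training-responsive feature clusters; each has a first-peak
#' amplitude after period 1 and a dampened second peak after period 2
#' (|second| < |first|), with three up-first and three down-first shapes.
#' Cluster sizes default to 51/35/67/64/70/20 so the planted responsive set
#' totals 307 features; the remaining features are low-expressed probes that
#' the detection and Q3 filters are expected to remove.
#'
#' @param cluster_archetypes 6 x 4 numeric matrix of wave templates (rows =
#'   clusters, columns = E1, A1, E2, A2, units log2).
#' @param cluster_sizes Six cluster sizes; their sum must not exceed the
#'   design's feature count.
#' @param participant_sd SD of the per-participant, per-feature baseline
#'   intercept (between-person expression individuality).
#' @param response_mean Population-mean multiplier on the wave amplitudes
#'   (default 0.5; the training main effect scales with it).
#' @param participant_response_sd SD of the per-participant wave-amplitude
#'   multiplier, drawn uniformly in `response_mean` ± sqrt(3)·sd (bounded,
#'   so no participant becomes a correlation outlier). Values above
#'   `response_mean` make the participant-by-training-state interaction
#'   variance exceed the training main effect, the structure that dominates
#'   the emulated study.
#' @param chip_sd SD of per-chip, per-feature batch offsets.
#' @param gender_effect Additive male-vs-female shift applied to a fixed 15%
#'   subset of features (gonosomal-like probes).
#' @param noise_sd Residual Gaussian noise SD per cell.
#' @param marker_effect Planted post-training marker shift: in the
#'   no-treatment period, post-training marker expression of CHO responders
#'   exceeds non-responders by exactly this amount before noise.
#' @param detection_dropout Probability that a low-baseline probe is flagged
#'   undetected in a sample.
#' @param vo2_noise_sd Measurement noise on VO2 max values (0 = noiseless
#'   trajectories, the generator default; the ordering of period gains then
#'   encodes the responder class exactly).
#' @param max_hr_effect Planted post-training decrease in maximal heart rate
#'   (beats/min), twice the clinical noise SD by default.
#' @return An `effect_config` list.
#' @export
effect_config <- function(cluster_archetypes = default_archetypes(),
                          cluster_sizes = c(51, 35, 67, 64, 70, 20),
                          participant_sd = 0.2,
                          response_mean = 0.55,
                          participant_response_sd = 0.65,
                          chip_sd = 0.15,
                          gender_effect = 0.5,
                          noise_sd = 0.2,
                          marker_effect = 1,
                          detection_dropout = 0.6,
                          vo2_noise_sd = 0,
                          max_hr_effect = 6) {
  if (!is.matrix(cluster_archetypes) || ncol(cluster_archetypes) != 4L) {
    abort("`cluster_archetypes` must be a k x 4 matrix over (E1, A1, E2, A2).")
  }
  if (length(cluster_sizes) != nrow(cluster_archetypes)) {
    abort("`cluster_sizes` must have one entry per archetype row.")
  }
  first_peak <- cluster_archetypes[, 2] - cluster_archetypes[, 1]
  second_peak <- cluster_archetypes[, 4] - cluster_archetypes[, 3]
  if (any(abs(second_peak) >= abs(first_peak) & abs(first_peak) > 0)) {
    abort("Each archetype needs a dampened second peak (|peak 2| < |peak 1|).")
  }
  for (nm in c("participant_sd", "participant_response_sd", "chip_sd",
               "noise_sd")) {
    assert_scalar_number(get(nm), nm, min = 0)
  }
  assert_scalar_number(detection_dropout, "detection_dropout", min = 0, max = 1)
  assert_scalar_number(vo2_noise_sd, "vo2_noise_sd", min = 0)
  structure(
    list(cluster_archetypes = cluster_archetypes,
         cluster_sizes = as.integer(cluster_sizes),
         participant_sd = participant_sd,
         response_mean = response_mean,
         participant_response_sd = participant_response_sd,
         chip_sd = chip_sd, gender_effect = gender_effect,
         noise_sd = noise_sd, marker_effect = marker_effect,
         detection_dropout = detection_dropout,
         vo2_noise_sd = vo2_noise_sd, max_hr_effect = max_hr_effect),
    class = "effect_config"
  )
}

#' Default wave archetypes
#'
#' Six templates over (E1, A1, E2, A2): three up-first shapes peaking after
#' period 1, returning toward (or past) baseline over the wash-out, and a
#' dampened second peak after period 2; three mirror-image down-first shapes.
#' The shapes differ after z-scaling (not only in amplitude), so they remain
#' distinguishable to profile clustering.
#'
#' @return A 6 x 4 matrix with rownames C1..C6.
#' @export
default_archetypes <- function() {
  a <- rbind(
    C1 = c(0,  1.0,  0.90,  1.60),  # up, sustained through wash-out, rising
    C2 = c(0, -1.0, -0.90, -1.60),
    C3 = c(0,  1.0, -1.00, -0.40),  # up, overshoot below baseline, partial recovery
    C4 = c(0, -1.0,  1.00,  0.40),
    C5 = c(0,  1.0,  0.00,  0.60),  # up, full wash-out reset, dampened second peak
    C6 = c(0, -1.0,  0.00, -0.60)
  )
  colnames(a) <- TIMEPOINTS
  a
}
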