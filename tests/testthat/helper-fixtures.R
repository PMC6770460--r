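# Shared fixtures for the test suite. Everything is built in code; the
# default synthetic study is cached per seed because several files reuse it.

.study_cache <- new.env(parent = emptyenv())

cached_study <- function(seed = 1, n_features = NULL, ...) {
  key <- paste0("s", seed, "_", rlang::hash(list(n_features, ...)))
  if (is.null(.study_cache[[key]])) {
    if (is.null(n_features)) {
      .study_cache[[key]] <- simulate_study(study_design(seed = seed, ...))
    } else {
      .study_cache[[key]] <- simulate_study(
        study_design(seed = seed, n_features = n_features, ...),
        effect_config(cluster_sizes = scaled_cluster_sizes(n_features)))
    }
  }
  .study_cache[[key]]
}

# shrink the default 307-feature cluster layout to small test matrices
scaled_cluster_sizes <- function(n_features) {
  pmax(1L, floor((n_features - 8) * c(51, 35, 67, 64, 70, 20) / 307))
}

cached_preprocessed <- function(seed = 1) {
  key <- paste0("p", seed)
  if (is.null(.study_cache[[key]])) {
    st <- cached_study(seed)
    .study_cache[[key]] <- suppressWarnings(preprocess_expression(st$expr))
  }
  .study_cache[[key]]
}

# small deterministic expression object
tiny_expr <- function(values, log2_scale = TRUE) {
  m <- as.matrix(values)
  if (is.null(rownames(m))) rownames(m) <- paste0("miR-t", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  mir_expr(m, log2_scale = log2_scale)
}

# minimal valid annotation for n participants x 4 timepoints
tiny_annotation <- function(n_participants = 4, order_groups = NULL) {
  og <- order_groups %||% rep(c(1L, 2L), length.out = n_participants)
  ann <- tidyr::expand_grid(
    participant_id = sprintf("P%02d", seq_len(n_participants)),
    timepoint = c("E1", "A1", "E2", "A2")
  )
  ann$sample_id <- paste0("s", seq_len(nrow(ann)))
  ann$order_group <- og[as.integer(sub("P", "", ann$participant_id))]
  ann$chip <- rep(c("c1", "c2"), length.out = nrow(ann))
  ann$gender <- rep(c("f", "m"), length.out = n_participants)[
    as.integer(sub("P", "", ann$participant_id))]
  validate_annotation(ann)
}

# independent hypergeometric upper-tail by explicit summation
hyper_tail_oracle <- function(k, N, K, n) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# independent BH step-up from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# independent Welch statistic, df and p from the closed form
welch_oracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  tt <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(statistic = tt, df = df, p_value = 2 * pt(abs(tt), df, lower.tail = FALSE))
}

# small regression instance shared by the model tests
make_regression_instance <- function(n = 40, p = 8, seed = 1, signal = TRUE) {
  set.seed(seed)
  ann <- tiny_annotation(n / 4)
  X <- matrix(rnorm(p * n), p, n, dimnames = list(paste0("f", 1:p), ann$sample_id))
  beta <- if (signal) c(2, -1.5, rep(0, p - 2)) else rep(0, p)
  y <- as.numeric(t(X) %*% beta) + rnorm(n, 0, if (signal) 0.3 else 1) + 38
  ph <- tibble::tibble(participant_id = ann$participant_id,
                       timepoint = as.character(ann$timepoint), vo2max = pmax(y, 1))
  list(x = mir_expr(X, log2_scale = TRUE), ann = ann,
       ph = validate_phenotypes(ph))
}

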