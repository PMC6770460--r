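test_that("collinear samples put all variance on PC1 and loadings are orthonormal", {
  dir <- rnorm(10)
  m <- sapply(seq(-2, 2, length.out = 5), function(a) a * dir)
  dimnames(m) <- list(paste0("f", 1:10), paste0("s", 1:5))
  p <- run_pca(mir_expr(m, log2_scale = TRUE))
  expect_equal(p$variance$proportion[1], 1, tolerance = 1e-12)
  L <- as.matrix(p$loadings[, -1])
  expect_equal(crossprod(L), diag(ncol(L)), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("PCA eigenvalues match a direct covariance eigendecomposition", {
  set.seed(21)
  m <- matrix(rnorm(200), 20, 10,
              dimnames = list(paste0("f", 1:20), paste0("s", 1:10)))
  p <- run_pca(mir_expr(m, log2_scale = TRUE))
  ev <- eigen(cov(t(m)), symmetric = TRUE)$values
  got <- p$variance$proportion * sum(ev[ev > 1e-12])
  expect_equal(got[seq_len(9)], ev[seq_len(9)], tolerance = 1e-9)
  # variance fractions invariant to sample order
  perm <- sample(10)
  p2 <- run_pca(expr_subset(mir_expr(m, log2_scale = TRUE), samples = perm))
  expect_equal(p2$variance$proportion, p$variance$proportion, tolerance = 1e-9)
})

test_that("loading selection applies thresholds and reports set means", {
  m <- rbind(f1 = c(2, -2, 0, 0), f2 = c(0, 0, 3, -3), f3 = rep(0.01, 4))
  colnames(m) <- paste0("s", 1:4)
  p <- run_pca(mir_expr(m, log2_scale = TRUE))
  sel <- select_high_loading_features(p, threshold = 0.5)
  expect_setequal(sel$features$feature_id, c("f1", "f2"))
  all_nonzero <- select_high_loading_features(p, threshold = 0)
  expect_true(all(c("f1", "f2") %in% all_nonzero$features$feature_id))
  expect_gt(sel$mean_abs_selected, sel$mean_abs_all)
  expect_equal(mean_abs_loading(p, c("f1", "f2")), sel$mean_abs_selected)
  expect_error(select_high_loading_features(p, threshold = -0.1), ">= 0")
  expect_error(mean_abs_loading(p, "nope"), "Unknown feature")
})

test_that("pure i.i.d. noise data attribute nearly all PVCA variance to the residual", {
  set.seed(5)
  m <- matrix(rnorm(200 * 40), 200, 40,
              dimnames = list(paste0("f", 1:200), paste0("s", 1:40)))
  ann <- tibble::tibble(sample_id = colnames(m),
                        grp = rep(c("a", "b"), 20),
                        batch = rep(c("x", "y", "z", "w"), each = 10))
  pv <- run_pvca(mir_expr(m, log2_scale = TRUE), ann, factors = c("grp", "batch"))
  expect_gte(pv$proportions$proportion[pv$proportions$term == "resid"], 0.9)
  expect_equal(sum(pv$proportions$proportion), 1, tolerance = 1e-9)
})

test_that("a dominant planted batch factor is attributed to that factor", {
  set.seed(6)
  chip <- rep(paste0("c", 1:4), each = 10)
  chip_eff <- matrix(rnorm(200 * 4, 0, 2), 200, 4)
  m <- chip_eff[, rep(1:4, each = 10)] + matrix(rnorm(200 * 40, 0, 0.2), 200, 40)
  dimnames(m) <- list(paste0("f", 1:200), paste0("s", 1:40))
  ann <- tibble::tibble(sample_id = colnames(m), chip = chip,
                        other = rep(c("u", "v"), 20))
  pv <- run_pvca(mir_expr(m, log2_scale = TRUE), ann, factors = c("chip", "other"))
  expect_gte(pv$proportions$proportion[pv$proportions$term == "chip"], 0.9)
})

test_that("PVCA proportions are equivariant under factor reordering", {
  prep <- cached_preprocessed(1)
  st <- cached_study(1)
  a <- suppressWarnings(run_pvca(prep$expr, st$annotation,
                                 factors = c("training_state", "chip", "gender")))
  b <- suppressWarnings(run_pvca(prep$expr, st$annotation,
                                 factors = c("gender", "training_state", "chip")))
  expect_equal(dplyr::arrange(a$proportions, term),
               dplyr::arrange(b$proportions, term), tolerance = 1e-4)
})

test_that("duplicate partitions and saturated interactions are dropped with warnings", {
  st <- cached_study(1)
  prep <- cached_preprocessed(1)
  ann <- st$annotation[st$annotation$sample_id %in% sample_ids(prep$expr), ]
  ann$participant_copy <- ann$participant_id
  expect_warning(
    pv <- run_pvca(prep$expr, ann, factors = c("participant_id", "participant_copy")),
    "replicates the partition")
  expect_warning(
    run_pvca(prep$expr, ann, factors = c("participant_id", "timepoint")),
    "one sample per level")
  expect_error(run_pvca(prep$expr, ann, factors = c("participant_id", "nope")),
               "not in annotation")
})

test_that("participant-related and training variance dominate the technical factors", {
  for (s in c(1, 7)) {
    st <- cached_study(s)
    prep <- suppressWarnings(preprocess_expression(st$expr))
    ann <- st$annotation[st$annotation$sample_id %in% sample_ids(prep$expr), ]
    pv <- suppressWarnings(run_pvca(
      prep$expr, ann,
      factors = c("participant_id", "training_state", "chip", "gender", "order_group")))
    pr <- setNames(pv$proportions$proportion, pv$proportions$term)
    # person-dependent expression: participant main effect plus the
    # participant-by-training-state interaction, taken together
    person <- pr[["participant_id"]] + pr[["participant_id:training_state"]]
    for (tech in c("chip", "gender", "order_group")) {
      expect_gt(person, pr[[tech]])
      expect_gt(pr[["training_state"]], pr[[tech]])
    }
  }
})

test_that("PVCA recovers planted variance fractions in a three-factor simulation", {
  # planted fractions: chip 0.3, participant 0.5, residual 0.2
  set.seed(31)
  est <- replicate(5, {
    part <- rep(paste0("p", 1:20), each = 3)
    chip <- sample(rep(paste0("c", 1:10), 6))
    pe <- matrix(rnorm(200 * 20, 0, sqrt(0.5)), 200, 20)
    ce <- matrix(rnorm(200 * 10, 0, sqrt(0.3)), 200, 10)
    m <- pe[, match(part, paste0("p", 1:20))] +
      ce[, match(chip, paste0("c", 1:10))] +
      matrix(rnorm(200 * 60, 0, sqrt(0.2)), 200, 60)
    dimnames(m) <- list(paste0("f", 1:200), paste0("s", 1:60))
    ann <- tibble::tibble(sample_id = colnames(m), participant = part, chip = chip)
    pv <- suppressWarnings(run_pvca(mir_expr(m, log2_scale = TRUE), ann,
                                    factors = c("participant", "chip")))
    pr <- setNames(pv$proportions$proportion, pv$proportions$term)
    c(pr[["participant"]], pr[["chip"]], pr[["resid"]])
  })
  avg <- rowMeans(est)
  expect_lt(abs(avg[1] - 0.5), 0.05)
  expect_lt(abs(avg[2] - 0.3), 0.05)
  expect_lt(abs(avg[3] - 0.2), 0.05)
})
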