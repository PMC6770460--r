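test_that("participant correlations follow monotone relationships exactly", {
  ann <- tiny_annotation(2)
  ph <- tidyr::expand_grid(participant_id = c("P01", "P02"),
                           timepoint = c("E1", "A1", "E2", "A2"))
  ph$vo2max <- c(30, 32, 34, 36, 40, 39, 38, 37)
  ph <- validate_phenotypes(ph)
  vals <- matrix(0, 2, nrow(ann), dimnames = list(c("up", "down"), ann$sample_id))
  # feature "up" tracks VO2, feature "down" reverses it
  vo2_of <- ph$vo2max[match(paste(ann$participant_id, ann$timepoint),
                            paste(ph$participant_id, ph$timepoint))]
  vals["up", ] <- 5 + 0.1 * vo2_of
  vals["down", ] <- 5 - 0.1 * vo2_of
  pc <- participant_correlations(mir_expr(vals, log2_scale = TRUE), ann, ph)
  expect_true(all(pc$rho[pc$feature_id == "up"] == 1))
  expect_true(all(pc$rho[pc$feature_id == "down"] == -1))
  # monotone-transform invariance
  vals2 <- vals
  vals2["up", ] <- exp(vals2["up", ])
  pc2 <- participant_correlations(mir_expr(vals2, log2_scale = TRUE), ann, ph)
  expect_equal(pc2$rho, pc$rho)
})

test_that("participant correlations equal an exhaustive rank oracle on 4 points", {
  set.seed(14)
  ann <- tiny_annotation(1)
  ph <- validate_phenotypes(tibble::tibble(
    participant_id = "P01", timepoint = c("E1", "A1", "E2", "A2"),
    vo2max = c(33.1, 37.2, 31.8, 39.0)))
  vals <- matrix(rnorm(12), 3, 4, dimnames = list(paste0("f", 1:3), ann$sample_id))
  pc <- participant_correlations(mir_expr(vals, log2_scale = TRUE), ann, ph)
  # Spearman rho from first principles: Pearson on ranks
  for (f in rownames(vals)) {
    r1 <- rank(vals[f, ann$sample_id[order(match(ann$timepoint, c("E1","A1","E2","A2")))]])
    expected <- cor(rank(vals[f, ]), rank(ph$vo2max[match(
      paste("P01", ann$timepoint), paste(ph$participant_id, ph$timepoint))]))
    expect_equal(pc$rho[pc$feature_id == f], expected, tolerance = 1e-12)
  }
})

test_that("participants with fewer than three matched timepoints get NA", {
  ann <- tiny_annotation(2)
  ph <- validate_phenotypes(tibble::tibble(
    participant_id = c("P01", "P01", "P01", "P02", "P02"),
    timepoint = c("E1", "A1", "E2", "E1", "A1"),
    vo2max = c(30, 31, 32, 40, 41)))
  vals <- matrix(rnorm(2 * nrow(ann)), 2, nrow(ann),
                 dimnames = list(c("a", "b"), ann$sample_id))
  pc <- participant_correlations(mir_expr(vals, log2_scale = TRUE), ann, ph)
  expect_true(all(is.na(pc$rho[pc$participant_id == "P02"])))
  expect_true(all(pc$n_timepoints[pc$participant_id == "P02"] == 2))
  expect_false(anyNA(pc$rho[pc$participant_id == "P01"]))
})

test_that("the unpenalized limit reproduces least squares", {
  d <- make_regression_instance()
  fit <- fit_vo2_model(d$x, d$ann, d$ph, alpha = 0, lambda = 0)
  ref <- lm(d$ph$vo2max ~ t(d$x$values))
  got <- fit$coefficients$coefficient[match(feature_ids(d$x),
                                            fit$coefficients$feature_id)]
  expect_lt(max(abs(unname(got) - unname(coef(ref)[-1]))), 1e-6)
  expect_lt(abs(fit$intercept - unname(coef(ref)[1])), 1e-6)
})

test_that("the tuned fit is reproducible and finds planted signal", {
  d <- make_regression_instance(seed = 5)
  f1 <- fit_vo2_model(d$x, d$ann, d$ph, folds = 4, repeats = 2, n_hyper = 12,
                      seed = 9)
  f2 <- fit_vo2_model(d$x, d$ann, d$ph, folds = 4, repeats = 2, n_hyper = 12,
                      seed = 9)
  expect_identical(f1$alpha, f2$alpha)
  expect_identical(f1$lambda, f2$lambda)
  expect_equal(f1$coefficients, f2$coefficients)
  expect_gt(f1$cv_rsq, 0.8)
  expect_setequal(head(f1$coefficients$feature_id, 2), c("f1", "f2"))
  g <- glance(f1)
  expect_equal(g$n_nonzero, f1$n_nonzero)
  expect_s3_class(tidy(f1), "tbl_df")
})

test_that("importance ranking is invariant to feature scaling", {
  d <- make_regression_instance(seed = 7)
  f1 <- fit_vo2_model(d$x, d$ann, d$ph, folds = 4, repeats = 2, n_hyper = 12,
                      seed = 3)
  scaled <- d$x
  scaled$values <- scaled$values * c(10, rep(1, 6), 0.1)
  f2 <- fit_vo2_model(scaled, d$ann, d$ph, folds = 4, repeats = 2, n_hyper = 12,
                      seed = 3)
  expect_identical(head(f1$coefficients$feature_id, 2),
                   head(f2$coefficients$feature_id, 2))
})

test_that("a pure-noise response yields negligible cross-validated R squared", {
  d <- make_regression_instance(n = 48, p = 30, seed = 11, signal = FALSE)
  f <- fit_vo2_model(d$x, d$ann, d$ph, folds = 4, repeats = 3, n_hyper = 12,
                     seed = 2)
  expect_lte(f$cv_rsq, 0.05)
})

test_that("regression guards its degenerate inputs", {
  d <- make_regression_instance()
  expect_error(fit_vo2_model(d$x, d$ann, d$ph, folds = 50), "exceeds")
  ph0 <- d$ph
  ph0$vo2max <- 40
  expect_error(fit_vo2_model(d$x, d$ann, ph0), "Constant VO2")
})

test_that("clinical tests report the planted contrasts with guarded degenerate cases", {
  st <- cached_study(1)
  ct <- clinical_tests(st$phenotypes, st$annotation)
  expect_true(all(c("p_value", "p_adj") %in% names(ct)))
  expect_true(all(ct$p_adj >= ct$p_value, na.rm = TRUE))
  # planted post-training drop in maximal heart rate (2 sd): detected by the
  # pooled unpaired Welch contrast in both periods
  hr <- ct[ct$parameter == "max_hr" & ct$contrast == "welch_pre_post", ]
  expect_true(all(hr$p_value < 0.05))
  expect_true(all(hr$estimate < 0))

  # identical pre/post gives p = 1; constant nonzero shift hits the floor
  ph <- tibble::tibble(
    participant_id = rep(sprintf("P%02d", 1:4), each = 4),
    timepoint = rep(c("E1", "A1", "E2", "A2"), 4),
    vo2max = 40, weight = rep(c(70, 72, 71, 73), 4))
  ann <- tiny_annotation(4)
  res <- suppressWarnings(clinical_tests(validate_phenotypes(ph), ann,
                                         columns = c("vo2max", "weight")))
  v <- res[res$parameter == "vo2max" & res$contrast == "paired_pre_post" &
             res$group == "pooled", ]
  expect_true(all(v$p_value == 1))
  w <- res[res$parameter == "weight" & res$contrast == "paired_pre_post" &
             res$group == "pooled", ]
  expect_true(all(w$p_value == .Machine$double.xmin))  # constant +2 shift
})
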