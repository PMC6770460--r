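make_pheno <- function(vo2_by_tp) {
  # vo2_by_tp: named list participant -> c(E1, A1, E2, A2)
  purrr::imap_dfr(vo2_by_tp, function(v, p) {
    tibble::tibble(participant_id = p, timepoint = c("E1", "A1", "E2", "A2"),
                   vo2max = v)
  }) |> validate_phenotypes()
}

two_person_annotation <- function(order_groups) {
  tiny_annotation(length(order_groups), order_groups = order_groups)
}

test_that("the recommendation rule compares the treated and untreated period deltas", {
  ann <- two_person_annotation(c(2L, 2L, 1L))
  ph <- make_pheno(list(
    P01 = c(30, 32, 31, 31.5),   # group 2: glucose period 1, d1 = 2 > d2 = 0.5 -> 1
    P02 = c(30, 29, 30, 29.8),   # d1 = -1 < d2 = -0.2 (less worsening untreated) -> 0
    P03 = c(35, 36, 35, 37)      # group 1: glucose period 2, d2 = 2 > d1 = 1 -> 1
  ))
  rec <- assign_recommendation_groups(ph, ann)
  r <- setNames(rec$assignment$r, rec$assignment$participant_id)
  expect_identical(r, c(P01 = 1L, P02 = 0L, P03 = 1L))
  expect_equal(rec$assignment$delta1[rec$assignment$participant_id == "P01"], 2)
  expect_equal(rec$assignment$delta2[rec$assignment$participant_id == "P01"], 0.5)
})

test_that("ties are not recommended and are flagged; missing VO2 excludes with reason", {
  ann <- two_person_annotation(c(2L, 1L))
  ph <- make_pheno(list(P01 = c(30, 31, 32, 33), P02 = c(30, 31, 32, NA)))
  rec <- assign_recommendation_groups(ph, ann)
  expect_identical(rec$assignment$participant_id, "P01")
  expect_identical(rec$assignment$r, 0L)
  expect_true(rec$assignment$tie)
  expect_identical(rec$excluded$participant_id, "P02")
  expect_match(rec$excluded$reason, "missing VO2")
})

test_that("the assignment depends only on within-participant differences", {
  ann <- two_person_annotation(c(2L, 1L))
  ph1 <- make_pheno(list(P01 = c(30, 33, 31, 32), P02 = c(40, 41, 40, 44)))
  ph2 <- ph1
  ph2$vo2max[ph2$participant_id == "P01"] <- ph2$vo2max[ph2$participant_id == "P01"] + 7
  r1 <- assign_recommendation_groups(ph1, ann)
  r2 <- assign_recommendation_groups(ph2, ann)
  expect_identical(r1$assignment$r, r2$assignment$r)
})

test_that("noiseless synthetic trajectories recover the planted responder class exactly", {
  for (s in c(1, 12)) {
    st <- cached_study(s)
    rec <- assign_recommendation_groups(st$phenotypes, st$annotation)
    expect_equal(nrow(rec$excluded), 0L)
    expect_identical(rec$assignment$r,
                     as.integer(st$truth$responder[rec$assignment$participant_id]))
  }
})

test_that("marker evaluation assigns each sample to exactly one cell and guards small groups", {
  st <- cached_study(1)
  prep <- cached_preprocessed(1)
  ann <- st$annotation[st$annotation$sample_id %in% sample_ids(prep$expr), ]
  rec <- assign_recommendation_groups(st$phenotypes, ann)
  ev <- evaluate_marker(prep$expr, ann, rec, "miR-532-5p")
  expect_equal(sum(ev$cells$n), nrow(ann))
  expect_equal(nrow(ev$tests), 4L)
  expect_false(anyNA(ev$tests$p_value))
  # the planted contrast shows exactly in the post-training no-glucose cell
  pn <- ev$tests[ev$tests$timepoint_class == "T2_post" &
                   ev$tests$condition == "-Glucose", ]
  expect_lt(pn$p_value, 0.05)
  others <- ev$tests[!(ev$tests$timepoint_class == "T2_post" &
                         ev$tests$condition == "-Glucose"), ]
  expect_gt(min(others$p_value), 0.05)
  expect_error(evaluate_marker(prep$expr, ann, rec, "not-a-feature"), "not present")
  expect_s3_class(tidy(rec), "tbl_df")
})

test_that("marker fold changes correlate with VO2 deltas within recommendation groups", {
  st <- cached_study(1)
  prep <- cached_preprocessed(1)
  ann <- st$annotation[st$annotation$sample_id %in% sample_ids(prep$expr), ]
  rec <- assign_recommendation_groups(st$phenotypes, ann)
  ev <- evaluate_marker(prep$expr, ann, rec, "miR-532-5p", st$phenotypes)
  expect_equal(nrow(ev$correlations), 4L)
  expect_true(all(abs(ev$correlations$rho) <= 1, na.rm = TRUE))
})

test_that("the Welch statistics agree with the closed-form oracle and are symmetric", {
  set.seed(20)
  a <- rnorm(10, 6.5, 0.3)
  b <- rnorm(9, 6.2, 0.4)
  ref <- welch_oracle(a, b)
  tt <- t.test(a, b)
  expect_equal(unname(tt$statistic), ref$statistic, tolerance = 1e-12)
  expect_equal(tt$p.value, ref$p_value, tolerance = 1e-12)
  swapped <- welch_oracle(b, a)
  expect_equal(swapped$p_value, ref$p_value, tolerance = 1e-12)
  expect_equal(swapped$statistic, -ref$statistic, tolerance = 1e-12)
})

test_that("summary statistics of the reported marker contrast give a Welch p near 0.024", {
  # group means/sds/sizes of the post-training no-glucose cell
  n1 <- 10; n2 <- 9
  m1 <- 6.727; s1 <- 0.233
  m2 <- 6.356; s2 <- 0.396
  se2 <- s1^2 / n1 + s2^2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(abs(tt), df, lower.tail = FALSE)
  expect_lt(abs(p - 0.02359), 0.01)
  expect_lt(p, 0.05)
})

test_that("the marker screen recovers the planted marker and respects alpha = 0", {
  st <- cached_study(1)
  prep <- cached_preprocessed(1)
  ann <- st$annotation[st$annotation$sample_id %in% sample_ids(prep$expr), ]
  rec <- assign_recommendation_groups(st$phenotypes, ann)
  sc <- screen_markers(prep$expr, ann, rec)
  expect_identical(sc$feature_id[1], "miR-532-5p")
  expect_equal(sc$rank[1], 1)
  expect_true(all(is.na(sc$rank[!sc$candidate])))
  # candidate pattern definition
  cand <- sc[sc$candidate, ]
  expect_true(all(cand$p_post_noglc < 0.05 & cand$p_pre_noglc >= 0.05 &
                    cand$p_pre_glc >= 0.05 & cand$p_post_glc >= 0.05))
  none <- screen_markers(prep$expr, ann, rec, alpha = 0)
  expect_equal(sum(none$candidate), 0L)
})
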