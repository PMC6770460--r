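make_paired_data <- function(n_features = 5, n_part = 6, shift = 0, noise = 0,
                             seed = 1) {
  set.seed(seed)
  ann <- tiny_annotation(n_part)
  base <- matrix(rnorm(n_features * n_part, 8, 1), n_features, n_part)
  vals <- matrix(NA_real_, n_features, nrow(ann),
                 dimnames = list(paste0("f", seq_len(n_features)), ann$sample_id))
  for (i in seq_len(nrow(ann))) {
    p <- as.integer(sub("P", "", ann$participant_id[i]))
    vals[, i] <- base[, p] +
      ifelse(ann$timepoint[i] %in% c("A1", "A2"), shift, 0) +
      rnorm(n_features, 0, noise)
  }
  list(expr = mir_expr(vals, log2_scale = TRUE), ann = ann)
}

test_that("identical pre and post samples give zero fold change and no calls", {
  d <- make_paired_data(shift = 0, noise = 0)
  de <- run_de(d$expr, d$ann, "pooled_P1")
  expect_true(all(de$table$log2fc == 0))
  expect_true(all(de$table$direction == "none"))
  expect_true(all(de$table$p_value == 1))
})

test_that("a planted two-unit shift is called up and matches t.test feature by feature", {
  d <- make_paired_data(n_features = 8, n_part = 10, shift = 2, noise = 0.1, seed = 3)
  de <- run_de(d$expr, d$ann, "pooled_P1")
  expect_true(all(de$table$direction == "up"))
  pre <- d$ann$sample_id[d$ann$timepoint == "E1"]
  post <- d$ann$sample_id[d$ann$timepoint == "A1"]
  for (f in feature_ids(d$expr)) {
    ref <- t.test(d$expr$values[f, post], d$expr$values[f, pre], paired = TRUE)
    row <- de$table[de$table$feature_id == f, ]
    expect_equal(row$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(row$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("unpaired mode matches a Welch oracle and subsets follow the design", {
  st <- cached_study(1)
  prep <- cached_preprocessed(1)
  ann <- st$annotation[st$annotation$sample_id %in% sample_ids(prep$expr), ]
  de <- run_de(prep$expr, ann, "CHO_P1", paired = FALSE)
  # CHO in period 1 = order group 2 participants only
  pre <- ann$sample_id[ann$timepoint == "E1" & ann$order_group == 2L]
  post <- ann$sample_id[ann$timepoint == "A1" & ann$order_group == 2L]
  f <- feature_ids(prep$expr)[5]
  orc <- welch_oracle(prep$expr$values[f, post], prep$expr$values[f, pre])
  row <- de$table[de$table$feature_id == f, ]
  expect_equal(row$statistic, orc$statistic, tolerance = 1e-12)
  expect_equal(row$p_value, orc$p_value, tolerance = 1e-12)
  expect_equal(row$n_pre, length(pre))
})

test_that("constant nonzero paired differences are reported at the representable floor", {
  ann <- tiny_annotation(6)
  set.seed(2)
  base <- matrix(round(rnorm(2 * 6, 8, 1) * 4) / 4, 2, 6)  # binary-exact values
  p_idx <- as.integer(sub("P", "", ann$participant_id))
  vals <- base[, p_idx] + 1.5 * rep(ann$timepoint %in% c("A1", "A2"), each = 2)
  dimnames(vals) <- list(c("f1", "f2"), ann$sample_id)
  d <- list(expr = mir_expr(vals, log2_scale = TRUE), ann = ann)
  expect_message(de <- run_de(d$expr, d$ann, "pooled_P1"), "constant nonzero")
  expect_true(all(de$table$p_value == .Machine$double.xmin))
  expect_true(all(is.infinite(de$table$statistic)))
  expect_true(all(de$table$direction == "up"))
})

test_that("volcano classification counts partition the features and ignore order", {
  prep <- cached_preprocessed(1)
  st <- cached_study(1)
  ann <- st$annotation[st$annotation$sample_id %in% sample_ids(prep$expr), ]
  de <- run_de(prep$expr, ann, "pooled_P1")
  cnt <- table(de$table$direction)
  expect_equal(sum(cnt), nrow(de$table))
  shuf <- expr_subset(prep$expr, features = sample(nrow(prep$expr$values)))
  de2 <- run_de(shuf, ann, "pooled_P1")
  m <- dplyr::inner_join(de$table, de2$table, by = "feature_id")
  expect_identical(m$direction.x, m$direction.y)
})

test_that("DE on permuted labels yields uniform p-values", {
  set.seed(77)
  n_part <- 12
  ann <- tiny_annotation(n_part)
  vals <- matrix(rnorm(2000 * nrow(ann), 8, 1), 2000, nrow(ann),
                 dimnames = list(paste0("f", 1:2000), ann$sample_id))
  de <- run_de(mir_expr(vals, log2_scale = TRUE), ann, "pooled_P1")
  ks <- suppressWarnings(ks.test(de$table$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("run_all_de covers the six comparison setups", {
  st <- cached_study(1)
  prep <- cached_preprocessed(1)
  ann <- st$annotation[st$annotation$sample_id %in% sample_ids(prep$expr), ]
  all_de <- run_all_de(prep$expr, ann)
  expect_setequal(unique(all_de$setup), comparison_setups()$setup)
  expect_equal(nrow(all_de), 6 * nrow(prep$expr$values))
  expect_error(run_de(prep$expr, ann, "nope"), "Unknown setup")
})

test_that("BH adjustment matches the step-up oracle and validates input", {
  expect_equal(bh_adjust(rep(0.03, 5)), rep(0.03, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(12)
  for (i in 1:5) {
    p <- runif(50)
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # adjusted never below raw
  p <- runif(30)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("Fisher set-difference test matches closed forms and fisher.test", {
  a <- paste0("m", 1:10)
  res <- fisher_set_difference(a, a, universe_size = 100)
  expect_equal(res$table[1, 1], 10)
  expect_equal(res$p_value,
               fisher.test(matrix(c(10, 0, 0, 90), 2))$p.value, tolerance = 1e-12)

  dis <- fisher_set_difference(paste0("x", 1:3), paste0("y", 1:3), 1000)
  expect_gt(dis$p_value, 0.9)

  # Table-1-like configuration: |A| = 32, |B| = 19, overlap 12, universe 307
  setA <- paste0("m", 1:32)
  setB <- paste0("m", c(1:12, 100:106))
  r <- fisher_set_difference(setA, setB, 307)
  expect_equal(unname(r$table),
               matrix(c(12, 20, 7, 268), 2, byrow = TRUE))
  expect_equal(r$p_value,
               fisher.test(matrix(c(12, 20, 7, 268), 2, byrow = TRUE))$p.value,
               tolerance = 1e-12)
  # union-based construction is the documented alternative
  ru <- fisher_set_difference(setA, setB, 307, construction = "union")
  expect_equal(ru$table[2, 2], 0)
  expect_error(fisher_set_difference(setA, setB, 10), "smaller")
})
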