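#' Principal variance component analysis (PVCA)
#'
#' Attributes expression variance to annotated design factors. The algorithm:
#' (1) eigendecompose the sample-by-sample covariance of the feature-centered
#' matrix; (2) retain the smallest set of leading principal components whose
#' cumulative eigenvalue share reaches `var_threshold`; (3) decompose each
#' retained PC score vector into variance components for all factors and all
#' identifiable pairwise interactions; (4) average the per-PC attributions
#' weighted by each PC's share of the total variance, assigning the variance
#' of the unretained trailing components — noise-dominated by construction —
#' to the residual; (5) clamp the aggregate at zero and normalize to sum 1.
#'
#' Two variance-component engines are available. The default `"anova"` engine
#' solves the Henderson-style method-of-moments system built from the
#' projection quadratic forms of every term; it is a linear (hence nearly
#' unbiased) functional of the data, so planted variance fractions are
#' recovered without the boundary-truncation inflation that maximum
#' likelihood engines show when many weak components are averaged.
#' `"reml"` fits `lme4` mixed models per component (non-negative components),
#' matching the estimator popularized by the original PVCA implementations;
#' it falls back to the moment solver when a fit fails.
#'
#' Interactions that replicate one of their parent partitions, or in which
#' most levels hold a single sample (e.g. participant x timepoint in a
#' cross-over with one sample per cell), are unidentifiable against parent or
#' residual variance and are dropped with a warning.
#'
#' @param x A [mir_expr] object (centered internally per feature; not scaled,
#'   following the PVCA convention).
#' @param annotation Annotation tibble containing `sample_id` and the factor
#'   columns.
#' @param factors Character vector of annotation columns to use as main
#'   effects; each needs >= 2 levels on the analyzed samples.
#' @param var_threshold Cumulative variance threshold for PC retention
#'   (default 0.9).
#' @param interactions Include pairwise interactions (default `TRUE`).
#' @param estimator `"anova"` (default) or `"reml"`.
#' @return A `mir_pvca` object whose `proportions` tibble has one row per
#'   term (`term`, `proportion`) including `resid`, proportions summing to 1;
#'   `per_component` holds the unconstrained per-PC attributions and weights;
#'   `n_components` records how many PCs were analyzed.
#' @export
run_pvca <- function(x, annotation, factors, var_threshold = 0.9,
                     interactions = TRUE, estimator = c("anova", "reml")) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(x, "mir_expr"))
  assert_scalar_number(var_threshold, "var_threshold", min = 0, max = 1)
  ann <- annotation[match(sample_ids(x), annotation$sample_id), , drop = FALSE]
  if (anyNA(ann$sample_id)) abort("Annotation must cover every analyzed sample.")
  missing <- setdiff(factors, names(ann))
  if (length(missing)) {
    abort(sprintf("Factor column(s) not in annotation: %s.",
                  paste(missing, collapse = ", ")))
  }
  fac <- lapply(setNames(factors, factors),
                function(f) factor(as.character(ann[[f]])))
  ok <- vapply(fac, nlevels, 1L) >= 2L
  if (!all(ok)) {
    warn(sprintf("Dropping single-level factor(s): %s.",
                 paste(factors[!ok], collapse = ", ")))
    fac <- fac[ok]
  }
  if (!length(fac)) abort("No usable factors (all have < 2 levels).")
  n <- ncol(x$values)

  terms <- build_pvca_terms(fac, n, interactions)

  xc <- x$values - rowMeans(x$values)
  cv <- crossprod(xc) / (nrow(xc) - 1)   # sample covariance across features
  eig <- eigen(cv, symmetric = TRUE)
  evals <- pmax(eig$values, 0)
  share <- evals / sum(evals)
  k <- which(cumsum(share) >= var_threshold)[1]
  if (is.na(k)) k <- length(share)
  weights <- share[seq_len(k)]

  mom <- mom_system(terms, n)
  per_pc <- matrix(0, k, length(terms) + 1L,
                   dimnames = list(NULL, c(names(terms), "resid")))
  for (i in seq_len(k)) {
    score <- eig$vectors[, i]
    vc <- if (estimator == "reml") {
      pvca_reml_one_pc(score, terms, mom)
    } else {
      mom_solve(score, mom)
    }
    tot <- sum(pmax(vc, 0))
    per_pc[i, ] <- if (tot > 0) vc / tot else c(rep(0, length(terms)), 1)
  }
  avg <- colSums(per_pc * weights)
  # trailing components below the retention threshold are noise-dominated
  avg[["resid"]] <- avg[["resid"]] + (1 - sum(weights))
  avg <- pmax(avg, 0)
  avg <- avg / sum(avg)
  structure(list(
    proportions = tibble(term = names(avg), proportion = unname(avg)) |>
      dplyr::arrange(dplyr::desc(.data$proportion)),
    per_component = as_tibble(per_pc) |>
      dplyr::mutate(component = dplyr::row_number(), weight = weights,
                    .before = 1L),
    n_components = k,
    var_threshold = var_threshold,
    estimator = estimator
  ), class = "mir_pvca")
}

# Assemble main-effect and identifiable pairwise-interaction grouping factors.
build_pvca_terms <- function(fac, n, interactions) {
  terms <- fac
  if (interactions && length(fac) >= 2L) {
    combos <- utils::combn(names(fac), 2L, simplify = FALSE)
    for (cb in combos) {
      ia <- interaction(fac[[cb[1]]], fac[[cb[2]]], drop = TRUE)
      nm <- paste(sort(cb), collapse = ":")  # canonical, order-invariant name
      if (nlevels(ia) >= n || mean(tabulate(ia) == 1L) > 0.5) {
        warn(sprintf("Interaction %s has (almost) one sample per level; dropped (not separable from residual variance).", nm))
        next
      }
      dup <- vapply(terms, function(t) identical_partition(t, ia), TRUE)
      if (any(dup)) {
        warn(sprintf("Interaction %s replicates the partition of %s; dropped.",
                     nm, names(terms)[dup][1]))
        next
      }
      if (nlevels(ia) < 2L) next
      terms[[nm]] <- ia
    }
  }
  terms
}

# Two grouping factors induce the same partition iff their joint factor has
# no more levels than either of them.
identical_partition <- function(a, b) {
  a <- droplevels(a); b <- droplevels(b)
  nlevels(a) == nlevels(b) &&
    nlevels(interaction(a, b, drop = TRUE)) == nlevels(a)
}

# Precompute the Henderson method-of-moments system shared by all PCs:
# for each term, the projection onto its (centered) group-mean space and the
# expected-value coefficients of every quadratic form.
mom_system <- function(terms, n) {
  M <- diag(n) - 1 / n
  Cs <- lapply(terms, function(g) {
    Z <- model.matrix(~ 0 + g)
    M %*% tcrossprod(Z) %*% M
  })
  Ps <- lapply(terms, function(g) {
    Z <- M %*% model.matrix(~ 0 + g)
    qrz <- qr(Z)
    Q <- qr.Q(qrz)[, seq_len(qrz$rank), drop = FALSE]
    tcrossprod(Q)
  })
  k <- length(terms)
  A <- matrix(0, k + 1L, k + 1L)
  for (m in seq_len(k)) {
    for (j in seq_len(k)) A[m, j] <- sum(Ps[[m]] * Cs[[j]])
    A[m, k + 1L] <- sum(diag(Ps[[m]]))
  }
  for (j in seq_len(k)) A[k + 1L, j] <- sum(diag(Cs[[j]]))
  A[k + 1L, k + 1L] <- n - 1
  list(A = A, Ps = Ps, names = c(names(terms), "resid"))
}

# Solve the moment equations for one score vector. The solution is left
# unconstrained per component (negative values average out across PCs);
# only the aggregated proportions are clamped.
mom_solve <- function(y, mom) {
  y <- y - mean(y)
  k <- length(mom$Ps)
  q <- c(vapply(mom$Ps, function(P) drop(crossprod(y, P %*% y)), 0), sum(y^2))
  sol <- tryCatch(qr.solve(mom$A, q), error = function(e) {
    c(rep(0, k), sum(y^2) / (length(y) - 1))
  })
  setNames(sol, mom$names)
}

# REML engine (per-PC lme4 fit, non-negative components); moment fallback.
pvca_reml_one_pc <- function(score, terms, mom) {
  df <- data.frame(.score = score, lapply(terms, identity),
                   check.names = FALSE)
  rhs <- paste(sprintf("(1 | `%s`)", names(terms)), collapse = " + ")
  fit <- tryCatch(
    suppressMessages(suppressWarnings(lme4::lmer(
      stats::as.formula(paste(".score ~", rhs)), data = df, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore",
                                  calc.derivs = FALSE)))),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    inform("REML fit failed for one component; using the moment solver.")
    return(mom_solve(score, mom))
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  out <- setNames(numeric(length(terms) + 1L), c(names(terms), "resid"))
  for (j in seq_len(nrow(vc))) {
    nm <- if (vc$grp[j] == "Residual") "resid" else vc$grp[j]
    out[nm] <- vc$vcov[j]
  }
  pmax(out, 0)
}

#' @export
print.mir_pvca <- function(x, ...) {
  cat(sprintf("<mir_pvca> %d components analyzed (threshold %.2f, %s estimator)\n",
              x$n_components, x$var_threshold, x$estimator))
  print(x$proportions, n = 8)
  invisible(x)
}

#' @rdname run_pvca
#' @param object A `mir_pvca` object (for `autoplot`).
#' @param ... Unused.
#' @export
autoplot.mir_pvca <- function(object, ...) {
  df <- dplyr::mutate(object$proportions,
                      term = factor(.data$term, levels = rev(.data$term)))
  ggplot2::ggplot(df, ggplot2::aes(.data$term, .data$proportion)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Weighted variance proportion") +
    ggplot2::theme_minimal()
}
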