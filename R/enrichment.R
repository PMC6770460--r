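#' Hypergeometric enrichment of sample clusters in an annotation flag
#'
#' For each cluster of samples (e.g. delineated on a 2-D embedding), tests
#' whether the cluster is enriched for flag-positive samples: the p-value is
#' the upper tail P(X >= k) of a hypergeometric draw of the cluster size from
#' the analyzed samples, where k is the number of flag-positives inside the
#' cluster. Embeddings themselves (t-SNE/UMAP) are treated as external; only
#' labels enter here.
#'
#' @param labels Data frame with columns `sample_id` and `cluster`.
#' @param flags Data frame with columns `sample_id` and a logical `flag`
#'   column (its name given by `flag_col`).
#' @param flag_col Name of the logical column in `flags` (default `"flag"`).
#' @return A tibble with one row per cluster: `cluster`, `n`, `k`,
#'   `expected`, `p_value`.
#' @examples
#' labels <- tibble::tibble(sample_id = paste0("s", 1:10),
#'                          cluster = rep(c("a", "b"), each = 5))
#' flags <- tibble::tibble(sample_id = paste0("s", 1:10),
#'                         flag = rep(c(TRUE, FALSE), each = 5))
#' cluster_enrichment(labels, flags)
#' @export
cluster_enrichment <- function(labels, flags, flag_col = "flag") {
  need <- c("sample_id", "cluster")
  if (!all(need %in% names(labels))) {
    abort("`labels` needs columns sample_id and cluster.")
  }
  if (!flag_col %in% names(flags)) {
    abort(sprintf("`flags` has no column '%s'.", flag_col))
  }
  df <- dplyr::inner_join(as_tibble(labels),
                          as_tibble(flags)[c("sample_id", flag_col)],
                          by = "sample_id")
  if (nrow(df) < nrow(labels)) {
    warn(sprintf("%d labelled sample(s) missing from `flags` were dropped.",
                 nrow(labels) - nrow(df)))
  }
  fl <- as.logical(df[[flag_col]])
  N <- nrow(df)
  K <- sum(fl)
  df |>
    dplyr::group_by(cluster = .data$cluster) |>
    dplyr::summarise(n = dplyr::n(), k = sum(.data[[flag_col]]),
                     .groups = "drop") |>
    dplyr::mutate(
      expected = .data$n * K / N,
      # upper tail P(X >= k), X ~ Hypergeom(N, K, n)
      p_value = phyper(.data$k - 1L, K, N - K, .data$n, lower.tail = FALSE)
    ) |>
    (\(tb) {
      if (any(tb$n == 0)) {
        warn("Empty cluster: p-value reported as 1.")
        tb$p_value[tb$n == 0] <- 1
      }
      tb
    })()
}
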