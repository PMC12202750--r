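#' t-SNE projection of feature vectors
#'
#' Seeded two-dimensional t-SNE embedding of (typically) the pooled
#' penultimate-layer features from [pooled_features()], used to visualize
#' class separation before and after training.
#'
#' @param features Numeric matrix (rows = examples) or data frame of
#'   feature columns.
#' @param seed Integer seed.
#' @param perplexity t-SNE perplexity (default 30); requires at least
#'   `3 * perplexity` rows.
#' @param labels Optional class labels carried into the output.
#' @return A tibble with columns `tsne1`, `tsne2` (and `label` if given), one
#'   row per input row.
#' @export
tsne_project <- function(features, seed = 1L, perplexity = 30, labels = NULL) {
  x <- as.matrix(features)
  if (nrow(x) < 3 * perplexity) {
    abort(paste0("t-SNE needs at least 3 * perplexity = ", 3 * perplexity,
                 " points; got ", nrow(x)))
  }
  set.seed(seed)
  fit <- Rtsne::Rtsne(x, dims = 2, perplexity = perplexity,
                      check_duplicates = FALSE, pca = FALSE, verbose = FALSE)
  out <- tibble(tsne1 = fit$Y[, 1], tsne2 = fit$Y[, 2])
  if (!is.null(labels)) out$label <- labels
  class(out) <- c("kd_tsne", class(out))
  out
}
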