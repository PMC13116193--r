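#' PCA embedding of a gait dataset
#'
#' Flattens each sample's channel matrix into a feature vector, centres
#' the features and projects onto the leading principal components, for
#' visualising how the gait classes cluster.
#'
#' @param dataset A `gait_dataset` (or a plain numeric matrix of samples
#'   in rows).
#' @param n_components Number of components to return (default 2).
#' @return List of class `pca_embedding`: `coordinates` (samples x
#'   `n_components`), `explained_variance` (fractions, non-increasing),
#'   `labels`, and the full `prcomp` fit under `$fit`.
#' @export
pca_embed <- function(dataset, n_components = 2L) {
  if (inherits(dataset, "gait_dataset")) {
    X <- do.call(rbind, lapply(dataset$samples,
                               function(s) as.numeric(s$channels)))
    labels <- vapply(dataset$samples, `[[`, "", "label")
  } else {
    X <- as.matrix(dataset)
    labels <- rownames(X)
  }
  if (n_components > ncol(X))
    stop("n_components (", n_components, ") exceeds the feature dimension (",
         ncol(X), ")")
  if (nrow(X) < n_components)
    stop("need at least n_components samples")
  fit <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(fit$rotation))
  ev <- fit$sdev^2 / sum(fit$sdev^2)
  structure(list(
    coordinates = fit$x[, seq_len(k), drop = FALSE],
    explained_variance = ev[seq_len(k)],
    labels = labels,
    fit = fit
  ), class = "pca_embedding")
}
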