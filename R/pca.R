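# PCA projection for chemical-space plots.

#' Project a feature block onto principal components
#'
#' Columns are z-scored before decomposition (mixing atom counts with logP
#' makes unscaled PCA meaningless); zero-variance columns are dropped.
#' Components are ordered by decreasing explained variance.
#'
#' @param features numeric matrix or `feature_block` (rows are compounds).
#' @param k number of components to return.
#' @return list with `scores` (n x k), `loadings`, `explained_variance`
#'   (proportion per component, all components), `dropped_columns`.
#' @export
pca_project <- function(features, k = 2) {
  x <- unclass(features)
  stopifnot(is.matrix(x), all(is.finite(x)))
  sds <- apply(x, 2L, stats::sd)
  keep <- sds > 0
  if (sum(keep) < k) stop("fewer informative columns than components requested")
  fit <- stats::prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  ev <- fit$sdev^2 / sum(fit$sdev^2)
  list(scores = fit$x[, seq_len(k), drop = FALSE],
       loadings = fit$rotation[, seq_len(k), drop = FALSE],
       explained_variance = ev,
       dropped_columns = colnames(x)[!keep])
}
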