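# Butina sphere-exclusion clustering and similarity-constrained fold
# assignment for cross-validation.

#' Butina sphere-exclusion clustering
#'
#' Classic Butina clustering on Tanimoto similarity: neighbor lists are
#' computed once at `similarity_floor`; centroid candidates are visited in
#' order of decreasing neighbor count (ties broken by input order); each
#' unassigned candidate becomes a centroid and claims its unassigned
#' neighbors. Every cluster member has similarity >= `similarity_floor`
#' to its centroid. Singletons are allowed.
#'
#' @param fingerprints 0/1 matrix, rows are compounds.
#' @param similarity_floor minimum Tanimoto similarity to the centroid.
#' @return integer vector of cluster ids (1-based, in order of cluster
#'   creation) with attribute `centroids` (row index of each centroid).
#' @export
butina_cluster <- function(fingerprints, similarity_floor = 0.3) {
  fp <- unclass(fingerprints)
  stopifnot(is.matrix(fp), nrow(fp) >= 1L)
  n <- nrow(fp)
  sims <- tanimoto_matrix(fp, fp)
  neighbors <- lapply(seq_len(n), function(i) {
    which(sims[i, ] >= similarity_floor & seq_len(n) != i)
  })
  counts <- lengths(neighbors)
  order_idx <- order(-counts, seq_len(n))
  cluster <- rep(NA_integer_, n)
  centroids <- integer(0)
  next_id <- 0L
  for (i in order_idx) {
    if (!is.na(cluster[i])) next
    next_id <- next_id + 1L
    members <- c(i, neighbors[[i]][is.na(cluster[neighbors[[i]]])])
    cluster[members] <- next_id
    centroids <- c(centroids, i)
  }
  attr(cluster, "centroids") <- centroids
  cluster
}

#' Assign Butina clusters to cross-validation folds
#'
#' Clusters are shuffled with the seeded generator and then assigned
#' greedily to the currently smallest fold, visiting clusters in
#' descending size order (the shuffle breaks ties between equal-sized
#' clusters). This keeps fold sizes as similar as possible while never
#' splitting a cluster; the fold-size spread is bounded by the largest
#' cluster size.
#'
#' @param cluster_ids integer vector from [butina_cluster()].
#' @param k number of folds.
#' @param seed integer seed for the shuffle.
#' @return a `fold_plan`: data.frame with `index`, `cluster_id`, `fold_id`
#'   (in 1..k).
#' @export
assign_folds <- function(cluster_ids, k = 5, seed = 42) {
  stopifnot(k >= 2)
  ids <- unique(cluster_ids)
  sizes <- vapply(ids, function(cl) sum(cluster_ids == cl), 0L)
  shuffled <- with_seed(seed, sample(seq_along(ids)))
  shuffled <- shuffled[order(-sizes[shuffled])]  # stable: ties stay shuffled
  fold_of_cluster <- integer(length(ids))
  fold_tot <- integer(k)
  for (pos in shuffled) {
    target <- which.min(fold_tot)  # ties: lowest fold id
    fold_of_cluster[pos] <- target
    fold_tot[target] <- fold_tot[target] + sizes[pos]
  }
  fold_id <- fold_of_cluster[match(cluster_ids, ids)]
  plan <- data.frame(index = seq_along(cluster_ids),
                     cluster_id = as.integer(cluster_ids),
                     fold_id = fold_id)
  class(plan) <- c("fold_plan", class(plan))
  plan
}

#' @export
print.fold_plan <- function(x, ...) {
  tab <- table(x$fold_id)
  cat(sprintf("fold_plan: %d compounds, %d clusters, %d folds (sizes %s)\n",
              nrow(x), length(unique(x$cluster_id)), length(tab),
              paste(as.integer(tab), collapse = "/")))
  invisible(x)
}

# Evaluate code with a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
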