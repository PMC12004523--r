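# SMOTE-style minority oversampling, applied to training folds only.

#' Balance classes by synthetic minority oversampling (SMOTE)
#'
#' Augments the minority class with synthetic points until the classes are
#' exactly balanced. Each synthetic point interpolates between a minority
#' point and one of its k nearest minority neighbors (Euclidean distance):
#' `x_new = x_i + u * (x_j - x_i)`, `u ~ U(0, 1)`. Original rows are
#' preserved verbatim. Two modes:
#' \describe{
#'   \item{`continuous`}{plain interpolation; on binary fingerprints this
#'     yields fractional bit values, which tree ensembles handle
#'     indifferently (intentional).}
#'   \item{`nominal`}{SMOTENC-style handling for binary panels: each
#'     synthetic feature takes the majority value among the pair's k
#'     nearest minority neighbors (ties resolved toward `x_i`).}
#' }
#'
#' @param x numeric feature matrix.
#' @param y label vector (two classes required).
#' @param mode `"continuous"` or `"nominal"`.
#' @param seed integer seed.
#' @param k number of minority neighbors considered.
#' @return list with balanced `x`, `y` and `n_synthetic`.
#' @export
smote_balance <- function(x, y, mode = c("continuous", "nominal"),
                          seed = 42, k = 5) {
  mode <- match.arg(mode)
  x <- unclass(x)
  stopifnot(is.matrix(x), nrow(x) == length(y))
  storage.mode(x) <- "double"  # synthetic rows are fractional
  classes <- unique(as.character(y))
  if (length(classes) != 2L) {
    stop("smote_balance() requires exactly two classes, got ",
         length(classes))
  }
  y <- as.character(y)
  n_by <- table(y)
  if (n_by[1] == n_by[2]) {
    return(list(x = x, y = y, n_synthetic = 0L))
  }
  minority <- names(n_by)[which.min(n_by)]
  min_idx <- which(y == minority)
  need <- as.integer(abs(diff(range(n_by))))
  xm <- x[min_idx, , drop = FALSE]
  nm <- nrow(xm)

  synth <- matrix(NA_real_, need, ncol(x))
  if (nm == 1L) {
    # degenerate: a single minority point can only be replicated
    synth[] <- rep(xm[1L, ], each = need)
  } else {
    k_eff <- min(k, nm - 1L)
    d <- as.matrix(stats::dist(xm))
    diag(d) <- Inf
    nn <- do.call(rbind, lapply(seq_len(nm), function(i) {
      order(d[i, ])[seq_len(k_eff)]
    }))
    draws <- with_seed(seed, {
      list(base = sample.int(nm, need, replace = TRUE),
           pick = sample.int(k_eff, need, replace = TRUE),
           gap = stats::runif(need))
    })
    for (s in seq_len(need)) {
      i <- draws$base[s]
      j <- nn[i, draws$pick[s]]
      if (mode == "continuous") {
        synth[s, ] <- xm[i, ] + draws$gap[s] * (xm[j, ] - xm[i, ])
      } else {
        votes <- xm[nn[i, ], , drop = FALSE]
        maj <- colSums(votes) / nrow(votes)
        synth[s, ] <- ifelse(maj > 0.5, 1, ifelse(maj < 0.5, 0, xm[i, ]))
      }
    }
  }
  colnames(synth) <- colnames(x)
  list(x = rbind(x, synth),
       y = c(y, rep(minority, need)),
       n_synthetic = need)
}
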