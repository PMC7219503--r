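#' Multidimensional dynamic time warping distance
#'
#' Elastic alignment distance between two multivariate feature series of
#' possibly different lengths. The local cost between two frames is the
#' Euclidean distance over the (optionally z-scored) feature dimensions;
#' the accumulated cost is minimized over all monotone warping paths with
#' steps (1,0), (0,1), (1,1). No warping window is applied (sessions are
#' short, so the exact optimum is affordable).
#'
#' Because the features mix units (degrees, m, m/s, m/s^2), callers
#' normally pass `stats` (per-feature mean/SD pooled over a gold-standard
#' bank, see [gold_standard_bank()]) so that all dimensions contribute on
#' a comparable scale.
#'
#' @param a,b Feature matrices (`L x F`) or `"feature_series"` objects.
#' @param features Character vector of feature columns to use; default
#'   all shared columns.
#' @param stats Optional list with `mean` and `sd` named vectors used to
#'   z-score both inputs before alignment.
#' @param normalize_by_path If `TRUE`, also report the accumulated cost
#'   divided by the warping-path length.
#' @return A list with `distance`, `normalized_distance`, and `path`
#'   (an `m x 2` matrix of 1-based index pairs from `(1,1)` to
#'   `(L1, L2)`).
#' @examples
#' a <- matrix(c(0, 1, 2, 3), ncol = 1)
#' mddtw_distance(a, a)$distance  # 0
#' @export
mddtw_distance <- function(a, b, features = NULL, stats = NULL,
                           normalize_by_path = TRUE) {
  A <- feature_matrix(a)
  B <- feature_matrix(b)
  if (ncol(A) != ncol(B)) stop("feature dimension mismatch")
  if (nrow(A) < 1L || nrow(B) < 1L) stop("empty series")
  if (!is.null(stats)) {
    A <- zscore_features(A, stats)
    B <- zscore_features(B, stats)
  }
  cols <- feature_cols(A, features)
  res <- mddtw_align_cpp(A, B, cols)
  list(distance = res$distance,
       normalized_distance = res$normalized_distance,
       path = res$path)
}

feature_matrix <- function(x) {
  if (inherits(x, "feature_series")) x$features
  else if (is.matrix(x)) x
  else stop("expected a feature matrix or 'feature_series'")
}

feature_cols <- function(mat, features) {
  if (is.null(features)) return(seq_len(ncol(mat)))
  if (!length(features)) stop("empty feature subset")
  idx <- match(features, colnames(mat))
  if (anyNA(idx))
    stop("unknown features: ", paste(features[is.na(idx)], collapse = ", "))
  idx
}

zscore_features <- function(mat, stats) {
  mu <- stats$mean
  sdv <- stats$sd
  if (!is.null(colnames(mat)) && !is.null(names(mu))) {
    mu <- mu[colnames(mat)]
    sdv <- sdv[colnames(mat)]
  }
  sdv[!is.finite(sdv) | sdv <= 0] <- 1
  sweep(sweep(mat, 2, mu), 2, sdv, "/")
}
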