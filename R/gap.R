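# Gap statistic machinery: pooled within-cluster dispersion, uniform
# reference draws, the gap curve and the decision rule. This is the engine
# recursively applied by part_recursive().

#' Pooled within-cluster dispersion W_k
#'
#' `W_k = sum_r D_r / (2 n_r)` where `D_r` is the sum over all ordered
#' pairs within cluster `r` of squared Euclidean distances. Computed via
#' the algebraically identical sum of squared deviations from cluster
#' centroids.
#'
#' @param points Numeric matrix (observations x features).
#' @param labels Cluster assignment, one per row; every cluster non-empty.
#' @return The scalar dispersion `W_k`.
#' @examples
#' within_dispersion(matrix(c(0, 2)), c(1, 1))  # D = 8, W = 8/4 = 2
#' @export
within_dispersion <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.factor(labels)
  if (length(labels) != nrow(points)) {
    stop("within_dispersion(): one label per row required")
  }
  counts <- as.vector(table(labels))
  if (any(counts == 0)) stop("within_dispersion(): empty cluster")
  ctr <- rowsum(points, labels) / counts
  sum((points - ctr[labels, , drop = FALSE])^2)
}

#' Reference draw for the Gap statistic
#'
#' Draws each feature independently from the uniform distribution over that
#' feature's observed range in `points` (the simple, unrotated reference of
#' the Gap construction). Uses the current RNG state.
#'
#' @param points Numeric matrix whose featurewise ranges define the support.
#' @param method `"range"` draws over the observed ranges of the features
#'   as given; `"pca"` first rotates to the principal axes of the centred
#'   data, draws uniformly over the component ranges, and rotates back
#'   (the reference that respects the shape of elongated point clouds).
#' @return Matrix of the same dimension as `points`.
#' @export
reference_sample <- function(points, method = c("range", "pca")) {
  method <- match.arg(method)
  points <- as.matrix(points)
  n <- nrow(points)
  p <- ncol(points)
  if (method == "pca" && n > 1) {
    ctr <- colMeans(points)
    Xc <- sweep(points, 2, ctr)
    V <- svd(Xc, nu = 0)$v
    Z <- Xc %*% V
    ref <- reference_sample(Z, method = "range")
    return(sweep(ref %*% t(V), 2, ctr, "+"))
  }
  lo <- apply(points, 2, min)
  hi <- apply(points, 2, max)
  matrix(stats::runif(n * p, rep(lo, each = n), rep(hi, each = n)), n, p)
}

# Cluster a point set into 1..kmax groups with one backend.
# Returns an n x kmax matrix of labels; the hclust backend cuts one Ward
# tree, the kmeans backend runs stats::kmeans with multiple restarts.
cluster_assignments <- function(points, kmax, clusterer = c("hclust", "kmeans"),
                                nstart = 20) {
  clusterer <- match.arg(clusterer)
  n <- nrow(points)
  kmax <- min(kmax, n)
  out <- matrix(1L, n, kmax)
  if (kmax >= 2) {
    if (clusterer == "hclust") {
      hc <- stats::hclust(stats::dist(points), method = "ward.D2")
      out[, 2:kmax] <- stats::cutree(hc, k = 2:kmax)
    } else {
      for (k in 2:kmax) {
        km <- suppressWarnings(
          stats::kmeans(points, centers = k, nstart = nstart, iter.max = 50)
        )
        out[, k] <- km$cluster
      }
    }
  }
  out
}

#' Gap curve for k = 1..kmax
#'
#' Clusters the observed points and `B` uniform reference draws for each
#' `k`, recording observed `log W_k`, the reference mean and standard
#' deviation of `log W_k`, the gap `E[log W] - log W`, and
#' `s_k = sd_k * sqrt(1 + 1/B)`. Deterministic given the RNG state (set
#' `seed` for reproducibility).
#'
#' @param points Numeric matrix (n x p), n >= 2.
#' @param kmax Largest number of clusters examined; truncated to `n - 1`
#'   with a warning if necessary.
#' @param B Number of reference draws (>= 10; study protocol uses 1000).
#' @param clusterer `"hclust"` (Ward) or `"kmeans"`.
#' @param nstart Restarts for the kmeans backend.
#' @param seed Optional integer seed.
#' @return An object of class `gap_curve`: data frame with columns `k`,
#'   `log_w`, `elog_w`, `gap`, `s_k`, plus attribute `B`.
#' @export
gap_statistic <- function(points, kmax = 10, B = 100,
                          clusterer = c("hclust", "kmeans"), nstart = 20,
                          reference = c("pca", "range"), seed = NULL) {
  clusterer <- match.arg(clusterer)
  reference <- match.arg(reference)
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2) stop("gap_statistic(): need at least 2 points")
  if (B < 10) stop("gap_statistic(): B must be at least 10")
  if (kmax >= n) {
    warning("gap_statistic(): kmax >= n; truncated to n - 1")
    kmax <- n - 1L
  }
  kmax <- max(1L, as.integer(kmax))
  if (!is.null(seed)) set.seed(seed)

  log_w_of <- function(x) {
    lab <- cluster_assignments(x, kmax, clusterer, nstart)
    vapply(seq_len(kmax), function(k) {
      w <- within_dispersion(x, lab[, k])
      log(max(w, .Machine$double.xmin))
    }, numeric(1))
  }
  log_w <- log_w_of(points)
  ref <- t(vapply(seq_len(B),
                  function(b) log_w_of(reference_sample(points, reference)),
                  numeric(kmax)))
  elog_w <- colMeans(ref)
  sd_k <- sqrt(colMeans(sweep(ref, 2, elog_w)^2))   # population sd over B draws
  s_k <- sd_k * sqrt(1 + 1 / B)

  structure(data.frame(k = seq_len(kmax), log_w = log_w, elog_w = elog_w,
                       gap = elog_w - log_w, s_k = s_k),
            B = B, clusterer = clusterer, class = c("gap_curve", "data.frame"))
}

#' Gap decision rule
#'
#' The smallest `k` with `gap(k) >= gap(k+1) - s_(k+1)`; if no `k`
#' satisfies the rule, `kmax` is returned with a warning.
#'
#' @param curve A [gap_statistic()] curve (or data frame with columns
#'   `gap` and `s_k`).
#' @return The chosen number of clusters.
#' @export
choose_k <- function(curve) {
  gap <- curve$gap
  s <- curve$s_k
  K <- length(gap)
  if (K == 1) return(1L)
  for (k in seq_len(K - 1)) {
    if (gap[k] >= gap[k + 1] - s[k + 1]) return(k)
  }
  warning("choose_k(): no k satisfied the gap rule; returning kmax")
  K
}
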