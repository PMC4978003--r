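#' Configuration for recursive Gap-statistic partitioning
#'
#' @param min_size Minimum cluster size; terminal clusters smaller than
#'   this are flagged as outliers (default 5).
#' @param kmax Largest number of clusters examined per recursion level
#'   (default 10).
#' @param B Reference draws per gap curve (default 1000, the study
#'   protocol; tests use smaller B since only the reference mean/sd depend
#'   on it).
#' @param clusterer `"hclust"` or `"kmeans"`.
#' @param nstart kmeans restarts (default 20).
#' @param seed Integer seed; child seeds for recursion levels are derived
#'   deterministically from it.
#' @param max_depth Defensive recursion cap (default 10).
#' @return An object of class `part_config`.
#' @export
part_config <- function(min_size = 5, kmax = 10, B = 1000,
                        clusterer = c("hclust", "kmeans"), nstart = 20,
                        seed = NULL, max_depth = 10) {
  clusterer <- match.arg(clusterer)
  stopifnot(min_size >= 2, kmax >= 2, B >= 10)
  structure(list(min_size = as.integer(min_size), kmax = as.integer(kmax),
                 B = as.integer(B), clusterer = clusterer,
                 nstart = as.integer(nstart), seed = seed,
                 max_depth = as.integer(max_depth)),
            class = "part_config")
}

#' PART: recursive Gap-statistic partitioning
#'
#' Estimates the number of clusters and assigns every sample by recursive
#' application of the Gap statistic. The gap curve is computed on the full
#' set; if the decision rule returns `k = 1` the set is one terminal
#' cluster, otherwise it is split into `k` groups with the configured
#' clusterer and the procedure recurses on every subset with at least
#' `2 * min_size` cases (smaller subsets are terminal). Terminal clusters
#' with fewer than `min_size` members are flagged `"OUTLIER"`; this
#' reproduces the behaviour of running both top-level and nested
#' sub-cluster discovery in one pass.
#'
#' @param points Numeric matrix (samples x features), e.g. nest centroids
#'   in LD-score space.
#' @param sample_labels Optional sample names (default the matrix row
#'   names, else `S1..Sn`).
#' @param config A [part_config()].
#' @return An object of class `part_partition`: list with `labels` (named
#'   character vector, cluster ids `"C1"...` or `"OUTLIER"`), `outliers`,
#'   `method`, and `trace` (one gap curve record per recursion node).
#' @export
part_recursive <- function(points, sample_labels = NULL,
                           config = part_config()) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2) stop("part_recursive(): need at least 2 samples")
  if (is.null(sample_labels)) {
    sample_labels <- rownames(points)
    if (is.null(sample_labels)) sample_labels <- paste0("S", seq_len(n))
  }
  if (anyDuplicated(sample_labels)) {
    stop("part_recursive(): sample labels must be unique")
  }

  trace <- list()
  clusters <- list()
  node_counter <- 0L

  recurse <- function(idx, depth, node_id) {
    node_counter <<- node_counter + 1L
    seed <- if (is.null(config$seed)) NULL else
      (config$seed + 1000003 * node_counter) %% .Machine$integer.max
    m <- length(idx)
    sub <- points[idx, , drop = FALSE]
    curve <- suppressWarnings(
      gap_statistic(sub, kmax = config$kmax, B = config$B,
                    clusterer = config$clusterer, nstart = config$nstart,
                    seed = seed)
    )
    k <- choose_k(curve)
    trace[[length(trace) + 1L]] <<- list(node = node_id, n = m, k = k,
                                         depth = depth, curve = curve)
    if (k == 1) {
      clusters[[length(clusters) + 1L]] <<- idx
      return(invisible())
    }
    lab <- cluster_assignments(sub, k, config$clusterer, config$nstart)[, k]
    for (g in sort(unique(lab))) {
      sub_idx <- idx[lab == g]
      if (length(sub_idx) >= 2 * config$min_size &&
          depth < config$max_depth) {
        recurse(sub_idx, depth + 1L, paste0(node_id, ".", g))
      } else {
        if (depth >= config$max_depth) {
          warning("part_recursive(): recursion depth cap reached")
        }
        clusters[[length(clusters) + 1L]] <<- sub_idx
      }
    }
  }

  if (n < 2 * config$min_size) {
    clusters[[1L]] <- seq_len(n)
  } else {
    recurse(seq_len(n), 1L, "1")
  }

  labels <- character(n)
  cid <- 0L
  for (cl in clusters) {
    if (length(cl) >= config$min_size) {
      cid <- cid + 1L
      labels[cl] <- paste0("C", cid)
    } else {
      labels[cl] <- "OUTLIER"
    }
  }
  names(labels) <- sample_labels
  structure(list(labels = labels,
                 outliers = sample_labels[labels == "OUTLIER"],
                 method = config$clusterer, n_clusters = cid,
                 trace = trace, config = config),
            class = "part_partition")
}

#' @export
print.part_partition <- function(x, ...) {
  cat("part_partition (", x$method, "): ", x$n_clusters, " cluster(s), ",
      length(x$outliers), " outlier(s) among ", length(x$labels),
      " samples\n", sep = "")
  print(table(x$labels))
  invisible(x)
}

#' Consensus of two PART partitions with wild-card flagging
#'
#' Matches the cluster labels of `b` to those of `a` by greedy
#' maximum-overlap assignment, then gives each sample its hypothesis label
#' when both methods agree under the matching and neither flags it as an
#' outlier; every other sample becomes `"WILDCARD"` (no prior hypothesis
#' imposed in the confirmatory analysis).
#'
#' @param a,b [part_recursive()] results over the same sample set.
#' @return Named character vector: hypothesis label (a's cluster ids) or
#'   `"WILDCARD"`.
#' @export
consensus_partition <- function(a, b) {
  la <- a$labels
  lb <- b$labels
  if (!setequal(names(la), names(lb))) {
    stop("consensus_partition(): partitions cover different sample sets")
  }
  lb <- lb[names(la)]
  ok <- la != "OUTLIER" & lb != "OUTLIER"
  map <- character(0)
  if (any(ok)) {
    tab <- table(la[ok], lb[ok])
    while (nrow(tab) > 0 && ncol(tab) > 0 && max(tab) > 0) {
      hit <- which(tab == max(tab), arr.ind = TRUE)[1, ]
      map[colnames(tab)[hit["col"]]] <- rownames(tab)[hit["row"]]
      tab <- tab[-hit["row"], -hit["col"], drop = FALSE]
    }
  }
  matched <- unname(map[lb])
  out <- ifelse(ok & !is.na(matched) & matched == la, la, "WILDCARD")
  names(out) <- names(la)
  out
}
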