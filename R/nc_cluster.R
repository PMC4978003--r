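#' Nest centroids in LD-score space
#'
#' The second step of NC clustering: the arithmetic mean of the LD scores
#' of every specimen in a nest sample. A singleton nest's centroid is that
#' member's projection.
#'
#' @param scores Matrix of LD scores (individuals x axes), e.g. from
#'   [project_lda()].
#' @param nest_codes Nest code per individual (or a [morph_dataset()] from
#'   which they are taken).
#' @return Matrix (nests x axes) with nest codes as row names and a
#'   `counts` attribute of member counts.
#' @export
nest_centroids <- function(scores, nest_codes) {
  if (inherits(nest_codes, "morph_dataset")) nest_codes <- nest_codes$nest_code
  nest_codes <- as.character(nest_codes)
  if (length(nest_codes) != nrow(scores)) {
    stop("nest_centroids(): one nest code per score row required")
  }
  f <- factor(nest_codes)
  counts <- as.vector(table(f))
  ctr <- rowsum(as.matrix(scores), f) / counts
  attr(ctr, "counts") <- stats::setNames(counts, levels(f))
  ctr
}

#' Pairwise Euclidean distances between nest centroids
#'
#' @param centroids Matrix from [nest_centroids()] (or any labelled point
#'   matrix).
#' @return A symmetric distance matrix (base `matrix`) with zero diagonal
#'   and the centroid labels.
#' @export
centroid_distances <- function(centroids) {
  if (nrow(centroids) < 2) stop("centroid_distances(): need >= 2 centroids")
  as.matrix(stats::dist(centroids, method = "euclidean"))
}

#' Agglomerative dendrogram over nest samples
#'
#' Hierarchical clustering of the nest-centroid distance matrix; the
#' default Ward linkage (`ward.D2`, operating on Euclidean distances)
#' matches the tree construction customary in the NC-clustering
#' literature. Leaves are nest codes.
#'
#' @param d Distance matrix from [centroid_distances()] (or a `dist`).
#' @param linkage One of `"ward"`, `"average"`, `"complete"`, `"single"`.
#' @return An `hclust` tree.
#' @export
build_dendrogram <- function(d, linkage = c("ward", "average", "complete",
                                            "single")) {
  linkage <- match.arg(linkage)
  method <- c(ward = "ward.D2", average = "average", complete = "complete",
              single = "single")[[linkage]]
  if (!inherits(d, "dist")) d <- stats::as.dist(as.matrix(d))
  stats::hclust(d, method = method)
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths follow the usual ultrametric convention (each leaf sits
#' at half the height of its first merge below the parent node); labels
#' with Newick metacharacters are quoted.
#'
#' @param tree An `hclust` tree (e.g. from [build_dendrogram()]).
#' @param path Optional file to write to.
#' @return The Newick string, invisibly when `path` is given.
#' @export
export_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(tree)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' One-call NC clustering
#'
#' Convenience wrapper running the full exploratory step: group-LDA with
#' nest samples as classes, projection, nest centroids (or individuals
#' when `level = "individual"`), pairwise distances and the dendrogram.
#'
#' @param ds A [morph_dataset()].
#' @param linkage Passed to [build_dendrogram()].
#' @param level `"nest"` (default; one leaf per nest sample) or
#'   `"individual"`.
#' @return List with `model`, `scores`, `centroids`, `distances`, `tree`.
#' @export
nc_cluster <- function(ds, linkage = "ward", level = c("nest", "individual")) {
  level <- match.arg(level)
  model <- fit_group_lda(ds)
  scores <- project_lda(model, ds)
  centroids <- if (level == "nest") nest_centroids(scores, ds)
               else structure(scores, counts = NULL)
  d <- centroid_distances(centroids)
  list(model = model, scores = scores, centroids = centroids,
       distances = d, tree = build_dendrogram(d, linkage = linkage))
}
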