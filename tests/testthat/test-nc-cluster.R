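test_that("group LDA solves the 1-D Fisher problem", {
  x <- matrix(c(-1, 0, 1, 9, 10, 11), ncol = 1)
  m <- fit_group_lda(x, groups = rep(c("a", "b"), each = 3),
                     standardize = FALSE)
  expect_equal(ncol(m$loadings), 1)
  sc <- project_lda(m, x)
  expect_gt(abs(mean(sc[4:6]) - mean(sc[1:3])), 0)
  # separation is maximal along the single axis: groups ordered as the data
  expect_true(all(sc[4:6] > max(sc[1:3])) || all(sc[4:6] < min(sc[1:3])))
})

test_that("group LDA matches a brute-force generalized eigensolution", {
  set.seed(1)
  X <- matrix(rnorm(12), 6, 2)
  g <- factor(rep(c("n1", "n2", "n3"), each = 2))
  m <- fit_group_lda(X, groups = g, standardize = FALSE)

  # independent oracle: explicit scatter matrices and eigen of solve(W) B
  gm <- apply(X, 2, function(col) tapply(col, g, mean))
  W <- matrix(0, 2, 2); B <- matrix(0, 2, 2)
  gbar <- colMeans(X)
  for (lev in levels(g)) {
    rows <- X[g == lev, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      d <- rows[i, ] - gm[lev, ]
      W <- W + tcrossprod(d)
    }
    d <- gm[lev, ] - gbar
    B <- B + nrow(rows) * tcrossprod(d)
  }
  gamma <- 2 / (2 + 3)   # p / (p + (n - G)) with n = 6, G = 3
  Wr <- (1 - gamma) * W + diag(gamma * sum(diag(W)) / 2, 2)
  eo <- eigen(solve(Wr) %*% B)
  ev_oracle <- sort(Re(eo$values), decreasing = TRUE)
  expect_equal(m$eigenvalues, ev_oracle[seq_along(m$eigenvalues)],
               tolerance = 1e-8)
  # leading axes span the same direction
  v1 <- Re(eo$vectors[, which.max(Re(eo$values))])
  cosang <- abs(sum(v1 * m$loadings[, 1])) /
    sqrt(sum(v1^2) * sum(m$loadings[, 1]^2))
  expect_equal(cosang, 1, tolerance = 1e-8)
})

test_that("LD scores are invariant to per-trait rescaling and handle degeneracy", {
  ds <- morph_dataset(make_specimen_df(12, n_nests = 4, seed = 9))
  m1 <- fit_group_lda(ds)
  s1 <- project_lda(m1, ds)

  df2 <- as.data.frame(ds)
  scales <- seq(0.5, 9, length.out = 18)
  df2[measured_traits()] <- sweep(df2[measured_traits()], 2, scales, "*")
  # rescaling breaks CWb<=CW etc., so fit from the raw matrix directly
  m2 <- fit_group_lda(as.matrix(df2[measured_traits()]), groups = df2$nest_code)
  s2 <- project_lda(m2, as.matrix(df2[measured_traits()]))
  expect_equal(abs(s2), abs(s1), tolerance = 1e-6, ignore_attr = TRUE)

  # duplicated trait column still yields finite loadings via the ridge
  X <- cbind(as.matrix(df2[measured_traits()]), DUP = df2$SL)
  m3 <- fit_group_lda(X, groups = df2$nest_code)
  expect_true(all(is.finite(m3$loadings)))

  # projecting the stored centers gives the zero score vector
  z <- project_lda(m1, matrix(m1$center, 1,
                              dimnames = list(NULL, m1$trait_order)))
  expect_equal(as.numeric(z), rep(0, ncol(m1$loadings)), tolerance = 1e-10)

  expect_error(fit_group_lda(trait_matrix(ds)[1:2, ], groups = c("n", "n")),
               "2 groups")
})

test_that("nest centroids are member means", {
  sc <- rbind(c(1, 2), c(3, 6), c(-2, -2), c(2, 2), c(5, 5))
  ctr <- nest_centroids(sc, c("n1", "n1", "n2", "n2", "n3"))
  expect_equal(ctr["n1", ], c(2, 4), ignore_attr = TRUE)
  expect_equal(ctr["n2", ], c(0, 0), ignore_attr = TRUE)   # symmetric pair
  expect_equal(ctr["n3", ], c(5, 5), ignore_attr = TRUE)   # singleton
  expect_equal(attr(ctr, "counts"), c(n1 = 2L, n2 = 2L, n3 = 1L))
})

test_that("centroid distances are Euclidean and match a double loop", {
  ctr <- rbind(a = c(0, 0), b = c(3, 4))
  d <- centroid_distances(ctr)
  expect_equal(d["a", "b"], 5)
  expect_equal(diag(d), c(a = 0, b = 0))

  set.seed(2)
  C <- matrix(rnorm(15), 5, 3, dimnames = list(paste0("n", 1:5), NULL))
  d2 <- centroid_distances(C)
  for (i in 1:5) for (j in 1:5) {
    expect_equal(d2[i, j], sqrt(sum((C[i, ] - C[j, ])^2)), tolerance = 1e-12)
  }
  expect_equal(d2, t(d2))
})

test_that("dendrograms merge nearest pairs first and export to Newick", {
  # two leaves: single merge at their distance (average linkage)
  d <- matrix(c(0, 7, 7, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- build_dendrogram(d, linkage = "average")
  expect_equal(t2$height, 7)
  nwk <- export_newick(t2)
  expect_match(nwk, "^\\(")
  expect_setequal(ape::read.tree(text = nwk)$tip.label, c("A", "B"))
  # ultrametric convention: both tips at height h/2
  phy <- ape::read.tree(text = nwk)
  expect_equal(unname(phy$edge.length), c(3.5, 3.5))

  # three collinear points 0, 1, 10: first merge joins the near pair
  x <- matrix(c(0, 1, 10), dimnames = list(c("p0", "p1", "p10"), NULL))
  for (link in c("ward", "average", "complete", "single")) {
    tr <- build_dendrogram(centroid_distances(x), linkage = link)
    expect_equal(sort(tr$merge[1, ]), c(-2, -1))
  }
  expect_error(build_dendrogram(d, linkage = "median"), "arg")

  # two blobs of four: root split separates the blobs
  set.seed(4)
  pts <- rbind(matrix(rnorm(8, 0, 0.1), 4), matrix(rnorm(8, 10, 0.1), 4))
  rownames(pts) <- paste0("s", 1:8)
  tr <- build_dendrogram(centroid_distances(pts))
  expect_equal(unname(stats::cutree(tr, 2)), rep(c(1, 2), each = 4))
  # round trip keeps topology
  phy2 <- ape::read.tree(text = export_newick(tr))
  expect_setequal(phy2$tip.label, paste0("s", 1:8))
})

test_that("species separate in LD-centroid space on well-separated synthetic data", {
  specs <- madecassus_group_specs()
  for (s in names(specs)) {                  # widen separation: shrink spread
    specs[[s]]$ratio_sds <- specs[[s]]$ratio_sds / 3
    specs[[s]]$cs_sd <- specs[[s]]$cs_sd / 3
  }
  ds <- generate_dataset(specs, seed = 8)
  nc <- nc_cluster(ds)
  truth <- tapply(ds$species, ds$nest_code, `[`, 1)[rownames(nc$centroids)]
  sil <- cluster::silhouette(as.integer(factor(truth)),
                             stats::as.dist(nc$distances))
  expect_gt(mean(sil[, 3]), 0.5)
})
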