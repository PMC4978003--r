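#' Linear discriminant analysis with nest samples as groups
#'
#' The dimensionality-reduction step of NC clustering: an LDA over all
#' individuals in which each nest sample is a class. Traits are centred and
#' scaled, within- and between-nest scatter matrices are formed, and the
#' generalized eigenproblem `B v = lambda W v` is solved after shrinking
#' the within-scatter toward a scaled identity,
#' `W* = (1 - gamma) W + gamma tr(W)/p I` (regularized discriminant
#' analysis in the Friedman sense). Shrinkage is what keeps the fit well
#' defined and stable when nest groups are tiny - most are singletons and
#' contribute nothing to `W`, so the pooled within-nest degrees of freedom
#' `n - G` are of the same order as the trait count and the raw scatter
#' estimate is very noisy. The default intensity `gamma = p / (p + (n - G))`
#' vanishes as the within-group information grows and approaches the
#' identity when `W` carries no information. Axes are ordered by
#' decreasing eigenvalue; all axes with eigenvalue above `1e-10` times the
#' largest are retained, capped at `min(G - 1, p)`. Loadings are
#' normalized so that `t(L) %*% W* %*% L = I`.
#'
#' @param ds A [morph_dataset()], or a numeric matrix of features.
#' @param groups Grouping factor; defaults to the dataset's nest codes.
#' @param traits Feature columns when `ds` is a dataset; default the 18
#'   measured traits (`CS` is excluded as a linear combination of `CL` and
#'   `CWb`).
#' @param standardize Centre and scale features before fitting (default
#'   `TRUE`); LD scores are invariant to per-trait affine rescaling either
#'   way, but standardization keeps the shrinkage target comparable across
#'   traits.
#' @param shrinkage `"auto"` for `p / (p + (n - G))`, or a number in
#'   `[0, 1)` fixing the shrinkage intensity directly.
#' @return An object of class `group_lda` with elements `loadings`
#'   (traits x axes), `eigenvalues`, `center`, `scale`, `trait_order`,
#'   `groups`, `shrinkage`.
#' @export
fit_group_lda <- function(ds, groups = NULL, traits = measured_traits(),
                          standardize = TRUE, shrinkage = "auto") {
  if (inherits(ds, "morph_dataset")) {
    X <- trait_matrix(ds, traits)
    if (is.null(groups)) groups <- ds$nest_code
  } else {
    X <- as.matrix(ds)
    if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
    traits <- colnames(X)
    if (is.null(groups)) stop("fit_group_lda(): 'groups' required for a matrix")
  }
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("fit_group_lda(): need at least 2 groups")
  n <- nrow(X); p <- ncol(X); G <- nlevels(groups)

  ctr <- if (standardize) colMeans(X) else rep(0, p)
  scl <- if (standardize) apply(X, 2, stats::sd) else rep(1, p)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")

  gm <- rowsum(Xs, groups) / as.vector(table(groups))
  M <- gm[groups, , drop = FALSE]
  R <- Xs - M
  W <- crossprod(R)
  gbar <- colMeans(Xs)
  Bc <- sweep(gm, 2, gbar)
  B <- crossprod(Bc * sqrt(as.vector(table(groups))))

  if (all(abs(W) < .Machine$double.eps * n)) {
    warning("fit_group_lda(): all groups are singletons; using identity ",
            "within-scatter")
    Wr <- diag(p)
    gamma <- 1
  } else {
    gamma <- if (identical(shrinkage, "auto")) {
      p / (p + max(n - G, 1))
    } else {
      stopifnot(is.numeric(shrinkage), shrinkage >= 0, shrinkage < 1)
      shrinkage
    }
    Wr <- (1 - gamma) * W + diag(max(gamma, 1e-8) * sum(diag(W)) / p, p)
  }

  Ch <- chol(Wr)
  Ci <- backsolve(Ch, diag(p))
  Msym <- crossprod(Ci, B %*% Ci)
  Msym <- (Msym + t(Msym)) / 2
  eg <- eigen(Msym, symmetric = TRUE)
  L <- Ci %*% eg$vectors
  ev <- pmax(eg$values, 0)

  keep <- seq_len(min(G - 1L, p))
  keep <- keep[ev[keep] > 1e-10 * max(ev[1], .Machine$double.xmin)]
  if (!length(keep)) keep <- 1L
  L <- L[, keep, drop = FALSE]
  ev <- ev[keep]
  # deterministic sign: largest-magnitude loading positive on each axis
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  dimnames(L) <- list(traits, paste0("LD", seq_len(ncol(L))))

  structure(list(loadings = L, eigenvalues = ev, center = ctr, scale = scl,
                 trait_order = traits, groups = levels(groups),
                 shrinkage = gamma),
            class = "group_lda")
}

#' @export
print.group_lda <- function(x, ...) {
  cat("group_lda: ", length(x$trait_order), " traits, ", length(x$groups),
      " groups, ", ncol(x$loadings), " retained axes\n", sep = "")
  invisible(x)
}

#' Project specimens into LD-score space
#'
#' Applies the stored standardization, then the discriminant loadings. Row
#' order is preserved.
#'
#' @param model A [fit_group_lda()] fit.
#' @param ds A [morph_dataset()] or numeric matrix with the model's traits.
#' @return Numeric matrix (individuals x retained axes).
#' @export
project_lda <- function(model, ds) {
  X <- if (inherits(ds, "morph_dataset")) trait_matrix(ds, model$trait_order)
       else as.matrix(ds)
  if (!is.null(colnames(X))) {
    miss <- setdiff(model$trait_order, colnames(X))
    if (length(miss)) stop("project_lda(): missing trait(s): ",
                           paste(miss, collapse = ", "))
    X <- X[, model$trait_order, drop = FALSE]
  } else if (ncol(X) != length(model$trait_order)) {
    stop("project_lda(): feature count mismatch")
  }
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  S <- Xs %*% model$loadings
  rownames(S) <- rownames(X)
  S
}

# ---- internal Gaussian equal-covariance classifier -------------------------
# Shared by the confirmatory LOOCV stage, wild-card assignment and the
# reduced-character function extractor. Class groups are large here
# (df = n - G >> p), so the pooled covariance needs only a near-zero
# stabilizing ridge, unlike the shrinkage used for the nest-group LDA.
# Posteriors come from the equal-covariance Gaussian model.

gaussian_lda_fit <- function(X, y, prior = c("proportional", "uniform")) {
  prior <- match.arg(prior)
  y <- factor(y)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X); G <- nlevels(y)
  if (G < 2) stop("gaussian_lda_fit(): need at least 2 classes")
  counts <- as.vector(table(y))
  if (any(counts < 2)) {
    warning("gaussian_lda_fit(): class(es) with fewer than 2 members: ",
            paste(levels(y)[counts < 2], collapse = ", "))
  }
  mu <- rowsum(X, y) / counts
  R <- X - mu[y, , drop = FALSE]
  df <- max(n - G, 1L)
  S <- crossprod(R) / df
  ridge <- 1e-8 * sum(diag(S)) / p
  if (ridge <= 0) ridge <- 1e-12
  Sr <- S + diag(ridge, p)
  Sinv <- chol2inv(chol(Sr))
  pri <- if (prior == "proportional") counts / n else rep(1 / G, G)
  list(levels = levels(y), mu = mu, Sinv = Sinv, log_prior = log(pri),
       counts = counts)
}

gaussian_lda_predict <- function(fit, X) {
  X <- as.matrix(X)
  A <- fit$mu %*% fit$Sinv                       # G x p
  const <- -0.5 * rowSums(A * fit$mu) + fit$log_prior
  sc <- X %*% t(A)                               # n x G
  sc <- sweep(sc, 2, const, "+")
  post <- exp(sc - apply(sc, 1, max))
  post <- post / rowSums(post)
  colnames(post) <- fit$levels
  # ties broken toward the alphabetically first label (levels are sorted)
  idx <- apply(post, 1, function(r) which(r >= max(r) - 1e-12)[1])
  tie <- apply(post, 1, function(r) sum(r >= max(r) - 1e-12) > 1)
  if (any(tie)) {
    message("gaussian_lda_predict(): ", sum(tie),
            " tie(s) broken toward the alphabetically first label")
  }
  list(class = factor(fit$levels[idx], levels = fit$levels),
       posterior = post)
}
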