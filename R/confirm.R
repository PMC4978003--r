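#' Hypothesis label set for confirmatory LDA
#'
#' Validates a specimen-to-hypothesis mapping: at least two non-wild-card
#' labels, each with at least two specimens. Wild-cards (`"WILDCARD"`) are
#' specimens carrying no prior hypothesis; they never participate in
#' training and are classified afterwards.
#'
#' @param labels Character vector of hypothesis labels or `"WILDCARD"`,
#'   named by specimen code (or in dataset row order).
#' @return The validated named character vector, classed `hypothesis_set`.
#' @export
hypothesis_set <- function(labels) {
  labels <- unlist(labels)
  labels <- stats::setNames(as.character(labels), names(labels))
  real <- labels[labels != "WILDCARD" & !is.na(labels)]
  tab <- table(real)
  if (length(tab) < 2) {
    stop("hypothesis_set(): need at least 2 non-wildcard hypothesis labels")
  }
  if (any(tab < 2)) {
    stop("hypothesis_set(): hypothesis class(es) with fewer than 2 ",
         "specimens: ", paste(names(tab)[tab < 2], collapse = ", "))
  }
  structure(labels, class = "hypothesis_set")
}

#' Confirmatory LDA with leave-one-out cross-validation
#'
#' Each non-wild-card specimen is held out in turn, an equal-covariance
#' Gaussian LDA is refit on all remaining non-wild-card specimens, and the
#' held-out case is assigned to the maximum-posterior class. The confusion
#' matrix (true hypothesis x predicted) is tallied at the individual
#' level. Wild-cards are then classified by a model trained on all
#' hypothesis cases. Class priors are proportional to training class sizes
#' by default.
#'
#' @param ds A [morph_dataset()] or numeric feature matrix.
#' @param hyp A [hypothesis_set()] (or a bare label vector), named by
#'   specimen code or in row order; `"WILDCARD"` entries get no prior
#'   hypothesis.
#' @param traits Feature columns when `ds` is a dataset.
#' @param prior `"proportional"` (default) or `"uniform"`.
#' @return An object of class `classification_result`: `confusion`,
#'   `per_class_pct`, `overall_pct`, `overall_pct_rounded`,
#'   `wildcard_assignments` (data frame with predicted label and maximum
#'   posterior), `predicted` (LOOCV prediction per hypothesis specimen).
#' @export
loocv_classify <- function(ds, hyp, traits = measured_traits(),
                           prior = "proportional") {
  X <- if (inherits(ds, "morph_dataset")) trait_matrix(ds, traits)
       else as.matrix(ds)
  labels <- unlist(hyp)
  labels <- stats::setNames(as.character(labels), names(labels))
  if (!is.null(names(labels)) && !is.null(rownames(X))) {
    labels <- labels[rownames(X)]
    labels[is.na(labels)] <- "WILDCARD"
  }
  if (length(labels) != nrow(X)) {
    stop("loocv_classify(): one hypothesis entry per specimen required")
  }
  labels <- unclass(hypothesis_set(labels))

  train <- which(labels != "WILDCARD")
  lv <- sort(unique(labels[train]))
  pred <- character(length(train))
  for (i in seq_along(train)) {
    keep <- train[-i]
    ytr <- labels[keep]
    if (min(table(ytr)) < 2) {
      warning("loocv_classify(): a hypothesis class fell below 2 members ",
              "in a hold-out fold")
    }
    fit <- suppressWarnings(gaussian_lda_fit(X[keep, , drop = FALSE], ytr,
                                             prior = prior))
    pred[i] <- as.character(
      gaussian_lda_predict(fit, X[train[i], , drop = FALSE])$class)
  }
  confusion <- table(factor(labels[train], levels = lv),
                     factor(pred, levels = lv))
  names(dimnames(confusion)) <- c("hypothesis", "predicted")

  wc <- which(labels == "WILDCARD")
  wildcard_assignments <- NULL
  full_fit <- suppressWarnings(gaussian_lda_fit(X[train, , drop = FALSE],
                                                labels[train], prior = prior))
  if (length(wc)) {
    pr <- gaussian_lda_predict(full_fit, X[wc, , drop = FALSE])
    wildcard_assignments <- data.frame(
      specimen = if (!is.null(rownames(X))) rownames(X)[wc] else wc,
      predicted = as.character(pr$class),
      posterior = apply(pr$posterior, 1, max),
      row.names = NULL, stringsAsFactors = FALSE
    )
    low <- wildcard_assignments$posterior < 0.5
    if (any(low)) {
      message("loocv_classify(): ", sum(low), " wild-card(s) assigned with ",
              "maximum posterior below 0.5")
    }
  }

  pcts <- confusion_summary(confusion)
  structure(list(confusion = unclass(confusion),
                 per_class_pct = pcts$per_class_pct,
                 overall_pct = pcts$overall_pct,
                 overall_pct_rounded = pcts$overall_pct_rounded,
                 predicted = stats::setNames(pred, rownames(X)[train]),
                 wildcard_assignments = wildcard_assignments,
                 model = full_fit),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat("LOOCV-LDA classification\n")
  print(x$confusion)
  cat("per-class percent correct:\n")
  print(round(x$per_class_pct, 1))
  cat(sprintf("overall: %.1f%% (%d%%)\n", x$overall_pct,
              x$overall_pct_rounded))
  if (!is.null(x$wildcard_assignments)) {
    cat(nrow(x$wildcard_assignments), "wild-card specimen(s) classified\n")
  }
  invisible(x)
}

#' Classify wild-card specimens against a fitted hypothesis model
#'
#' @param result A [loocv_classify()] result (its full-data model is
#'   reused).
#' @param ds Dataset or matrix of wild-card specimens.
#' @param traits Feature columns when `ds` is a dataset.
#' @return Data frame with `specimen`, `predicted`, `posterior`.
#' @export
classify_wildcards <- function(result, ds, traits = measured_traits()) {
  X <- if (inherits(ds, "morph_dataset")) trait_matrix(ds, traits)
       else as.matrix(ds)
  pr <- gaussian_lda_predict(result$model, X)
  data.frame(
    specimen = if (!is.null(rownames(X))) rownames(X) else seq_len(nrow(X)),
    predicted = as.character(pr$class),
    posterior = apply(pr$posterior, 1, max),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Percent-correct summaries of a classification matrix
#'
#' Per-class percent correct is `100 * diagonal / row sum`; overall percent
#' is `100 * trace / total`. Classes with empty rows get `NA` with a
#' warning.
#'
#' @param confusion Square non-negative count matrix, rows = true class,
#'   columns = predicted, with matching dimnames.
#' @return List with `per_class_pct` (named, unrounded), `overall_pct` and
#'   `overall_pct_rounded` (nearest integer, as conventionally printed).
#' @examples
#' m <- rbind(c(59, 0, 2, 0), c(0, 7, 0, 0), c(2, 0, 82, 0), c(0, 0, 0, 79))
#' dimnames(m) <- rep(list(c("flavus", "gibber", "madecassus", "nitidus")), 2)
#' confusion_summary(m)$overall_pct_rounded  # 98
#' @export
confusion_summary <- function(confusion) {
  m <- as.matrix(confusion)
  if (nrow(m) != ncol(m)) stop("confusion_summary(): matrix must be square")
  if (any(m < 0) || any(m != round(m))) {
    stop("confusion_summary(): entries must be non-negative integers")
  }
  rs <- rowSums(m)
  per <- ifelse(rs > 0, 100 * diag(m) / rs, NA_real_)
  if (any(rs == 0)) {
    warning("confusion_summary(): empty class row(s); percent undefined")
  }
  names(per) <- rownames(m)
  overall <- 100 * sum(diag(m)) / sum(m)
  list(per_class_pct = per, overall_pct = overall,
       overall_pct_rounded = as.integer(round(overall)))
}

#' Write a classification matrix in the published table layout
#'
#' Classes as rows and columns plus a final `percent.correct` column (one
#' decimal).
#'
#' @param result A [loocv_classify()] result or a bare confusion matrix.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_confusion_csv <- function(result, path) {
  m <- if (inherits(result, "classification_result")) result$confusion
       else as.matrix(result)
  pct <- confusion_summary(m)$per_class_pct
  df <- data.frame(class = rownames(m), as.data.frame.matrix(m),
                   percent.correct = round(pct, 1), check.names = FALSE,
                   row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
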