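#' Linear discriminant identification function
#'
#' A discriminant of the form `D = sum_i x_i * trait_i + c` over trait
#' lengths in micrometres, as printed in identification keys, optionally
#' with per-class score summaries (mean and range) used to read an
#' identity off the score.
#'
#' @param name Function name, e.g. `"D2"`.
#' @param coefficients Named numeric vector, per-micrometre coefficients.
#' @param constant The additive constant `c`.
#' @param class_scores Optional data frame with columns `class`, `mean`,
#'   `min`, `max`, `n`.
#' @return An object of class `discriminant_function`.
#' @export
discriminant_function <- function(name, coefficients, constant,
                                  class_scores = NULL) {
  coefficients <- unlist(coefficients)
  if (!length(coefficients) || is.null(names(coefficients)) ||
      all(coefficients == 0)) {
    stop("discriminant_function(): need at least one named nonzero ",
         "coefficient")
  }
  stopifnot(is.finite(constant), all(is.finite(coefficients)))
  structure(list(name = name, coefficients = coefficients,
                 constant = constant, class_scores = class_scores),
            class = "discriminant_function")
}

#' @export
print.discriminant_function <- function(x, ...) {
  terms <- sprintf("%+.4g*%s", x$coefficients, names(x$coefficients))
  cat(x$name, " = ", paste(terms, collapse = " "),
      sprintf(" %+.4g\n", x$constant), sep = "")
  if (!is.null(x$class_scores)) print(x$class_scores)
  invisible(x)
}

#' Published discriminant function D2 (flavus vs nitidus)
#'
#' The two-trait function `D2 = +0.0847*SL - 0.0625*MW - 15.038`
#' separating the cryptic pair N. flavus / N. nitidus, with the published
#' per-species score means and ranges (flavus +3.09, range +0.98 to +5.33;
#' nitidus -2.39, range -4.63 to +0.19). Trait lengths in micrometres.
#'
#' @return A [discriminant_function()].
#' @export
discriminant_D2 <- function() {
  discriminant_function(
    "D2", c(SL = 0.0847, MW = -0.0625), -15.038,
    class_scores = data.frame(
      class = c("flavus", "nitidus"),
      mean = c(3.09, -2.39), min = c(0.98, -4.63), max = c(5.33, 0.19),
      n = c(61L, 79L), stringsAsFactors = FALSE
    )
  )
}

#' Published discriminant function D4 (madecassus vs flavus + nitidus)
#'
#' `D4 = +0.0511*PoOC - 0.0486*CW - 0.0702*PEW + 0.0435*PEL + 8.3829`,
#' with published class scores madecassus -1.70 [-4.61, 0.26], flavus
#' +2.39 [0.42, 5.02], nitidus +3.18 [0.51, 5.98]; the madecassus range
#' does not overlap either other species.
#'
#' @return A [discriminant_function()].
#' @export
discriminant_D4 <- function() {
  discriminant_function(
    "D4", c(PoOC = 0.0511, CW = -0.0486, PEW = -0.0702, PEL = 0.0435),
    8.3829,
    class_scores = data.frame(
      class = c("madecassus", "flavus", "nitidus"),
      mean = c(-1.70, 2.39, 3.18), min = c(-4.61, 0.42, 0.51),
      max = c(0.26, 5.02, 5.98), n = c(84L, 61L, 79L),
      stringsAsFactors = FALSE
    )
  )
}

#' Evaluate a discriminant function on trait measurements
#'
#' Substitutes trait lengths in micrometres into the linear equation and
#' returns the dimensionless score `sum coefficient * trait + constant`.
#'
#' @param fn A [discriminant_function()].
#' @param traits Named numeric vector, single-row data frame, or a
#'   [morph_dataset()]; must contain every coefficient's trait.
#' @return Numeric score vector, one per row/specimen.
#' @examples
#' evaluate_discriminant(discriminant_D2(), c(SL = 482, MW = 361))
#' @export
evaluate_discriminant <- function(fn, traits) {
  stopifnot(inherits(fn, "discriminant_function"))
  if (is.numeric(traits) && !is.null(names(traits))) {
    traits <- as.data.frame(as.list(traits))
  }
  traits <- as.data.frame(traits)
  miss <- setdiff(names(fn$coefficients), names(traits))
  if (length(miss)) {
    stop("evaluate_discriminant(): missing trait(s): ",
         paste(miss, collapse = ", "))
  }
  m <- as.matrix(traits[names(fn$coefficients)])
  as.numeric(m %*% fn$coefficients + fn$constant)
}

#' Extract a reduced-character discriminant function
#'
#' Greedy forward selection of a small trait set for a two-class linear
#' discriminant: at each step the trait whose addition minimizes the
#' leave-one-out error of the two-class Fisher discriminant joins the set
#' (ties broken by the larger standardized class-mean separation);
#' selection stops at zero error or `max_traits`. The returned function is
#' the Fisher direction over the raw micrometre traits, scaled to unit
#' pooled within-class score standard deviation, signed so `classes[1]`
#' has the positive mean, with the constant centring the pooled grand mean
#' score at zero. These refit coefficients are the package's own, not the
#' published D2/D4 values.
#'
#' @param ds A [morph_dataset()] or feature matrix.
#' @param labels Class label per specimen.
#' @param classes Length-2 character vector naming the pair to separate;
#'   each class needs at least 3 cases.
#' @param max_traits Largest trait set to consider (default 2).
#' @param traits Candidate trait columns.
#' @return A [discriminant_function()] with attribute `loocv_error` (the
#'   achieved leave-one-out error rate) and per-class score summaries.
#' @export
extract_reduced_function <- function(ds, labels, classes, max_traits = 2,
                                     traits = measured_traits()) {
  X <- if (inherits(ds, "morph_dataset")) trait_matrix(ds, traits)
       else as.matrix(ds)
  labels <- as.character(labels)
  stopifnot(length(classes) == 2)
  keep <- labels %in% classes
  if (min(table(labels[keep])) < 3) {
    stop("extract_reduced_function(): each class needs at least 3 cases")
  }
  X <- X[keep, , drop = FALSE]
  y <- factor(labels[keep], levels = classes)
  traits <- colnames(X)

  loo_error <- function(cols) {
    sub <- X[, cols, drop = FALSE]
    wrong <- 0L
    for (i in seq_len(nrow(sub))) {
      fit <- suppressWarnings(
        gaussian_lda_fit(sub[-i, , drop = FALSE], y[-i]))
      pr <- gaussian_lda_predict(fit, sub[i, , drop = FALSE])$class
      wrong <- wrong + (as.character(pr) != as.character(y[i]))
    }
    wrong / nrow(sub)
  }
  separation <- function(cols) {
    w <- fisher_direction(X[, cols, drop = FALSE], y)
    sc <- X[, cols, drop = FALSE] %*% w$w
    abs(mean(sc[y == classes[1]]) - mean(sc[y == classes[2]])) / w$pooled_sd
  }

  selected <- character(0)
  err <- Inf
  while (length(selected) < max_traits) {
    cand <- setdiff(traits, selected)
    errs <- vapply(cand, function(t) loo_error(c(selected, t)), numeric(1))
    if (min(errs) >= err) break   # no candidate improves: stop enlarging
    best <- which(errs == min(errs))
    if (length(best) > 1) {
      seps <- vapply(cand[best], function(t) separation(c(selected, t)),
                     numeric(1))
      best <- best[which.max(seps)]
    }
    selected <- c(selected, cand[best[1]])
    err <- min(errs)
    if (err == 0) break
  }
  if (err > 0) {
    warning(sprintf(paste0("extract_reduced_function(): classes not fully ",
                           "separated at max_traits; achieved LOOCV error ",
                           "%.3f"), err))
  }

  fd <- fisher_direction(X[, selected, drop = FALSE], y)
  w <- fd$w / fd$pooled_sd
  sc <- X[, selected, drop = FALSE] %*% w
  if (mean(sc[y == classes[1]]) < mean(sc[y == classes[2]])) {
    w <- -w
    sc <- -sc
  }
  const <- -mean(sc)
  sc <- sc + const
  cs_tab <- do.call(rbind, lapply(classes, function(cl) {
    s <- sc[y == cl]
    data.frame(class = cl, mean = mean(s), min = min(s), max = max(s),
               n = length(s), stringsAsFactors = FALSE)
  }))
  fn <- discriminant_function(
    paste0("D_", paste(selected, collapse = "_")),
    stats::setNames(as.numeric(w), selected), const, class_scores = cs_tab)
  attr(fn, "loocv_error") <- err
  fn
}

# Two-class Fisher direction w = S^-1 (m1 - m2) with pooled-sd of scores.
fisher_direction <- function(X, y) {
  X <- as.matrix(X)
  lv <- levels(y)
  m1 <- colMeans(X[y == lv[1], , drop = FALSE])
  m2 <- colMeans(X[y == lv[2], , drop = FALSE])
  R <- X - rbind(m1, m2)[as.integer(y), , drop = FALSE]
  S <- crossprod(R) / max(nrow(X) - 2, 1)
  S <- S + diag(1e-8 * sum(diag(S)) / ncol(X) + 1e-300, ncol(X))
  w <- solve(S, m1 - m2)
  pooled_sd <- sqrt(max(as.numeric(t(w) %*% S %*% w), .Machine$double.xmin))
  list(w = w, pooled_sd = pooled_sd)
}

#' Head-shape ratio check of the key (CW/PoOC threshold)
#'
#' The key separates ocher-phenotype N. madecassus from the
#' flavus/nitidus pair by the head index `CW/PoOC`: values strictly above
#' 1.85 fall on the madecassus side. Exactly 1.85 is treated as the
#' flavus/nitidus side and reported as borderline.
#'
#' @param record Named numeric vector or one-row data frame with `CW` and
#'   `PoOC` in micrometres.
#' @return `"madecassus-side"` or `"flavus/nitidus-side"`, with attribute
#'   `ratio`.
#' @export
ratio_check_cw_pooc <- function(record) {
  if (is.numeric(record) && !is.null(names(record))) {
    record <- as.data.frame(as.list(record))
  }
  if (!all(c("CW", "PoOC") %in% names(record))) {
    stop("ratio_check_cw_pooc(): CW and PoOC required")
  }
  r <- record[["CW"]][1] / record[["PoOC"]][1]
  if (r == 1.85) message("ratio_check_cw_pooc(): CW/PoOC exactly at the ",
                         "1.85 threshold; treated as flavus/nitidus-side")
  out <- if (r > 1.85) "madecassus-side" else "flavus/nitidus-side"
  attr(out, "ratio") <- r
  out
}

#' Run a specimen through the dichotomous key
#'
#' The worker key for the group: (1) a conspicuous mesothoracic hump
#' identifies N. gibber (Mauritius); (2) dark brown to black body colour
#' identifies the dark phenotype of N. madecassus; (3) `CW/PoOC > 1.85`
#' identifies the ocher phenotype of N. madecassus; (4) otherwise the
#' published D2 score splits the cryptic pair by the nearer published
#' class mean (+3.09 flavus vs -2.39 nitidus). Elevation (flavus mean
#' 1190 m, nitidus 383 m) is reported as corroborating evidence only and
#' never decides.
#'
#' @param record Named numeric vector or one-row data frame with traits in
#'   micrometres (`CW`, `PoOC`, `SL`, `MW` used).
#' @param hump Logical: mesothoracic hump conspicuous?
#' @param color `"dark"` or `"yellow-light"`.
#' @param elevation Optional elevation in metres.
#' @return An object of class `key_decision`: list with `label`, `trace`
#'   (couplets visited with the evidence that fired) and `evidence`.
#' @export
key_classify <- function(record, hump, color = c("yellow-light", "dark"),
                         elevation = NULL) {
  if (missing(hump) || is.na(hump)) stop("key_classify(): 'hump' flag required")
  color <- match.arg(color)
  trace <- character(0)

  finish <- function(label, evidence) {
    structure(list(label = label, trace = trace, evidence = evidence),
              class = "key_decision")
  }

  trace <- c(trace, sprintf("couplet 1: mesothoracic hump %s",
                            if (hump) "conspicuous" else "absent"))
  if (hump) return(finish("gibber", "qualitative flag: mesothoracic hump"))

  trace <- c(trace, sprintf("couplet 2: body colour %s", color))
  if (color == "dark") {
    return(finish("madecassus", "qualitative flag: dark colour"))
  }

  side <- ratio_check_cw_pooc(record)
  trace <- c(trace, sprintf("couplet 3: CW/PoOC = %.3f (threshold 1.85)",
                            attr(side, "ratio")))
  if (side == "madecassus-side") {
    return(finish("madecassus", sprintf("ratio threshold: CW/PoOC = %.3f > 1.85",
                                        attr(side, "ratio"))))
  }

  d2 <- discriminant_D2()
  score <- evaluate_discriminant(d2, record)
  cs <- d2$class_scores
  nearest <- cs$class[which.min(abs(score - cs$mean))]
  in_range <- any(score >= cs$min & score <= cs$max)
  trace <- c(trace, sprintf("couplet 4: D2 = %+.2f (flavus mean %+.2f, nitidus mean %+.2f)",
                            score, cs$mean[cs$class == "flavus"],
                            cs$mean[cs$class == "nitidus"]))
  if (!in_range) {
    warning("key_classify(): D2 score outside both published ranges; ",
            "classified by nearest mean with low confidence")
  }
  if (!is.null(elevation)) {
    hint <- if (elevation > 786) "flavus" else "nitidus"  # midpoint of 1190/383
    trace <- c(trace, sprintf(
      "corroborating (never decisive): elevation %.0f m hints %s", elevation,
      hint))
  }
  finish(nearest, sprintf("discriminant score: D2 = %+.2f nearest %s mean",
                          score, nearest))
}

#' @export
print.key_decision <- function(x, ...) {
  cat("key decision:", x$label, "\n")
  for (step in x$trace) cat("  -", step, "\n")
  cat("  evidence:", x$evidence, "\n")
  invisible(x)
}

#' Published LOOCV classification matrix of the group revision
#'
#' The individual-level confusion matrix reported for the four-species
#' confirmatory analysis (rows = hypothesis, columns = prediction). Note
#' the published per-class percent for madecassus (96.7) disagrees with
#' its own row, which gives 82/84 = 97.6; [confusion_summary()] reports
#' the computed value.
#'
#' @return 4x4 integer matrix with species dimnames.
#' @export
madecassus_group_confusion <- function() {
  m <- rbind(flavus = c(59L, 0L, 2L, 0L),
             gibber = c(0L, 7L, 0L, 0L),
             madecassus = c(2L, 0L, 82L, 0L),
             nitidus = c(0L, 0L, 0L, 79L))
  colnames(m) <- rownames(m)
  names(dimnames(m)) <- c("hypothesis", "predicted")
  m
}
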