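#' Measured trait abbreviations
#'
#' The 18 continuous worker traits, all measured in micrometres, that form
#' the feature space of the delimitation pipeline. `CS` (absolute cephalic
#' size) is not in this set: it is derived as the arithmetic mean of `CL`
#' and `CWb` and serves as the size denominator for ratio traits.
#'
#' @return Character vector of 18 trait abbreviations.
#' @seealso [trait_catalogue()] for definitions, [compute_cs()].
#' @export
measured_traits <- function() {
  c("CL", "CW", "CWb", "EL", "FRS", "ML", "MW", "MPST", "NOH", "NOL",
    "PEH", "PEL", "PEW", "PoOC", "PPH", "PPL", "PPW", "SL")
}

#' Trait catalogue
#'
#' Definitions of the measured traits plus the derived absolute cephalic
#' size `CS`. Exactly one catalogue entry is derived.
#'
#' @return A data frame with columns `abbreviation`, `description` and
#'   `derived`.
#' @export
trait_catalogue <- function() {
  defs <- c(
    CL   = "Maximum cephalic length in median line",
    CW   = "Maximum cephalic width, compound eyes included",
    CWb  = "Maximum cephalic width behind (excluding) the compound eyes",
    EL   = "Maximum diameter of the compound eye",
    FRS  = "Distance between the frontal carinae",
    ML   = "Mesosoma length from anterior pronotal face to propodeal lobe",
    MW   = "Maximum mesosoma (pronotal) width",
    MPST = "Distance from propodeal stigma centre to metapleural corner",
    NOH  = "Maximum height of the petiolar node",
    NOL  = "Length of the petiolar node",
    PEH  = "Maximum petiole height",
    PEL  = "Diagonal petiolar length in lateral view",
    PEW  = "Maximum petiole width in dorsal view",
    PoOC = "Postocular distance",
    PPH  = "Maximum postpetiole height in lateral view",
    PPL  = "Postpetiole length",
    PPW  = "Maximum postpetiole width in dorsal view",
    SL   = "Maximum straight-line scape length"
  )
  out <- data.frame(
    abbreviation = c(names(defs), "CS"),
    description = c(unname(defs),
                    "Absolute cephalic size: arithmetic mean of CL and CWb"),
    derived = c(rep(FALSE, length(defs)), TRUE),
    stringsAsFactors = FALSE
  )
  stopifnot(!anyDuplicated(out$abbreviation), sum(out$derived) == 1L)
  out
}

#' Absolute cephalic size
#'
#' `CS` is the arithmetic mean of cephalic length `CL` and head-capsule
#' width without eyes `CWb`, in micrometres. It is the size denominator
#' used for all ratio traits.
#'
#' @param cl Cephalic length in micrometres (> 0). Vectorized.
#' @param cwb Cephalic width behind the eyes in micrometres (> 0).
#' @return Numeric vector of CS values in micrometres.
#' @examples
#' compute_cs(700, 550)  # 625
#' @export
compute_cs <- function(cl, cwb) {
  if (any(!is.finite(cl)) || any(!is.finite(cwb)) ||
      any(cl <= 0) || any(cwb <= 0)) {
    stop("compute_cs(): 'cl' and 'cwb' must be finite and strictly positive")
  }
  (cl + cwb) / 2
}

#' Names of the ratio traits used for species-wise summaries
#'
#' The shape descriptors on which species are compared: each measured
#' trait divided by `CS`, plus the head-shape indices `CL/CW`, `CL/CWb`,
#' `PoOC/CL` and `CW/PoOC`.
#'
#' @return Character vector of ratio names (slash-separated pairs).
#' @export
ratio_names <- function() {
  c(paste0(measured_traits(), "/CS"),
    "CL/CW", "CL/CWb", "PoOC/CL", "CW/PoOC")
}

#' Derive dimensionless ratio traits from raw measurements
#'
#' Divides every measured trait by absolute cephalic size `CS` and adds the
#' named head indices `CL/CW`, `CL/CWb`, `PoOC/CL` and `CW/PoOC`. Because
#' every ratio is a quotient of lengths the result is invariant to a common
#' rescaling of all measurements (the generator and the tests rely on this
#' scale covariance).
#'
#' @param x A data frame (or [morph_dataset()]) containing the measured
#'   trait columns in micrometres, or a named numeric vector for a single
#'   specimen.
#' @return A data frame of ratios (one row per specimen), with
#'   slash-separated column names as printed in species-wise trait tables.
#' @examples
#' rec <- c(CL = 758.5, CW = 627, CWb = 625.5, EL = 180, FRS = 215,
#'          ML = 960, MW = 430, MPST = 305, NOH = 90, NOL = 230,
#'          PEH = 195, PEL = 350, PEW = 150, PoOC = 350, PPH = 185,
#'          PPL = 190, PPW = 240, SL = 540)
#' derive_ratios(rec)[["CL/CWb"]]
#' @export
derive_ratios <- function(x) {
  if (is.numeric(x) && !is.null(names(x))) {
    x <- as.data.frame(as.list(x))
  }
  x <- as.data.frame(x)
  need <- measured_traits()
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("derive_ratios(): missing trait column(s): ", paste(miss, collapse = ", "))
  }
  if (any(!vapply(x[need], is.numeric, logical(1)))) {
    stop("derive_ratios(): trait columns must be numeric")
  }
  m <- as.matrix(x[need])
  if (any(!is.finite(m)) || any(m <= 0)) {
    stop("derive_ratios(): trait values must be finite and strictly positive")
  }
  cs <- compute_cs(m[, "CL"], m[, "CWb"])
  out <- as.data.frame(sweep(m, 1L, cs, "/"))
  names(out) <- paste0(need, "/CS")
  out[["CL/CW"]]   <- m[, "CL"] / m[, "CW"]
  out[["CL/CWb"]]  <- m[, "CL"] / m[, "CWb"]
  out[["PoOC/CL"]] <- m[, "PoOC"] / m[, "CL"]
  out[["CW/PoOC"]] <- m[, "CW"] / m[, "PoOC"]
  rownames(out) <- rownames(x)
  out
}
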