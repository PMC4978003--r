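#' Construct a validated morphometric dataset
#'
#' A `morph_dataset` is a data frame of specimen-level measurements with one
#' row per measured worker: a `specimen_code`, a `nest_code` grouping
#' nestmates (workers from one nest or collection event, assumed close
#' relatives), the 18 measured traits in micrometres, the derived `CS`
#' column, and optional `species`, `latitude`, `longitude` and `elevation`
#' metadata. Validation enforces the anatomical sanity constraints: all
#' traits strictly positive, `CWb <= CW` (the head is at least as wide with
#' the eyes as without) and `PoOC <= CL`. `CS` is always recomputed from
#' `CL` and `CWb`; a supplied `CS` column is checked against the recomputed
#' value, not trusted.
#'
#' @param df Data frame with columns `specimen_code`, `nest_code` and all
#'   columns named by [measured_traits()]. Optional: `CS`, `species`,
#'   `latitude`, `longitude`, `elevation`.
#' @param drop_incomplete If `TRUE`, rows with missing trait values are
#'   dropped with a message giving the count; if `FALSE` (default) they are
#'   an error.
#' @return An object of class `morph_dataset` (a data frame).
#' @export
morph_dataset <- function(df, drop_incomplete = FALSE) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("specimen_code", "nest_code", measured_traits())
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("morph_dataset(): missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  df$specimen_code <- as.character(df$specimen_code)
  df$nest_code <- as.character(df$nest_code)
  if (anyDuplicated(df$specimen_code)) {
    stop("morph_dataset(): duplicated specimen_code values")
  }

  tr <- measured_traits()
  for (t in tr) {
    if (!is.numeric(df[[t]])) {
      bad <- df$specimen_code[is.na(suppressWarnings(as.numeric(df[[t]])))]
      stop("morph_dataset(): non-numeric values in trait '", t, "'",
           if (length(bad)) paste0(" (specimens: ",
                                   paste(utils::head(bad, 5), collapse = ", "), ")"))
    }
  }
  incomplete <- !stats::complete.cases(df[tr])
  if (any(incomplete)) {
    if (drop_incomplete) {
      message("morph_dataset(): dropping ", sum(incomplete),
              " record(s) with missing trait values")
      df <- df[!incomplete, , drop = FALSE]
    } else {
      stop("morph_dataset(): missing trait values for specimen(s): ",
           paste(utils::head(df$specimen_code[incomplete], 5), collapse = ", "))
    }
  }
  m <- as.matrix(df[tr])
  nonpos <- rowSums(!is.finite(m) | m <= 0) > 0
  if (any(nonpos)) {
    stop("morph_dataset(): non-positive or non-finite trait value(s) for ",
         "specimen(s): ",
         paste(utils::head(df$specimen_code[nonpos], 5), collapse = ", "))
  }
  bad_cw <- df$CWb > df$CW * (1 + 1e-9)
  if (any(bad_cw)) {
    stop("morph_dataset(): CWb > CW for specimen(s): ",
         paste(utils::head(df$specimen_code[bad_cw], 5), collapse = ", "))
  }
  bad_pooc <- df$PoOC > df$CL * (1 + 1e-9)
  if (any(bad_pooc)) {
    stop("morph_dataset(): PoOC > CL for specimen(s): ",
         paste(utils::head(df$specimen_code[bad_pooc], 5), collapse = ", "))
  }
  cs <- compute_cs(df$CL, df$CWb)
  if ("CS" %in% names(df)) {
    off <- abs(df$CS - cs) > 1e-6 * cs
    off[is.na(off)] <- FALSE
    if (any(off)) {
      warning("morph_dataset(): supplied CS disagrees with (CL + CWb)/2 for ",
              sum(off), " specimen(s); CS recomputed")
    }
  }
  df$CS <- cs
  if (!"species" %in% names(df)) df$species <- NA_character_
  df$species <- as.character(df$species)
  for (col in c("latitude", "longitude", "elevation")) {
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  }
  rownames(df) <- df$specimen_code
  class(df) <- c("morph_dataset", "data.frame")
  df
}

#' @export
print.morph_dataset <- function(x, ...) {
  ns <- nests(x)
  cat("morph_dataset: ", nrow(x), " specimens in ", length(ns),
      " nest samples\n", sep = "")
  sp <- x$species[!is.na(x$species)]
  if (length(sp)) {
    cat("species labels: ",
        paste(sprintf("%s (%d)", names(table(sp)), table(sp)), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Nest membership of a dataset
#'
#' @param ds A [morph_dataset()].
#' @return Named list mapping each nest code to the integer row indices of
#'   its member specimens, in row order.
#' @export
nests <- function(ds) {
  split(seq_len(nrow(ds)), ds$nest_code)
}

#' Extract the raw trait matrix
#'
#' @param ds A [morph_dataset()].
#' @param traits Trait columns to extract; default the 18 measured traits
#'   (CS, being a linear combination of CL and CWb, is deliberately not a
#'   feature).
#' @return Numeric matrix (specimens x traits) with specimen codes as row
#'   names.
#' @export
trait_matrix <- function(ds, traits = measured_traits()) {
  miss <- setdiff(traits, names(ds))
  if (length(miss)) {
    stop("trait_matrix(): missing trait column(s): ", paste(miss, collapse = ", "))
  }
  m <- as.matrix(as.data.frame(ds)[traits])
  rownames(m) <- ds$specimen_code
  m
}

#' Read a specimen-level morphometric table from CSV
#'
#' One row per specimen, header row with the trait abbreviations; units are
#' micrometres throughout. Column names can be remapped via `col_map` when
#' the file uses different headers.
#'
#' @param path Path to a comma-separated file.
#' @param col_map Optional named character vector mapping required names to
#'   the file's column names, e.g. `c(specimen_code = "CASENT")`.
#' @param drop_incomplete Passed to [morph_dataset()].
#' @return A [morph_dataset()].
#' @export
read_morph_csv <- function(path, col_map = NULL, drop_incomplete = FALSE) {
  if (!file.exists(path)) stop("read_morph_csv(): file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      src <- col_map[[std]]
      if (!src %in% names(df)) {
        stop("read_morph_csv(): mapped column '", src, "' not in file")
      }
      names(df)[names(df) == src] <- std
    }
  }
  morph_dataset(df, drop_incomplete = drop_incomplete)
}

#' Write a morphometric dataset to CSV
#'
#' Round-trips losslessly through [read_morph_csv()].
#'
#' @param ds A [morph_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_morph_csv <- function(ds, path) {
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE)
  invisible(path)
}

#' Species-wise summary of size and ratio traits
#'
#' For each species: the number of individuals and mean, sample (n-1)
#' standard deviation, minimum and maximum of `CS` and of every ratio trait,
#' in the layout of published species-wise trait tables. For a species with
#' a single individual the standard deviation is reported as 0 and flagged.
#'
#' @param ds A [morph_dataset()].
#' @param labels Optional character vector of species labels, either named
#'   by specimen code or in row order; defaults to the dataset's `species`
#'   column. Unlabelled specimens are ignored.
#' @param ratios Which ratio statistics to tabulate. Defaults to `CS` plus
#'   the head indices and each trait divided by `CS`.
#' @return Data frame with columns `species`, `n`, `statistic`, `mean`,
#'   `sd`, `min`, `max`, `sd_degenerate`.
#' @export
summarize_by_species <- function(ds, labels = NULL,
                                 ratios = c("CS", "CL/CW", "CL/CWb", "PoOC/CL",
                                            setdiff(paste0(measured_traits(), "/CS"),
                                                    c("CL/CS", "CW/CS", "CWb/CS",
                                                      "PoOC/CS")))) {
  if (is.null(labels)) labels <- ds$species
  if (!is.null(names(labels))) labels <- labels[ds$specimen_code]
  labels <- as.character(labels)
  keep <- !is.na(labels) & labels != ""
  if (!any(keep)) stop("summarize_by_species(): no labelled specimens")
  vals <- cbind(CS = ds$CS, derive_ratios(ds))[keep, , drop = FALSE]
  labels <- labels[keep]
  miss <- setdiff(ratios, names(vals))
  if (length(miss)) stop("summarize_by_species(): unknown statistic(s): ",
                         paste(miss, collapse = ", "))
  out <- do.call(rbind, lapply(sort(unique(labels)), function(sp) {
    v <- vals[labels == sp, ratios, drop = FALSE]
    n <- nrow(v)
    data.frame(
      species = sp, n = n, statistic = ratios,
      mean = vapply(v, mean, numeric(1)),
      sd = if (n > 1) vapply(v, stats::sd, numeric(1)) else rep(0, length(ratios)),
      min = vapply(v, min, numeric(1)),
      max = vapply(v, max, numeric(1)),
      sd_degenerate = n < 2,
      row.names = NULL, stringsAsFactors = FALSE
    )
  }))
  out
}

#' Write a species-wise summary table to CSV
#'
#' @param summary Output of [summarize_by_species()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_species_summary <- function(summary, path) {
  utils::write.csv(summary, path, row.names = FALSE)
  invisible(path)
}
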