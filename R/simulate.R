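# Ratios are the primitive random quantities of the generator; raw traits
# are reconstructed as ratio x CS. This mirrors how species-wise trait
# tables are parameterized and keeps size (CS) and shape (ratios) separate.

# The 17 ratio parameters a simulation spec must provide. CL, CWb, CW and
# PoOC are recovered from CS and the three head indices:
#   CL  = 2 CS r_CL/CWb / (1 + r_CL/CWb),  CWb = 2 CS / (1 + r_CL/CWb),
#   CW  = CL / r_CL/CW,                    PoOC = CL * r_PoOC/CL.
sim_ratio_names <- function() {
  c("CL/CW", "CL/CWb", "PoOC/CL",
    paste0(c("FRS", "SL", "EL", "MW", "PEW", "PPW", "ML", "PEL", "NOL",
             "MPST", "PEH", "NOH", "PPH", "PPL"), "/CS"))
}

#' Simulation specification for one species
#'
#' Describes one species as a truncated-normal size distribution (`CS`, in
#' micrometres) plus independent-mean normal distributions for 17
#' dimensionless ratio traits, and a nest-sampling design.
#'
#' @param label Species label carried into the generated dataset.
#' @param cs_mean,cs_sd Mean and standard deviation of `CS` in micrometres.
#' @param ratio_means,ratio_sds Named numeric vectors over
#'   `CL/CW`, `CL/CWb`, `PoOC/CL` and the 14 trait`/CS` ratios.
#' @param n_nests Number of nest samples to generate.
#' @param n_workers Total number of workers; when given (and
#'   `workers_per_nest` is `NULL`) nests receive either one or two workers
#'   so that totals are exact (`n_workers - n_nests` nests of two).
#' @param workers_per_nest Alternative design: a single count, or a range
#'   `c(lo, hi)` sampled uniformly per nest.
#' @return An object of class `species_sim_spec`.
#' @export
species_sim_spec <- function(label, cs_mean, cs_sd, ratio_means, ratio_sds,
                             n_nests, n_workers = NULL,
                             workers_per_nest = NULL) {
  rn <- sim_ratio_names()
  if (!setequal(names(ratio_means), rn) || !setequal(names(ratio_sds), rn)) {
    stop("species_sim_spec(): ratio_means/ratio_sds must be named over: ",
         paste(rn, collapse = ", "))
  }
  ratio_means <- ratio_means[rn]
  ratio_sds <- ratio_sds[rn]
  stopifnot(cs_mean > 0, cs_sd >= 0, all(ratio_means > 0),
            all(ratio_sds >= 0), n_nests >= 1)
  if (is.null(n_workers) && is.null(workers_per_nest)) {
    workers_per_nest <- 1L
  }
  if (!is.null(n_workers)) {
    if (n_workers < n_nests || n_workers > 2L * n_nests) {
      stop("species_sim_spec(): with exact totals, n_nests <= n_workers <= ",
           "2 * n_nests is required")
    }
  }
  structure(list(label = label, cs_mean = cs_mean, cs_sd = cs_sd,
                 ratio_means = ratio_means, ratio_sds = ratio_sds,
                 n_nests = as.integer(n_nests),
                 n_workers = if (is.null(n_workers)) NULL else as.integer(n_workers),
                 workers_per_nest = workers_per_nest),
            class = "species_sim_spec")
}

#' Published simulation parameters for the Nesomyrmex madecassus group
#'
#' Species-wise means and standard deviations of `CS` and the ratio traits
#' for the four species of the group (N. flavus, N. gibber, N. madecassus,
#' N. nitidus), as reported in the group's taxonomic revision, with nest
#' counts chosen so the default dataset reproduces the study design: 231
#' workers in 172 nest samples (61/45 flavus, 7/5 gibber, 84/63 madecassus,
#' 79/59 nitidus). The gibber `PEH/CS` deviation is printed as 0.00 at two
#' decimals; 0.005 (the printing half-unit) is used.
#'
#' @return List of four [species_sim_spec()] objects.
#' @export
madecassus_group_specs <- function() {
  rn <- sim_ratio_names()
  tab <- rbind(
    #          CL/CW CL/CWb PoOC/CL FRS   SL    EL    MW    PEW   PPW   ML    PEL   NOL   MPST  PEH   NOH   PPH   PPL
    flavus     = c(1.21, 1.26, 0.48, 0.30, 0.80, 0.25, 0.60, 0.22, 0.35, 1.38, 0.53, 0.35, 0.44, 0.28, 0.13, 0.27, 0.30),
    gibber     = c(1.11, 1.17, 0.41, 0.33, 0.80, 0.25, 0.64, 0.21, 0.30, 1.41, 0.50, 0.33, 0.46, 0.29, 0.15, 0.26, 0.26),
    madecassus = c(1.15, 1.18, 0.46, 0.31, 0.78, 0.26, 0.62, 0.22, 0.35, 1.35, 0.50, 0.33, 0.44, 0.28, 0.13, 0.27, 0.27),
    nitidus    = c(1.19, 1.23, 0.48, 0.31, 0.74, 0.26, 0.60, 0.22, 0.33, 1.31, 0.51, 0.34, 0.43, 0.27, 0.12, 0.26, 0.27)
  )
  sds <- rbind(
    flavus     = c(0.04, 0.04, 0.01, 0.01, 0.02, 0.01, 0.02, 0.01, 0.01, 0.04, 0.02, 0.02, 0.01, 0.01, 0.01, 0.01, 0.02),
    gibber     = c(0.02, 0.02, 0.01, 0.01, 0.01, 0.01, 0.01, 0.01, 0.02, 0.01, 0.03, 0.01, 0.01, 0.005, 0.01, 0.01, 0.02),
    madecassus = c(0.02, 0.02, 0.01, 0.01, 0.02, 0.01, 0.02, 0.01, 0.02, 0.04, 0.02, 0.02, 0.02, 0.01, 0.01, 0.01, 0.02),
    nitidus    = c(0.03, 0.03, 0.01, 0.01, 0.02, 0.01, 0.01, 0.01, 0.02, 0.03, 0.02, 0.02, 0.02, 0.01, 0.01, 0.01, 0.02)
  )
  colnames(tab) <- colnames(sds) <- rn
  cs <- list(flavus = c(602, 35), gibber = c(724, 33),
             madecassus = c(692, 37), nitidus = c(496, 26))
  design <- list(flavus = c(45, 61), gibber = c(5, 7),
                 madecassus = c(63, 84), nitidus = c(59, 79))
  lapply(stats::setNames(nm = rownames(tab)), function(sp) {
    species_sim_spec(sp, cs[[sp]][1], cs[[sp]][2],
                     ratio_means = tab[sp, ], ratio_sds = sds[sp, ],
                     n_nests = design[[sp]][1], n_workers = design[[sp]][2])
  })
}

# Cholesky factor of the exchangeable correlation matrix (1-rho) I + rho J.
exch_chol <- function(p, rho) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  C <- matrix(rho, p, p)
  diag(C) <- 1
  ch <- tryCatch(chol(C), error = function(e) {
    stop("generate_dataset(): correlation matrix is not positive definite")
  })
  ch
}

# One multivariate draw: sigma-scaled, exchangeably correlated.
draw_dev <- function(chol_corr, sds, scale) {
  as.numeric(crossprod(chol_corr, stats::rnorm(length(sds)))) * sds * scale
}

# Reconstruct the 18 raw traits (micrometres) from CS and the 17 ratios.
ratios_to_traits <- function(cs, r) {
  cl <- 2 * cs * r[["CL/CWb"]] / (1 + r[["CL/CWb"]])
  cwb <- 2 * cs / (1 + r[["CL/CWb"]])
  out <- c(CL = cl, CW = cl / r[["CL/CW"]], CWb = cwb,
           PoOC = cl * r[["PoOC/CL"]])
  rest <- sim_ratio_names()[-(1:3)]
  traits <- sub("/CS$", "", rest)
  out <- c(out, stats::setNames(r[rest] * cs, traits))
  out[measured_traits()]
}

valid_ratio_vec <- function(r) {
  all(r > 0) &&
    r[["CL/CWb"]] >= r[["CL/CW"]] &&   # implies CWb <= CW
    r[["PoOC/CL"]] <= 1                # implies PoOC <= CL
}

#' Generate a synthetic nest-structured morphometric dataset
#'
#' Emulates the statistical structure the delimitation pipeline assumes:
#' species-level clusters in ratio space, a shared nest-level shift
#' (nestmates are close relatives and so more alike than random
#' conspecifics), and a common exchangeable correlation among ratio
#' deviations within an individual. For each nest a shift vector with an
#' `eta` fraction of the ratio variance is drawn; each worker adds an
#' independent deviation carrying the remaining `1 - eta`, so marginal
#' ratio variances equal the spec's `sigma^2` exactly. `CS` is drawn from a
#' normal truncated at zero (by rejection; negligible at realistic
#' parameters) and raw traits are reconstructed as ratio times `CS`.
#' Specimens whose drawn ratio vector would violate the anatomical
#' invariants (`CWb <= CW`, `PoOC <= CL`, positivity) are redrawn.
#'
#' @param specs List of [species_sim_spec()]; default the published
#'   four-species parameters of [madecassus_group_specs()].
#' @param eta Fraction of ratio variance at the nest level, in `[0, 1)`.
#' @param rho Common correlation among ratio deviations, in `[0, 1)`.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return A [morph_dataset()] whose `species` column carries the true
#'   labels.
#' @examples
#' ds <- generate_dataset(seed = 1)
#' table(ds$species)
#' @export
generate_dataset <- function(specs = madecassus_group_specs(), eta = 0.3,
                             rho = 0.2, seed = NULL) {
  if (eta < 0 || eta >= 1) stop("generate_dataset(): eta must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  if (inherits(specs, "species_sim_spec")) specs <- list(specs)
  p <- length(sim_ratio_names())
  ch <- exch_chol(p, rho)

  rows <- list()
  for (spec in specs) {
    sizes <- nest_sizes(spec)
    prefix <- toupper(substr(spec$label, 1, 3))
    for (j in seq_along(sizes)) {
      nest_code <- sprintf("%s-N%03d", prefix, j)
      shift <- draw_dev(ch, spec$ratio_sds, sqrt(eta))
      for (i in seq_len(sizes[j])) {
        r <- NULL
        for (try in 1:1000) {
          cand <- spec$ratio_means + shift +
            draw_dev(ch, spec$ratio_sds, sqrt(1 - eta))
          if (valid_ratio_vec(cand)) { r <- cand; break }
        }
        if (is.null(r)) {
          stop("generate_dataset(): could not draw a valid ratio vector; ",
               "check the spec for species '", spec$label, "'")
        }
        cs <- -1
        while (cs <= 0) cs <- stats::rnorm(1, spec$cs_mean, spec$cs_sd)
        rows[[length(rows) + 1L]] <- c(
          list(specimen_code = sprintf("%s-%d", nest_code, i),
               nest_code = nest_code, species = spec$label),
          as.list(ratios_to_traits(cs, r))
        )
      }
    }
  }
  df <- do.call(rbind, lapply(rows, function(x) as.data.frame(x, check.names = FALSE)))
  morph_dataset(df)
}

# Per-nest worker counts for one species spec.
nest_sizes <- function(spec) {
  if (!is.null(spec$workers_per_nest)) {
    w <- spec$workers_per_nest
    if (length(w) == 1L) return(rep(as.integer(w), spec$n_nests))
    return(sample(seq(w[1], w[2]), spec$n_nests, replace = TRUE))
  }
  sizes <- rep(1L, spec$n_nests)
  doubles <- spec$n_workers - spec$n_nests
  if (doubles > 0) sizes[sample.int(spec$n_nests, doubles)] <- 2L
  sizes
}
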