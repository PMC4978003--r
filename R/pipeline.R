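# End-to-end orchestration: simulate/read -> NC clustering -> PART with
# both backends -> consensus wild-cards -> confirmatory LOOCV-LDA ->
# final species hypothesis per specimen.

# One seed fans out to fixed per-stage child seeds so each stochastic
# stage is independently reproducible.
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) + 97561 * h) %% .Machine$integer.max
}

#' Pipeline configuration
#'
#' Exactly one of `input` (a specimen CSV path) or `specs` (simulation
#' specifications) drives the data stage.
#'
#' @param input Optional path to a specimen-level CSV.
#' @param specs Optional list of [species_sim_spec()]; defaults to the
#'   published four-species parameters when `input` is `NULL`.
#' @param eta,rho Generator parameters, see [generate_dataset()].
#' @param linkage,level Dendrogram options, see [nc_cluster()].
#' @param min_size,kmax,B,nstart PART options, see [part_config()].
#' @param prior Confirmatory-LDA prior, see [loocv_classify()].
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, specs = NULL, eta = 0.3, rho = 0.2,
                            linkage = "ward", level = "nest", min_size = 5,
                            kmax = 10, B = 1000, nstart = 20,
                            prior = "proportional", seed = 1) {
  if (!is.null(input) && !is.null(specs)) {
    stop("pipeline_config(): give either 'input' or 'specs', not both")
  }
  if (is.null(input) && is.null(specs)) specs <- madecassus_group_specs()
  structure(list(input = input, specs = specs, eta = eta, rho = rho,
                 linkage = linkage, level = level, min_size = min_size,
                 kmax = kmax, B = B, nstart = nstart, prior = prior,
                 seed = seed),
            class = "pipeline_config")
}

#' Run the full delimitation pipeline
#'
#' Executes, in order: data acquisition (reading or simulation), NC
#' clustering, PART with both the hclust and kmeans backends, consensus
#' with wild-card flagging, and - when at least two hypothesis classes
#' remain - confirmatory LOOCV-LDA with wild-card classification. The
#' final label of a hypothesis specimen is its (confirmed) hypothesis
#' cluster; wild-cards receive their maximum-posterior assignment.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `pipeline_report`: list with `dataset`,
#'   `nc` (clustering results), `part_hclust`, `part_kmeans`, `consensus`
#'   (per nest), `hypothesis` (per specimen), `classification`
#'   (a [loocv_classify()] result or `NULL` if skipped), `final_labels`
#'   (per specimen), `config`, `seeds`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  seeds <- list(simulate = derive_seed(config$seed, "simulate"),
                part_hclust = derive_seed(config$seed, "part_hclust"),
                part_kmeans = derive_seed(config$seed, "part_kmeans"))

  ds <- if (!is.null(config$input)) {
    read_morph_csv(config$input)
  } else {
    generate_dataset(config$specs, eta = config$eta, rho = config$rho,
                     seed = seeds$simulate)
  }

  nc <- nc_cluster(ds, linkage = config$linkage, level = config$level)

  pc <- function(clusterer, seed) {
    part_config(min_size = config$min_size, kmax = config$kmax,
                B = config$B, clusterer = clusterer, nstart = config$nstart,
                seed = seed)
  }
  part_h <- part_recursive(nc$centroids, config = pc("hclust", seeds$part_hclust))
  part_k <- part_recursive(nc$centroids, config = pc("kmeans", seeds$part_kmeans))
  consensus <- consensus_partition(part_h, part_k)

  hyp <- stats::setNames(consensus[ds$nest_code], ds$specimen_code)
  n_classes <- length(unique(hyp[hyp != "WILDCARD"]))
  classification <- NULL
  final <- hyp
  if (n_classes < 2) {
    message("run_pipeline(): fewer than 2 hypothesis classes; confirmatory ",
            "LDA skipped")
  } else {
    classification <- loocv_classify(ds, hyp, prior = config$prior)
    if (!is.null(classification$wildcard_assignments)) {
      wa <- classification$wildcard_assignments
      final[wa$specimen] <- wa$predicted
    }
  }

  structure(list(dataset = ds, nc = nc, part_hclust = part_h,
                 part_kmeans = part_k, consensus = consensus,
                 hypothesis = hyp, classification = classification,
                 final_labels = final, config = config, seeds = seeds),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  print(x$dataset)
  cat("PART hclust: ", x$part_hclust$n_clusters, " cluster(s); kmeans: ",
      x$part_kmeans$n_clusters, " cluster(s)\n", sep = "")
  cat("wild-card nests: ", sum(x$consensus == "WILDCARD"), "/",
      length(x$consensus), "\n", sep = "")
  if (!is.null(x$classification)) {
    cat(sprintf("confirmatory LOOCV overall: %.1f%%\n",
                x$classification$overall_pct))
  }
  cat("final labels:\n")
  print(table(x$final_labels))
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Emits the Newick tree, per-nest and per-specimen label tables, the
#' confusion matrix in the published table layout, a species-wise summary
#' table over the final labels, and a JSON run manifest with the
#' configuration and all seeds.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  put <- function(name) {
    f <- file.path(dir, name)
    files <<- c(files, f)
    f
  }

  export_newick(report$nc$tree, put("dendrogram.nwk"))

  nest_tab <- data.frame(
    nest_code = names(report$consensus),
    part_hclust = report$part_hclust$labels[names(report$consensus)],
    part_kmeans = report$part_kmeans$labels[names(report$consensus)],
    consensus = unname(report$consensus),
    row.names = NULL, stringsAsFactors = FALSE
  )
  utils::write.csv(nest_tab, put("nest_labels.csv"), row.names = FALSE)

  spec_tab <- data.frame(
    specimen_code = report$dataset$specimen_code,
    nest_code = report$dataset$nest_code,
    hypothesis = unname(report$hypothesis[report$dataset$specimen_code]),
    final = unname(report$final_labels[report$dataset$specimen_code]),
    row.names = NULL, stringsAsFactors = FALSE
  )
  utils::write.csv(spec_tab, put("specimen_labels.csv"), row.names = FALSE)

  if (!is.null(report$classification)) {
    write_confusion_csv(report$classification, put("confusion.csv"))
  }

  summ <- summarize_by_species(report$dataset,
                               labels = report$final_labels)
  write_species_summary(summ, put("species_summary.csv"))

  manifest <- list(
    package = "ncpart",
    version = as.character(utils::packageVersion("ncpart")),
    r_version = as.character(getRversion()),
    seed = report$config$seed,
    stage_seeds = report$seeds,
    config = report$config[c("eta", "rho", "linkage", "level", "min_size",
                             "kmax", "B", "nstart", "prior")],
    n_specimens = nrow(report$dataset),
    n_nests = length(unique(report$dataset$nest_code)),
    n_clusters_hclust = report$part_hclust$n_clusters,
    n_clusters_kmeans = report$part_kmeans$n_clusters,
    wildcard_nests = sum(report$consensus == "WILDCARD"),
    overall_pct = if (is.null(report$classification)) NULL
                  else report$classification$overall_pct
  )
  jsonlite::write_json(manifest, put("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(files)
}
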