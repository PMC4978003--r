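# Shared fixture builders. All data is generated in code; base_traits is a
# single anatomically consistent worker (micrometres).

base_traits <- function() {
  c(CL = 700, CW = 610, CWb = 590, EL = 175, FRS = 210, ML = 950, MW = 420,
    MPST = 300, NOH = 90, NOL = 230, PEH = 195, PEL = 350, PEW = 150,
    PoOC = 330, PPH = 185, PPL = 190, PPW = 240, SL = 540)
}

# n specimens jittered around base_traits, assigned to nests round-robin.
make_specimen_df <- function(n, n_nests = max(1, n %/% 2), jitter_sd = 5,
                             seed = 42) {
  set.seed(seed)
  tr <- base_traits()
  rows <- lapply(seq_len(n), function(i) {
    v <- tr * exp(stats::rnorm(length(tr), 0, jitter_sd / 1000))
    v["CWb"] <- min(v["CWb"], v["CW"])
    v["PoOC"] <- min(v["PoOC"], v["CL"])
    c(list(specimen_code = sprintf("SP%03d", i),
           nest_code = sprintf("N%02d", (i - 1) %% n_nests + 1)),
      as.list(v))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
}

# Two clearly separated artificial species (shift selected traits), for
# classifier fixtures.
make_two_species_ds <- function(n_per = 10, shift = 80, seed = 7) {
  df <- make_specimen_df(2 * n_per, n_nests = 2 * n_per, seed = seed)
  idx <- seq_len(n_per)
  df$SL[idx] <- df$SL[idx] + shift
  df$species <- rep(c("A", "B"), each = n_per)
  morph_dataset(df)
}

# Small simulation spec: one compact species cloud, cheap to generate.
toy_spec <- function(label = "toy", n_nests = 10, n_workers = 15,
                     workers_per_nest = NULL, cs_mean = 600, cs_sd = 20) {
  if (!is.null(workers_per_nest)) n_workers <- NULL
  rn <- sim_ratio_names()
  means <- stats::setNames(rep(0.4, length(rn)), rn)
  means["CL/CW"] <- 1.10; means["CL/CWb"] <- 1.40; means["PoOC/CL"] <- 0.45
  sds <- stats::setNames(rep(0.01, length(rn)), rn)
  species_sim_spec(label, cs_mean, cs_sd, means, sds, n_nests = n_nests,
                   n_workers = n_workers, workers_per_nest = workers_per_nest)
}
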