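# Synthetic LFQ experiments with the statistical structure the pipeline
# assumes: log-normal protein abundances, small replicate noise, a logistic
# intensity-dependent (MNAR) dropout, intensity-linked Poisson spectral
# counts, and a small fraction of "cargo" proteins upregulated under BafA1.
# Ground-truth cargo labels accompany every table.

#' Parameters of the synthetic LFQ generator
#'
#' Defaults emulate a 4-vs-4 replicate proximity-labelling experiment:
#' per-protein mean log2 abundances ~ Normal(25, 3^2), replicate noise sd 0.5
#' (all in log2 units), logistic dropout centred at log2 intensity 22 with
#' unit scale (roughly 10-20% missingness overall, concentrated in
#' low-abundance proteins), spectral counts Poisson with 0.5 expected counts
#' per log2 unit above the dropout midpoint, and 2% of proteins spiked as
#' cargo with a log2(4.67) fold change under BafA1.
#'
#' @param n_proteins Number of protein groups (default 2000).
#' @param n_replicates Biological replicates per condition (default 4).
#' @param cargo_fraction Fraction of proteins that are true cargo
#'   (default 0.02).
#' @param cargo_log2fc log2 fold change added to cargo under BafA1
#'   (default `log2(4.67)`).
#' @param protein_mean,protein_sd Mean/sd of per-protein mean log2 abundance
#'   (defaults 25, 3).
#' @param replicate_sd Replicate noise sd in log2 units (default 0.5).
#' @param dropout_midpoint log2 intensity at 50% dropout (default 22;
#'   `-Inf` disables dropout entirely).
#' @param dropout_scale Logistic scale of the dropout curve (default 1).
#' @param msms_rate Expected spectral counts per log2 unit above the dropout
#'   midpoint (default 0.5).
#' @return A validated list of class `simulation_params`.
#' @export
simulation_params <- function(n_proteins = 2000, n_replicates = 4,
                              cargo_fraction = 0.02,
                              cargo_log2fc = log2(4.67),
                              protein_mean = 25, protein_sd = 3,
                              replicate_sd = 0.5,
                              dropout_midpoint = 22, dropout_scale = 1,
                              msms_rate = 0.5) {
  stopifnot(n_proteins >= 1, n_replicates >= 2,
            cargo_fraction >= 0, cargo_fraction <= 1,
            protein_sd > 0, replicate_sd > 0, dropout_scale > 0,
            msms_rate >= 0)
  structure(list(
    n_proteins = as.integer(n_proteins),
    n_replicates = as.integer(n_replicates),
    cargo_fraction = cargo_fraction, cargo_log2fc = cargo_log2fc,
    protein_mean = protein_mean, protein_sd = protein_sd,
    replicate_sd = replicate_sd,
    dropout_midpoint = dropout_midpoint, dropout_scale = dropout_scale,
    msms_rate = msms_rate
  ), class = "simulation_params")
}

#' Simulate one LFQ experiment with ground truth
#'
#' Per protein p a mean abundance `mu_p ~ Normal(protein_mean, protein_sd^2)`
#' is drawn once. Each sample's true log2 intensity is
#' `x = mu_p + effect + Normal(0, replicate_sd^2)`, where `effect` is
#' `cargo_log2fc` for cargo proteins under BafA1 and 0 otherwise. Each value
#' is observed with probability
#' `1 / (1 + exp((dropout_midpoint - x) / dropout_scale))`, so low-intensity
#' values drop out more (MNAR). Observed entries get raw LFQ `2^x` and a
#' spectral count `Poisson(max(0, msms_rate * (x - dropout_midpoint)) + 0.1)`;
#' unobserved entries get 0 for both.
#'
#' @param params A [simulation_params()] object.
#' @param experiment_id Experiment label used in sample ids (default "exp1").
#' @param seed Optional integer seed for full reproducibility.
#' @param cargo_ids Optional explicit cargo set (character); by default
#'   `round(n_proteins * cargo_fraction)` proteins are sampled.
#' @return A list with elements `table` (`lfq_tbl`), `design` (`lfq_design`)
#'   and `truth` (character vector of cargo protein ids).
#' @export
simulate_experiment <- function(params = simulation_params(),
                                experiment_id = "exp1", seed = NULL,
                                cargo_ids = NULL) {
  stopifnot(inherits(params, "simulation_params"))
  gen <- function() simulate_experiment_impl(params, experiment_id, cargo_ids)
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

simulate_experiment_impl <- function(params, experiment_id, cargo_ids) {
  n <- params$n_proteins
  ids <- sprintf("P%05d", seq_len(n))
  if (is.null(cargo_ids)) {
    n_cargo <- round(n * params$cargo_fraction)
    cargo_ids <- sample(ids, n_cargo)
  } else {
    stopifnot(all(cargo_ids %in% ids))
  }
  is_cargo <- ids %in% cargo_ids
  mu <- stats::rnorm(n, params$protein_mean, params$protein_sd)

  design <- as_lfq_design(tibble::tibble(
    sample_id = c(
      paste0(experiment_id, "_vehicle_", seq_len(params$n_replicates)),
      paste0(experiment_id, "_bafa1_", seq_len(params$n_replicates))
    ),
    condition = rep(c("vehicle", "bafa1"), each = params$n_replicates),
    replicate = rep(seq_len(params$n_replicates), 2),
    experiment = experiment_id
  ))

  table <- tibble::tibble(protein_id = ids, gene_name = "",
                          reverse = FALSE, contaminant = FALSE,
                          site_only = FALSE)
  # spectral counts scale with intensity above the detection region; with
  # dropout disabled the anchor falls back to one protein-sd below the mean
  count_ref <- if (is.finite(params$dropout_midpoint)) {
    params$dropout_midpoint
  } else {
    params$protein_mean - params$protein_sd
  }
  for (i in seq_len(nrow(design))) {
    effect <- if (design$condition[i] == "bafa1") {
      ifelse(is_cargo, params$cargo_log2fc, 0)
    } else 0
    x <- mu + effect + stats::rnorm(n, 0, params$replicate_sd)
    p_obs <- stats::plogis((x - params$dropout_midpoint) /
                             params$dropout_scale)
    obs <- stats::runif(n) < p_obs
    lambda <- pmax(0, params$msms_rate * (x - count_ref)) + 0.1
    counts <- stats::rpois(n, lambda)
    s <- design$sample_id[i]
    table[[paste0("lfq_", s)]] <- ifelse(obs, 2^x, 0)
    table[[paste0("msms_", s)]] <- ifelse(obs, counts, 0L)
  }
  list(table = as_lfq_table(table), design = design,
       truth = sort(cargo_ids))
}

#' Simulate a two-experiment study over one protein universe
#'
#' Mirrors a discovery experiment plus a repeat: the first experiment uses
#' `params1` (default 4 + 4 samples, total n = 8), the second `params2`
#' (default: `params1` with 3 replicates per condition, total n = 6). Both
#' experiments share the same protein identifiers; with
#' `shared_cargo = TRUE` (default) the same proteins are cargo in both.
#'
#' @param params1 [simulation_params()] for the first experiment.
#' @param params2 Parameters for the second; default derives from `params1`
#'   with `n_replicates = 3`.
#' @param shared_cargo Share cargo identities across experiments?
#' @param seed Optional integer seed.
#' @return A list with `experiments` (named list of `list(table, design)`),
#'   `design` (the two designs row-bound) and `truth` (named list of cargo id
#'   vectors per experiment).
#' @export
simulate_study <- function(params1 = simulation_params(), params2 = NULL,
                           shared_cargo = TRUE, seed = NULL) {
  if (is.null(params2)) {
    args <- unclass(params1)
    args$n_replicates <- 3L
    params2 <- do.call(simulation_params, args)
  }
  stopifnot(params1$n_proteins == params2$n_proteins)
  gen <- function() {
    e1 <- simulate_experiment_impl(params1, "exp1", cargo_ids = NULL)
    cargo2 <- if (shared_cargo) e1$truth else NULL
    e2 <- simulate_experiment_impl(params2, "exp2", cargo_ids = cargo2)
    list(
      experiments = list(
        exp1 = list(table = e1$table, design = e1$design),
        exp2 = list(table = e2$table, design = e2$design)
      ),
      design = as_lfq_design(dplyr::bind_rows(e1$design, e2$design)),
      truth = list(exp1 = e1$truth, exp2 = e2$truth)
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
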