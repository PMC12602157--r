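#' Parameter-sweep design
#'
#' The experiment crosses the listed parameter values (cartesian product)
#' and runs every combination on `n_environments` randomly generated
#' environments, `n_replicates` times each - 25 x 50 = 1250 simulations
#' per combination at the defaults. Environments are generated once per
#' (n_plants) value from seeds `master_seed + environment index`;
#' behavioural run seeds are derived deterministically from the master
#' seed and the (combination, environment, replicate) indices, so an
#' interrupted sweep can be resumed from its per-run outputs.
#'
#' @param renewal_durations nectar refill times to sweep (s).
#' @param alphas learning rates to sweep.
#' @param betas exploration-exploitation values to sweep.
#' @param ps pollen deposition rates to sweep.
#' @param n_bees_values bee counts to sweep.
#' @param n_plants_values plant counts to sweep.
#' @param n_environments environments per condition.
#' @param n_replicates replicate runs per environment.
#' @param master_seed master seed for environment generation and run-seed
#'   derivation.
#' @param side_length,n_max arena side (m) and maximal plant nectar (uL).
#' @param ... further arguments passed to [bee_sim_config()] (e.g.
#'   `duration`, `max_bout_distance`).
#' @return A list of class `bee_sweep_config`.
#' @export
bee_sweep_config <- function(renewal_durations = c(200, 400, 600, 800, 1000, 1200),
                             alphas = c(0, 0.5), betas = 10, ps = 0.5,
                             n_bees_values = 2, n_plants_values = 20,
                             n_environments = 25, n_replicates = 50,
                             master_seed = 1, side_length = 1000, n_max = 8,
                             ...) {
  structure(list(renewal_durations = renewal_durations, alphas = alphas,
                 betas = betas, ps = ps, n_bees_values = n_bees_values,
                 n_plants_values = n_plants_values,
                 n_environments = n_environments, n_replicates = n_replicates,
                 master_seed = master_seed, side_length = side_length,
                 n_max = n_max, extra = list(...)),
            class = "bee_sweep_config")
}

#' Deterministic run-seed derivation
#'
#' Chains the indices through a Lehmer-style multiplicative hash modulo
#' the Mersenne prime 2^31 - 1, so every (combination, environment,
#' replicate) triple maps to a distinct, reproducible 31-bit seed.
#'
#' @param master_seed integer master seed.
#' @param combination,environment,replicate 1-based indices.
#' @return Integer seed below 2^31.
#' @export
derive_seed <- function(master_seed, combination, environment, replicate) {
  h <- (abs(master_seed) + 1) %% 2147483647
  for (x in c(combination, environment, replicate)) {
    h <- (h * 48271 + x) %% 2147483647
  }
  as.integer(h)
}

#' Enumerate a sweep without running it
#'
#' @param sweep a `bee_sweep_config`.
#' @return Data frame with one row per simulation run: the parameter
#'   combination (with its `combination` index), `environment`,
#'   `replicate`, and the derived `seed`.
#' @export
enumerate_sweep <- function(sweep) {
  combos <- expand.grid(renewal_duration = sweep$renewal_durations,
                        alpha = sweep$alphas, beta = sweep$betas,
                        p = sweep$ps, n_bees = sweep$n_bees_values,
                        n_plants = sweep$n_plants_values,
                        KEEP.OUT.ATTRS = FALSE)
  combos$combination <- seq_len(nrow(combos))
  runs <- merge(combos,
                expand.grid(environment = seq_len(sweep$n_environments),
                            replicate = seq_len(sweep$n_replicates),
                            KEEP.OUT.ATTRS = FALSE))
  runs <- runs[order(runs$combination, runs$environment, runs$replicate), ]
  runs$seed <- mapply(derive_seed, sweep$master_seed, runs$combination,
                      runs$environment, runs$replicate)
  rownames(runs) <- NULL
  runs
}

#' Run a full parameter sweep
#'
#' Executes every run enumerated by [enumerate_sweep()], computes the
#' per-run metric summary, and aggregates it per parameter combination.
#'
#' @param sweep a `bee_sweep_config`.
#' @param modularity compute the pollen-network modularity per run
#'   (substantially slower; default `FALSE` for bulk sweeps).
#' @param progress print one line per completed combination.
#' @return List with `runs` (one summary row per simulation, with its
#'   design columns) and `summary` (means per combination).
#' @export
run_sweep <- function(sweep, modularity = FALSE, progress = FALSE) {
  runs <- enumerate_sweep(sweep)
  envs <- list()   # cache: one environment set per (n_plants, renewal) pair
  out <- vector("list", nrow(runs))
  for (r in seq_len(nrow(runs))) {
    row <- runs[r, ]
    key <- paste(row$n_plants, row$renewal_duration, row$environment, sep = "/")
    if (is.null(envs[[key]])) {
      envs[[key]] <- generate_environment(
        row$n_plants, side_length = sweep$side_length, n_max = sweep$n_max,
        renewal_duration = row$renewal_duration,
        seed = sweep$master_seed + row$environment)
    }
    cfg <- do.call(bee_sim_config,
                   c(list(n_bees = row$n_bees, alpha = row$alpha,
                          beta = row$beta, p = row$p), sweep$extra))
    sim <- run_simulation(envs[[key]], cfg, seed = row$seed)
    out[[r]] <- compute_all_metrics(sim, modularity = modularity)$summary
    if (progress && (r == nrow(runs) || runs$combination[r + 1] != row$combination)) {
      message(sprintf("combination %d/%d done", row$combination,
                      max(runs$combination)))
    }
  }
  runs <- cbind(runs, do.call(rbind, out))
  metric_cols <- setdiff(names(out[[1]]), character(0))
  agg <- stats::aggregate(
    runs[metric_cols],
    by = runs[c("renewal_duration", "alpha", "beta", "p", "n_bees", "n_plants")],
    FUN = function(x) mean(x, na.rm = TRUE))
  list(runs = runs, summary = agg)
}
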