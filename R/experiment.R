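#' Configuration of a replicated LR experiment
#'
#' @param sim A [sim_config()] describing the generative model.
#' @param scenarios Character vector of partitioning scenarios (see
#'   [make_partition()]).
#' @param models Character vector among `"gompertz"` (true model) and
#'   `"quadratic"` (wrong model).
#' @param n_replicates Number of simulation replicates (study design: 20).
#' @param mcmc An [mcmc_config()]; its seed field is overridden by
#'   deterministic per-chain seeds derived from `seed`.
#' @param seed Master seed; every replicate/chain seed derives from it.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(sim = sim_config(scale = "desk"),
                              scenarios = c("between_animals",
                                            "by_age_within_animals",
                                            "between_animals_and_by_age"),
                              models = c("gompertz", "quadratic"),
                              n_replicates = 20,
                              mcmc = mcmc_config(n_iter = 2000, burn_in = 500,
                                                 thin = 2),
                              seed = 1L) {
  stopifnot(inherits(sim, "sim_config"), inherits(mcmc, "mcmc_config"),
            n_replicates >= 2)
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  models <- match.arg(models, several.ok = TRUE)
  structure(list(sim = sim, scenarios = scenarios, models = models,
                 n_replicates = as.integer(n_replicates), mcmc = mcmc,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Run a replicated LR model-adequacy experiment
#'
#' The full pipeline, per replicate: simulate a growth dataset; for each
#' model fit the whole data once and each scenario's partial data; compute
#' the EBV surfaces of the validation animals from both fits, the Gibbs
#' genetic-variance estimate from the partial fit's training animals, and
#' the per-day LR statistics; average them across validation days. After
#' all replicates, run the across-replicate t-tests: bias statistics
#' (\eqn{\hat\Delta}, true \eqn{\Delta}) against 0, dispersion statistics
#' (\eqn{\hat b_{wp}}, true slope) against 1, and the covariance-gap test
#' against 0, separately per scenario-model cell.
#'
#' Replicate and chain seeds are derived deterministically from the master
#' seed, so a rerun with the same configuration reproduces every number.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional directory; if given, writes `day_stats.csv`,
#'   `replicate_summary.csv`, `tests.csv` and a `manifest.txt` of settings
#'   and seeds.
#' @param verbose Print per-replicate progress.
#' @return An object of class `lr_experiment`: list of tibbles `day_stats`
#'   (replicate x scenario x model x age), `replicate_summary`, `tests`,
#'   plus the `config`.
#' @examples
#' \donttest{
#' cfg <- experiment_config(sim = sim_config(n_animals = 45, scale = "desk",
#'                                           ages = seq(70, 500, 20)),
#'                          models = "quadratic", n_replicates = 2,
#'                          mcmc = mcmc_config(n_iter = 200, burn_in = 100,
#'                                             thin = 1))
#' res <- run_experiment(cfg)
#' res$tests
#' }
#' @export
run_experiment <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max, config$n_replicates)
  day_all <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    if (verbose) message("replicate ", r, "/", config$n_replicates)
    day_all[[r]] <- .run_replicate(config, r, rep_seeds[r])
  }
  day_stats <- dplyr::bind_rows(day_all)
  replicate_summary <- day_stats |>
    dplyr::group_by(.data$replicate, .data$scenario, .data$model) |>
    dplyr::group_modify(~ lr_summarize(.x)) |>
    dplyr::ungroup()
  tests <- replicate_summary |>
    dplyr::group_by(.data$scenario, .data$model) |>
    dplyr::group_modify(function(d, key) {
      dplyr::bind_rows(
        lr_t_test(d$delta_hat, 0, "delta_hat"),
        lr_t_test(d$delta_true, 0, "delta_true"),
        lr_t_test(d$slope_hat, 1, "slope_hat"),
        lr_t_test(d$slope_true, 1, "slope_true"),
        lr_covariance_gap_test(d))
    }) |>
    dplyr::ungroup()
  out <- structure(list(day_stats = day_stats,
                        replicate_summary = replicate_summary,
                        tests = tests, config = config,
                        rep_seeds = rep_seeds),
                   class = "lr_experiment")
  if (!is.null(out_dir)) .write_experiment(out, out_dir)
  out
}

.run_replicate <- function(config, r, seed_r) {
  ds <- simulate_growth(config$sim, seed = seed_r)
  res <- list()
  for (model in config$models) {
    # Fixed-at-truth variance components, expressed on the fitted model's
    # latent scale (basis projection for the quadratic wrong model).
    if (model == "quadratic") {
      se_m <- quadratic_latent_covariance(config$sim$sigma_e, config$sim$mu,
                                          config$sim$ages)
      sa_m <- quadratic_latent_covariance(config$sim$sigma_alpha,
                                          config$sim$mu, config$sim$ages)
    } else {
      se_m <- config$sim$sigma_e
      sa_m <- config$sim$sigma_alpha
    }
    chain_seed <- function(k) (seed_r + 7919L * k) %% .Machine$integer.max
    mc_w <- config$mcmc
    mc_w$seed <- chain_seed(1L)
    fit_w <- fit_growth_model(ds$records, ds$genotypes, model = model,
                              sigma_e = se_m, sigma_alpha = sa_m,
                              residual_bands = config$sim$residual_bands,
                              mcmc = mc_w)
    for (si in seq_along(config$scenarios)) {
      sc <- config$scenarios[si]
      part <- make_partition(ds, sc)
      mc_p <- config$mcmc
      mc_p$seed <- chain_seed(1L + si)
      fit_p <- fit_growth_model(part$partial_records, ds$genotypes,
                                model = model,
                                sigma_e = se_m, sigma_alpha = sa_m,
                                residual_bands = config$sim$residual_bands,
                                mcmc = mc_p)
      val <- as.character(part$validation_animals)
      va <- part$validation_ages
      ebv_p <- posterior_ebv(fit_p, val, va)
      ebv_w <- posterior_ebv(fit_w, val, va)
      u <- ds$bv[val, as.character(va), drop = FALSE]
      vu <- estimate_genetic_variance(fit_p, va)
      day <- lr_day_stats(u, ebv_p, ebv_w, vu) |>
        dplyr::mutate(replicate = r, scenario = sc, model = model,
                      .before = 1)
      res[[paste(model, sc)]] <- day
    }
  }
  dplyr::bind_rows(res)
}

.write_experiment <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(x$day_stats, file.path(out_dir, "day_stats.csv"),
                   row.names = FALSE)
  utils::write.csv(x$replicate_summary,
                   file.path(out_dir, "replicate_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(x$tests, file.path(out_dir, "tests.csv"),
                   row.names = FALSE)
  manifest <- c(
    paste0("master_seed = ", x$config$seed),
    paste0("replicate_seeds = ", paste(x$rep_seeds, collapse = ",")),
    paste0("scenarios = ", paste(x$config$scenarios, collapse = ",")),
    paste0("models = ", paste(x$config$models, collapse = ",")),
    paste0("n_replicates = ", x$config$n_replicates),
    paste0("mcmc = ", x$config$mcmc$n_iter, "/", x$config$mcmc$burn_in, "/",
           x$config$mcmc$thin),
    .serialize_config(x$config$sim))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}

#' @export
print.lr_experiment <- function(x, ...) {
  cat("<lr_experiment> ", x$config$n_replicates, " replicates, scenarios: ",
      paste(x$config$scenarios, collapse = ", "), "; models: ",
      paste(x$config$models, collapse = ", "), "\n", sep = "")
  print(x$tests, n = Inf)
  invisible(x)
}

#' Tidy the across-replicate test table of an experiment
#'
#' @param x An `lr_experiment`.
#' @param ... Unused.
#' @return The `tests` tibble (scenario, model, statistic, t, p-value).
#' @export
tidy.lr_experiment <- function(x, ...) x$tests

#' One-row-per-cell summary of an experiment
#'
#' @param x An `lr_experiment`.
#' @param ... Unused.
#' @return A tibble with one row per scenario-model cell and the
#'   across-replicate means of the LR statistics.
#' @export
glance.lr_experiment <- function(x, ...) {
  x$replicate_summary |>
    dplyr::group_by(.data$scenario, .data$model) |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric) &
                                     !dplyr::any_of("replicate"), mean),
                     .groups = "drop")
}
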