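# Parameter-recovery experiments: simulate -> full pipeline ->
# bias/RMSE of SFSI, ANR and PE against the configured truth.

# Noise-free expected cell means implied by a sim_config, as a long
# cell table compatible with indices_from_cells().
truth_cells <- function(config) {
  g <- config$genotypes
  lf <- config$leaf_fraction
  purrr::map_dfr(c("nf", "f"), function(tr) {
    treatment <- if (tr == "f") "+F" else "non-F"
    shoot <- if (tr == "f") g$base_shoot else g$base_shoot * (1 - g$resp_shoot)
    tuber <- if (tr == "f") g$base_tuber else g$base_tuber * (1 - g$resp_tuber)
    up <- lapply(nutrient_levels(), function(nut) {
      (lf * shoot * g[[paste0("leaf_", nut)]] +
         tuber * g[[paste0("tuber_", nut, "_", tr)]]) / 1000
    })
    names(up) <- paste0("uptake_", nutrient_levels(), "_g")
    tibble::tibble(genotype = g$genotype, treatment = treatment,
                   dry_shoot_g = shoot, dry_tuber_g = tuber,
                   uptake_N_g = up$uptake_N_g, uptake_P_g = up$uptake_P_g,
                   uptake_K_g = up$uptake_K_g) |>
      tidyr::pivot_longer(-c("genotype", "treatment"),
                          names_to = "trait", values_to = "mean")
  })
}

#' Configured truth of the NUE indices
#'
#' The index values (PD, SFSI, ANR, PE) implied by a simulation
#' configuration's noise-free expected cell means — the estimands of a
#' [recovery_experiment()].
#'
#' @param config A [sim_config()].
#' @param trial_cfg A [trial_config()] supplying the nutrient supply.
#' @param traits,yield_trait,eps As in [nue_analysis()].
#' @return The per-genotype index table (see [nue_analysis()]).
#' @export
truth_indices <- function(config, trial_cfg = trial_config(),
                          traits = c("dry_shoot_g", "dry_tuber_g"),
                          yield_trait = "dry_tuber_g", eps = 1e-6) {
  supply <- setNames(
    vapply(nutrient_levels(), function(n) per_plant_supply(trial_cfg, n), 0),
    nutrient_levels()
  )
  indices_from_cells(truth_cells(config), supply, traits, yield_trait, eps)
}

# Index estimates from one simulated record set (fast path: no t-tests,
# no bootstrap).
estimate_indices <- function(records, supply, traits, yield_trait, eps) {
  plant_traits <- derive_traits(records) |>
    dplyr::inner_join(plant_uptake(records),
                      by = c("genotype", "block", "treatment", "plant_id"))
  cells <- summarize_trial(
    plant_traits,
    traits = c(traits, paste0("uptake_", nutrient_levels(), "_g"))
  )
  indices_from_cells(cells, supply, traits, yield_trait, eps)
}

#' Parameter-recovery experiment
#'
#' Simulates `n_reps` independent trials from `config`, runs the full
#' pipeline on each, and summarizes bias and root-mean-square error of
#' the SFSI, ANR and PE estimates against the configured truth
#' ([truth_indices()]). Also records, per replicate, the Spearman rank
#' correlation between estimated and true genotype SFSI for the yield
#' trait — the rank-recovery diagnostic.
#'
#' @param config A [sim_config()].
#' @param n_reps Number of simulated trials (>= 1).
#' @param trial_cfg A [trial_config()] for the nutrient supply.
#' @param traits,yield_trait,eps As in [nue_analysis()].
#' @param seed Seed for the whole experiment; defaults to `config$seed`.
#' @return An object of class `yam_recovery`; [tidy()] gives the
#'   per-genotype bias/RMSE table, [glance()] the replicate-level
#'   rank-recovery summary.
#' @export
recovery_experiment <- function(config, n_reps = 200,
                                trial_cfg = trial_config(n_blocks = config$n_blocks),
                                traits = c("dry_shoot_g", "dry_tuber_g"),
                                yield_trait = "dry_tuber_g", eps = 1e-6,
                                seed = config$seed) {
  stopifnot(inherits(config, "sim_config"), n_reps >= 1)
  supply <- setNames(
    vapply(nutrient_levels(), function(n) per_plant_supply(trial_cfg, n), 0),
    nutrient_levels()
  )
  truth <- indices_from_cells(truth_cells(config), supply, traits,
                              yield_trait, eps)
  run <- function() {
    purrr::map(seq_len(n_reps), function(i) {
      estimate_indices(sim_once(config), supply, traits, yield_trait, eps)
    })
  }
  reps <- if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())

  est_long <- purrr::imap_dfr(reps, function(r, i) {
    dplyr::mutate(
      dplyr::select(r, "genotype", "measure", "sfsi", "anr_pct", "pe_g_per_g"),
      rep = i
    )
  }) |>
    tidyr::pivot_longer(c("sfsi", "anr_pct", "pe_g_per_g"),
                        names_to = "statistic", values_to = "estimate") |>
    dplyr::filter(!is.na(.data$estimate))
  truth_long <- truth |>
    dplyr::select("genotype", "measure", "sfsi", "anr_pct", "pe_g_per_g") |>
    tidyr::pivot_longer(c("sfsi", "anr_pct", "pe_g_per_g"),
                        names_to = "statistic", values_to = "truth") |>
    dplyr::filter(!is.na(.data$truth))
  summary_tbl <- est_long |>
    dplyr::inner_join(truth_long, by = c("genotype", "measure", "statistic")) |>
    dplyr::group_by(.data$genotype, .data$measure, .data$statistic) |>
    dplyr::summarize(truth = .data$truth[1],
                     mean_estimate = mean(.data$estimate),
                     bias = mean(.data$estimate - .data$truth),
                     rmse = sqrt(mean((.data$estimate - .data$truth)^2)),
                     .groups = "drop")

  truth_sfsi <- truth$sfsi[truth$measure == yield_trait]
  names(truth_sfsi) <- truth$genotype[truth$measure == yield_trait]
  spearman <- vapply(reps, function(r) {
    est <- r$sfsi[r$measure == yield_trait]
    names(est) <- r$genotype[r$measure == yield_trait]
    stats::cor(est[names(truth_sfsi)], truth_sfsi, method = "spearman")
  }, 0)

  structure(
    list(summary = summary_tbl, spearman = spearman, truth = truth,
         n_reps = n_reps, config = config, yield_trait = yield_trait),
    class = "yam_recovery"
  )
}

#' @export
print.yam_recovery <- function(x, ...) {
  cat(sprintf("Parameter-recovery experiment: %d replicates\n", x$n_reps))
  cat(sprintf("  SFSI (%s) rank recovery: Spearman > 0.8 in %.0f%% of replicates\n",
              x$yield_trait, 100 * mean(x$spearman > 0.8)))
  print(as.data.frame(
    dplyr::mutate(x$summary, dplyr::across(dplyr::where(is.numeric),
                                           ~ round(.x, 3)))
  ), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.yam_recovery <- function(x, ...) x$summary

#' @export
glance.yam_recovery <- function(x, ...) {
  tibble::tibble(
    n_reps = x$n_reps,
    spearman_mean = mean(x$spearman),
    prop_spearman_gt_0.8 = mean(x$spearman > 0.8),
    mean_abs_bias_sfsi = mean(abs(
      x$summary$bias[x$summary$statistic == "sfsi"]
    ))
  )
}
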