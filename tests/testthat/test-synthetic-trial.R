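test_that("simulation is reproducible and seed-sensitive", {
  cfg <- sim_config(seed = 42)
  a <- simulate_trial(cfg)
  b <- simulate_trial(cfg)
  expect_identical(a, b)
  c2 <- simulate_trial(sim_config(seed = 43))
  expect_false(isTRUE(all.equal(a$dry_weight_g, c2$dry_weight_g)))
  expect_no_error(validate_trial(a))
  expect_equal(nrow(a), 6 * 2 * 4 * 3 * 3) # plants x organs
})

test_that("config validation rejects impossible parameters", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(seed = 1, cv_plant = -0.1), "variation")
  g <- calibrate_genotype_params()
  g$resp_tuber[1] <- 1.2
  expect_error(sim_config(seed = 1, genotypes = g), "responsiveness")
  expect_error(sim_config(seed = 1, genotypes = g[, 1:3]), "missing column")
})

test_that("sim config YAML round-trips", {
  cfg <- sim_config(seed = 9, n_blocks = 3, cv_plant = 0.15)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  cfg2 <- read_sim_config(path)
  expect_equal(cfg2$seed, 9L)
  expect_equal(cfg2$cv_plant, 0.15)
  expect_equal(as.data.frame(cfg2$genotypes), as.data.frame(cfg$genotypes),
               tolerance = 1e-12)
  expect_identical(simulate_trial(cfg2), simulate_trial(cfg))
  expect_error(read_sim_config(tempfile()), "not found")
})

noise_free <- function(seed = 1) {
  sim_config(seed = seed, cv_main = 0, cv_sub = 0, cv_plant = 0,
             cv_conc = 0, cv_dm = 0)
}

test_that("noise-free simulation hits the calibration targets exactly", {
  records <- simulate_trial(noise_free())
  traits <- derive_traits(records) |>
    dplyr::inner_join(plant_uptake(records),
                      by = c("genotype", "block", "treatment", "plant_id"))
  cells <- summarize_trial(traits)
  ref <- dplyr::bind_rows(
    reference_means(),
    dplyr::transmute(reference_uptake(), genotype, treatment,
                     trait = paste0("uptake_", nutrient, "_g"),
                     mean = uptake_g)
  )
  joined <- dplyr::inner_join(cells, ref,
                              by = c("genotype", "treatment", "trait"),
                              suffix = c("_sim", "_ref"))
  expect_equal(nrow(joined), nrow(ref))
  expect_equal(joined$mean_sim, joined$mean_ref, tolerance = 1e-9)
  expect_true(all(joined$sd == 0))
})

test_that("default-noise simulation recovers the configured tuber PD", {
  cfg <- sim_config(seed = 42)
  pds <- withr::with_seed(42, {
    vapply(1:20, function(i) {
      cells <- summarize_trial(derive_traits(simulate_trial(cfg, seed = NULL)),
                               traits = "dry_tuber_g")
      w <- tidyr::pivot_wider(cells[c("genotype", "treatment", "mean")],
                              names_from = treatment, values_from = mean)
      percent_difference(w[["non-F"]][w$genotype == "TDr1499"],
                         w[["+F"]][w$genotype == "TDr1499"])
    }, 0)
  })
  expect_lt(abs(mean(pds) - 51.9), 5)
})

test_that("recovery experiment has zero error without noise", {
  rec <- recovery_experiment(noise_free(), n_reps = 2)
  expect_equal(max(abs(rec$summary$bias)), 0, tolerance = 1e-9)
  expect_equal(max(rec$summary$rmse), 0, tolerance = 1e-9)
  expect_true(all(rec$spearman == 1))
  expect_equal(glance(rec)$prop_spearman_gt_0.8, 1)
})

test_that("doubling plant-level noise does not shrink estimator RMSE", {
  rmse_by_stat <- function(cv) {
    rec <- recovery_experiment(sim_config(seed = 314, cv_plant = cv),
                               n_reps = 60)
    tidy(rec) |>
      dplyr::group_by(statistic) |>
      dplyr::summarize(rmse = mean(rmse), .groups = "drop")
  }
  lo <- rmse_by_stat(0.2)
  hi <- rmse_by_stat(0.4)
  cmp <- dplyr::inner_join(lo, hi, by = "statistic", suffix = c("_lo", "_hi"))
  expect_true(all(cmp$rmse_hi >= cmp$rmse_lo))
})

test_that("SFSI estimates converge as blocks grow", {
  cfg <- sim_config(seed = 271, n_blocks = 64)
  rec <- recovery_experiment(cfg, n_reps = 30,
                             trial_cfg = trial_config(n_blocks = 64))
  bias <- tidy(rec) |>
    dplyr::filter(statistic == "sfsi", measure == "dry_tuber_g")
  expect_true(all(abs(bias$bias) < 0.02))
})
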