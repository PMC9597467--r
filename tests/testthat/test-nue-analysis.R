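noise_free_fit <- function(n_boot = 0, ...) {
  cfg <- sim_config(seed = 4, cv_main = 0, cv_sub = 0, cv_plant = 0,
                    cv_conc = 0, cv_dm = 0)
  nue_analysis(simulate_trial(cfg), n_boot = n_boot, ...)
}

test_that("the pipeline reproduces the published PD/SFSI on calibrated data", {
  fit <- noise_free_fit()
  rep <- tidy(fit)
  shoot <- dplyr::filter(rep, measure == "dry_shoot_g") |>
    dplyr::arrange(genotype)
  expect_equal(round(shoot$pd_pct, 1),
               c(41.1, 40.3, 25.4, 14.4, 23.7, 26.2), tolerance = 1e-8)
  expect_equal(round(shoot$sfsi, 2),
               c(1.31, 1.28, 0.81, 0.46, 0.75, 0.83), tolerance = 1e-8)
  tuber <- dplyr::filter(rep, measure == "dry_tuber_g") |>
    dplyr::arrange(genotype)
  expect_equal(round(tuber$sfsi, 2),
               c(1.44, 1.26, 0.96, 0.48, 0.66, 0.82), tolerance = 1e-8)
  expect_equal(tuber$class,
               c("susceptible", "susceptible", "tolerant", "tolerant",
                 "tolerant", "tolerant"))

  n_uptake <- dplyr::filter(rep, measure == "uptake_N_g") |>
    dplyr::arrange(genotype)
  expect_equal(round(n_uptake$anr_pct[n_uptake$genotype == "TDr1499"], 1), 46.7)
  expect_equal(round(n_uptake$pe_g_per_g[n_uptake$genotype == "TDr1499"], 1),
               121.1)
})

test_that("tidy and glance expose the fitted analysis", {
  fit <- nue_analysis(simulate_trial(sim_config(seed = 12)),
                      n_boot = 100, seed = 5)
  rep <- tidy(fit)
  expect_setequal(
    names(rep),
    c("genotype", "measure", "non_F_mean", "plus_F_mean", "pd_pct", "sfsi",
      "anr_pct", "pe_g_per_g", "class", "contrast_p", "contrast_significant",
      "sfsi_se", "anr_se", "pe_se")
  )
  expect_equal(nrow(rep), 6 * 5) # 2 biomass traits + 3 nutrients
  boot_rows <- dplyr::filter(rep, measure == "dry_tuber_g")
  expect_true(all(is.finite(boot_rows$sfsi_se)))
  expect_true(all(boot_rows$sfsi_se > 0))

  g <- glance(fit)
  expect_equal(g$n_genotypes, 6)
  expect_equal(g$n_plants, 144)
  expect_equal(g$n_blocks, 4)
  expect_true(is.finite(g$fii_dry_tuber_g))

  # bootstrap is seed-reproducible
  fit2 <- nue_analysis(simulate_trial(sim_config(seed = 12)),
                       n_boot = 100, seed = 5)
  expect_equal(tidy(fit2), rep)
})

test_that("plot methods return ggplot objects", {
  fit <- noise_free_fit(n_boot = 20, seed = 2)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(fit, type = "anr"), "ggplot")
  expect_s3_class(autoplot(fit, type = "pe"), "ggplot")
  expect_s3_class(plot_trait_means(fit$cells), "ggplot")
  rec <- recovery_experiment(sim_config(seed = 3), n_reps = 3)
  expect_s3_class(autoplot(rec), "ggplot")
})

test_that("run_simulate and run_analyze produce deterministic artifacts", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  cfg <- sim_config(seed = 77)
  csv1 <- run_simulate(cfg, out1)
  csv2 <- run_simulate(cfg, out2)
  expect_true(file.exists(csv1))
  expect_identical(unname(tools::md5sum(csv1)), unname(tools::md5sum(csv2)))
  expect_true(file.exists(file.path(out1, "manifest.json")))
  manifest <- jsonlite::read_json(file.path(out1, "manifest.json"))
  expect_equal(manifest$command, "simulate")
  expect_equal(manifest$n_records, 432)

  res1 <- file.path(out1, "analysis")
  res2 <- file.path(out2, "analysis")
  fit <- run_analyze(csv1, res1, n_boot = 50, seed = 3)
  expect_s3_class(fit, "yam_nue")
  for (f in c("summary.csv", "uptake.csv", "nue_report.csv", "contrasts.csv",
              "letters.csv", "anova.csv", "manifest.json")) {
    expect_true(file.exists(file.path(res1, f)))
  }
  run_analyze(csv2, res2, n_boot = 50, seed = 3)
  expect_identical(unname(tools::md5sum(file.path(res1, "nue_report.csv"))),
                   unname(tools::md5sum(file.path(res2, "nue_report.csv"))))

  # config round-trip through the YAML used by the command-line wrapper
  cfg_path <- file.path(out1, "sim_config.yaml")
  expect_identical(simulate_trial(read_sim_config(cfg_path)),
                   simulate_trial(cfg))
})

test_that("analysis rejects unusable inputs cleanly", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(make_trial()[0, ], path)
  expect_error(run_analyze(path, withr::local_tempdir()), "no data rows")
  expect_error(run_simulate(config = NULL, out_dir = tempdir()),
               "sim_config or config_path")
  expect_error(run_simulate(config_path = tempfile(), out_dir = tempdir()),
               "not found")
})
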