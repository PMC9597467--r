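# Fixture builders: tiny hand-made record collections used across tests.

organ_row <- function(genotype, block, treatment, plant_id, organ,
                      fresh = NA_real_, dry = 0,
                      N = NA_real_, P = NA_real_, K = NA_real_) {
  tibble::tibble(
    genotype = genotype, block = as.integer(block), treatment = treatment,
    plant_id = plant_id, organ = organ,
    fresh_weight_g = fresh, dry_weight_g = dry,
    conc_N_mg_g = N, conc_P_mg_g = P, conc_K_mg_g = K
  )
}

# one plant with leaf + stem + tuber; concentrations on leaf and tuber
make_plant <- function(genotype = "G1", block = 1, treatment = "non-F",
                       plant_id = "p1",
                       leaf_dry = 40, stem_dry = 30,
                       tuber_fresh = 800, tuber_dry = 240,
                       leaf_conc = c(N = 25, P = 3, K = 20),
                       tuber_conc = c(N = 7, P = 1, K = 5)) {
  dplyr::bind_rows(
    organ_row(genotype, block, treatment, plant_id, "leaf",
              fresh = leaf_dry / 0.3, dry = leaf_dry,
              N = leaf_conc[["N"]], P = leaf_conc[["P"]], K = leaf_conc[["K"]]),
    organ_row(genotype, block, treatment, plant_id, "stem",
              fresh = stem_dry / 0.25, dry = stem_dry),
    organ_row(genotype, block, treatment, plant_id, "tuber",
              fresh = tuber_fresh, dry = tuber_dry,
              N = tuber_conc[["N"]], P = tuber_conc[["P"]], K = tuber_conc[["K"]])
  )
}

# balanced mini trial: genotypes x treatments x blocks x plants, constant
# values per genotype x treatment (from a value function)
make_trial <- function(genotypes = c("G1", "G2"), blocks = 2, plants = 2,
                       tuber_dry_fun = function(g, tr) if (tr == "+F") 300 else 200) {
  purrr::pmap_dfr(
    tidyr::expand_grid(genotype = genotypes, treatment = c("non-F", "+F"),
                       block = seq_len(blocks), plant = seq_len(plants)),
    function(genotype, treatment, block, plant) {
      td <- tuber_dry_fun(genotype, treatment)
      make_plant(genotype, block, treatment, sprintf("p%d", plant),
                 tuber_fresh = td / 0.3, tuber_dry = td)
    }
  )
}

# reference tables reshaped as a cell summary (n = 12 plants per cell)
reference_cell_summary <- function() {
  dplyr::bind_rows(
    reference_means(),
    dplyr::transmute(reference_uptake(),
                     genotype = genotype, treatment = treatment,
                     trait = paste0("uptake_", nutrient, "_g"),
                     mean = uptake_g)
  ) |>
    dplyr::mutate(n = 12L, sd = 0)
}

expect_no_error <- function(expr) expect_error(expr, NA)
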