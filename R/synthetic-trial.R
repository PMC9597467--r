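# Synthetic split-plot trial generator. Emulates the reference design:
# randomized complete blocks (4), fertility treatment on main plots (2),
# genotype on subplots (6), 3 sampled plants per subplot, with
# multiplicative lognormal noise at the main-plot, subplot and plant
# levels. Genotype parameters are calibrated so that noise-free cell
# means reproduce the published genotype x treatment means.

#' Published genotype x treatment reference means
#'
#' Genotype x treatment means of the 2018 Ibadan white Guinea yam trial
#' shipped with the package: dry shoot weight, dry tuber weight and
#' tuber dry matter content (`reference_means()`), and N/P/K uptakes
#' (`reference_uptake()`). These calibrate the simulator's defaults and
#' serve as desk-scale inputs for recomputing the published indices.
#'
#' @return A tibble in long format.
#' @export
reference_means <- function() {
  readr::read_csv(system.file("extdata", "reference_trait_means.csv",
                              package = "yamnue"),
                  show_col_types = FALSE)
}

#' @rdname reference_means
#' @export
reference_uptake <- function() {
  readr::read_csv(system.file("extdata", "reference_uptake_means.csv",
                              package = "yamnue"),
                  show_col_types = FALSE)
}

#' Calibrate per-genotype simulation parameters
#'
#' Builds the genotype parameter table of [sim_config()] from reference
#' genotype x treatment means. The +F trait means are taken as base
#' values with responsiveness = PD/100 (so the non-F mean is
#' base x (1 - responsiveness)); tuber tissue concentrations are solved
#' per genotype x treatment x nutrient so that expected plant uptakes
#' match the reference uptake means given fixed leaf concentrations and
#' the leaf share of shoot dry weight.
#'
#' @param trait_means,uptake_means Reference tables in the format of
#'   [reference_means()] / [reference_uptake()].
#' @param leaf_conc Named vector of leaf tissue concentrations in
#'   mg g^-1 dry matter (defaults N 30, P 3, K 25 — typical yam foliage).
#' @param leaf_fraction Leaf share of shoot dry weight (default 0.55).
#' @return A tibble with one row per genotype.
#' @export
calibrate_genotype_params <- function(trait_means = reference_means(),
                                      uptake_means = reference_uptake(),
                                      leaf_conc = c(N = 30, P = 3, K = 25),
                                      leaf_fraction = 0.55) {
  wide <- trait_means |>
    dplyr::mutate(treatment = dplyr::if_else(.data$treatment == "+F", "f", "nf")) |>
    tidyr::pivot_wider(names_from = c("trait", "treatment"),
                       values_from = "mean")
  out <- tibble::tibble(
    genotype = wide$genotype,
    base_shoot = wide$dry_shoot_g_f,
    resp_shoot = 1 - wide$dry_shoot_g_nf / wide$dry_shoot_g_f,
    base_tuber = wide$dry_tuber_g_f,
    resp_tuber = 1 - wide$dry_tuber_g_nf / wide$dry_tuber_g_f,
    dm_nf = wide$tuber_dm_pct_nf,
    dm_f = wide$tuber_dm_pct_f,
    leaf_N = unname(leaf_conc["N"]),
    leaf_P = unname(leaf_conc["P"]),
    leaf_K = unname(leaf_conc["K"])
  )
  up <- uptake_means |>
    dplyr::mutate(treatment = dplyr::if_else(.data$treatment == "+F", "f", "nf"))
  for (nut in nutrient_levels()) {
    for (tr in c("nf", "f")) {
      u <- up |>
        dplyr::filter(.data$nutrient == nut, .data$treatment == tr) |>
        dplyr::arrange(match(.data$genotype, out$genotype))
      shoot <- if (tr == "f") out$base_shoot else out$base_shoot * (1 - out$resp_shoot)
      tuber <- if (tr == "f") out$base_tuber else out$base_tuber * (1 - out$resp_tuber)
      conc <- (u$uptake_g * 1000 - leaf_fraction * shoot * leaf_conc[nut]) / tuber
      if (any(conc < 0)) {
        stop("infeasible calibration: negative tuber concentration for ",
             nut, " under ", tr, call. = FALSE)
      }
      out[[paste0("tuber_", nut, "_", tr)]] <- conc
    }
  }
  out
}

#' Simulation configuration
#'
#' All knobs of the synthetic split-plot trial. The defaults are the
#' reference trial's conditions: 4 blocks, 3 plants per subplot, six
#' genotypes calibrated to the published means, and coefficients of
#' variation 0.10 / 0.10 / 0.20 at the main-plot / subplot / plant
#' levels (multiplicative lognormal noise).
#'
#' @param seed Integer seed; mandatory, drives all randomness.
#' @param genotypes Genotype parameter table, see
#'   [calibrate_genotype_params()].
#' @param n_blocks,n_plants Blocks and plants per subplot.
#' @param cv_main,cv_sub,cv_plant CVs of the main-plot, subplot and
#'   plant-level multiplicative noise.
#' @param cv_conc CV of tissue-concentration noise.
#' @param cv_dm CV of tuber dry-matter-content noise.
#' @param leaf_fraction Leaf share of shoot dry weight (stems get the
#'   remainder).
#' @param shoot_dm_fraction Named vector: dry matter fraction of fresh
#'   leaf and stem tissue, used to back out fresh shoot weights.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed,
                       genotypes = calibrate_genotype_params(),
                       n_blocks = 4, n_plants = 3,
                       cv_main = 0.10, cv_sub = 0.10, cv_plant = 0.20,
                       cv_conc = 0.08, cv_dm = 0.05,
                       leaf_fraction = 0.55,
                       shoot_dm_fraction = c(leaf = 0.30, stem = 0.25)) {
  if (missing(seed) || !is.finite(seed)) {
    stop("sim_config requires an integer seed", call. = FALSE)
  }
  cvs <- c(cv_main, cv_sub, cv_plant, cv_conc, cv_dm)
  if (any(!is.finite(cvs)) || any(cvs < 0)) {
    stop("coefficients of variation must be finite and >= 0", call. = FALSE)
  }
  if (n_blocks < 1 || n_plants < 1) {
    stop("n_blocks and n_plants must be >= 1", call. = FALSE)
  }
  if (leaf_fraction <= 0 || leaf_fraction >= 1) {
    stop("leaf_fraction must lie in (0, 1)", call. = FALSE)
  }
  req <- c("genotype", "base_shoot", "resp_shoot", "base_tuber", "resp_tuber",
           "dm_nf", "dm_f", "leaf_N", "leaf_P", "leaf_K",
           paste0("tuber_", rep(nutrient_levels(), each = 2), "_",
                  c("nf", "f")))
  missing_cols <- setdiff(req, names(genotypes))
  if (length(missing_cols)) {
    stop("genotypes table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(genotypes$resp_shoot <= -1) || any(genotypes$resp_shoot >= 1) ||
      any(genotypes$resp_tuber <= -1) || any(genotypes$resp_tuber >= 1)) {
    stop("responsiveness must lie in (-1, 1)", call. = FALSE)
  }
  if (any(genotypes$dm_nf <= 0) || any(genotypes$dm_nf >= 100) ||
      any(genotypes$dm_f <= 0) || any(genotypes$dm_f >= 100)) {
    stop("dry matter content must lie in (0, 100)", call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), genotypes = genotypes,
         n_blocks = as.integer(n_blocks), n_plants = as.integer(n_plants),
         cv_main = cv_main, cv_sub = cv_sub, cv_plant = cv_plant,
         cv_conc = cv_conc, cv_dm = cv_dm,
         leaf_fraction = leaf_fraction,
         shoot_dm_fraction = shoot_dm_fraction),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  seed %d; %d blocks x 2 treatments x %d genotypes x %d plants\n",
              x$seed, x$n_blocks, nrow(x$genotypes), x$n_plants))
  cat(sprintf("  CVs: main plot %.2f, subplot %.2f, plant %.2f, conc %.2f, DM %.2f\n",
              x$cv_main, x$cv_sub, x$cv_plant, x$cv_conc, x$cv_dm))
  invisible(x)
}

#' Read or write a simulation configuration YAML file
#'
#' @param path Path to a YAML file with the scalar fields of
#'   [sim_config()] plus a `genotypes` list of per-genotype parameters.
#' @return [read_sim_config()] returns a `sim_config`;
#'   [write_sim_config()] returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("sim config must carry a seed", call. = FALSE)
  gen <- dplyr::bind_rows(lapply(y$genotypes, tibble::as_tibble))
  args <- y[setdiff(names(y), "genotypes")]
  do.call(sim_config, c(args, list(genotypes = gen)))
}

#' @rdname read_sim_config
#' @param config A [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  y <- unclass(config)
  y$shoot_dm_fraction <- as.list(y$shoot_dm_fraction)
  y$genotypes <- lapply(seq_len(nrow(config$genotypes)), function(i) {
    as.list(config$genotypes[i, ])
  })
  # full double precision so a reread config simulates identically
  yaml::write_yaml(y, path, precision = 17)
  invisible(path)
}

# lognormal multiplier with mean 1 and the given CV
ln_mult <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

# One draw of the trial under the current RNG state.
sim_once <- function(config) {
  g <- config$genotypes
  B <- config$n_blocks
  P <- config$n_plants
  trs <- treatment_levels()

  plants <- tidyr::expand_grid(
    block = seq_len(B), treatment = trs, genotype = g$genotype,
    plant = seq_len(P)
  )
  gi <- match(plants$genotype, g$genotype)
  is_f <- plants$treatment == "+F"

  shoot_mean <- ifelse(is_f, g$base_shoot[gi],
                       g$base_shoot[gi] * (1 - g$resp_shoot[gi]))
  tuber_mean <- ifelse(is_f, g$base_tuber[gi],
                       g$base_tuber[gi] * (1 - g$resp_tuber[gi]))
  dm_mean <- ifelse(is_f, g$dm_f[gi], g$dm_nf[gi])

  mp <- tidyr::expand_grid(block = seq_len(B), treatment = trs)
  mp$e <- ln_mult(nrow(mp), config$cv_main)
  sp <- tidyr::expand_grid(block = seq_len(B), treatment = trs,
                           genotype = g$genotype)
  sp$e <- ln_mult(nrow(sp), config$cv_sub)
  e_mp <- mp$e[match(paste(plants$block, plants$treatment),
                     paste(mp$block, mp$treatment))]
  e_sp <- sp$e[match(paste(plants$block, plants$treatment, plants$genotype),
                     paste(sp$block, sp$treatment, sp$genotype))]

  n <- nrow(plants)
  shoot <- shoot_mean * e_mp * e_sp * ln_mult(n, config$cv_plant)
  tuber <- tuber_mean * e_mp * e_sp * ln_mult(n, config$cv_plant)
  dm <- pmin(dm_mean * ln_mult(n, config$cv_dm), 99.9)

  lf <- config$leaf_fraction
  leaf_dry <- lf * shoot
  stem_dry <- (1 - lf) * shoot
  tuber_fresh <- tuber / (dm / 100)

  conc <- function(organ, nut) {
    means <- if (organ == "leaf") {
      g[[paste0("leaf_", nut)]][gi]
    } else {
      ifelse(is_f, g[[paste0("tuber_", nut, "_f")]][gi],
             g[[paste0("tuber_", nut, "_nf")]][gi])
    }
    means * ln_mult(n, config$cv_conc)
  }

  base <- tibble::tibble(
    genotype = plants$genotype,
    block = as.integer(plants$block),
    treatment = plants$treatment,
    plant_id = sprintf("p%d", plants$plant)
  )
  organ_row <- function(organ, fresh, dry, cN, cP, cK) {
    dplyr::mutate(base, organ = organ, fresh_weight_g = fresh,
                  dry_weight_g = dry, conc_N_mg_g = cN, conc_P_mg_g = cP,
                  conc_K_mg_g = cK)
  }
  out <- dplyr::bind_rows(
    organ_row("leaf", leaf_dry / config$shoot_dm_fraction[["leaf"]], leaf_dry,
              conc("leaf", "N"), conc("leaf", "P"), conc("leaf", "K")),
    organ_row("stem", stem_dry / config$shoot_dm_fraction[["stem"]], stem_dry,
              NA_real_, NA_real_, NA_real_),
    organ_row("tuber", tuber_fresh, tuber,
              conc("tuber", "N"), conc("tuber", "P"), conc("tuber", "K"))
  ) |>
    dplyr::arrange(.data$block, .data$treatment, .data$genotype,
                   .data$plant_id, match(.data$organ, organ_levels()))
  out[trial_columns]
}

#' Simulate a split-plot fertility trial
#'
#' Generates plant-level records with the statistical structure the
#' analysis assumes: genotype x treatment expected values from the
#' configured parameters (+F mean = base, non-F mean =
#' base x (1 - responsiveness)), multiplicative lognormal noise shared
#' at the main-plot and subplot levels and independent at the plant
#' level, fresh weights backed out of dry matter fractions, and tissue
#' concentrations drawn around the configured organ means. Output
#' always satisfies the trial data-model invariants. With all CVs at
#' zero the cell means equal the configured targets exactly.
#'
#' @param config A [sim_config()].
#' @param seed Seed for the draw; defaults to `config$seed`. Pass `NULL`
#'   to consume the current RNG state (used for replicate experiments).
#' @return A validated tibble of plant records (one row per
#'   plant x organ).
#' @export
simulate_trial <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) sim_once(config)
  else withr::with_seed(as.integer(seed), sim_once(config))
}
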