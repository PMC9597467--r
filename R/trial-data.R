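# Data model, validation and CSV/YAML I/O for plant-level trial records.
#
# A trial is a long tibble with one row per plant x organ and the exact
# columns in `trial_columns`: genotype, block, treatment (non-F | +F),
# plant_id, organ (leaf | stem | tuber), fresh_weight_g, dry_weight_g,
# conc_N_mg_g, conc_P_mg_g, conc_K_mg_g. Concentrations are in mg per g
# dry matter; in the trial design only leaf and tuber tissue is assayed,
# so stem concentrations are normally missing.

#' Trial configuration
#'
#' Fertilizer rates and planting density of a two-level fertility trial.
#' The defaults are the rates of the 2018 Ibadan white Guinea yam trial:
#' 90, 50 and 75 kg ha^-1 of N, P and K on the fertilized main plots and
#' 20,000 plants ha^-1.
#'
#' @param rate_N,rate_P,rate_K Fertilizer rates in kg ha^-1 (>= 0).
#' @param plant_density Planting density in plants ha^-1 (> 0).
#' @param n_blocks Number of complete blocks (replications, >= 2).
#' @return An object of class `trial_config`.
#' @seealso [per_plant_supply()], [read_trial_config()]
#' @export
#' @examples
#' cfg <- trial_config()
#' per_plant_supply(cfg, "N") # 4.5 g/plant
trial_config <- function(rate_N = 90, rate_P = 50, rate_K = 75,
                         plant_density = 20000, n_blocks = 4) {
  rates <- c(rate_N, rate_P, rate_K)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("fertilizer rates must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(plant_density) || plant_density <= 0) {
    stop("plant_density must be finite and > 0", call. = FALSE)
  }
  if (!is.finite(n_blocks) || n_blocks < 2) {
    stop("n_blocks must be >= 2", call. = FALSE)
  }
  structure(
    list(rate_N = rate_N, rate_P = rate_P, rate_K = rate_K,
         plant_density = plant_density, n_blocks = as.integer(n_blocks)),
    class = "trial_config"
  )
}

#' @export
print.trial_config <- function(x, ...) {
  cat("<trial_config>\n")
  cat(sprintf("  rates (kg/ha): N %g, P %g, K %g\n", x$rate_N, x$rate_P, x$rate_K))
  cat(sprintf("  plant density: %g plants/ha\n", x$plant_density))
  cat(sprintf("  blocks: %d\n", x$n_blocks))
  invisible(x)
}

#' Read or write a trial configuration YAML file
#'
#' The file carries the keys `rate_N_kg_ha`, `rate_P_kg_ha`,
#' `rate_K_kg_ha`, `plant_density_ha` and `n_blocks`.
#'
#' @param path Path to a YAML file.
#' @return [read_trial_config()] returns a [trial_config()];
#'   [write_trial_config()] returns `path` invisibly.
#' @export
read_trial_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  required <- c("rate_N_kg_ha", "rate_P_kg_ha", "rate_K_kg_ha",
                "plant_density_ha", "n_blocks")
  missing <- setdiff(required, names(y))
  if (length(missing)) {
    stop("config file ", path, " is missing key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  trial_config(rate_N = y$rate_N_kg_ha, rate_P = y$rate_P_kg_ha,
               rate_K = y$rate_K_kg_ha, plant_density = y$plant_density_ha,
               n_blocks = y$n_blocks)
}

#' @rdname read_trial_config
#' @param config A [trial_config()].
#' @export
write_trial_config <- function(config, path) {
  stopifnot(inherits(config, "trial_config"))
  yaml::write_yaml(
    list(rate_N_kg_ha = config$rate_N, rate_P_kg_ha = config$rate_P,
         rate_K_kg_ha = config$rate_K, plant_density_ha = config$plant_density,
         n_blocks = config$n_blocks),
    path
  )
  invisible(path)
}

#' Per-plant nutrient supply
#'
#' Converts a fertilizer rate in kg ha^-1 into the supply per plant in
#' g plant^-1, the `F` term of the apparent recovery efficiency:
#' `rate * 1000 / plant_density`. At the default rates and density this
#' gives 4.5, 2.5 and 3.75 g plant^-1 of N, P and K.
#'
#' @param config A [trial_config()].
#' @param nutrient One of `"N"`, `"P"`, `"K"`.
#' @return Supply in grams per plant.
#' @export
per_plant_supply <- function(config, nutrient = c("N", "P", "K")) {
  stopifnot(inherits(config, "trial_config"))
  nutrient <- match.arg(nutrient)
  if (config$plant_density <= 0) {
    stop("plant_density must be > 0", call. = FALSE)
  }
  config[[paste0("rate_", nutrient)]] * 1000 / config$plant_density
}

#' Validate plant-level trial records
#'
#' Checks the documented schema and the data-model invariants: factor
#' levels, non-negative weights, `dry_weight_g <= fresh_weight_g`,
#' concentrations finite, non-negative and < 1000 mg g^-1, a fresh
#' weight on every tuber row, and uniqueness of
#' (genotype, block, treatment, plant_id, organ). Every offending data
#' row is reported by number (row 1 = first row after the header).
#'
#' @param data A data frame of plant-level records.
#' @return `data` (as a tibble), invisibly, if valid; otherwise an error
#'   listing all violations.
#' @export
validate_trial <- function(data) {
  missing_cols <- setdiff(trial_columns, names(data))
  if (length(missing_cols)) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  problems <- character()
  note <- function(rows, msg) {
    if (length(rows)) c(problems, paste0("row ", rows, ": ", msg)) else problems
  }

  problems <- note(which(!data$treatment %in% treatment_levels()),
                   "treatment must be 'non-F' or '+F'")
  problems <- note(which(!data$organ %in% organ_levels()),
                   "organ must be one of leaf, stem, tuber")
  blk <- suppressWarnings(as.numeric(data$block))
  problems <- note(which(!is.finite(blk) | blk < 1 | blk != round(blk)),
                   "block must be a positive integer")
  fw <- data$fresh_weight_g
  dw <- data$dry_weight_g
  problems <- note(which(!is.na(fw) & (!is.finite(fw) | fw < 0)),
                   "fresh_weight_g must be finite and >= 0")
  problems <- note(which(!is.na(dw) & (!is.finite(dw) | dw < 0)),
                   "dry_weight_g must be finite and >= 0")
  problems <- note(which(!is.na(fw) & !is.na(dw) & dw > fw),
                   "dry_weight_g exceeds fresh_weight_g")
  problems <- note(which(data$organ == "tuber" & is.na(fw)),
                   "tuber rows require fresh_weight_g")
  for (nut in nutrient_levels()) {
    cc <- data[[paste0("conc_", nut, "_mg_g")]]
    problems <- note(which(!is.na(cc) & (!is.finite(cc) | cc < 0 | cc >= 1000)),
                     paste0("conc_", nut, "_mg_g must be finite, >= 0 and < 1000"))
  }
  key <- data[c("genotype", "block", "treatment", "plant_id", "organ")]
  problems <- note(which(duplicated(key)),
                   "duplicate (genotype, block, treatment, plant_id, organ)")

  if (length(problems)) {
    problems <- problems[order(as.integer(sub("^row (\\d+):.*$", "\\1", problems)))]
    stop("validation error:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(data)
}

#' Read plant-level trial records from CSV
#'
#' Reads the long-format plant x organ CSV (see [validate_trial()] for
#' the schema) and validates every row. Row counts are preserved;
#' malformed rows abort the read with their row numbers.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble of plant records.
#' @seealso [write_trial()], [simulate_trial()]
#' @export
read_trial <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  data <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            genotype = readr::col_character(),
                            block = readr::col_integer(),
                            treatment = readr::col_character(),
                            plant_id = readr::col_character(),
                            organ = readr::col_character(),
                            .default = readr::col_double()
                          ))
  attr(data, "spec") <- NULL
  attr(data, "problems") <- NULL
  if (nrow(data) == 0) stop("no data rows in ", path, call. = FALSE)
  validate_trial(data)
  tibble::as_tibble(data)
}

#' Write plant-level trial records to CSV
#'
#' Lossless inverse of [read_trial()]: the written file re-reads to an
#' identical record collection. Records are validated before writing;
#' an empty collection is an error.
#'
#' @param data A tibble of plant records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(data, path) {
  if (!is.data.frame(data) || nrow(data) == 0) {
    stop("cannot write an empty record collection", call. = FALSE)
  }
  validate_trial(data)
  readr::write_csv(data[trial_columns], path)
  invisible(path)
}
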