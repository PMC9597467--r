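# Per-plant N/P/K uptake from organ dry weights and tissue concentrations.

#' Per-plant nutrient uptake
#'
#' Total uptake of each nutrient per plant, in g plant^-1: the sum over
#' plant parts of organ dry weight (g) times tissue concentration
#' (mg g^-1 dry matter), divided by 1000.
#'
#' The trial design assays only leaf and tuber tissue, so stem rows
#' normally carry no concentrations. Under the default
#' `policy = "zero"` an organ with a missing concentration contributes
#' zero to that nutrient; under `policy = "strict"` any organ with dry
#' mass but a missing concentration is an error.
#'
#' @param records Validated plant records (see [read_trial()]).
#' @param policy Absent-organ policy, `"zero"` or `"strict"`.
#' @return One row per plant: genotype, block, treatment, plant_id,
#'   uptake_N_g, uptake_P_g, uptake_K_g.
#' @export
#' @examples
#' # leaf 60 g dry at 20 mg/g N plus tuber 200 g dry at 7 mg/g N
#' # gives 60*20/1000 + 200*7/1000 = 2.6 g N per plant
plant_uptake <- function(records, policy = c("zero", "strict")) {
  policy <- match.arg(policy)
  records <- validate_trial(records)
  conc_cols <- paste0("conc_", nutrient_levels(), "_mg_g")
  if (policy == "strict") {
    has_mass <- !is.na(records$dry_weight_g) & records$dry_weight_g > 0
    missing_conc <- rowSums(is.na(records[conc_cols])) > 0
    bad <- which(has_mass & missing_conc)
    if (length(bad)) {
      stop("strict policy: organ with dry mass but missing concentration(s) ",
           "on row(s) ", paste(utils::head(bad, 5), collapse = ", "),
           call. = FALSE)
    }
  }
  records |>
    dplyr::group_by(.data$genotype, .data$block, .data$treatment, .data$plant_id) |>
    dplyr::summarize(
      uptake_N_g = sum(.data$dry_weight_g * .data$conc_N_mg_g / 1000, na.rm = TRUE),
      uptake_P_g = sum(.data$dry_weight_g * .data$conc_P_mg_g / 1000, na.rm = TRUE),
      uptake_K_g = sum(.data$dry_weight_g * .data$conc_K_mg_g / 1000, na.rm = TRUE),
      .groups = "drop"
    )
}

#' Ratio of mean uptakes between two nutrients
#'
#' For each genotype x treatment cell, the ratio of the mean uptake of
#' one nutrient to another (e.g. N:P). In the reference trial the non-F
#' N:P ratios across genotypes span 7.0 to 9.7.
#'
#' @param cell_summary Output of [summarize_trial()] containing
#'   `uptake_<nutrient>_g` traits.
#' @param num,den Nutrients (`"N"`, `"P"` or `"K"`) for numerator and
#'   denominator.
#' @return A tibble: genotype, treatment, ratio.
#' @export
uptake_ratio <- function(cell_summary, num, den) {
  num <- match.arg(num, nutrient_levels())
  den <- match.arg(den, nutrient_levels())
  pick <- function(nut, name) {
    cell_summary |>
      dplyr::filter(.data$trait == paste0("uptake_", nut, "_g")) |>
      dplyr::select("genotype", "treatment", !!name := "mean")
  }
  joined <- dplyr::inner_join(pick(num, "num_mean"), pick(den, "den_mean"),
                              by = c("genotype", "treatment"))
  if (nrow(joined) == 0) {
    stop("cell_summary carries no uptake traits for ", num, " and ", den,
         call. = FALSE)
  }
  if (any(joined$den_mean <= 0)) {
    stop("undefined ratio: denominator uptake is zero or negative", call. = FALSE)
  }
  joined |>
    dplyr::mutate(ratio = .data$num_mean / .data$den_mean) |>
    dplyr::select("genotype", "treatment", "ratio")
}
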