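# Derived biomass traits and genotype x treatment aggregation.

#' Tuber dry matter content
#'
#' Percent dry matter of the tuber: the dry weight of a tuber sample
#' relative to its fresh weight, times 100.
#'
#' @param sample_fresh Fresh weight of the tuber sample, g (> 0).
#' @param sample_dry Dry weight of the same sample, g (0 <= dry <= fresh).
#' @return Dry matter content in percent (0-100). Vectorized.
#' @export
#' @examples
#' tuber_dm_percent(100, 31.2) # 31.2
tuber_dm_percent <- function(sample_fresh, sample_dry) {
  if (any(!is.finite(sample_fresh)) || any(sample_fresh <= 0)) {
    stop("sample_fresh must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(sample_dry)) || any(sample_dry < 0) ||
      any(sample_dry > sample_fresh)) {
    stop("sample_dry must lie in [0, sample_fresh]", call. = FALSE)
  }
  100 * sample_dry / sample_fresh
}

#' Total dry tuber weight
#'
#' Total fresh tuber weight scaled by the tuber dry matter content.
#'
#' @param total_fresh Total fresh tuber weight, g (>= 0).
#' @param dm_percent Tuber dry matter content, percent in [0, 100].
#' @return Total dry tuber weight in g. Vectorized.
#' @export
total_dry_tuber_weight <- function(total_fresh, dm_percent) {
  if (any(!is.finite(total_fresh)) || any(total_fresh < 0)) {
    stop("total_fresh must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(dm_percent)) || any(dm_percent < 0) || any(dm_percent > 100)) {
    stop("dm_percent must lie in [0, 100]", call. = FALSE)
  }
  total_fresh * dm_percent / 100
}

#' Dry shoot weight
#'
#' Sum of leaf and stem dry weights, g plant^-1.
#'
#' @param leaf_dry,stem_dry Dry weights in g (>= 0).
#' @return Dry shoot weight in g. Vectorized.
#' @export
dry_shoot_weight <- function(leaf_dry, stem_dry) {
  if (any(!is.finite(leaf_dry)) || any(leaf_dry < 0) ||
      any(!is.finite(stem_dry)) || any(stem_dry < 0)) {
    stop("leaf_dry and stem_dry must be finite and >= 0", call. = FALSE)
  }
  leaf_dry + stem_dry
}

#' Per-plant derived biomass traits
#'
#' Collapses the long plant x organ records to one row per plant with
#' the derived traits: `dry_shoot_g` (leaf + stem dry weight),
#' `tuber_dm_pct` (100 x tuber dry/fresh), `dry_tuber_g`, and
#' `fresh_tuber_g`. A missing leaf or stem row contributes zero to the
#' shoot; a missing tuber row is an error because every plant in the
#' yield analysis must carry one.
#'
#' @param records Validated plant records (see [read_trial()]).
#' @return One row per plant: genotype, block, treatment, plant_id and
#'   the derived trait columns.
#' @export
derive_traits <- function(records) {
  records <- validate_trial(records)
  keys <- c("genotype", "block", "treatment", "plant_id")
  wide <- records |>
    dplyr::select(dplyr::all_of(c(keys, "organ", "fresh_weight_g", "dry_weight_g"))) |>
    tidyr::pivot_wider(names_from = "organ",
                       values_from = c("fresh_weight_g", "dry_weight_g"))
  for (col in c("fresh_weight_g_leaf", "fresh_weight_g_stem", "fresh_weight_g_tuber",
                "dry_weight_g_leaf", "dry_weight_g_stem", "dry_weight_g_tuber")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  no_tuber <- is.na(wide$dry_weight_g_tuber) | is.na(wide$fresh_weight_g_tuber)
  if (any(no_tuber)) {
    who <- wide[no_tuber, keys]
    stop("yield analysis requires a tuber measurement for every plant; missing for: ",
         paste(utils::head(do.call(paste, c(who, sep = "/")), 5), collapse = ", "),
         call. = FALSE)
  }
  wide |>
    dplyr::mutate(
      dry_shoot_g = dry_shoot_weight(
        dplyr::coalesce(.data$dry_weight_g_leaf, 0),
        dplyr::coalesce(.data$dry_weight_g_stem, 0)
      ),
      tuber_dm_pct = tuber_dm_percent(.data$fresh_weight_g_tuber,
                                      .data$dry_weight_g_tuber),
      dry_tuber_g = .data$dry_weight_g_tuber,
      fresh_tuber_g = .data$fresh_weight_g_tuber
    ) |>
    dplyr::select(dplyr::all_of(keys), "dry_shoot_g", "tuber_dm_pct",
                  "dry_tuber_g", "fresh_tuber_g")
}

#' Genotype x treatment trait summaries
#'
#' Means, standard deviations and counts of per-plant traits for every
#' genotype x treatment cell, pooling plants across blocks (the trial
#' samples 3 plants x 4 blocks = 12 plants per cell). Block structure is
#' retained only by the statistics module.
#'
#' @param plant_traits Per-plant trait table, e.g. from [derive_traits()],
#'   optionally joined with [plant_uptake()].
#' @param traits Character vector of trait columns to summarize; default
#'   all non-key numeric columns.
#' @return A long tibble: genotype, treatment, trait, n, mean, sd.
#' @export
summarize_trial <- function(plant_traits, traits = NULL) {
  keys <- c("genotype", "block", "treatment", "plant_id")
  stopifnot(all(keys %in% names(plant_traits)))
  if (is.null(traits)) traits <- setdiff(names(plant_traits), keys)
  out <- plant_traits |>
    tidyr::pivot_longer(dplyr::all_of(traits), names_to = "trait",
                        values_to = "value") |>
    dplyr::group_by(.data$genotype, .data$treatment, .data$trait) |>
    dplyr::summarize(n = sum(!is.na(.data$value)),
                     mean = mean(.data$value, na.rm = TRUE),
                     sd = stats::sd(.data$value, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::mutate(sd = dplyr::if_else(.data$n == 1, 0, .data$sd))
  grid <- tidyr::expand_grid(genotype = unique(plant_traits$genotype),
                             treatment = unique(plant_traits$treatment),
                             trait = traits)
  empty <- dplyr::anti_join(grid, dplyr::filter(out, .data$n >= 1),
                            by = c("genotype", "treatment", "trait"))
  if (nrow(empty)) {
    stop("empty genotype x treatment cell(s): ",
         paste(utils::head(paste(empty$genotype, empty$treatment, empty$trait,
                                 sep = "/"), 5), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Grand means per treatment
#'
#' The trial-wide mean of a trait under each treatment. The default
#' convention is the unweighted mean of the genotype means (the mean-row
#' convention of genotype x treatment tables); `method = "plants"`
#' weights genotype means by their plant counts, which coincides with
#' the plant-level mean for balanced data.
#'
#' @param cell_summary Output of [summarize_trial()].
#' @param method `"genotype_means"` (default) or `"plants"`.
#' @return A tibble: treatment, trait, grand_mean.
#' @export
grand_means <- function(cell_summary, method = c("genotype_means", "plants")) {
  method <- match.arg(method)
  cell_summary |>
    dplyr::group_by(.data$treatment, .data$trait) |>
    dplyr::summarize(
      grand_mean = if (method == "genotype_means") mean(.data$mean)
                   else sum(.data$mean * .data$n) / sum(.data$n),
      .groups = "drop"
    )
}
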