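# End-to-end NUE analysis: records -> traits + uptakes -> cell means ->
# indices (PD, SFSI, ANR, PE) with susceptibility classes, per-genotype
# treatment contrasts, and block-level bootstrap uncertainty.

# Index computation on a long cell-mean table (genotype, treatment,
# trait, mean). Shared by the fitted analysis, the bootstrap, and the
# simulator's truth computation.
indices_from_cells <- function(cells, supply, traits, yield_trait,
                               eps = 1e-6,
                               grand_mean_method = "genotype_means") {
  if (!"n" %in% names(cells)) cells$n <- 1L
  gm <- grand_means(cells, grand_mean_method)
  wide <- cells |>
    dplyr::select("genotype", "treatment", "trait", "mean") |>
    tidyr::pivot_wider(names_from = "treatment", values_from = "mean")

  trait_rows <- purrr::map_dfr(traits, function(tr) {
    w <- dplyr::filter(wide, .data$trait == tr)
    g <- dplyr::filter(gm, .data$trait == tr)
    y_lf <- g$grand_mean[g$treatment == "non-F"]
    y_hf <- g$grand_mean[g$treatment == "+F"]
    s <- sfsi(w[["non-F"]], w[["+F"]], y_lf, y_hf)
    tibble::tibble(
      genotype = w$genotype, measure = tr,
      non_F_mean = w[["non-F"]], plus_F_mean = w[["+F"]],
      pd_pct = percent_difference(w[["non-F"]], w[["+F"]]),
      sfsi = s,
      anr_pct = NA_real_, pe_g_per_g = NA_real_,
      class = classify_susceptibility(s)
    )
  })

  yield <- dplyr::filter(wide, .data$trait == yield_trait)
  uptake_traits <- intersect(paste0("uptake_", nutrient_levels(), "_g"),
                             unique(wide$trait))
  nutrient_rows <- purrr::map_dfr(uptake_traits, function(tr) {
    nut <- sub("^uptake_([NPK])_g$", "\\1", tr)
    w <- dplyr::filter(wide, .data$trait == tr) |>
      dplyr::arrange(match(.data$genotype, yield$genotype))
    tibble::tibble(
      genotype = w$genotype, measure = tr,
      non_F_mean = w[["non-F"]], plus_F_mean = w[["+F"]],
      pd_pct = NA_real_, sfsi = NA_real_,
      anr_pct = apparent_recovery_efficiency(w[["+F"]], w[["non-F"]],
                                             supply[[nut]]),
      pe_g_per_g = physiological_efficiency(yield[["+F"]], yield[["non-F"]],
                                            w[["+F"]], w[["non-F"]], eps),
      class = NA_character_
    )
  })
  dplyr::bind_rows(trait_rows, nutrient_rows)
}

# Block-level bootstrap of SFSI / ANR / PE. `block_cells` is a long
# tibble (genotype, treatment, block, trait, mean of plants in that
# subplot); blocks are resampled with replacement and the index
# computation repeated on the resampled cell means.
boot_indices <- function(block_cells, supply, traits, yield_trait, eps,
                         n_boot, conf_level, grand_mean_method) {
  genos <- sort(unique(block_cells$genotype))
  blocks <- sort(unique(block_cells$block))
  trs <- treatment_levels()
  measures <- sort(unique(block_cells$trait))
  arr <- array(NA_real_,
               dim = c(length(measures), length(genos), 2, length(blocks)),
               dimnames = list(measures, genos, trs, blocks))
  arr[cbind(match(block_cells$trait, measures),
            match(block_cells$genotype, genos),
            match(block_cells$treatment, trs),
            match(block_cells$block, blocks))] <- block_cells$mean
  if (anyNA(arr)) stop("bootstrap requires a complete block structure", call. = FALSE)

  uptake_traits <- intersect(paste0("uptake_", nutrient_levels(), "_g"), measures)
  stat_names <- c(paste0("sfsi:", traits),
                  paste0("anr:", uptake_traits),
                  paste0("pe:", uptake_traits))
  one_rep <- function() {
    idx <- sample(seq_along(blocks), length(blocks), replace = TRUE)
    cm <- apply(arr[, , , idx, drop = FALSE], 1:3, mean)
    out <- matrix(NA_real_, nrow = length(genos), ncol = length(stat_names),
                  dimnames = list(genos, stat_names))
    for (tr in traits) {
      x_lf <- cm[tr, , "non-F"]; x_hf <- cm[tr, , "+F"]
      # balanced resamples: both grand-mean conventions coincide
      out[, paste0("sfsi:", tr)] <- (1 - x_lf / x_hf) / (1 - mean(x_lf) / mean(x_hf))
    }
    y_lf <- cm[yield_trait, , "non-F"]; y_hf <- cm[yield_trait, , "+F"]
    for (ut in uptake_traits) {
      nut <- sub("^uptake_([NPK])_g$", "\\1", ut)
      du <- cm[ut, , "+F"] - cm[ut, , "non-F"]
      out[, paste0("anr:", ut)] <- du / supply[[nut]] * 100
      out[, paste0("pe:", ut)] <- ifelse(abs(du) > eps, (y_hf - y_lf) / du, NA_real_)
    }
    out
  }
  reps <- array(NA_real_, dim = c(n_boot, length(genos), length(stat_names)),
                dimnames = list(NULL, genos, stat_names))
  for (b in seq_len(n_boot)) reps[b, , ] <- one_rep()
  probs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  purrr::map_dfr(stat_names, function(sn) {
    parts <- strsplit(sn, ":", fixed = TRUE)[[1]]
    vals <- reps[, , sn, drop = FALSE]
    tibble::tibble(
      genotype = genos,
      statistic = parts[1],
      measure = parts[2],
      se = apply(vals, 2, stats::sd, na.rm = TRUE),
      lower = apply(vals, 2, stats::quantile, probs = probs[1], na.rm = TRUE),
      upper = apply(vals, 2, stats::quantile, probs = probs[2], na.rm = TRUE)
    )
  })
}

#' Full nutrient-use-efficiency analysis of a trial
#'
#' Runs the whole pipeline on plant-level records: derives per-plant
#' biomass traits and N/P/K uptakes, aggregates to genotype x treatment
#' cell means, and computes per genotype the percent difference and
#' soil fertility susceptibility index for each biomass trait, the
#' apparent nutrient recovery efficiency and physiological efficiency
#' for each nutrient, and the susceptible/tolerant classification
#' (SFSI > 1 = susceptible). Per-genotype non-F vs +F t-tests are
#' attached as significance annotations, and index uncertainty is
#' estimated by a block-level bootstrap.
#'
#' @param records Plant-level records (see [read_trial()] or
#'   [simulate_trial()]).
#' @param config A [trial_config()] supplying fertilizer rates and plant
#'   density for the per-plant nutrient supply.
#' @param policy Absent-organ policy for uptake, see [plant_uptake()].
#' @param traits Biomass traits receiving PD/SFSI; defaults to dry shoot
#'   and dry tuber weight.
#' @param yield_trait Trait used as yield in the physiological
#'   efficiency; default `"dry_tuber_g"`.
#' @param eps Degenerate-denominator threshold for physiological
#'   efficiency, g.
#' @param alpha Significance level for the treatment contrasts.
#' @param n_boot Bootstrap resamples for index uncertainty (block-level,
#'   default 1000; 0 disables).
#' @param conf_level Bootstrap confidence level.
#' @param seed Optional integer seed for the bootstrap.
#' @param grand_mean_method Grand-mean convention, see [grand_means()].
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return An object of class `yam_nue`. Use [tidy()] for the
#'   per-genotype index table, [glance()] for trial-level summaries, and
#'   [autoplot()] for standard displays.
#' @export
nue_analysis <- function(records, config = trial_config(),
                         policy = c("zero", "strict"),
                         traits = c("dry_shoot_g", "dry_tuber_g"),
                         yield_trait = "dry_tuber_g",
                         eps = 1e-6, alpha = 0.05,
                         n_boot = 1000, conf_level = 0.95, seed = NULL,
                         grand_mean_method = c("genotype_means", "plants"),
                         var_equal = FALSE) {
  policy <- match.arg(policy)
  grand_mean_method <- match.arg(grand_mean_method)
  stopifnot(inherits(config, "trial_config"))
  if (!yield_trait %in% traits) {
    stop("yield_trait must be one of `traits`", call. = FALSE)
  }

  plant_traits <- derive_traits(records) |>
    dplyr::inner_join(plant_uptake(records, policy = policy),
                      by = c("genotype", "block", "treatment", "plant_id"))
  uptake_cols <- paste0("uptake_", nutrient_levels(), "_g")
  measures <- c(traits, "tuber_dm_pct", uptake_cols)
  cells <- summarize_trial(plant_traits, traits = measures)
  supply <- setNames(
    vapply(nutrient_levels(), function(n) per_plant_supply(config, n), 0),
    nutrient_levels()
  )

  report <- indices_from_cells(cells, supply, traits, yield_trait, eps,
                               grand_mean_method)
  contrasts <- purrr::map_dfr(
    c(traits, uptake_cols),
    function(tr) treatment_contrast(plant_traits, tr, alpha = alpha,
                                    var_equal = var_equal)
  )
  report <- report |>
    dplyr::left_join(
      dplyr::select(contrasts, "genotype", measure = "trait",
                    contrast_p = "p_value",
                    contrast_significant = "significant"),
      by = c("genotype", "measure")
    )

  boot <- NULL
  if (n_boot > 0) {
    block_cells <- plant_traits |>
      tidyr::pivot_longer(dplyr::all_of(setdiff(measures, "tuber_dm_pct")),
                          names_to = "trait", values_to = "value") |>
      dplyr::group_by(.data$genotype, .data$treatment, .data$block, .data$trait) |>
      dplyr::summarize(mean = mean(.data$value), .groups = "drop")
    run_boot <- function() {
      boot_indices(block_cells, supply, traits, yield_trait, eps,
                   n_boot, conf_level, grand_mean_method)
    }
    boot <- if (is.null(seed)) run_boot()
            else withr::with_seed(as.integer(seed), run_boot())
  }

  fii <- grand_means(cells, grand_mean_method) |>
    dplyr::filter(.data$trait %in% traits) |>
    tidyr::pivot_wider(names_from = "treatment", values_from = "grand_mean") |>
    dplyr::mutate(fii = fertility_intensity_index(.data[["non-F"]],
                                                  .data[["+F"]])) |>
    dplyr::select("trait", y_lf = "non-F", y_hf = "+F", "fii")

  structure(
    list(report = report, cells = cells, fii = fii, boot = boot,
         plant_traits = plant_traits, contrasts = contrasts,
         config = config, traits = traits, yield_trait = yield_trait,
         supply = supply, alpha = alpha, eps = eps, n_boot = n_boot,
         conf_level = conf_level, policy = policy,
         grand_mean_method = grand_mean_method),
    class = "yam_nue"
  )
}

#' @export
print.yam_nue <- function(x, ...) {
  cat("Nutrient-use-efficiency analysis\n")
  cat(sprintf("  %d genotypes, %d plants, %d blocks\n",
              length(unique(x$report$genotype)),
              nrow(x$plant_traits),
              length(unique(x$plant_traits$block))))
  cat(sprintf("  fertility intensity index: %s\n",
              paste(sprintf("%s %.3f", x$fii$trait, x$fii$fii), collapse = ", ")))
  cat("\nBiomass susceptibility (PD %, SFSI):\n")
  tr <- x$report |>
    dplyr::filter(.data$measure %in% x$traits) |>
    dplyr::mutate(non_F_mean = round(.data$non_F_mean, 1),
                  plus_F_mean = round(.data$plus_F_mean, 1),
                  pd_pct = round(.data$pd_pct, 1),
                  sfsi = round(.data$sfsi, 2)) |>
    dplyr::select("genotype", "measure", "non_F_mean", "plus_F_mean",
                  "pd_pct", "sfsi", "class")
  print(as.data.frame(tr), row.names = FALSE)
  cat("\nNutrient recovery and physiological efficiency:\n")
  nu <- x$report |>
    dplyr::filter(!.data$measure %in% x$traits) |>
    dplyr::mutate(non_F_mean = round(.data$non_F_mean, 2),
                  plus_F_mean = round(.data$plus_F_mean, 2),
                  anr_pct = round(.data$anr_pct, 1),
                  pe_g_per_g = round(.data$pe_g_per_g, 1)) |>
    dplyr::select("genotype", "measure", "non_F_mean", "plus_F_mean",
                  "anr_pct", "pe_g_per_g")
  print(as.data.frame(nu), row.names = FALSE)
  invisible(x)
}

#' Tidy a fitted NUE analysis
#'
#' @param x A `yam_nue` object.
#' @param ... Unused.
#' @return The per-genotype index table: genotype, measure, non-F and
#'   +F means, pd_pct, sfsi, anr_pct, pe_g_per_g, class, contrast p and
#'   significance, plus bootstrap `sfsi_se`, `anr_se`, `pe_se` columns
#'   when a bootstrap was run.
#' @export
tidy.yam_nue <- function(x, ...) {
  out <- x$report
  if (!is.null(x$boot)) {
    se <- x$boot |>
      dplyr::select("genotype", "statistic", "measure", "se") |>
      tidyr::pivot_wider(names_from = "statistic", values_from = "se",
                         names_glue = "{statistic}_se")
    out <- dplyr::left_join(out, se, by = c("genotype", "measure"))
  }
  out
}

#' @rdname tidy.yam_nue
#' @return [glance()] returns a one-row tibble with trial dimensions,
#'   the per-trait fertility intensity indices, and analysis settings.
#' @export
glance.yam_nue <- function(x, ...) {
  fii <- setNames(as.list(x$fii$fii), paste0("fii_", x$fii$trait))
  tibble::as_tibble(c(
    list(n_genotypes = length(unique(x$report$genotype)),
         n_plants = nrow(x$plant_traits),
         n_blocks = length(unique(x$plant_traits$block))),
    fii,
    list(alpha = x$alpha, n_boot = x$n_boot, policy = x$policy)
  ))
}
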