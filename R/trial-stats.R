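# Classical statistics for the split-plot trial: per-genotype treatment
# contrasts, Tukey HSD with compact letter display, Pearson correlation,
# and the split-plot ANOVA with its two error strata.

#' Per-genotype treatment contrast
#'
#' Two-sample t-test of non-F vs +F plant values for each genotype
#' (Welch by default; set `var_equal = TRUE` for the pooled-variance
#' test). Two-sided p-values.
#'
#' @param plant_traits Per-plant trait table (see [derive_traits()]).
#' @param trait Trait column to test.
#' @param alpha Significance level.
#' @param var_equal Assume equal variances.
#' @return A tibble with one row per genotype: genotype, trait, the two
#'   arm means, t_statistic, df, p_value, significant.
#' @export
treatment_contrast <- function(plant_traits, trait, alpha = 0.05,
                               var_equal = FALSE) {
  stopifnot(trait %in% names(plant_traits))
  plant_traits |>
    dplyr::group_by(.data$genotype) |>
    dplyr::group_modify(function(d, key) {
      x <- d[[trait]][d$treatment == "non-F"]
      y <- d[[trait]][d$treatment == "+F"]
      if (length(x) < 2 || length(y) < 2) {
        stop("treatment contrast for genotype ", key$genotype,
             " needs >= 2 plants per arm", call. = FALSE)
      }
      if (stats::sd(x) == 0 && stats::sd(y) == 0) {
        # degenerate spread: identical arms carry no evidence against the
        # null; distinct constant arms are perfectly separated
        sep <- mean(x) != mean(y)
        return(tibble::tibble(trait = trait, mean_non_F = mean(x),
                              mean_plus_F = mean(y),
                              t_statistic = if (sep) Inf else 0,
                              df = length(x) + length(y) - 2,
                              p_value = if (sep) 0 else 1))
      }
      tt <- stats::t.test(x, y, var.equal = var_equal)
      tibble::tibble(trait = trait, mean_non_F = mean(x), mean_plus_F = mean(y),
                     t_statistic = unname(tt$statistic),
                     df = unname(tt$parameter), p_value = tt$p.value)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant = .data$p_value < alpha)
}

#' Compact letter display from a p-value matrix
#'
#' Insert-and-absorb letter assignment: groups sharing no letter differ
#' significantly (pairwise p < alpha); groups sharing a letter do not.
#' Letters are swept in order of descending mean, ties broken by group
#' label, so output is deterministic.
#'
#' @param p_matrix Symmetric matrix of pairwise p-values with group
#'   names as dimnames.
#' @param means Named vector of group means (same groups).
#' @param alpha Significance level.
#' @return A named character vector of letter strings, in descending
#'   mean order.
#' @export
compact_letters <- function(p_matrix, means, alpha = 0.05) {
  groups <- names(means)[order(-means, names(means))]
  # columns are letter classes: character vectors of member groups
  cols <- list(groups)
  pairs <- which(upper.tri(p_matrix) & p_matrix < alpha, arr.ind = TRUE)
  pair_names <- apply(pairs, 1, function(ij) {
    c(rownames(p_matrix)[ij[1]], colnames(p_matrix)[ij[2]])
  })
  if (length(pair_names)) {
    for (k in seq_len(ncol(pair_names))) {
      a <- pair_names[1, k]; b <- pair_names[2, k]
      new_cols <- list()
      for (col in cols) {
        if (a %in% col && b %in% col) {
          new_cols <- c(new_cols, list(setdiff(col, a)), list(setdiff(col, b)))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      # absorb columns that are subsets of another
      keep <- rep(TRUE, length(new_cols))
      for (i in seq_along(new_cols)) {
        for (j in seq_along(new_cols)) {
          if (i != j && keep[i] && keep[j] &&
              all(new_cols[[i]] %in% new_cols[[j]]) &&
              !(length(new_cols[[i]]) == length(new_cols[[j]]) && i < j)) {
            keep[i] <- FALSE
          }
        }
      }
      cols <- new_cols[keep]
    }
  }
  # order letter classes by their highest-mean member
  first_pos <- vapply(cols, function(col) min(match(col, groups)), 0)
  cols <- cols[order(first_pos)]
  letters_out <- vapply(groups, function(g) {
    paste0(letters[which(vapply(cols, function(col) g %in% col, TRUE))],
           collapse = "")
  }, "")
  letters_out
}

#' Tukey HSD letters for genotype comparisons within a treatment
#'
#' One-way ANOVA on plant values of one treatment, pairwise Tukey
#' studentized-range tests across genotypes, and a compact letter
#' display ([compact_letters()]).
#'
#' @param plant_traits Per-plant trait table.
#' @param trait Trait column to compare.
#' @param treatment Treatment level to subset (`"non-F"` or `"+F"`).
#' @param alpha Significance level.
#' @return A tibble (genotype, n, mean, letters) in descending mean
#'   order, with the pairwise p-value matrix in attribute `p_matrix`.
#' @export
tukey_letters <- function(plant_traits, trait, treatment, alpha = 0.05) {
  stopifnot(trait %in% names(plant_traits))
  treatment <- match.arg(treatment, treatment_levels())
  d <- plant_traits[plant_traits$treatment == treatment,
                    c("genotype", trait)]
  names(d) <- c("genotype", "value")
  counts <- table(d$genotype)
  if (length(counts) < 2) stop(">= 2 genotypes required", call. = FALSE)
  if (any(counts < 2)) {
    stop("genotype(s) with < 2 plants: ",
         paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)
  }
  d$genotype <- factor(d$genotype)
  fit <- stats::aov(value ~ genotype, data = d)
  tk <- stats::TukeyHSD(fit)$genotype
  genos <- levels(d$genotype)
  p_matrix <- matrix(1, length(genos), length(genos),
                     dimnames = list(genos, genos))
  for (nm in rownames(tk)) {
    gg <- strsplit(nm, "-", fixed = TRUE)[[1]]
    p_matrix[gg[1], gg[2]] <- p_matrix[gg[2], gg[1]] <- tk[nm, "p adj"]
  }
  means <- tapply(d$value, d$genotype, mean)
  lets <- compact_letters(p_matrix, means, alpha)
  out <- tibble::tibble(
    genotype = names(lets),
    n = as.integer(counts[names(lets)]),
    mean = as.numeric(means[names(lets)]),
    letters = unname(lets)
  )
  attr(out, "p_matrix") <- p_matrix
  attr(out, "treatment") <- treatment
  out
}

#' Pearson correlation with t-based p-value
#'
#' Product-moment correlation of two equal-length vectors (n >= 3) with
#' the two-sided p-value from the t transform.
#'
#' @param x,y Numeric vectors (typically genotype means).
#' @return A one-row tibble: r, t_statistic, df, p_value, n.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate),
                 t_statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = ct$p.value,
                 n = length(x))
}

#' Split-plot ANOVA
#'
#' Classical split-plot analysis with fertilizer treatment on main plots
#' and genotype on subplots: plants are first averaged to subplot means,
#' then `aov(value ~ treatment * genotype + Error(block/treatment))`
#' tests the treatment against the main-plot error (block x treatment)
#' and genotype and the interaction against the subplot error.
#'
#' @param plant_traits Per-plant trait table with a complete
#'   block x treatment x genotype structure (no missing cells).
#' @param trait Trait column to analyse.
#' @return A tibble with one row per term: stratum, term, df, sum_sq,
#'   mean_sq, statistic (F), p_value.
#' @export
split_plot_anova <- function(plant_traits, trait) {
  stopifnot(trait %in% names(plant_traits))
  sub <- plant_traits |>
    dplyr::group_by(.data$block, .data$treatment, .data$genotype) |>
    dplyr::summarize(value = mean(.data[[trait]]), .groups = "drop")
  n_b <- length(unique(sub$block))
  n_t <- length(unique(sub$treatment))
  n_g <- length(unique(sub$genotype))
  if (nrow(sub) != n_b * n_t * n_g || anyNA(sub$value)) {
    stop("missing cells: split-plot ANOVA requires a complete ",
         "block x treatment x genotype structure", call. = FALSE)
  }
  sub$block <- factor(sub$block)
  sub$treatment <- factor(sub$treatment, levels = treatment_levels())
  sub$genotype <- factor(sub$genotype)
  fit <- stats::aov(value ~ treatment * genotype + Error(block / treatment),
                    data = sub)
  s <- summary(fit)
  rows <- purrr::map_dfr(names(s), function(stratum) {
    tab <- s[[stratum]][[1]]
    tibble::tibble(
      stratum = sub("^Error: ", "", stratum),
      term = trimws(rownames(tab)),
      df = tab[["Df"]],
      sum_sq = tab[["Sum Sq"]],
      mean_sq = tab[["Mean Sq"]],
      statistic = if ("F value" %in% colnames(tab)) tab[["F value"]] else NA_real_,
      p_value = if ("Pr(>F)" %in% colnames(tab)) tab[["Pr(>F)"]] else NA_real_
    )
  })
  rows$trait <- trait
  rows
}
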