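# Nutrient-use-efficiency indices: percent difference, fertility
# intensity index, SFSI, apparent recovery efficiency, physiological
# efficiency, and susceptibility classification. All functions are pure
# and vectorized; they operate on genotype x treatment means.

#' Percent difference between fertility levels
#'
#' Relative reduction of a genotype's trait mean under the unfertilized
#' condition: `((x_hf - x_lf) / x_hf) * 100`, where `x_lf` and `x_hf`
#' are the genotype means under non-F and +F. Negative when the genotype
#' does better without fertilizer.
#'
#' @param x_lf,x_hf Genotype trait means under non-F and +F; `x_hf > 0`.
#' @return Percent difference. Vectorized.
#' @export
#' @examples
#' percent_difference(76.9, 130.5) # 41.1 at 1 d.p.
percent_difference <- function(x_lf, x_hf) {
  if (any(!is.finite(x_hf)) || any(x_hf <= 0)) {
    stop("undefined index: x_hf must be finite and > 0", call. = FALSE)
  }
  (x_hf - x_lf) / x_hf * 100
}

#' Soil fertility intensity index
#'
#' Trial-wide stress severity: `1 - y_lf / y_hf`, computed from the
#' grand means of all genotypes under non-F and +F. Zero means the
#' unfertilized condition imposed no stress.
#'
#' @param y_lf,y_hf Grand trait means under non-F and +F; `y_hf > 0`.
#' @return Dimensionless index in (-Inf, 1]. Vectorized.
#' @export
fertility_intensity_index <- function(y_lf, y_hf) {
  if (any(!is.finite(y_hf)) || any(y_hf <= 0)) {
    stop("undefined index: y_hf must be finite and > 0", call. = FALSE)
  }
  1 - y_lf / y_hf
}

#' Soil fertility susceptibility index (SFSI)
#'
#' A genotype's relative trait reduction normalized by the trial-wide
#' fertility intensity index:
#' `(1 - x_lf/x_hf) / (1 - y_lf/y_hf)`.
#' Values above 1 mark genotypes more susceptible to low soil fertility
#' than the trial average, values below 1 more tolerant. Satisfies
#' `sfsi * fertility_intensity_index == percent_difference / 100`
#' exactly.
#'
#' @param x_lf,x_hf Genotype trait means under non-F and +F.
#' @param y_lf,y_hf Grand trait means under non-F and +F.
#' @return Dimensionless index. Vectorized.
#' @export
#' @examples
#' sfsi(76.9, 130.5, 56.9, 83.0) # 1.31 at 2 d.p.
sfsi <- function(x_lf, x_hf, y_lf, y_hf) {
  if (any(!is.finite(x_hf)) || any(x_hf <= 0)) {
    stop("undefined index: x_hf must be finite and > 0", call. = FALSE)
  }
  fii <- fertility_intensity_index(y_lf, y_hf)
  if (any(fii == 0)) {
    stop("undefined index: fertility intensity index is zero (no stress differential)",
         call. = FALSE)
  }
  (1 - x_lf / x_hf) / fii
}

#' Apparent nutrient recovery efficiency
#'
#' Efficiency of capturing the applied nutrient:
#' `(ut_f - ut_n) / f_supply * 100`, in percent, where `ut_f` and
#' `ut_n` are total per-plant uptakes (g plant^-1) under +F and non-F
#' and `f_supply` is the nutrient supplied per plant (g plant^-1, see
#' [per_plant_supply()]). May be negative.
#'
#' @param ut_f,ut_n Mean uptakes under +F and non-F, g plant^-1.
#' @param f_supply Nutrient supply, g plant^-1 (> 0).
#' @return Recovery efficiency in percent. Vectorized.
#' @export
apparent_recovery_efficiency <- function(ut_f, ut_n, f_supply) {
  if (any(!is.finite(f_supply)) || any(f_supply <= 0)) {
    stop("undefined index: f_supply must be finite and > 0", call. = FALSE)
  }
  (ut_f - ut_n) / f_supply * 100
}

#' Physiological efficiency
#'
#' Dry tuber yield gained per unit of extra nutrient absorbed:
#' `(tw_f - tw_n) / (ut_f - ut_n)`, in g dry tuber per g nutrient.
#' When the uptake difference is within `eps` of zero the ratio is
#' undefined and returned as `NA` (a flagged missing value, never a
#' silent zero or an error).
#'
#' @param tw_f,tw_n Mean dry tuber weights under +F and non-F, g.
#' @param ut_f,ut_n Mean uptakes under +F and non-F, g plant^-1.
#' @param eps Degenerate-denominator threshold in g; default 1e-6.
#' @return Efficiency in g g^-1, or `NA` where undefined. Vectorized.
#' @export
physiological_efficiency <- function(tw_f, tw_n, ut_f, ut_n, eps = 1e-6) {
  du <- ut_f - ut_n
  out <- ifelse(abs(du) > eps, (tw_f - tw_n) / du, NA_real_)
  as.numeric(out)
}

#' Classify genotype susceptibility from SFSI
#'
#' `"susceptible"` when SFSI > 1, `"tolerant"` otherwise (SFSI exactly 1
#' is classified tolerant; the susceptibility criterion is strictly
#' greater than 1). Any per-genotype significance flag from the
#' treatment contrast is carried alongside as an annotation by
#' [nue_analysis()], never as part of the criterion.
#'
#' @param sfsi Numeric SFSI values.
#' @return Character vector, `"susceptible"` or `"tolerant"` (`NA` for
#'   undefined SFSI).
#' @export
classify_susceptibility <- function(sfsi) {
  ifelse(is.na(sfsi), NA_character_,
         ifelse(sfsi > 1, "susceptible", "tolerant"))
}
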