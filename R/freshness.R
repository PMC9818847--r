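# Egg freshness and morphology indicators. All functions are vectorized and
# deterministic; units are stated per argument.

#' Haugh unit
#'
#' The standard logarithmic freshness index combining thick-albumen height
#' and egg weight: `HU = 100 * log10(H - 1.7 * W^0.37 + 7.57)` (base-10
#' logarithm). Higher values mean fresher eggs.
#'
#' @param H Thick-albumen height in mm (mean of four site measurements).
#' @param W Egg weight in g.
#' @return Haugh units (HU).
#' @examples
#' haugh_unit(H = 6.5, W = 58)
#' @export
haugh_unit <- function(H, W) {
  stopifnot(all(H > 0), all(W > 0))
  arg <- H - 1.7 * W^0.37 + 7.57
  if (any(arg <= 0)) {
    i <- which(arg <= 0)[1]
    abort(sprintf("non-positive log argument for H = %g mm, W = %g g",
                  H[pmin(i, length(H))], W[pmin(i, length(W))]),
          class = "iplslasso_domain_error")
  }
  100 * log10(arg)
}

#' Albumen height reproducing a target Haugh unit
#'
#' Inverts the Haugh-unit formula: the height that, together with weight
#' `W`, gives exactly `hu`.
#'
#' @param hu Target Haugh unit.
#' @param W Egg weight in g.
#' @return Albumen height in mm.
#' @export
albumen_height_for_hu <- function(hu, W) {
  stopifnot(all(W > 0))
  10^(hu / 100) + 1.7 * W^0.37 - 7.57
}

#' Weight loss rate
#'
#' Percent weight lost relative to the arrival weight. A current weight
#' above the arrival weight yields a negative rate with a warning (flagged
#' measurement anomaly), not an error.
#'
#' @param arrival_g Arrival weight in g (> 0).
#' @param current_g Current weight in g.
#' @return Weight loss in percent.
#' @export
weight_loss_rate <- function(arrival_g, current_g) {
  if (any(arrival_g <= 0)) {
    abort("arrival weight must be positive", class = "iplslasso_domain_error")
  }
  wlr <- 100 * (arrival_g - current_g) / arrival_g
  if (any(wlr < 0)) {
    warn(sprintf("%d sample(s) gained weight: negative weight loss rate",
                 sum(wlr < 0)))
  }
  wlr
}

#' Yolk coefficient
#'
#' Yolk center height divided by yolk diameter; declines as eggs age.
#'
#' @param height_mm Yolk center height in mm (> 0).
#' @param diameter_mm Yolk diameter in mm (> 0).
#' @return Dimensionless ratio.
#' @export
yolk_coefficient <- function(height_mm, diameter_mm) {
  if (any(height_mm <= 0) || any(diameter_mm <= 0)) {
    abort("yolk measurements must be positive", class = "iplslasso_domain_error")
  }
  height_mm / diameter_mm
}

#' Egg shape index
#'
#' Long axis divided by short axis.
#'
#' @param long_mm Long axis in mm.
#' @param short_mm Short axis in mm, `0 < short_mm <= long_mm`.
#' @return Dimensionless ratio >= 1.
#' @export
shape_index <- function(long_mm, short_mm) {
  if (any(short_mm <= 0)) {
    abort("short axis must be positive", class = "iplslasso_domain_error")
  }
  if (any(long_mm < short_mm)) {
    abort("long axis must not be shorter than the short axis",
          class = "iplslasso_domain_error")
  }
  long_mm / short_mm
}

#' Indicator table for an egg cohort
#'
#' @param cohort A cohort tibble as produced by [generate_cohort()] (or any
#'   data frame with the same measurement columns).
#' @return A tibble with per-egg `hu`, `wlr_pct`, `yolk_coef` and
#'   `shape_idx` columns appended.
#' @export
freshness_indicators <- function(cohort) {
  cohort <- as_tibble(cohort)
  dplyr::mutate(
    cohort,
    hu = haugh_unit(.data$albumen_height_mm, .data$weight_g),
    wlr_pct = weight_loss_rate(.data$arrival_weight_g, .data$weight_g),
    yolk_coef = yolk_coefficient(.data$yolk_height_mm, .data$yolk_diameter_mm),
    shape_idx = shape_index(.data$long_axis_mm, .data$short_axis_mm)
  )
}
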