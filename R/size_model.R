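#' Quasi-equilibrium concentrations for the selectivity calculation
#'
#' The selectivity model assumes the reductant and hydroxide concentrations
#' stay close to their values at quasi-equilibrium. By default those are the
#' recipe's initial concentrations; [selectivity_inputs_from_trace()] instead
#' samples them from a simulated trace at a chosen time.
#'
#' @param c_cit_reactive_0 CtH2- concentration (mol/L).
#' @param c_ta_0 TA concentration (mol/L).
#' @param c_oh_0 OH- concentration (mol/L).
#' @return A list of class `selectivity_inputs`.
#' @export
selectivity_inputs <- function(c_cit_reactive_0, c_ta_0, c_oh_0) {
  vals <- c(c_cit_reactive_0, c_ta_0, c_oh_0)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("quasi-equilibrium concentrations must be finite and >= 0",
         call. = FALSE)
  }
  structure(list(c_cit_reactive_0 = c_cit_reactive_0, c_ta_0 = c_ta_0,
                 c_oh_0 = c_oh_0),
            class = "selectivity_inputs")
}

#' Sample quasi-equilibrium concentrations from a kinetic trace
#'
#' @param trace A `kinetic_trace` from [simulate_reduction()].
#' @param at Time (s) at which to read concentrations (nearest grid point).
#' @return A [selectivity_inputs()] object.
#' @export
selectivity_inputs_from_trace <- function(trace, at = trace$t_s[1]) {
  stopifnot(inherits(trace, "kinetic_trace"))
  i <- which.min(abs(trace$t_s - at))
  selectivity_inputs(
    c_cit_reactive_0 = trace$c_cit_reactive_M[i],
    c_ta_0 = trace$c_ta_M[i],
    c_oh_0 = attr(trace, "c_oh") %||% 10^(7.7 - 14)
  )
}

#' Reduction-to-passivation selectivity
#'
#' The fate of the dosed precursor is decided by the competition between
#' reduction (TA route plus citrate route) and hydroxide passivation. With
#' precursor order 1 in every channel the precursor concentration cancels
#' and the selectivity at quasi-equilibrium is
#'
#' \deqn{\sigma = \frac{k_{ta}\,c_{TA,0}^{\,l} + k_{cit}\,c_{CtH_2^-,0}}
#'                     {k_{pass}\,c_{OH^-,0}}}
#'
#' @param inputs A [selectivity_inputs()] object.
#' @param params A [rate_parameters()] object.
#' @return Dimensionless selectivity (>= 0).
#' @export
#' @examples
#' selectivity(selectivity_inputs(1.3e-7, 1e-4, 5e-7), rate_parameters())
selectivity <- function(inputs, params) {
  stopifnot(inherits(inputs, "selectivity_inputs"),
            inherits(params, "rate_parameters"))
  numerator <- params$k_ta * inputs$c_ta_0^params$l +
    params$k_cit * inputs$c_cit_reactive_0
  denominator <- params$k_pass * inputs$c_oh_0
  if (denominator < 1e-300) {
    stop(paste0(
      "passivation rate is zero (k_pass * c_oh_0 < 1e-300): ",
      "selectivity is infinite and undefined as a ratio"), call. = FALSE)
  }
  numerator / denominator
}

#' Predict the final core diameter after a growth dose
#'
#' All gold that is reduced rather than passivated partitions equally over
#' the existing particles (no secondary nucleation), so particle volume grows
#' by the reduced-gold-to-seed-gold mole ratio and the diameter follows the
#' cube-root mass law:
#'
#' \deqn{d_{final} = d_{seed}\,\Big(1 + \frac{\sigma}{1+\sigma}\,R\Big)^{1/3}}
#'
#' where \eqn{R} is the ratio of dosed gold to the gold already in the seeds
#' and \eqn{\sigma/(1+\sigma)} the reduced fraction. `sigma = Inf` (no
#' passivation) gives full incorporation.
#'
#' @param d_seed Seed core diameter (nm, > 0).
#' @param sigma Selectivity (>= 0, may be `Inf`).
#' @param gold_ratio Moles of gold dosed per mole of gold in the seeds
#'   (>= 0).
#' @return A one-row tibble of class `size_prediction` with columns
#'   `d_seed`, `sigma`, `gold_ratio`, `reduced_fraction`, `d_final` (nm).
#' @export
#' @examples
#' predict_final_diameter(3, sigma = 480, gold_ratio = 1.4)
predict_final_diameter <- function(d_seed, sigma, gold_ratio) {
  if (length(d_seed) != 1L || !is.finite(d_seed) || d_seed <= 0) {
    stop("d_seed must be a single positive diameter (nm)", call. = FALSE)
  }
  if (length(sigma) != 1L || is.na(sigma) || sigma < 0) {
    stop("sigma must be a single value >= 0", call. = FALSE)
  }
  if (length(gold_ratio) != 1L || !is.finite(gold_ratio) || gold_ratio < 0) {
    stop("gold_ratio must be a single value >= 0", call. = FALSE)
  }
  f_red <- if (is.infinite(sigma)) 1 else sigma / (1 + sigma)
  d_final <- d_seed * (1 + f_red * gold_ratio)^(1 / 3)
  tibble::new_tibble(
    list(d_seed = d_seed, sigma = sigma, gold_ratio = gold_ratio,
         reduced_fraction = f_red, d_final = d_final),
    nrow = 1L, class = "size_prediction"
  )
}

#' Hydrodynamic diameter estimate from a core diameter
#'
#' For small citrate-capped particles the hydrodynamic (DLS) diameter runs
#' about 1 nm above the bare (TEM) core diameter; this reporting helper adds
#' that offset.
#'
#' @param d_core TEM-equivalent core diameter(s), nm.
#' @param offset_nm Offset to add (default 1 nm).
#' @return Hydrodynamic diameter estimate(s), nm.
#' @export
hydrodynamic_diameter <- function(d_core, offset_nm = 1) {
  if (any(!is.finite(d_core)) || any(d_core <= 0)) {
    stop("d_core must be positive", call. = FALSE)
  }
  d_core + offset_nm
}
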