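#' Default citric acid dissociation constants
#'
#' Literature pKa values for the three carboxylic acid protons of citric acid
#' at 25 degrees C. The synthesis protocol modelled here never prints its
#' working speciation constants, so these are exposed as an overridable
#' default rather than hard-wired.
#'
#' @return Numeric vector of length 3, strictly increasing (pKa1, pKa2, pKa3).
#' @export
#' @examples
#' citrate_pka()
citrate_pka <- function() {
  c(pKa1 = 3.13, pKa2 = 4.76, pKa3 = 6.40)
}

#' Fixed stoichiometric constants of the TA-citrate reduction mechanism
#'
#' Tannic acid (TA) carries ten phenolic groups, each donating two electrons
#' on oxidation to the quinone, so one TA molecule supplies twenty electrons.
#' Reducing one Au(III) ion to Au(0) consumes three electrons, giving the
#' 3/20 TA:Au mole ratio used throughout the kinetic model.
#'
#' @param electrons_per_phenol Electrons donated per phenolic group (default 2).
#' @param phenols_per_ta Number of phenolic groups per TA molecule (default 10).
#' @param electrons_per_au Electrons required to reduce Au(III) to Au(0)
#'   (default 3).
#' @return A list of class `stoichiometry_constants` with the three counts and
#'   the derived `ta_per_au` ratio.
#' @export
#' @examples
#' stoichiometry_constants()$ta_per_au  # 0.15
stoichiometry_constants <- function(electrons_per_phenol = 2L,
                                    phenols_per_ta = 10L,
                                    electrons_per_au = 3L) {
  for (v in c(electrons_per_phenol, phenols_per_ta, electrons_per_au)) {
    if (length(v) != 1L || !is.finite(v) || v < 0 || v != round(v)) {
      stop("stoichiometric counts must be single non-negative integers",
           call. = FALSE)
    }
  }
  capacity <- ta_electron_capacity(phenols_per_ta,
                                   electrons_per_phenol = electrons_per_phenol)
  if (capacity == 0) {
    stop("TA electron capacity is zero; ta_per_au is undefined", call. = FALSE)
  }
  structure(
    list(
      electrons_per_phenol = as.integer(electrons_per_phenol),
      phenols_per_ta = as.integer(phenols_per_ta),
      electrons_per_au = as.integer(electrons_per_au),
      ta_per_au = electrons_per_au / capacity
    ),
    class = "stoichiometry_constants"
  )
}

#' @export
print.stoichiometry_constants <- function(x, ...) {
  cat("TA-Au stoichiometry: ",
      x$electrons_per_phenol, " e-/phenol x ", x$phenols_per_ta,
      " phenols = ", x$electrons_per_phenol * x$phenols_per_ta,
      " e-/TA; ", x$electrons_per_au, " e-/Au; TA:Au = ",
      format(x$ta_per_au), "\n", sep = "")
  invisible(x)
}

#' Electron donation capacity of a tannic acid molecule
#'
#' @param n_phenolic_groups Number of phenolic groups (non-negative integer).
#' @param electrons_per_phenol Electrons per group (default 2).
#' @return Total electrons the molecule can donate.
#' @export
#' @examples
#' ta_electron_capacity(10)  # 20
ta_electron_capacity <- function(n_phenolic_groups, electrons_per_phenol = 2L) {
  if (length(n_phenolic_groups) != 1L || !is.finite(n_phenolic_groups) ||
      n_phenolic_groups < 0 || n_phenolic_groups != round(n_phenolic_groups)) {
    stop("n_phenolic_groups must be a single non-negative integer",
         call. = FALSE)
  }
  as.integer(electrons_per_phenol * n_phenolic_groups)
}

#' TA:Au stoichiometric mole ratio
#'
#' Moles of TA consumed per mole of Au(III) reduced through the TA route.
#'
#' @param constants A [stoichiometry_constants()] object.
#' @return Dimensionless ratio (3/20 = 0.15 for the default constants).
#' @export
#' @examples
#' ta_au_stoichiometric_ratio()  # 0.15
ta_au_stoichiometric_ratio <- function(constants = stoichiometry_constants()) {
  stopifnot(inherits(constants, "stoichiometry_constants"))
  capacity <- ta_electron_capacity(
    constants$phenols_per_ta,
    electrons_per_phenol = constants$electrons_per_phenol
  )
  if (capacity == 0) {
    stop("TA electron capacity is zero; ratio undefined", call. = FALSE)
  }
  constants$electrons_per_au / capacity
}

#' Triprotic speciation of citrate
#'
#' Closed-form Henderson-Hasselbalch distribution of total citrate over its
#' four protonation states CtH3, CtH2^-, CtH^2- and Ct^3- at a given pH.
#' The doubly-protonated anion CtH2^- is the species treated as the reactive
#' citrate reductant by the kinetic model.
#'
#' @param total_citrate Total citrate concentration (mol/L, >= 0).
#' @param pH Solution pH in \[0, 14\].
#' @param pKa Strictly increasing numeric triple of acid dissociation
#'   constants; default [citrate_pka()].
#' @return A tibble of class `citrate_speciation` with one row and columns
#'   `total_citrate`, `pH`, `c_CtH3`, `c_CtH2_minus`, `c_CtH_2minus`,
#'   `c_Ct_3minus` (all mol/L). The four species sum to `total_citrate`.
#' @export
#' @examples
#' speciate_citrate(2.2e-3, pH = 7.7)
speciate_citrate <- function(total_citrate, pH, pKa = citrate_pka()) {
  if (length(total_citrate) != 1L || !is.finite(total_citrate) ||
      total_citrate < 0) {
    stop("total_citrate must be a single non-negative number", call. = FALSE)
  }
  if (length(pH) != 1L || !is.finite(pH) || pH < 0 || pH > 14) {
    stop("pH must be a single value in [0, 14]", call. = FALSE)
  }
  if (length(pKa) != 3L || any(!is.finite(pKa)) || any(diff(pKa) <= 0)) {
    stop("pKa must be a strictly increasing numeric triple", call. = FALSE)
  }
  h <- 10^(-pH)
  ka <- unname(10^(-pKa))
  # unnormalized weights of CtH3, CtH2-, CtH2-, Ct3-
  w <- c(h^3, h^2 * ka[1], h * ka[1] * ka[2], ka[1] * ka[2] * ka[3])
  alpha <- w / sum(w)
  tibble::new_tibble(
    list(
      total_citrate = total_citrate,
      pH = pH,
      c_CtH3 = total_citrate * alpha[1],
      c_CtH2_minus = total_citrate * alpha[2],
      c_CtH_2minus = total_citrate * alpha[3],
      c_Ct_3minus = total_citrate * alpha[4]
    ),
    nrow = 1L,
    class = "citrate_speciation"
  )
}

#' Speciation profile over a pH grid
#'
#' Convenience wrapper evaluating [speciate_citrate()] over a vector of pH
#' values, in the long format used for CSV export and plotting.
#'
#' @param total_citrate Total citrate concentration (mol/L).
#' @param pH Numeric vector of pH values.
#' @param pKa pKa triple, see [speciate_citrate()].
#' @return Tibble with columns `pH`, `species`, `concentration`.
#' @export
speciation_profile <- function(total_citrate, pH, pKa = citrate_pka()) {
  rows <- lapply(pH, function(p) {
    s <- speciate_citrate(total_citrate, p, pKa)
    tibble::tibble(
      pH = p,
      species = c("CtH3", "CtH2-", "CtH2-2", "Ct3-"),
      concentration = c(s$c_CtH3, s$c_CtH2_minus, s$c_CtH_2minus,
                        s$c_Ct_3minus)
    )
  })
  do.call(rbind, rows)
}
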