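M_AU_G_MOL <- 196.97   # atomic mass of gold, g/mol
RHO_AU_G_CM3 <- 19.3   # density of bulk gold, g/cm^3
NM3_TO_CM3 <- 1e-21

#' Moles of gold per particle for a given core diameter
#'
#' Bulk-gold density relation: a sphere of diameter `d_core` holds
#' `rho * (pi/6) d^3 / M` moles of gold.
#'
#' @param d_core Core diameter (nm, > 0).
#' @return Moles of gold per particle.
#' @export
gold_per_particle <- function(d_core) {
  if (any(!is.finite(d_core)) || any(d_core <= 0)) {
    stop("d_core must be positive (nm)", call. = FALSE)
  }
  RHO_AU_G_CM3 * (pi / 6) * d_core^3 * NM3_TO_CM3 / M_AU_G_MOL
}

#' Core diameter holding a given amount of gold
#'
#' Inverse of [gold_per_particle()].
#'
#' @param g Moles of gold per particle (> 0).
#' @return Core diameter (nm).
#' @export
diameter_from_gold <- function(g) {
  if (any(!is.finite(g)) || any(g <= 0)) {
    stop("gold per particle must be positive", call. = FALSE)
  }
  (6 * g * M_AU_G_MOL / (pi * RHO_AU_G_CM3 * NM3_TO_CM3))^(1 / 3)
}

#' Particle number concentration from gold concentration and size
#'
#' \deqn{N = \frac{[Au^{3+}]\,m_{a,Au}}{\rho_{Au}\,(\pi/6)\,d^3}} with unit
#' bookkeeping to particles per mL (gold mass per mL divided by the mass of
#' one particle; `m_a,Au` = 196.97 g/mol, `rho_Au` = 19.3 g/cm^3).
#'
#' @param c_au Cumulative gold concentration (mol/L, >= 0).
#' @param d_core Core diameter (nm, > 0).
#' @return Particles per mL.
#' @export
#' @examples
#' particle_number_concentration(1.25e-4, 3)
particle_number_concentration <- function(c_au, d_core) {
  if (any(!is.finite(c_au)) || any(c_au < 0)) {
    stop("c_au must be >= 0", call. = FALSE)
  }
  (c_au / 1000) / gold_per_particle(d_core)  # mol per mL / mol per particle
}

#' Total nanoparticle surface area per unit volume
#'
#' `S = N * pi * d^2`, in nm^2 per mL.
#'
#' @param n_conc Particles per mL (>= 0).
#' @param d_core Core diameter (nm, >= 0).
#' @return Surface area (nm^2 per mL).
#' @export
total_surface_area <- function(n_conc, d_core) {
  if (any(!is.finite(n_conc)) || any(n_conc < 0) ||
      any(!is.finite(d_core)) || any(d_core < 0)) {
    stop("n_conc and d_core must be >= 0", call. = FALSE)
  }
  n_conc * pi * d_core^2
}

#' State of a colloid batch
#'
#' The particle number concentration is derived from the cumulative gold
#' concentration and the core diameter via the bulk-gold density relation,
#' so the gold-per-particle invariant holds by construction.
#'
#' @param volume_ml Batch volume (mL, >= 0).
#' @param c_au Cumulative gold concentration (mol/L, >= 0).
#' @param d_core TEM-equivalent core diameter (nm, > 0).
#' @return A list of class `colloid_state` with fields `volume_ml`, `c_au`,
#'   `d_core`, `n_conc` (particles/mL).
#' @export
#' @examples
#' colloid_state(25, 1.25e-4, 3)
colloid_state <- function(volume_ml, c_au, d_core) {
  if (length(volume_ml) != 1L || !is.finite(volume_ml) || volume_ml < 0) {
    stop("volume_ml must be a single value >= 0", call. = FALSE)
  }
  structure(
    list(volume_ml = volume_ml, c_au = c_au, d_core = d_core,
         n_conc = particle_number_concentration(c_au, d_core)),
    class = "colloid_state"
  )
}

#' @export
print.colloid_state <- function(x, ...) {
  cat(sprintf(
    "colloid: %.4g mL, [Au] %.4g M, d %.3g nm, %.4g particles/mL\n",
    x$volume_ml, x$c_au, x$d_core, x$n_conc))
  invisible(x)
}

#' One seeded-growth round
#'
#' @param index Round ordinal (1-based).
#' @param c_au_final_target Cumulative gold concentration after dosing
#'   (mol/L).
#' @param v_extract_ml Volume extracted before the round (mL, default 10).
#' @param v_replace_ml Citrate-solution volume replacing it (mL, default 10).
#' @param c_cit_replace Citrate concentration of the replacement (mol/L,
#'   default 2.2e-3).
#' @param label Optional sample label.
#' @return A list of class `synthesis_round`.
#' @export
synthesis_round <- function(index, c_au_final_target, v_extract_ml = 10,
                            v_replace_ml = 10, c_cit_replace = 2.2e-3,
                            label = NULL) {
  if (c_au_final_target < 0 || v_extract_ml < 0 || v_replace_ml < 0) {
    stop("round volumes and target must be >= 0", call. = FALSE)
  }
  structure(
    list(index = as.integer(index), c_au_final_target = c_au_final_target,
         v_extract_ml = v_extract_ml, v_replace_ml = v_replace_ml,
         c_cit_replace = c_cit_replace,
         label = label %||% paste0("round_", index)),
    class = "synthesis_round"
  )
}

#' Seeded-growth recipe
#'
#' A seed-formation condition plus an ordered list of growth rounds. The
#' default reproduces the published protocol: 25 mL seed solution with
#' 2.2 mM sodium citrate, 6 mM potassium carbonate, 0.1 mM TA and a final
#' Au(III) concentration of 125 uM (the 3 nm seed batch), then seven rounds
#' in which 10 mL is extracted and replaced with 10 mL of 2.2 mM citrate and
#' 20 mM chloroauric acid stock is dosed to cumulative targets
#' 0.15, 0.175, 0.2, 0.225, 0.25, 0.275, 0.3 mM.
#'
#' @param rounds List of [synthesis_round()] objects; default the published
#'   series.
#' @param seed_volume_ml,seed_c_au Seed batch volume (mL) and gold
#'   concentration (mol/L).
#' @param seed_c_nacit,seed_c_ta,seed_c_k2co3 Seed-formation reagent
#'   concentrations (mol/L).
#' @param c_stock Gold stock concentration used for dosing (mol/L).
#' @param labels Sample labels for the default rounds.
#' @return A list of class `recipe`.
#' @export
#' @examples
#' default_recipe()
default_recipe <- function(rounds = NULL,
                           seed_volume_ml = 25, seed_c_au = 1.25e-4,
                           seed_c_nacit = 2.2e-3, seed_c_ta = 1e-4,
                           seed_c_k2co3 = 6e-3, c_stock = 0.02,
                           labels = c("uGNP_5", "uGNP_6", "uGNP_7", "uGNP_8",
                                      "uGNP_10", "uGNP_12", "uGNP_15")) {
  if (is.null(rounds)) {
    targets <- c(1.5e-4, 1.75e-4, 2e-4, 2.25e-4, 2.5e-4, 2.75e-4, 3e-4)
    rounds <- lapply(seq_along(targets), function(i) {
      synthesis_round(i, targets[i], label = labels[i])
    })
  }
  targets <- vapply(rounds, function(r) r$c_au_final_target, numeric(1))
  if (length(targets) > 1L && any(diff(targets) <= 0)) {
    stop("round gold targets must be strictly increasing", call. = FALSE)
  }
  structure(
    list(seed = list(volume_ml = seed_volume_ml, c_au = seed_c_au,
                     c_nacit = seed_c_nacit, c_ta = seed_c_ta,
                     c_k2co3 = seed_c_k2co3),
         c_stock = c_stock, rounds = rounds),
    class = "recipe"
  )
}

#' @export
print.recipe <- function(x, ...) {
  cat(sprintf("seeded-growth recipe: seed %.4g mL at [Au] %.4g M, %d rounds\n",
              x$seed$volume_ml, x$seed$c_au, length(x$rounds)))
  for (r in x$rounds) {
    cat(sprintf("  %d %-8s extract %.3g mL, replace %.3g mL, target [Au] %.4g M\n",
                r$index, r$label, r$v_extract_ml, r$v_replace_ml,
                r$c_au_final_target))
  }
  invisible(x)
}

#' Forward-simulate a seeded-growth recipe
#'
#' Per round: extraction removes gold and particles proportionally (the
#' concentration is unchanged, total amounts scale by the retained volume
#' fraction); the replacement citrate volume dilutes both; gold stock is
#' dosed to the round's cumulative concentration target with the added stock
#' volume tracked exactly in the balance; all newly reduced gold partitions
#' equally over the existing particles (no secondary nucleation), so the
#' core diameter follows the cube-root mass law.
#'
#' @param recipe A [default_recipe()]-style `recipe`.
#' @param seed A [colloid_state()] for the seed batch (default: the recipe's
#'   seed block with a 3 nm core).
#' @param d_seed Seed core diameter used when `seed` is NULL (nm).
#' @param yield Fraction of dosed gold actually incorporated (default 1,
#'   i.e. 100% reduction yield; < 1 for sensitivity analysis).
#' @return A tibble with one row per state (seed first): `round`, `label`,
#'   `volume_ml`, `v_stock_added_ml`, `c_au_M`, `n_conc_per_ml`,
#'   `d_theoretical_nm`, `s_total_nm2_per_ml`.
#' @export
#' @examples
#' simulate_recipe(default_recipe())
simulate_recipe <- function(recipe, seed = NULL, d_seed = 3, yield = 1) {
  stopifnot(inherits(recipe, "recipe"))
  if (is.null(seed)) {
    seed <- colloid_state(recipe$seed$volume_ml, recipe$seed$c_au, d_seed)
  }
  stopifnot(inherits(seed, "colloid_state"))
  if (yield <= 0 || yield > 1) stop("yield must be in (0, 1]", call. = FALSE)

  n_states <- length(recipe$rounds) + 1L
  out <- vector("list", n_states)
  v <- seed$volume_ml
  c_au <- seed$c_au            # cumulative dosed gold, mol/L
  n_conc <- seed$n_conc
  g_pp <- gold_per_particle(seed$d_core)  # incorporated gold per particle
  dosed_pp <- g_pp             # cumulative dosed gold per particle
  out[[1]] <- list(round = 0L, label = "seed", volume_ml = v,
                   v_stock_added_ml = 0, c_au_M = c_au,
                   n_conc_per_ml = n_conc, d_theoretical_nm = seed$d_core)

  for (r in recipe$rounds) {
    if (r$v_extract_ml > v) {
      stop(sprintf("round %d (%s): extraction volume %.3g mL exceeds batch volume %.3g mL",
                   r$index, r$label, r$v_extract_ml, v), call. = FALSE)
    }
    v_ret <- v - r$v_extract_ml
    v2 <- v_ret + r$v_replace_ml
    dil <- v_ret / v2
    c_res <- c_au * dil
    n_res <- n_conc * dil
    if (r$c_au_final_target < c_res - 1e-15) {
      stop(sprintf("round %d (%s): target [Au] %.4g M is below the post-extraction residual %.4g M",
                   r$index, r$label, r$c_au_final_target, c_res),
           call. = FALSE)
    }
    if (r$c_au_final_target >= recipe$c_stock) {
      stop(sprintf("round %d (%s): target [Au] %.4g M not reachable with %.4g M stock",
                   r$index, r$label, r$c_au_final_target, recipe$c_stock),
           call. = FALSE)
    }
    v_add <- v2 * (r$c_au_final_target - c_res) /
      (recipe$c_stock - r$c_au_final_target)
    v3 <- v2 + v_add
    c_au <- r$c_au_final_target
    n_conc <- n_res * v2 / v3
    # per-particle amounts are unchanged by extraction/dilution; the new
    # dose per particle is cumulative dosed gold per particle minus what was
    # dosed before, incorporated at the reduction yield
    new_dose_pp <- c_au / (1000 * n_conc) - dosed_pp
    g_pp <- g_pp + yield * new_dose_pp
    dosed_pp <- dosed_pp + new_dose_pp
    v <- v3
    d <- diameter_from_gold(g_pp)
    out[[r$index + 1L]] <- list(
      round = r$index, label = r$label, volume_ml = v,
      v_stock_added_ml = v_add, c_au_M = c_au, n_conc_per_ml = n_conc,
      d_theoretical_nm = d)
  }
  df <- do.call(rbind, lapply(out, function(z) tibble::as_tibble(z)))
  df$s_total_nm2_per_ml <- total_surface_area(df$n_conc_per_ml,
                                              df$d_theoretical_nm)
  df
}

#' Equal-surface-area dilution factors
#'
#' Each sample is diluted so that all present the same total nanoparticle
#' surface area per unit volume; the reference (dilution factor 1.00) is the
#' sample with the smallest total surface area.
#'
#' @param samples A data frame with either a `s_total_nm2_per_ml` column or
#'   both `c_au_M` and `d_core_nm` columns (from which number concentration
#'   and surface area are computed), plus an optional `label` column.
#' @return The input tibble with `n_conc_per_ml`/`s_total_nm2_per_ml` filled
#'   in where derivable and a `df` column of dilution factors (>= 1, exactly
#'   one equal to 1).
#' @export
#' @examples
#' dilution_factors(tibble::tibble(
#'   label = c("uGNP_3", "uGNP_15"),
#'   c_au_M = c(1.25e-4, 3e-4), d_core_nm = c(3, 15)))
dilution_factors <- function(samples) {
  samples <- tibble::as_tibble(samples)
  if (nrow(samples) < 1L) stop("need at least one sample", call. = FALSE)
  if (!("s_total_nm2_per_ml" %in% names(samples))) {
    if (!all(c("c_au_M", "d_core_nm") %in% names(samples))) {
      stop("samples need either s_total_nm2_per_ml or c_au_M + d_core_nm",
           call. = FALSE)
    }
    samples$n_conc_per_ml <- particle_number_concentration(
      samples$c_au_M, samples$d_core_nm)
    samples$s_total_nm2_per_ml <- total_surface_area(
      samples$n_conc_per_ml, samples$d_core_nm)
  }
  s <- samples$s_total_nm2_per_ml
  if (any(!is.finite(s)) || any(s < 0)) {
    stop("surface areas must be finite and >= 0", call. = FALSE)
  }
  if (all(s == 0)) stop("all surface areas are zero", call. = FALSE)
  samples$df <- s / min(s[s > 0])
  samples
}

#' Design a dosing schedule for target diameters
#'
#' Inverse of [simulate_recipe()]: given a strictly increasing series of
#' target core diameters, computes the cumulative gold concentration target
#' of each round so the forward simulation reproduces the diameters.
#'
#' @param d_targets Strictly increasing target diameters (nm); the first
#'   must be >= the seed diameter.
#' @param seed A [colloid_state()] for the seed batch.
#' @param round_template A [synthesis_round()] providing extraction /
#'   replacement volumes and replacement citrate concentration.
#' @param c_stock Gold stock concentration (mol/L).
#' @return A `recipe` whose rounds carry the computed
#'   `c_au_final_target` values.
#' @export
#' @examples
#' plan_dosing(c(5, 8), colloid_state(25, 1.25e-4, 3))
plan_dosing <- function(d_targets, seed,
                        round_template = synthesis_round(1, 0),
                        c_stock = 0.02) {
  stopifnot(inherits(seed, "colloid_state"))
  if (length(d_targets) < 1L || any(diff(d_targets) <= 0)) {
    stop("d_targets must be strictly increasing", call. = FALSE)
  }
  if (d_targets[1] < seed$d_core) {
    stop("first target is below the seed diameter (gold cannot be removed)",
         call. = FALSE)
  }
  v <- seed$volume_ml
  c_au <- seed$c_au
  n_conc <- seed$n_conc
  g_pp <- gold_per_particle(seed$d_core)
  rounds <- vector("list", length(d_targets))
  for (i in seq_along(d_targets)) {
    g_t <- gold_per_particle(d_targets[i])
    if (round_template$v_extract_ml > v) {
      stop(sprintf("round %d: extraction volume exceeds batch volume", i),
           call. = FALSE)
    }
    v_ret <- v - round_template$v_extract_ml
    v2 <- v_ret + round_template$v_replace_ml
    dil <- v_ret / v2
    c_res <- c_au * dil
    n_res <- n_conc * dil
    # choose v_add so that total incorporated gold / particles = g_t:
    # (c_res*v2 + c_stock*v_add)/1000 = g_t * n_res * v2
    v_add <- (1000 * g_t * n_res * v2 - c_res * v2) / c_stock
    if (v_add < -1e-12) {
      stop(sprintf("round %d: target %.3g nm would require removing gold", i,
                   d_targets[i]), call. = FALSE)
    }
    v_add <- max(v_add, 0)
    v3 <- v2 + v_add
    c_target <- (c_res * v2 + c_stock * v_add) / v3
    rounds[[i]] <- synthesis_round(
      i, c_target,
      v_extract_ml = round_template$v_extract_ml,
      v_replace_ml = round_template$v_replace_ml,
      c_cit_replace = round_template$c_cit_replace,
      label = sprintf("target_%gnm", d_targets[i]))
    v <- v3
    c_au <- c_target
    n_conc <- n_res * v2 / v3
    g_pp <- g_t
  }
  default_recipe(rounds = rounds, seed_volume_ml = seed$volume_ml,
                 seed_c_au = seed$c_au, c_stock = c_stock)
}

#' Ligand surface density
#'
#' Ligands available per unit of nanoparticle surface area, e.g. to check a
#' PEG dose against the ~3.3 molecules/nm^2 needed for full surface
#' coverage of small gold particles.
#'
#' @param n_ligands Ligand count per mL (>= 0).
#' @param s_total Total particle surface area (nm^2 per mL, > 0).
#' @return Ligands per nm^2.
#' @export
ligand_surface_density <- function(n_ligands, s_total) {
  if (any(!is.finite(n_ligands)) || any(n_ligands < 0)) {
    stop("n_ligands must be >= 0", call. = FALSE)
  }
  if (any(!is.finite(s_total)) || any(s_total <= 0)) {
    stop("s_total must be > 0", call. = FALSE)
  }
  n_ligands / s_total
}

#' Published per-round gold concentration series
#'
#' The cumulative Au(III) concentration of each sample in the published
#' synthesis series, with the nominal core-size labels.
#'
#' @return Tibble with `label`, `d_nominal_nm`, `c_au_M`.
#' @export
published_round_targets <- function() {
  tibble::tibble(
    label = c("uGNP_3", "uGNP_5", "uGNP_6", "uGNP_7", "uGNP_8", "uGNP_10",
              "uGNP_12", "uGNP_15"),
    d_nominal_nm = c(3, 5, 6, 7, 8, 10, 12, 15),
    c_au_M = c(1.25e-4, 1.5e-4, 1.75e-4, 2e-4, 2.25e-4, 2.5e-4, 2.75e-4,
               3e-4)
  )
}
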