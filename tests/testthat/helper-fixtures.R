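# Shared fixtures: the seed-formation conditions and calibrated parameters.

seed_ph <- 7.7

seed_state <- function(c_ta = 1e-4, c_precursor = 1.25e-4,
                       c_nacit = 2.2e-3, pH = seed_ph) {
  sp <- speciate_citrate(c_nacit, pH)
  reaction_state(c_precursor = c_precursor, c_ta = c_ta,
                 c_cit_reactive = sp$c_CtH2_minus, c_oh = 10^(pH - 14))
}

# Independent spreadsheet-style bookkeeping of the published recipe,
# tracking total moles and particle counts per round rather than
# concentrations (the production code's state variables).
recipe_bookkeeping_oracle <- function(targets = c(1.5e-4, 1.75e-4, 2e-4,
                                                  2.25e-4, 2.5e-4, 2.75e-4,
                                                  3e-4),
                                      v0 = 25, c0 = 1.25e-4, d0 = 3,
                                      c_stock = 0.02, v_extract = 10,
                                      v_replace = 10) {
  m_au <- 196.97; rho <- 19.3
  vol_particle <- function(d) (pi / 6) * d^3 * 1e-21        # cm^3
  moles_particle <- function(d) rho * vol_particle(d) / m_au
  n_total <- c0 * v0 / 1000 / moles_particle(d0)            # particle count
  au_total <- c0 * v0 / 1000                                # mol in flask
  v <- v0
  d <- d0
  ds <- numeric(length(targets))
  for (i in seq_along(targets)) {
    keep <- (v - v_extract) / v
    n_total <- n_total * keep
    au_total <- au_total * keep
    v <- v - v_extract + v_replace
    # dose stock to reach cumulative target concentration
    v_add <- v * (targets[i] - au_total / (v / 1000)) /
      (c_stock - targets[i])
    au_total <- au_total + c_stock * v_add / 1000
    v <- v + v_add
    gpp <- au_total / n_total
    d <- (6 * gpp * m_au / (pi * rho * 1e-21))^(1 / 3)
    ds[i] <- d
  }
  ds
}
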