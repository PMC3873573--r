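# Frozen default parameter set for the cell-population simulator.
#
# Values were tuned once (scripts/tune_defaults.R) so that the simulated study
# conditions reproduce the qualitative bands of the platform it emulates:
# inclusion kinetics increasing with time, expression and polyQ length; an
# inclusion-bearing (i) death rate of 50-75% and a no-inclusion (ni) death
# rate of 15-30% at 46 h; an hsp40 arm with ~25% relative suppression of
# inclusion formation; an hsp70 arm with ~15 percentage-point protection of
# i-cells; and a poor-FlAsH-reactive ni subpopulation of ~0.5% of transfected
# cells for the 46Q construct. They are frozen here and are not arguments the
# rest of the package re-tunes.

.aggflux_defaults <- list(
  # expression law: log-normal Httex1 molecules/cell (arbitrary units)
  expression_meanlog = log(1000),
  expression_sdlog   = 1.0,
  # mKate2 co-expression: slope on initial Httex1 plus log-normal noise
  reporter_slope = 0.5,
  reporter_sdlog = 0.25,
  # inclusion nucleation: hazard = k_nuc * (E/E_ref)^h_exp * q_gain(Q) * mod
  k_nuc  = 0.0015,   # h^-1 at reference expression, Q = 46
  h_exp  = 2,        # expression cooperativity exponent
  exp_cap = 16,      # saturation of (E/E_ref)^h_exp at extreme expression
  gamma_q = 1.5,     # q_gain(Q) = max(0, (Q - 36)/10)^gamma_q
  # spontaneous oligomer enrichment of cells without inclusions
  k_olig = 3e-5,     # h^-1, scaled by q_gain(Q)
  # first-order conversion rates once a state change has nucleated
  k_conv      = 0.8, # h^-1, monomer+oligomer -> inclusion
  k_conv_olig = 0.5, # h^-1, monomer -> oligomer in oligomer-enriched cells
  # death hazards (h^-1)
  mu_ni = 0.005,
  mu_i  = 0.09,
  # conditional fates of dead cells (debris only for inclusion bearers)
  p_leach  = 0.25,
  p_debris = 0.35,
  # turnover and growth
  k_deg       = 0.002, # h^-1 Httex1 degradation
  growth_rate = 0.03   # h^-1 division hazard
)

#' Default chaperone arm modifiers
#'
#' Multiplicative modifiers applied to the simulator hazards for each
#' co-transfection arm. The reference arm (`"alone"`, Httex1 with a blank
#' plasmid) has all modifiers equal to 1. The hsp40 arm suppresses inclusion
#' nucleation (so that the all-cell inclusion fraction at 46 h drops by
#' roughly a quarter relative to the reference) and is mildly detrimental to
#' survival; the hsp70 arm does not alter nucleation but protects
#' inclusion-bearing cells from death (about 15 percentage points at 46 h);
#' the combined arm suppresses nucleation most strongly, removes the hsp70
#' survival benefit, raises death of cells lacking inclusions by 5-10 points,
#' accelerates Httex1 degradation, improves mKate2 folding yield and gives a
#' modest growth advantage.
#'
#' @return Named list with one entry per arm (`alone`, `hsp40`, `hsp70`,
#'   `hsp40+hsp70`), each a list of multiplicative modifiers:
#'   `mod_nuc`, `mod_death_i`, `mod_death_ni`, `mod_deg`, `mod_growth`,
#'   `mod_yield`.
#' @examples
#' default_arm_modifiers()$alone
#' @export
default_arm_modifiers <- function() {
  list(
    "alone" = list(mod_nuc = 1, mod_death_i = 1, mod_death_ni = 1,
                   mod_deg = 1, mod_growth = 1, mod_yield = 1),
    "hsp40" = list(mod_nuc = 0.55, mod_death_i = 1.05, mod_death_ni = 1.05,
                   mod_deg = 1.2, mod_growth = 1.05, mod_yield = 1.05),
    "hsp70" = list(mod_nuc = 1, mod_death_i = 0.55, mod_death_ni = 1,
                   mod_deg = 1.2, mod_growth = 1.05, mod_yield = 1.05),
    "hsp40+hsp70" = list(mod_nuc = 0.45, mod_death_i = 1, mod_death_ni = 2.2,
                         mod_deg = 4, mod_growth = 1.25, mod_yield = 1.2)
  )
}
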