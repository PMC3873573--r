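#' polyQ-length scaling of the inclusion-nucleation hazard
#'
#' Non-pathogenic polyQ lengths (Q <= 36) never nucleate inclusions; beyond
#' the pathogenic threshold the gain rises monotonically. The functional form
#' `max(0, (Q - 36)/10)^gamma` encodes only the ordering of aggregation
#' propensity with repeat length (46 < 72 < 97), normalised so the 46Q
#' construct has unit gain.
#'
#' @param Q Glutamine repeat length (integer, scalar or vector).
#' @param gamma Shape exponent (default 1.5).
#' @return Non-negative numeric vector, 0 for Q <= 36.
#' @export
q_gain <- function(Q, gamma = .aggflux_defaults$gamma_q) {
  pmax(0, (Q - 36) / 10)^gamma
}

#' Build a simulator configuration
#'
#' Collects every parameter of the stochastic cell-population model into a
#' validated configuration object. Defaults are the frozen values describing
#' the study conditions the package emulates; see the methods vignette for
#' their rationale.
#'
#' @param polyQ_length Glutamine repeat length of the Httex1 construct
#'   (typically one of 25, 46, 72, 97).
#' @param n_cells Number of cells transfected at time 0.
#' @param time_points Hours post-transfection at which snapshots are taken
#'   (must be multiples of `dt`).
#' @param dt Hazard-stepping interval in hours.
#' @param arm Chaperone co-transfection arm, one of
#'   `names(default_arm_modifiers())`.
#' @param chaperone_mods Named list of per-arm modifier lists (see
#'   [default_arm_modifiers()]).
#' @param expression_meanlog,expression_sdlog Log-normal law for initial
#'   Httex1 abundance (arbitrary molecules/cell).
#' @param reporter_slope,reporter_sdlog mKate2 co-expression slope on the
#'   initial Httex1 level and its log-normal noise.
#' @param k_nuc Baseline inclusion-nucleation hazard (h^-1) at reference
#'   expression for unit polyQ gain.
#' @param h_exp Expression cooperativity exponent of nucleation.
#' @param exp_cap Saturation of the expression term: the factor
#'   `(E/E_ref)^h_exp` is capped at this value, reflecting that nucleation
#'   probability cannot grow without bound at extreme supersaturation.
#' @param gamma_q Shape of the polyQ gain, see [q_gain()].
#' @param k_olig Hazard (h^-1, scaled by the polyQ gain) of a cell without an
#'   inclusion entering an oligomer-enriched state.
#' @param k_conv First-order conversion rate (h^-1) of monomer/oligomer into
#'   the inclusion after nucleation.
#' @param k_conv_olig First-order monomer-to-oligomer conversion rate (h^-1)
#'   in oligomer-enriched cells.
#' @param mu_ni,mu_i Death hazards (h^-1) for cells without/with inclusions.
#' @param p_leach,p_debris Conditional fates of a dying cell: probability of
#'   leaching cytosol, and (inclusion bearers only) of lysing to a free
#'   inclusion with debris; the remainder stays as an intact dead cell.
#' @param k_deg Httex1 degradation rate (h^-1).
#' @param growth_rate Division hazard (h^-1).
#' @param seed Integer seed for the single global generator.
#' @return A list of class `aggflux_config`.
#' @export
sim_config <- function(polyQ_length = 46,
                       n_cells = 5000,
                       time_points = c(18, 25, 30, 46),
                       dt = 0.5,
                       arm = "alone",
                       chaperone_mods = default_arm_modifiers(),
                       expression_meanlog = .aggflux_defaults$expression_meanlog,
                       expression_sdlog = .aggflux_defaults$expression_sdlog,
                       reporter_slope = .aggflux_defaults$reporter_slope,
                       reporter_sdlog = .aggflux_defaults$reporter_sdlog,
                       k_nuc = .aggflux_defaults$k_nuc,
                       h_exp = .aggflux_defaults$h_exp,
                       exp_cap = .aggflux_defaults$exp_cap,
                       gamma_q = .aggflux_defaults$gamma_q,
                       k_olig = .aggflux_defaults$k_olig,
                       k_conv = .aggflux_defaults$k_conv,
                       k_conv_olig = .aggflux_defaults$k_conv_olig,
                       mu_ni = .aggflux_defaults$mu_ni,
                       mu_i = .aggflux_defaults$mu_i,
                       p_leach = .aggflux_defaults$p_leach,
                       p_debris = .aggflux_defaults$p_debris,
                       k_deg = .aggflux_defaults$k_deg,
                       growth_rate = .aggflux_defaults$growth_rate,
                       seed = NULL) {
  cfg <- list(polyQ_length = polyQ_length, n_cells = n_cells,
              time_points = sort(time_points), dt = dt, arm = arm,
              chaperone_mods = chaperone_mods,
              expression_meanlog = expression_meanlog,
              expression_sdlog = expression_sdlog,
              reporter_slope = reporter_slope,
              reporter_sdlog = reporter_sdlog,
              k_nuc = k_nuc, h_exp = h_exp, exp_cap = exp_cap,
              gamma_q = gamma_q,
              k_olig = k_olig, k_conv = k_conv, k_conv_olig = k_conv_olig,
              mu_ni = mu_ni, mu_i = mu_i,
              p_leach = p_leach, p_debris = p_debris,
              k_deg = k_deg, growth_rate = growth_rate, seed = seed)
  validate_sim_config(cfg)
  class(cfg) <- "aggflux_config"
  cfg
}

validate_sim_config <- function(cfg) {
  haz <- c(cfg$k_nuc, cfg$k_olig, cfg$k_conv, cfg$k_conv_olig,
           cfg$mu_ni, cfg$mu_i, cfg$k_deg, cfg$growth_rate)
  if (any(!is.finite(haz)) || any(haz < 0))
    stop("all hazards must be finite and >= 0")
  if (cfg$p_leach < 0 || cfg$p_debris < 0 ||
      cfg$p_leach + cfg$p_debris > 1)
    stop("p_leach + p_debris must lie in [0, 1]")
  if (q_gain(25, cfg$gamma_q) != 0)
    stop("q_gain must vanish for non-pathogenic polyQ lengths")
  if (!cfg$arm %in% names(cfg$chaperone_mods))
    stop("unknown arm '", cfg$arm, "'")
  if (cfg$dt <= 0) stop("dt must be positive")
  if (any(abs(cfg$time_points / cfg$dt -
              round(cfg$time_points / cfg$dt)) > 1e-9))
    stop("time_points must be multiples of dt")
  invisible(cfg)
}

# integer status codes used internally
.STATUS <- c(live = 1L, dead_intact = 2L, leached = 3L, lysed_debris = 4L)
.STATUS_NAMES <- names(.STATUS)

#' Simulate a transfected cell population
#'
#' Discrete-time hazard stepping of each cell's aggregation, death, clearance
#' and division dynamics. Per step, a live cell may nucleate an inclusion
#' with hazard `k_nuc * (E/E_ref)^h_exp * q_gain(Q) * mod_nuc`, may die with
#' hazard `mu_ni` or `mu_i` (times the arm's death modifier), and may divide
#' with the growth hazard; a dying cell resolves to an intact dead cell, a
#' leached ghost (membrane reporter retained, cytosol lost) or -- for
#' inclusion bearers only -- a free inclusion with debris. Httex1 decays at
#' `k_deg` in live cells; after nucleation the monomer and oligomer fractions
#' convert first-order into the inclusion fraction. Inclusion formation is
#' absorbing (no reverse flux).
#'
#' @param config An [sim_config()] object.
#' @return A data frame of class `aggflux_cells`, one row per cell per
#'   requested time point, with columns `id`, `time`, `arm`, `polyQ`,
#'   `E_htt`, `E_htt0`, `E_mkate`, `f_mono`, `f_olig`, `f_inc`,
#'   `has_inclusion`, `status` (one of live, dead_intact, leached,
#'   lysed_debris). The attribute `accounting` records, per step, the exact
#'   population bookkeeping (births and deaths), which always balances.
#' @examples
#' cells <- simulate_population(sim_config(polyQ_length = 97, n_cells = 200,
#'                                         time_points = c(18, 46), seed = 1))
#' mean(subset(cells, time == 46)$has_inclusion)
#' @export
simulate_population <- function(config) {
  validate_sim_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  mods <- config$chaperone_mods[[config$arm]]
  E_ref <- exp(config$expression_meanlog)
  qg <- q_gain(config$polyQ_length, config$gamma_q)
  dt <- config$dt

  n0 <- config$n_cells
  E0 <- stats::rlnorm(n0, config$expression_meanlog, config$expression_sdlog)
  st <- list(
    id = seq_len(n0),
    E0 = E0,
    E = E0,
    Emk = config$reporter_slope * E0 * mods$mod_yield *
      stats::rlnorm(n0, 0, config$reporter_sdlog),
    f_mono = rep(1, n0), f_olig = rep(0, n0), f_inc = rep(0, n0),
    has_inc = rep(FALSE, n0), olig_state = rep(FALSE, n0),
    status = rep(.STATUS[["live"]], n0)
  )
  next_id <- n0 + 1L

  # per-step hazard probabilities must stay small for the stepping to be valid
  max_haz <- max(config$k_nuc * config$exp_cap * qg * mods$mod_nuc,
                 config$mu_i * mods$mod_death_i,
                 config$mu_ni * mods$mod_death_ni,
                 config$growth_rate * mods$mod_growth)
  if (!is.finite(max_haz)) stop("non-finite hazards")
  if (max_haz * dt > 0.2)
    stop("per-step event probability exceeds 0.2; reduce dt")

  n_steps <- round(max(config$time_points) / dt)
  take_at <- round(config$time_points / dt)
  snapshots <- vector("list", length(config$time_points))
  accounting <- data.frame(step = integer(0), n_before = integer(0),
                           births = integer(0), deaths = integer(0),
                           n_after = integer(0))
  if (0 %in% take_at)
    snapshots[[match(0, take_at)]] <- snapshot_df(st, 0, config)

  for (step in seq_len(n_steps)) {
    live <- st$status == .STATUS[["live"]]
    n_live <- sum(live)
    n_before <- length(st$id)
    births <- 0L; deaths <- 0L
    if (n_live > 0) {
      idx <- which(live)
      Erel <- st$E[idx] / E_ref
      lam_nuc <- ifelse(st$has_inc[idx], 0,
                        config$k_nuc * pmin(Erel^config$h_exp, config$exp_cap) *
                          qg * mods$mod_nuc)
      lam_olig <- ifelse(st$has_inc[idx] | st$olig_state[idx], 0,
                         config$k_olig * qg)
      mu <- ifelse(st$has_inc[idx],
                   config$mu_i * mods$mod_death_i,
                   config$mu_ni * mods$mod_death_ni)
      if (any(!is.finite(c(lam_nuc, lam_olig, mu))))
        stop("non-finite hazards")
      # nucleation
      nuc <- stats::runif(n_live) < 1 - exp(-lam_nuc * dt)
      st$has_inc[idx[nuc]] <- TRUE
      # oligomer enrichment
      olg <- stats::runif(n_live) < 1 - exp(-lam_olig * dt)
      st$olig_state[idx[olg]] <- TRUE
      # intracellular conversion
      inc_i <- idx[st$has_inc[idx]]
      if (length(inc_i)) {
        d <- 1 - exp(-config$k_conv * dt)
        conv <- (st$f_mono[inc_i] + st$f_olig[inc_i]) * d
        st$f_inc[inc_i] <- st$f_inc[inc_i] + conv
        st$f_mono[inc_i] <- st$f_mono[inc_i] * (1 - d)
        st$f_olig[inc_i] <- st$f_olig[inc_i] * (1 - d)
        # renormalise against floating drift so fractions sum to 1 exactly
        tot <- st$f_mono[inc_i] + st$f_olig[inc_i] + st$f_inc[inc_i]
        st$f_mono[inc_i] <- st$f_mono[inc_i] / tot
        st$f_olig[inc_i] <- st$f_olig[inc_i] / tot
        st$f_inc[inc_i] <- st$f_inc[inc_i] / tot
      }
      olig_i <- idx[st$olig_state[idx] & !st$has_inc[idx]]
      if (length(olig_i)) {
        d <- 1 - exp(-config$k_conv_olig * dt)
        st$f_olig[olig_i] <- st$f_olig[olig_i] + st$f_mono[olig_i] * d
        st$f_mono[olig_i] <- st$f_mono[olig_i] * (1 - d)
      }
      # death and fate
      die <- stats::runif(n_live) < 1 - exp(-mu * dt)
      die_i <- idx[die]
      if (length(die_i)) {
        u <- stats::runif(length(die_i))
        fate <- rep(.STATUS[["dead_intact"]], length(die_i))
        fate[u < config$p_leach] <- .STATUS[["leached"]]
        deb <- u >= config$p_leach &
          u < config$p_leach + config$p_debris & st$has_inc[die_i]
        fate[deb] <- .STATUS[["lysed_debris"]]
        st$status[die_i] <- fate
        deaths <- length(die_i)
      }
      # degradation (surviving live cells)
      still <- idx[!die]
      st$E[still] <- st$E[still] * exp(-config$k_deg * mods$mod_deg * dt)
      # division: daughters duplicate the parent state
      gr <- config$growth_rate * mods$mod_growth
      div <- still[stats::runif(length(still)) < 1 - exp(-gr * dt)]
      if (length(div)) {
        births <- length(div)
        st <- within_append(st, div, next_id)
        next_id <- next_id + births
      }
    }
    accounting <- rbind(accounting,
                        data.frame(step = step, n_before = n_before,
                                   births = births, deaths = deaths,
                                   n_after = length(st$id)))
    hit <- match(step, take_at)
    if (!is.na(hit)) snapshots[[hit]] <- snapshot_df(st, step * dt, config)
  }

  out <- do.call(rbind, snapshots)
  rownames(out) <- NULL
  attr(out, "accounting") <- accounting
  attr(out, "config") <- config
  class(out) <- c("aggflux_cells", class(out))
  out
}

within_append <- function(st, div, next_id) {
  nb <- length(div)
  st$id <- c(st$id, seq.int(next_id, length.out = nb))
  for (f in c("E0", "E", "Emk", "f_mono", "f_olig", "f_inc",
              "has_inc", "olig_state", "status"))
    st[[f]] <- c(st[[f]], st[[f]][div])
  st
}

snapshot_df <- function(st, time, config) {
  data.frame(
    id = st$id, time = time, arm = config$arm, polyQ = config$polyQ_length,
    E_htt = st$E, E_htt0 = st$E0, E_mkate = st$Emk,
    f_mono = st$f_mono, f_olig = st$f_olig, f_inc = st$f_inc,
    has_inclusion = st$has_inc,
    status = .STATUS_NAMES[st$status],
    stringsAsFactors = FALSE
  )
}

#' Pool a cell population into a lysate composition
#'
#' Abundance-weighted pooling of the per-cell molecular fractions into the
#' population-level proportions of Httex1 as monomer, oligomer and inclusion,
#' as a cell lysate would present them. Cytosol of leached cells is lost
#' before harvest, so only live cells, intact dead cells and free-inclusion
#' debris contribute.
#'
#' @param cells An `aggflux_cells` snapshot (one time point).
#' @return List of class `aggflux_lysate` with `p_mono`, `p_olig`, `p_inc`
#'   (summing to 1) and `total_signal` (summed Httex1 abundance, a.u.).
#' @examples
#' cells <- data.frame(E_htt = c(1, 1), f_mono = c(1, 0), f_olig = c(0, 0),
#'                     f_inc = c(0, 1), status = "live")
#' pool_lysate(cells)$p_inc
#' @export
pool_lysate <- function(cells) {
  if (NROW(cells) == 0) stop("empty population")
  keep <- cells$status %in% c("live", "dead_intact", "lysed_debris")
  cells <- cells[keep, , drop = FALSE]
  w <- cells$E_htt
  if (sum(w) <= 0) stop("all-zero Httex1 abundance")
  out <- list(
    p_mono = sum(w * cells$f_mono) / sum(w),
    p_olig = sum(w * cells$f_olig) / sum(w),
    p_inc = sum(w * cells$f_inc) / sum(w),
    total_signal = sum(w)
  )
  class(out) <- "aggflux_lysate"
  out
}

#' Construct a lysate composition directly
#'
#' @param p_mono,p_olig,p_inc Molecular fractions (must sum to 1).
#' @param total_signal Summed fluorophore abundance (a.u.).
#' @return An `aggflux_lysate` object.
#' @export
lysate_composition <- function(p_mono, p_olig, p_inc, total_signal = 1) {
  if (p_mono < 0 || p_olig < 0 || p_inc < 0)
    stop("fractions must be >= 0")
  if (abs(p_mono + p_olig + p_inc - 1) > 1e-9)
    stop("fractions must sum to 1")
  structure(list(p_mono = p_mono, p_olig = p_olig, p_inc = p_inc,
                 total_signal = total_signal),
            class = "aggflux_lysate")
}
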