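#' Default cytometer panel configuration
#'
#' Brightness factors, pulse geometry, noise levels and stain behaviour used
#' when converting simulated cells into cytometer events. Channel naming
#' follows the detection panel: Pacific Blue / BV421 detects Cerulean, FITC
#' detects FlAsH, PE-Texas Red detects mKate2, APC detects SYTOX. Brightness
#' ratios between channels are arbitrary fixed constants (no spillover model).
#'
#' @param ... Named overrides of any default entry.
#' @return Named list of panel parameters.
#' @export
panel_config <- function(...) {
  p <- list(
    b_cer = 1, b_mk = 1, b_flash = 0.5,     # channel brightness per molecule
    beam_sigma = 1,                          # laser beam sd (transit-time a.u.)
    diffuse_frac = 0.25,                     # diffuse profile sd per unit diameter
    punct_sigma = 0.3,                       # near-point inclusion profile sd
    width_threshold = 2,                     # absolute detector floor for width
    diam_meanlog = log(12), diam_sdlog = 0.05,  # cell diameter law (a.u.)
    ssc_per_area = 10,                       # scatter signal per diameter^2
    noise_cv = 0.08,                         # multiplicative channel noise (sdlog)
    noise_sd = 1,                            # additive detector noise (a.u.)
    sytox_pos = 5000, sytox_neg = 30,        # APC levels for +/- events
    # stain response probabilities by true state
    sytox_p_dead_intact = 0.995,
    sytox_fp_live = 0.001,
    sytox_p_leached = 0.4,                   # leached ghosts mostly SYTOX-miss
    sytox_p_debris = 0.4,
    leach_cyto_frac = 0.003,                 # residual cytosolic signal after leach
    debris_mk_frac = 0.02,                   # mKate2 carried by free inclusions
    debris_diffuse_frac = 0.05,              # diffuse remnant on debris
    debris_size_frac = 0.45,                 # debris diameter vs parent cell
    autofluor_meanlog = log(15), autofluor_sdlog = 0.5
  )
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown panel entries: ", paste(bad, collapse = ", "))
  p[names(over)] <- over
  p
}

#' Synthesize a cytometer pulse from diffuse and punctate signal
#'
#' The transit profile of a cell is modelled as a centred Gaussian whose sd
#' is proportional to the cell diameter (the diffuse fluorophore) plus a
#' near-point Gaussian carrying the punctate (inclusion) signal, convolved
#' with a Gaussian laser beam. Because all components are Gaussian the
#' convolution is evaluated in closed form; height is the profile maximum,
#' area its integral, and width the transit duration above a fixed absolute
#' threshold (an instrument-style detector floor) or, optionally, above a
#' fixed fraction of the pulse height.
#'
#' All arguments are vectorised over events.
#'
#' @param diffuse_signal,punctate_signal Non-negative signal amounts (a.u.).
#' @param cell_diameter Cell diameter (a.u. of transit time extent).
#' @param beam_sigma Laser beam Gaussian sd (> 0).
#' @param noise_sd Additive Gaussian noise sd; 0 gives a deterministic pulse.
#' @param threshold Width threshold (a.u., default the panel detector floor).
#' @param threshold_mode `"absolute"` (instrument floor) or `"relative"`
#'   (fraction of pulse height).
#' @param diffuse_frac Diffuse profile sd per unit cell diameter.
#' @param punct_sigma Punctate profile sd (same units as `beam_sigma`).
#' @return Data frame with columns `height`, `area`, `width`.
#' @export
synthesize_pulse <- function(diffuse_signal, punctate_signal, cell_diameter,
                             beam_sigma = 1, noise_sd = 0,
                             threshold = 2,
                             threshold_mode = c("absolute", "relative"),
                             diffuse_frac = 0.25, punct_sigma = 0.3) {
  threshold_mode <- match.arg(threshold_mode)
  n <- max(length(diffuse_signal), length(punctate_signal),
           length(cell_diameter))
  Ad <- rep_len(diffuse_signal, n)
  Ap <- rep_len(punctate_signal, n)
  diam <- rep_len(cell_diameter, n)
  if (any(Ad < 0) || any(Ap < 0)) stop("signals must be >= 0")
  if (beam_sigma <= 0) stop("beam_sigma must be > 0")
  if (all(Ad + Ap == 0) && noise_sd == 0)
    stop("degenerate pulse: zero signal and zero noise")
  sd_d <- sqrt((diffuse_frac * diam)^2 + beam_sigma^2)
  sd_p <- sqrt(punct_sigma^2 + rep_len(beam_sigma, n)^2)

  height0 <- Ad / (sd_d * sqrt(2 * pi)) + Ap / (sd_p * sqrt(2 * pi))
  area0 <- Ad + Ap
  if (noise_sd > 0) {
    height <- pmax(height0 + stats::rnorm(n, 0, noise_sd), 0)
    area <- pmax(area0 + stats::rnorm(n, 0, noise_sd * sqrt(2 * pi)), 0)
  } else {
    height <- height0
    area <- area0
  }
  thr <- if (threshold_mode == "absolute") rep_len(threshold, n)
         else threshold * height0
  width <- pulse_width_bisect(Ad, Ap, sd_d, sd_p, thr)
  data.frame(height = height, area = area, width = width)
}

# half-width where Ad*dnorm(t,0,sd_d) + Ap*dnorm(t,0,sd_p) crosses thr;
# the profile is a mixture of centred Gaussians, hence monotone in |t|,
# so vectorised bisection converges unconditionally
pulse_width_bisect <- function(Ad, Ap, sd_d, sd_p, thr) {
  prof <- function(t) Ad * stats::dnorm(t, 0, sd_d) +
    Ap * stats::dnorm(t, 0, sd_p)
  peak <- prof(0)
  lo <- numeric(length(Ad))
  hi <- pmax(sd_d, sd_p) * 8
  out <- numeric(length(Ad))
  solve <- peak > thr & thr > 0
  if (any(solve)) {
    l <- lo[solve]; h <- hi[solve]
    Ads <- Ad[solve]; Aps <- Ap[solve]
    sds <- sd_d[solve]; sps <- sd_p[solve]; ths <- thr[solve]
    for (i in 1:60) {
      m <- (l + h) / 2
      v <- Ads * stats::dnorm(m, 0, sds) + Aps * stats::dnorm(m, 0, sps)
      up <- v > ths
      l[up] <- m[up]
      h[!up] <- m[!up]
    }
    out[solve] <- l + h  # 2 * midpoint
  }
  out
}

#' Convert a simulated cell population into flow-cytometry events
#'
#' Applies the measurement rules of the reporter system: live and intact dead
#' cells give Cerulean proportional to Httex1 (with the inclusion fraction as
#' the punctate share), membrane mKate2 proportional to the reporter level,
#' and FlAsH proportional to the monomeric Httex1 only (the biarsenical dye
#' binds the tetracysteine tag exclusively in the monomer). Leached ghosts
#' retain membrane mKate2 but have lost nearly all cytosolic signal; lysed
#' debris appears as one event per cell dominated by the punctate Cerulean of
#' the free inclusion with little mKate2. SYTOX reactivity is drawn from the
#' per-state response probabilities in the panel (leached and debris events
#' are frequently SYTOX-negative, having lost their nucleic acids).
#' Optionally adds untransfected cells and small-particle background.
#'
#' @param cells `aggflux_cells` rows from a single time point.
#' @param panel A [panel_config()].
#' @param n_untransfected,n_particles,n_doublets Background event counts.
#' @param stain_sytox Set `FALSE` to emulate an unstained tube (no dye in
#'   the sample): every event reads at the background APC level. Use this to
#'   build the unstained reference for [sytox_gate()].
#' @param seed Optional integer seed.
#' @return Data frame of class `aggflux_events`: per channel (`cer`, `mk`,
#'   `fl`, `sytox`, `ssc`) pulse height `_h`, area `_a` and width `_w`
#'   columns, plus truth columns (`truth_id`, `truth_class`, `truth_status`,
#'   `truth_inclusion`, `truth_sytox`, `truth_f_mono`) that no gating
#'   function reads.
#' @export
cells_to_events <- function(cells, panel = panel_config(),
                            n_untransfected = 0, n_particles = 0,
                            n_doublets = 0, stain_sytox = TRUE,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (NROW(cells) == 0 && n_untransfected + n_particles == 0)
    stop("no cells and no background requested")
  if (NROW(cells) > 0 && length(unique(cells$time)) > 1)
    stop("cells_to_events expects a single time point; subset first")
  n <- NROW(cells)
  status <- if (n) cells$status else character(0)
  if (n && !all(status %in% .STATUS_NAMES))
    stop("unknown status value: ",
         paste(setdiff(unique(status), .STATUS_NAMES), collapse = ", "))

  ln <- function(m) stats::rlnorm(m, 0, panel$noise_cv)
  diam <- stats::rlnorm(n, panel$diam_meanlog, panel$diam_sdlog)

  cer_d <- cer_p <- mk_d <- fl_d <- numeric(n)
  sy_p <- numeric(n)
  is_lv <- status == "live"
  is_di <- status == "dead_intact"
  is_le <- status == "leached"
  is_db <- status == "lysed_debris"

  intact <- is_lv | is_di
  if (any(intact)) {
    E <- cells$E_htt[intact]
    cer_d[intact] <- panel$b_cer * E * (1 - cells$f_inc[intact])
    cer_p[intact] <- panel$b_cer * E * cells$f_inc[intact]
    mk_d[intact] <- panel$b_mk * cells$E_mkate[intact]
    fl_d[intact] <- panel$b_flash * E * cells$f_mono[intact]
  }
  if (any(is_le)) {
    E <- cells$E_htt[is_le]
    cer_d[is_le] <- panel$b_cer * E * panel$leach_cyto_frac
    mk_d[is_le] <- panel$b_mk * cells$E_mkate[is_le]
    fl_d[is_le] <- panel$b_flash * E * cells$f_mono[is_le] *
      panel$leach_cyto_frac
  }
  if (any(is_db)) {
    E <- cells$E_htt[is_db]
    cer_p[is_db] <- panel$b_cer * E * cells$f_inc[is_db]
    cer_d[is_db] <- panel$b_cer * E * (1 - cells$f_inc[is_db]) *
      panel$debris_diffuse_frac
    mk_d[is_db] <- panel$b_mk * cells$E_mkate[is_db] * panel$debris_mk_frac
    fl_d[is_db] <- panel$b_flash * E * cells$f_mono[is_db] *
      panel$debris_diffuse_frac
    diam[is_db] <- diam[is_db] * panel$debris_size_frac
  }
  sy_p[is_lv] <- panel$sytox_fp_live
  sy_p[is_di] <- panel$sytox_p_dead_intact
  sy_p[is_le] <- panel$sytox_p_leached
  sy_p[is_db] <- panel$sytox_p_debris
  truth_sytox <- stats::runif(n) < sy_p
  if (!stain_sytox) truth_sytox[] <- FALSE

  mk_code <- function(cd, cp, mkd, fld, sypos, diam, m) {
    sy <- ifelse(sypos, panel$sytox_pos, panel$sytox_neg) * ln(m)
    pw <- function(d, p) synthesize_pulse(
      d, p, diam, beam_sigma = panel$beam_sigma, noise_sd = panel$noise_sd,
      threshold = panel$width_threshold,
      diffuse_frac = panel$diffuse_frac, punct_sigma = panel$punct_sigma)
    cer <- pw(cd * ln(m), cp * ln(m))
    mk <- pw(mkd * ln(m), 0)
    fl <- pw(fld * ln(m), 0)
    syp <- pw(sy, 0)
    ssc <- pw(panel$ssc_per_area * diam^2 * ln(m), 0)
    data.frame(cer_h = cer$height, cer_a = cer$area, cer_w = cer$width,
               mk_h = mk$height, mk_a = mk$area, mk_w = mk$width,
               fl_h = fl$height, fl_a = fl$area, fl_w = fl$width,
               sytox_h = syp$height, sytox_a = syp$area, sytox_w = syp$width,
               ssc_h = ssc$height, ssc_a = ssc$area, ssc_w = ssc$width)
  }

  out <- NULL
  if (n) {
    ev <- mk_code(cer_d, cer_p, mk_d, fl_d, truth_sytox, diam, n)
    ev$truth_id <- cells$id
    ev$truth_class <- "cell"
    ev$truth_status <- status
    ev$truth_inclusion <- cells$has_inclusion
    ev$truth_sytox <- truth_sytox
    ev$truth_f_mono <- cells$f_mono
    out <- ev
  }
  if (n_untransfected > 0) {
    m <- n_untransfected
    af <- function() stats::rlnorm(m, panel$autofluor_meanlog,
                                   panel$autofluor_sdlog)
    d <- stats::rlnorm(m, panel$diam_meanlog, panel$diam_sdlog)
    sy <- stain_sytox & stats::runif(m) < panel$sytox_fp_live
    ev <- mk_code(af(), numeric(m), af(), af(), sy, d, m)
    ev$truth_id <- NA_integer_
    ev$truth_class <- "untransfected"
    ev$truth_status <- "live"
    ev$truth_inclusion <- FALSE
    ev$truth_sytox <- sy
    ev$truth_f_mono <- NA_real_
    out <- rbind(out, ev)
  }
  if (n_particles > 0) {
    m <- n_particles
    d <- 0.15 * stats::rlnorm(m, panel$diam_meanlog, panel$diam_sdlog)
    lowaf <- function() 0.2 * stats::rlnorm(m, panel$autofluor_meanlog,
                                            panel$autofluor_sdlog)
    ev <- mk_code(lowaf(), numeric(m), lowaf(), lowaf(),
                  rep(FALSE, m), d, m)
    ev$truth_id <- NA_integer_
    ev$truth_class <- "particle"
    ev$truth_status <- "live"
    ev$truth_inclusion <- FALSE
    ev$truth_sytox <- FALSE
    ev$truth_f_mono <- NA_real_
    out <- rbind(out, ev)
  }
  if (n_doublets > 0 && n >= 2) {
    m <- n_doublets
    i1 <- sample.int(n, m, replace = TRUE)
    i2 <- sample.int(n, m, replace = TRUE)
    d <- 2 * stats::rlnorm(m, panel$diam_meanlog, panel$diam_sdlog)
    sy <- truth_sytox[i1] | truth_sytox[i2]
    ev <- mk_code(cer_d[i1] + cer_d[i2], cer_p[i1] + cer_p[i2],
                  mk_d[i1] + mk_d[i2], fl_d[i1] + fl_d[i2], sy, d, m)
    ev$truth_id <- NA_integer_
    ev$truth_class <- "doublet"
    ev$truth_status <- "live"
    ev$truth_inclusion <- cells$has_inclusion[i1] | cells$has_inclusion[i2]
    ev$truth_sytox <- sy
    ev$truth_f_mono <- NA_real_
    out <- rbind(out, ev)
  }
  rownames(out) <- NULL
  class(out) <- c("aggflux_events", class(out))
  out
}

#' Simulate sedimentation-velocity radial scans
#'
#' Generates absorbance/fluorescence scans of non-diffusing species in a
#' sector-shaped cell. Each species of sedimentation coefficient `s`
#' contributes a step boundary at `r_m * exp(omega^2 s t)` with plateau
#' concentration diluted by the radial-dilution law `exp(-2 omega^2 s t)`.
#' A small logistic edge width stands in for diffusional spreading so that
#' downstream fitting is non-degenerate; set `edge_width = 0` for hard steps.
#'
#' @param species Data frame with columns `s` (svedbergs, >= 0) and `signal`
#'   (loading signal, a.u.).
#' @param rotor_rpm Rotor speed (revolutions per minute).
#' @param scan_times Increasing vector of scan times (seconds).
#' @param meniscus_cm,base_cm Cell geometry (cm), meniscus < base.
#' @param n_radii Number of radial samples per scan.
#' @param noise_sd Additive Gaussian noise sd (a.u.).
#' @param edge_width Logistic boundary width (cm).
#' @param temperature_C Recorded temperature metadata.
#' @param seed Optional integer seed.
#' @return List of class `aggflux_scans`; each element has `radius_cm`,
#'   `signal`, `time_s`, `rotor_rpm`, `meniscus_cm`, `base_cm`, `temp_C`.
#' @export
simulate_radial_scans <- function(species, rotor_rpm, scan_times,
                                  meniscus_cm = 6.0, base_cm = 7.2,
                                  n_radii = 400, noise_sd = 0,
                                  edge_width = 0.005, temperature_C = 20,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(species$s < 0)) stop("sedimentation coefficients must be >= 0")
  if (is.unsorted(scan_times, strictly = TRUE))
    stop("scan_times must be strictly increasing")
  if (meniscus_cm >= base_cm) stop("meniscus must be below the base")
  omega <- 2 * pi * rotor_rpm / 60
  r <- seq(meniscus_cm, base_cm, length.out = n_radii)
  pelleted <- FALSE
  scans <- lapply(scan_times, function(t) {
    sig <- numeric(n_radii)
    for (k in seq_len(NROW(species))) {
      s <- species$s[k] * 1e-13  # svedberg -> seconds
      rb <- meniscus_cm * exp(omega^2 * s * t)
      if (rb > base_cm) pelleted <<- TRUE
      plateau <- species$signal[k] * exp(-2 * omega^2 * s * t)
      frac <- if (s == 0) rep(1, n_radii)  # non-sedimenting: flat plateau
              else if (edge_width > 0) stats::plogis((r - rb) / edge_width)
              else as.numeric(r >= rb)
      sig <- sig + plateau * frac
    }
    if (noise_sd > 0) sig <- sig + stats::rnorm(n_radii, 0, noise_sd)
    list(radius_cm = r, signal = sig, time_s = t, rotor_rpm = rotor_rpm,
         meniscus_cm = meniscus_cm, base_cm = base_cm, temp_C = temperature_C)
  })
  if (pelleted)
    warning("at least one species boundary moved beyond the cell base ",
            "(fully pelleted) within the scan window")
  structure(scans, class = "aggflux_scans")
}

#' Simulate a size-exclusion chromatogram of a lysate
#'
#' Emulates a large-pore resin separating Httex1 species by size: the
#' monomer pool elutes as a narrow Gaussian at its calibrated volume, the
#' oligomer pool as an earlier, broader peak (default three times wider), and
#' inclusions are occluded by the column entirely, so the loaded signal is
#' `(1 - p_inc) * total_signal`.
#'
#' @param lysate An `aggflux_lysate` composition.
#' @param column List with `v_total` (ml), `v_mono`, `v_olig` (elution
#'   centres, ml), `w_mono`, `w_olig` (Gaussian sd, ml), `frac_ml`
#'   (fraction size, ml).
#' @param noise_sd Additive fluorescence noise sd (a.u. per ml).
#' @param seed Optional integer seed.
#' @return Data frame of class `aggflux_chrom` with columns `elution_ml`
#'   and `fluorescence` (a.u. per ml), plus the column metadata as
#'   attribute `column`.
#' @export
simulate_chromatogram <- function(lysate, column = sec_column(),
                                  noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(lysate, "aggflux_lysate"))
  if (column$v_mono >= column$v_total || column$v_olig >= column$v_total ||
      column$v_mono <= 0 || column$v_olig <= 0)
    stop("peak centres outside the column volume range")
  V <- seq(column$frac_ml / 2, column$v_total - column$frac_ml / 2,
           by = column$frac_ml)
  loaded <- (1 - lysate$p_inc) * lysate$total_signal
  mo <- lysate$p_mono + lysate$p_olig
  m <- if (mo > 0) loaded * lysate$p_mono / mo else 0
  o <- if (mo > 0) loaded * lysate$p_olig / mo else 0
  fl <- m * stats::dnorm(V, column$v_mono, column$w_mono) +
    o * stats::dnorm(V, column$v_olig, column$w_olig)
  if (noise_sd > 0) fl <- pmax(fl + stats::rnorm(length(V), 0, noise_sd), 0)
  out <- data.frame(elution_ml = V, fluorescence = fl)
  attr(out, "column") <- column
  class(out) <- c("aggflux_chrom", class(out))
  out
}

#' Default large-pore size-exclusion column geometry
#'
#' @param v_total Total column volume (ml).
#' @param v_mono,v_olig Calibrated elution centres (ml); oligomers elute
#'   earlier (larger species).
#' @param w_mono,w_olig Peak Gaussian sd (ml); the oligomer peak is broad.
#' @param frac_ml Collected fraction size (ml).
#' @return Named list of column parameters.
#' @export
sec_column <- function(v_total = 120, v_mono = 85, v_olig = 55,
                       w_mono = 3, w_olig = 9, frac_ml = 1) {
  list(v_total = v_total, v_mono = v_mono, v_olig = v_olig,
       w_mono = w_mono, w_olig = w_olig, frac_ml = frac_ml)
}
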