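#' Default sedimentation-coefficient grid
#'
#' 50 logarithmically spaced points spanning 1-5000 S, covering lysate
#' oligomers (~140 S), purified oligomer fractions (~196 S) and larger
#' species short of inclusions.
#'
#' @param n Number of grid points.
#' @param s_min,s_max Grid range (svedbergs).
#' @return Increasing numeric vector.
#' @export
lsgs_default_grid <- function(n = 50, s_min = 1, s_max = 5000) {
  10^seq(log10(s_min), log10(s_max), length.out = n)
}

# trapezoid weights of an increasing grid
grid_ds <- function(s) {
  n <- length(s)
  ds <- numeric(n)
  ds[1] <- (s[2] - s[1]) / 2
  ds[n] <- (s[n] - s[n - 1]) / 2
  if (n > 2) ds[2:(n - 1)] <- (s[3:n] - s[1:(n - 2)]) / 2
  ds
}

# design matrix of non-diffusing step boundaries with radial dilution,
# evaluated at every (radius, time) sample of the scans
lsgs_design <- function(scans, s_grid, edge_width) {
  sc1 <- scans[[1]]
  omega <- 2 * pi * sc1$rotor_rpm / 60
  r <- unlist(lapply(scans, `[[`, "radius_cm"))
  t <- unlist(lapply(scans, function(s) rep(s$time_s, length(s$radius_cm))))
  A <- matrix(0, length(r), length(s_grid))
  for (j in seq_along(s_grid)) {
    s <- s_grid[j] * 1e-13
    rb <- sc1$meniscus_cm * exp(omega^2 * s * t)
    dil <- exp(-2 * omega^2 * s * t)
    frac <- if (edge_width > 0) stats::plogis((r - rb) / edge_width)
            else as.numeric(r >= rb)
    A[, j] <- dil * frac
  }
  list(A = A, b = unlist(lapply(scans, `[[`, "signal")),
       omega = omega, r = r, t = t)
}

# non-negative least squares with optional second-difference (Tikhonov)
# smoothing of g(s); penalty rows are appended to the design
nnls_penalized <- function(A, b, ds, lambda, baseline = TRUE) {
  n_s <- length(ds)
  Afull <- if (baseline) cbind(A, 1) else A
  if (lambda > 0 && n_s > 2) {
    D <- matrix(0, n_s - 2, ncol(Afull))
    for (i in seq_len(n_s - 2)) {
      # second difference acting on g = c / ds
      D[i, i] <- lambda / ds[i]
      D[i, i + 1] <- -2 * lambda / ds[i + 1]
      D[i, i + 2] <- lambda / ds[i + 2]
    }
    Afull <- rbind(Afull, D)
    b <- c(b, numeric(n_s - 2))
  }
  fit <- pracma::lsqnonneg(Afull, b)
  x <- fit$x
  list(c = x[seq_len(n_s)],
       baseline = if (baseline) x[n_s + 1] else 0)
}

#' Fit an ls-g*(s) sedimentation-coefficient distribution
#'
#' Least-squares fit of a distribution of non-interacting, non-diffusing
#' species to a family of radial scans. Each grid point `s_j` contributes a
#' step boundary at `r_m * exp(omega^2 s_j t)` with plateau diluted by
#' `exp(-2 omega^2 s_j t)`; amplitudes are found by non-negative least
#' squares with an optional second-difference smoothness penalty on g(s) and
#' a flat baseline. The penalty weight can be chosen automatically by the
#' discrepancy principle: the largest weight whose penalized RMSD stays
#' within 10% of the unpenalized fit.
#'
#' @param scans `aggflux_scans` list (>= 3 scans spanning boundary movement).
#' @param s_grid Increasing positive grid (svedbergs).
#' @param lambda Penalty weight, or `"auto"` for the discrepancy rule.
#' @param edge_width Logistic boundary width used in the model (cm); match
#'   the instrument's diffusion-mimicking width, or 0 for hard steps.
#' @param baseline Include a flat baseline column.
#' @return List of class `aggflux_lsgs`: `s`, `g` (signal per svedberg),
#'   `c` (amplitudes per grid point), `mode_s`, `integral`, `rmsd`,
#'   `lambda`, `baseline`.
#' @export
fit_lsgs <- function(scans, s_grid = lsgs_default_grid(), lambda = "auto",
                     edge_width = 0.005, baseline = TRUE) {
  if (length(scans) < 3)
    stop("at least 3 scans spanning boundary movement are required")
  if (is.unsorted(s_grid, strictly = TRUE) || any(s_grid <= 0))
    stop("s_grid must be positive and strictly increasing")
  des <- lsgs_design(scans, s_grid, edge_width)
  ds <- grid_ds(s_grid)
  # grid conditioning: at the latest scan at least one adjacent pair of grid
  # points must produce boundaries separated by more than the radial spacing
  sc1 <- scans[[1]]
  t_max <- max(vapply(scans, `[[`, numeric(1), "time_s"))
  rb <- sc1$meniscus_cm * exp(des$omega^2 * s_grid * 1e-13 * t_max)
  dr <- stats::median(diff(sc1$radius_cm))
  if (all(diff(rb) < dr))
    stop("ill-conditioned s grid: no adjacent boundary positions are ",
         "resolvable at the data spacing")
  if (all(des$b == 0)) {
    warning("all-zero scans: returning zero distribution")
    g <- numeric(length(s_grid))
    return(structure(list(s = s_grid, g = g, c = g, mode_s = NA_real_,
                          integral = 0, rmsd = 0, lambda = 0, baseline = 0),
                     class = "aggflux_lsgs"))
  }
  fit0 <- nnls_penalized(des$A, des$b, ds, 0, baseline)
  rmsd_of <- function(f)
    sqrt(mean((des$A %*% f$c + f$baseline - des$b)^2))
  rmsd0 <- rmsd_of(fit0)
  if (identical(lambda, "auto")) {
    # discrepancy principle on a geometric ladder
    scale <- max(abs(des$b)) / max(ds)
    best <- fit0; best_l <- 0
    for (l in scale * 10^seq(-6, 0, by = 1)) {
      f <- nnls_penalized(des$A, des$b, ds, l, baseline)
      if (rmsd_of(f) <= 1.1 * max(rmsd0, 1e-12)) {
        best <- f; best_l <- l
      } else break
    }
    fit <- best; lambda <- best_l
  } else if (lambda > 0) {
    fit <- nnls_penalized(des$A, des$b, ds, lambda, baseline)
  } else {
    fit <- fit0
  }
  g <- fit$c / ds
  structure(list(s = s_grid, g = g, c = fit$c,
                 mode_s = s_grid[which.max(g)],
                 integral = sum(fit$c),
                 rmsd = rmsd_of(fit),
                 lambda = lambda, baseline = fit$baseline),
            class = "aggflux_lsgs")
}

#' Correct an observed sedimentation coefficient to standard conditions
#'
#' Applies the Svedberg solvent correction to the standard state of water at
#' 20 degrees C:
#' `s20w = s_obs * (eta_Tb / eta_20w) * (1 - vbar rho_20w) / (1 - vbar rho_Tb)`
#' with water constants rho = 0.99823 g/ml and eta = 1.002 cP.
#'
#' @param s_obs Observed sedimentation coefficient (svedbergs).
#' @param density Solvent density (g/ml).
#' @param viscosity Solvent viscosity (cP).
#' @param vbar Partial specific volume (ml/g), in (0.5, 1.0).
#' @return Corrected s20,w (svedbergs).
#' @export
s20w_correct <- function(s_obs, density, viscosity, vbar = 0.73) {
  rho_w <- 0.99823; eta_w <- 1.002
  if (density <= 0 || viscosity <= 0) stop("density and viscosity must be > 0")
  if (vbar <= 0.5 || vbar >= 1.0) stop("vbar must lie in (0.5, 1.0)")
  buoy <- 1 - vbar * density
  if (buoy <= 0) stop("flotation regime: (1 - vbar * rho) <= 0")
  s_obs * (viscosity / eta_w) * (1 - vbar * rho_w) / buoy
}

#' Solvent conditions of 2 M sucrose
#'
#' Density and viscosity of approximately 2 M (~55% w/w at the densities
#' used here) aqueous sucrose near 10 degrees C, from standard sucrose
#' tables (CRC Handbook / Barber 1966 polynomial fits), shipped as package
#' defaults because high-viscosity runs are performed in this solvent.
#'
#' @return List with `density` (g/ml), `viscosity` (cP), `temperature_C`.
#' @export
sucrose_2M_conditions <- function() {
  list(density = 1.25, viscosity = 15, temperature_C = 11)
}

#' Inclusion fraction from a high-viscosity sedimentation run
#'
#' In 2 M sucrose at low rotor speed only inclusions sediment; every other
#' Httex1 species stays uniformly distributed. The scans are decomposed into
#' a non-sedimenting constant plus a moving-boundary amplitude (the latter
#' fitted over a grid of apparent sedimentation coefficients), both
#' referenced to the earliest-scan total, and the inclusion fraction is the
#' boundary share of the total signal.
#'
#' @param scans `aggflux_scans` from a high-viscosity run; must include an
#'   early near-uniform scan and later scans with a depleted region.
#' @param s_grid Apparent-s grid for the sedimenting component (svedbergs).
#'   By default it is derived from the scan geometry: from the slowest
#'   boundary that traverses at least 10% of the solution column by the last
#'   scan (anything slower is indistinguishable from the non-sedimenting
#'   component) up to the fastest boundary still inside the cell at the
#'   first scan.
#' @param edge_width Boundary edge width used in the model (cm).
#' @return List with `p_inc`, `sedimenting`, `non_sedimenting` (amplitudes
#'   at t = 0 reference), `total`, and a `diagnostic` message when no
#'   boundary is detectable.
#' @export
inclusion_fraction <- function(scans, s_grid = NULL, edge_width = 0.005) {
  if (length(scans) < 2) stop("need at least an early and a late scan")
  if (is.null(s_grid)) {
    sc1 <- scans[[1]]
    omega <- 2 * pi * sc1$rotor_rpm / 60
    times <- vapply(scans, `[[`, numeric(1), "time_s")
    col_h <- sc1$base_cm - sc1$meniscus_cm
    s_min <- log(1 + 0.1 * col_h / sc1$meniscus_cm) /
      (omega^2 * max(times)) * 1e13
    s_max <- log(sc1$base_cm / sc1$meniscus_cm) /
      (omega^2 * min(times)) * 1e13
    s_grid <- 10^seq(log10(s_min), log10(s_max), length.out = 30)
  }
  des <- lsgs_design(scans, s_grid, edge_width)
  ds <- grid_ds(s_grid)
  fit <- nnls_penalized(des$A, des$b, ds, 0, baseline = TRUE)
  sed <- sum(fit$c)
  nonsed <- fit$baseline
  total <- sed + nonsed
  diagnostic <- NULL
  if (total <= 0) {
    diagnostic <- "no signal detected"
    p <- NA_real_
  } else {
    p <- sed / total
    if (sed / total < 1e-3 && nonsed > 0)
      diagnostic <- "no detectable sedimenting boundary"
  }
  list(p_inc = p, sedimenting = sed, non_sedimenting = nonsed,
       total = total, diagnostic = diagnostic)
}

#' Loading signal from the earliest scan
#'
#' The plateau of the earliest scan, corrected back to time zero by the
#' radial-dilution factor `exp(2 omega^2 s t)` for a known (or fitted)
#' sedimentation coefficient.
#'
#' @param scans `aggflux_scans`.
#' @param s Sedimentation coefficient used for the dilution correction
#'   (svedbergs); 0 applies no correction.
#' @param plateau_quantile Radial range (upper fraction of the cell) over
#'   which the plateau is taken as a median.
#' @return Loading signal (a.u.).
#' @export
total_signal <- function(scans, s = 0, plateau_quantile = 0.4) {
  if (length(scans) == 0) stop("empty scan list")
  times <- vapply(scans, `[[`, numeric(1), "time_s")
  sc <- scans[[which.min(times)]]
  omega <- 2 * pi * sc$rotor_rpm / 60
  cut <- sc$meniscus_cm + (1 - plateau_quantile) *
    (sc$base_cm - sc$meniscus_cm)
  plateau <- stats::median(sc$signal[sc$radius_cm >= cut])
  plateau * exp(2 * omega^2 * s * 1e-13 * sc$time_s)
}
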