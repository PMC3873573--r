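#' @name gating
#' @title Reproducible quantile-based gating tree
#'
#' @description
#' The gating tree classifies cytometer events in five stages, each a pure
#' function of the event table and explicit control populations:
#' \enumerate{
#'   \item \code{\link{pregate}}: remove the smallest particles and clumped
#'     cells on the scatter channel;
#'   \item \code{\link{transfection_gate}}: exclude untransfected cells by a
#'     quantile threshold referenced to an untransfected control, passed if
#'     either reporter channel exceeds it (so leached, Cerulean-dark ghosts
#'     are retained via membrane mKate2);
#'   \item \code{\link{classify_MDL}}: a robust line through the correlated
#'     Cerulean-mKate2 cloud defines the Major (M) population; events with a
#'     large Cerulean excess over the band are Debris (D, free inclusions),
#'     and mKate2-bright but Cerulean-dark events are Leached (L);
#'   \item \code{\link{sytox_gate}}: membrane-permeability staining
#'     thresholded against an unstained control;
#'   \item \code{\link{pulsa_gate}} and \code{\link{flash_gate}}: pulse-shape
#'     and FlAsH-reactivity classification of M events against a
#'     diffuse (25Q-like) calibration control.
#' }
#' Every threshold is derived as a stated quantile of a control population
#' and stored with provenance in a gate set, in place of hand-drawn gates.
#' All intensities are log-transformed as \code{log10(signal + 1)}; events
#' that would be negative are clamped to zero and counted.
NULL

log10p <- function(x) log10(pmax(x, 0) + 1)

#' Pre-gate on the scatter channel
#'
#' Removes events below a size floor (exclusive lower bound) and clumped
#' cells above a doublet bound on the scatter area/height ratio. When bounds
#' are not supplied they are derived from the event cloud itself: the floor
#' is a quarter of the median scatter height, the doublet bound 1.5 times the
#' median area/height ratio.
#'
#' @param events An `aggflux_events` table.
#' @param size_floor Scatter-height floor (a.u.).
#' @param doublet_ratio Maximum scatter area/height ratio.
#' @return List with `mask` (logical), `size_floor`, `doublet_ratio`.
#' @export
pregate <- function(events, size_floor = NULL, doublet_ratio = NULL) {
  if (NROW(events) == 0) stop("empty event table")
  if (is.null(size_floor))
    size_floor <- 0.25 * stats::median(events$ssc_h)
  if (is.null(doublet_ratio))
    doublet_ratio <- 1.5 * stats::median(events$ssc_a /
                                           pmax(events$ssc_h, .Machine$double.eps))
  mask <- events$ssc_h >= size_floor &
    events$ssc_a / pmax(events$ssc_h, .Machine$double.eps) <= doublet_ratio
  list(mask = mask, size_floor = size_floor, doublet_ratio = doublet_ratio)
}

#' Transfection gate referenced to an untransfected control
#'
#' The threshold is the 99.9th percentile of the control's per-event maximum
#' of the two reporter areas; an event passes if it exceeds the threshold in
#' either reporter channel, so cells that have leached their cytosolic
#' Cerulean are retained through membrane mKate2.
#'
#' @param events Event table.
#' @param reference Untransfected control events.
#' @param q Reference quantile (default 0.999).
#' @return List with `mask`, `threshold`.
#' @export
transfection_gate <- function(events, reference, q = 0.999) {
  if (NROW(reference) == 0) stop("empty untransfected reference")
  ref_max <- pmax(reference$cer_a, reference$mk_a)
  thr <- as.numeric(stats::quantile(ref_max, q, names = FALSE))
  if (NROW(events) > 0) {
    samp_med <- stats::median(pmax(events$cer_a, events$mk_a))
    if (mean(ref_max > samp_med) > 0.2)
      stop("untransfected reference overlaps the sample by more than 20%; ",
           "controls appear mislabeled")
  }
  mask <- events$cer_a > thr | events$mk_a > thr
  list(mask = mask, threshold = thr)
}

# deterministic Theil-Sen estimate: slopes of points paired across the
# x-ordered half-split, robust to a minority of off-band events
theil_sen <- function(x, y) {
  o <- order(x)
  x <- x[o]; y <- y[o]
  n <- length(x)
  h <- floor(n / 2)
  i <- seq_len(h); j <- i + h
  dx <- x[j] - x[i]
  ok <- abs(dx) > .Machine$double.eps
  slope <- stats::median((y[j] - y[i])[ok] / dx[ok])
  intercept <- stats::median(y - slope * x)
  list(slope = slope, intercept = intercept)
}

#' Classify transfected events into M, D and L populations
#'
#' A robust (Theil-Sen) line is fitted through the dense central cloud in
#' log-Cerulean versus log-mKate2 space. Events whose Cerulean excess over
#' the band exceeds `k` times the MAD of the residuals are Debris (free
#' inclusions with remnants); events with Cerulean at or below the
#' transfection threshold but mKate2 above it are Leached ghosts; everything
#' else is the Major population of intact cells.
#'
#' @param events Transfected event table.
#' @param transfection_threshold Threshold from [transfection_gate()].
#' @param k Band half-width in units of residual MAD.
#' @param fit Optional precomputed fit (list with `slope`, `intercept`,
#'   `mad`), e.g. from a stored gate set; when supplied the line is reused
#'   rather than refitted so labelling is bit-for-bit reproducible.
#' @return List with `labels` (factor M/D/L), `fit` (slope, intercept, mad),
#'   `k`, `n_clamped` (events clamped at zero before log transform).
#' @export
classify_MDL <- function(events, transfection_threshold, k = 5, fit = NULL) {
  n <- NROW(events)
  if (n < 50 && is.null(fit))
    stop("too few events (< 50) for a stable M-band fit")
  is_L <- events$cer_a <= transfection_threshold &
    events$mk_a > transfection_threshold
  x <- log10p(events$mk_a)
  y <- log10p(events$cer_a)
  n_clamped <- sum(events$cer_a < 0 | events$mk_a < 0)
  if (is.null(fit)) {
    fit <- theil_sen(x[!is_L], y[!is_L])
    fit$mad <- stats::mad((y - fit$intercept - fit$slope * x)[!is_L])
  }
  resid <- y - fit$intercept - fit$slope * x
  labels <- rep("M", n)
  labels[resid > k * fit$mad] <- "D"
  labels[is_L] <- "L"
  list(labels = factor(labels, levels = c("M", "D", "L")),
       fit = fit, k = k, n_clamped = n_clamped)
}

#' SYTOX viability gate referenced to an unstained control
#'
#' @param events Event table.
#' @param unstained_reference Unstained control events.
#' @param q Reference quantile (default 0.999).
#' @return List with `labels` (factor "+"/"-") and `threshold`.
#' @export
sytox_gate <- function(events, unstained_reference, q = 0.999) {
  if (!"sytox_a" %in% names(events)) stop("APC (SYTOX) channel missing")
  if (NROW(unstained_reference) == 0) stop("empty unstained reference")
  thr <- as.numeric(stats::quantile(unstained_reference$sytox_a, q,
                                    names = FALSE))
  labels <- factor(ifelse(events$sytox_a > thr, "+", "-"),
                   levels = c("+", "-"))
  list(labels = labels, threshold = thr)
}

# quantile envelope of y over deciles of x, evaluated for new data;
# events beyond the calibration range are clamped to the outer deciles
decile_envelope <- function(x_cal, y_cal, q, n_bins = 10) {
  edges <- unique(stats::quantile(x_cal, seq(0, 1, length.out = n_bins + 1),
                                  names = FALSE))
  bin <- cut(x_cal, edges, include.lowest = TRUE, labels = FALSE)
  env <- tapply(y_cal, bin, stats::quantile, probs = q, names = FALSE)
  list(edges = edges, envelope = as.numeric(env))
}

envelope_lookup <- function(env, x) {
  b <- findInterval(x, env$edges, all.inside = TRUE)
  b <- pmin(pmax(b, 1), length(env$envelope))
  env$envelope[b]
}

#' Pulse-shape (PulSA) gate for inclusion-bearing cells
#'
#' Cells whose Cerulean is concentrated in an inclusion transit the laser as
#' a near-point source: at matched pulse height their pulse width falls far
#' below that of cells with dispersed cytosolic Httex1. The boundary is the
#' lower quantile envelope of a known-diffuse (25Q-like) calibration
#' population's width, taken per height decile; events below the envelope
#' are classified `i`, the rest `ni`.
#'
#' @param events M-population event table to classify.
#' @param calibration Diffuse-control events (>= 500 required).
#' @param q Envelope quantile (default 0.005).
#' @param envelope Optional precomputed envelope (from a gate set).
#' @return List with `labels` (factor i/ni) and `envelope`.
#' @export
pulsa_gate <- function(events, calibration = NULL, q = 0.005,
                       envelope = NULL) {
  if (is.null(envelope)) {
    if (NROW(calibration) < 500)
      stop("PulSA calibration requires at least 500 diffuse-control events")
    envelope <- decile_envelope(log10p(calibration$cer_h),
                                calibration$cer_w, q)
  }
  bound <- envelope_lookup(envelope, log10p(events$cer_h))
  labels <- factor(ifelse(events$cer_w < bound, "i", "ni"),
                   levels = c("i", "ni"))
  list(labels = labels, envelope = envelope)
}

#' FlAsH-reactivity gate for biochemically aggregated Httex1
#'
#' The biarsenical dye binds the tetracysteine tag of Httex1 only in the
#' monomer, so cells whose FlAsH/Cerulean ratio falls below the lower
#' envelope of a monomeric (25Q-like) reference are poor-FlAsH-reactive
#' (PFR): most of their Httex1 is self-aggregated. The envelope is the
#' reference's lower quantile of log10(FlAsH/Cerulean) per Cerulean decile.
#'
#' @param events M-population event table to classify.
#' @param reference Monomeric-control events.
#' @param q Envelope quantile (default 0.005).
#' @param envelope Optional precomputed envelope.
#' @return List with `labels` (factor PFR/high) and `envelope`.
#' @export
flash_gate <- function(events, reference = NULL, q = 0.002,
                       envelope = NULL) {
  if (is.null(envelope)) {
    if (NROW(reference) == 0) stop("empty FlAsH reference")
    ratio_ref <- log10p(reference$fl_a) - log10p(reference$cer_a)
    envelope <- decile_envelope(log10p(reference$cer_a), ratio_ref, q)
  }
  ratio <- log10p(events$fl_a) - log10p(events$cer_a)
  bound <- envelope_lookup(envelope, log10p(events$cer_a))
  labels <- factor(ifelse(ratio < bound, "PFR", "high"),
                   levels = c("PFR", "high"))
  list(labels = labels, envelope = envelope)
}

#' Derive a complete gate set from controls
#'
#' Computes every threshold of the gating tree from the sample and its
#' control populations and records the provenance of each. The returned gate
#' set makes [apply_gates()] a pure function: re-applying the same gate set
#' to the same events reproduces labels bit-for-bit.
#'
#' @param events Sample events (used for the pre-gate bounds and M-band fit).
#' @param untransfected Untransfected control events.
#' @param unstained Unstained (SYTOX) control events.
#' @param diffuse_calibration Diffuse 25Q-like control events, themselves
#'   pre-gated internally, used for the PulSA and FlAsH envelopes.
#' @param k_mdl M-band half width in residual MADs.
#' @param q_transfection,q_sytox,q_pulsa,q_flash Quantiles of the respective
#'   control-derived thresholds.
#' @return List of class `aggflux_gateset`.
#' @export
derive_gateset <- function(events, untransfected, unstained,
                           diffuse_calibration, k_mdl = 5,
                           q_transfection = 0.999, q_sytox = 0.999,
                           q_pulsa = 0.005, q_flash = 0.002) {
  pg <- pregate(events)
  tf <- transfection_gate(events[pg$mask, , drop = FALSE], untransfected,
                          q = q_transfection)
  ev_t <- events[pg$mask, , drop = FALSE][tf$mask, , drop = FALSE]
  mdl <- classify_MDL(ev_t, tf$threshold, k = k_mdl)
  sy <- sytox_gate(ev_t, unstained, q = q_sytox)
  cal_pg <- pregate(diffuse_calibration,
                    size_floor = pg$size_floor,
                    doublet_ratio = pg$doublet_ratio)
  cal <- diffuse_calibration[cal_pg$mask, , drop = FALSE]
  cal <- cal[cal$cer_a > tf$threshold, , drop = FALSE]
  pu <- pulsa_gate(ev_t[mdl$labels == "M", , drop = FALSE], cal, q = q_pulsa)
  fg <- flash_gate(ev_t[mdl$labels == "M", , drop = FALSE], cal, q = q_flash)
  gs <- list(
    size_floor = pg$size_floor, doublet_ratio = pg$doublet_ratio,
    transfection_threshold = tf$threshold,
    mdl_fit = mdl$fit, k_mdl = k_mdl,
    sytox_threshold = sy$threshold,
    pulsa_envelope = pu$envelope,
    flash_envelope = fg$envelope,
    log_transform = "log10(signal + 1), negatives clamped to 0",
    provenance = list(
      pregate = "bounds derived from sample scatter cloud",
      transfection = sprintf("%.3f quantile of untransfected max(reporter)",
                             q_transfection),
      mdl = sprintf("Theil-Sen band, +/- %g MAD", k_mdl),
      sytox = sprintf("%.3f quantile of unstained APC", q_sytox),
      pulsa = sprintf("%.4f width quantile per height decile of diffuse control",
                      q_pulsa),
      flash = sprintf("%.4f ratio quantile per Cerulean decile of monomer control",
                      q_flash)
    )
  )
  class(gs) <- "aggflux_gateset"
  gs
}

#' Apply a gate set to an event table
#'
#' Deterministically labels every event through the full gating tree. PulSA
#' and FlAsH labels are assigned only to transfected M events (others are
#' `NA`); every transfected event carries exactly one of M/D/L, so child
#' counts sum exactly to their parent at every level.
#'
#' @param events Event table.
#' @param gateset An `aggflux_gateset` from [derive_gateset()].
#' @return Data frame of per-event labels: `pregate`, `transfected`, `mdl`,
#'   `sytox`, `pulsa`, `flash`.
#' @export
apply_gates <- function(events, gateset) {
  stopifnot(inherits(gateset, "aggflux_gateset"))
  n <- NROW(events)
  lab <- data.frame(
    pregate = pregate(events, gateset$size_floor, gateset$doublet_ratio)$mask,
    transfected = FALSE,
    mdl = factor(rep(NA_character_, n), levels = c("M", "D", "L")),
    sytox = factor(rep(NA_character_, n), levels = c("+", "-")),
    pulsa = factor(rep(NA_character_, n), levels = c("i", "ni")),
    flash = factor(rep(NA_character_, n), levels = c("PFR", "high"))
  )
  thr <- gateset$transfection_threshold
  lab$transfected <- lab$pregate & (events$cer_a > thr | events$mk_a > thr)
  ti <- which(lab$transfected)
  if (length(ti)) {
    ev_t <- events[ti, , drop = FALSE]
    lab$mdl[ti] <- classify_MDL(ev_t, thr, k = gateset$k_mdl,
                                fit = gateset$mdl_fit)$labels
    lab$sytox[ti] <- factor(ifelse(ev_t$sytox_a > gateset$sytox_threshold,
                                   "+", "-"), levels = c("+", "-"))
    mi <- ti[lab$mdl[ti] == "M"]
    if (length(mi)) {
      ev_m <- events[mi, , drop = FALSE]
      lab$pulsa[mi] <- pulsa_gate(ev_m,
                                  envelope = gateset$pulsa_envelope)$labels
      lab$flash[mi] <- flash_gate(ev_m,
                                  envelope = gateset$flash_envelope)$labels
    }
  }
  lab
}

#' Serialize / read a gate set as JSON
#'
#' @param gateset An `aggflux_gateset`.
#' @param path File path.
#' @return `read_gateset` returns an `aggflux_gateset`.
#' @export
write_gateset <- function(gateset, path) {
  jsonlite::write_json(unclass(gateset), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_gateset
#' @export
read_gateset <- function(path) {
  gs <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(gs) <- "aggflux_gateset"
  gs
}
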