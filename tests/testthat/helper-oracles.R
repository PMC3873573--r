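# Independent oracles, deliberately implemented apart from the package code.

# numeric convolution of the two-component transit profile with the beam
pulse_oracle <- function(Ad, Ap, diam, beam = 1, thr = 2,
                         diffuse_frac = 0.25, punct = 0.3) {
  du <- 0.02
  u <- seq(-50, 50, by = du)
  src <- Ad * stats::dnorm(u, 0, diffuse_frac * diam) +
    Ap * stats::dnorm(u, 0, punct)
  prof <- vapply(u, function(t) sum(src * stats::dnorm(t - u, 0, beam)) * du,
                 numeric(1))
  c(height = max(prof), area = pracma::trapz(u, prof),
    width = sum(prof > thr) * du)
}

# brute-force ls-g*(s) design on an arbitrary (e.g. 10x finer) grid
brute_lsgs <- function(scans, s_grid, edge_width = 0.005) {
  om <- 2 * pi * scans[[1]]$rotor_rpm / 60
  rows <- lapply(scans, function(sc) {
    sapply(s_grid, function(s) {
      rb <- sc$meniscus_cm * exp(om^2 * s * 1e-13 * sc$time_s)
      exp(-2 * om^2 * s * 1e-13 * sc$time_s) *
        stats::plogis((sc$radius_cm - rb) / edge_width)
    })
  })
  A <- cbind(do.call(rbind, rows), 1)
  b <- unlist(lapply(scans, `[[`, "signal"))
  x <- pracma::lsqnonneg(A, b)$x
  ds <- diff(s_grid)
  ds <- c(ds[1] / 2, (s_grid[-c(1, 2)] - s_grid[1:(length(s_grid) - 2)]) / 2,
          ds[length(ds)] / 2)
  list(s = s_grid, g = x[seq_along(s_grid)] / ds, c = x[seq_along(s_grid)])
}

# abundance-weighted pooling by direct per-cell summation
pool_oracle <- function(cells) {
  keep <- cells$status %in% c("live", "dead_intact", "lysed_debris")
  num <- c(0, 0, 0); den <- 0
  for (i in which(keep)) {
    w <- cells$E_htt[i]
    num <- num + w * c(cells$f_mono[i], cells$f_olig[i], cells$f_inc[i])
    den <- den + w
  }
  num / den
}

local_maxima <- function(g) which(diff(sign(diff(g))) < 0) + 1
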