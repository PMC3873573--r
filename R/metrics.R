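wilson_interval <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = ctr - hw, upper = ctr + hw)
}

#' Expression-binned inclusion kinetics
#'
#' Bins PulSA-labelled events into log-spaced Cerulean expression bins over
#' the central 99% of the intensity range and reports the fraction of cells
#' with inclusions (i population) per bin, with Wilson confidence intervals.
#' Bins holding fewer than 20 events are flagged as sparse.
#'
#' @param events Event table.
#' @param labels Label table from [apply_gates()].
#' @param n_bins Number of log-spaced bins (default 8).
#' @param min_count Sparse-bin flag threshold.
#' @return Data frame with bin edges and centres, counts, i-fraction,
#'   Wilson interval and `flagged`.
#' @export
bin_by_expression <- function(events, labels, n_bins = 8, min_count = 20) {
  sel <- !is.na(labels$pulsa)
  if (!any(sel)) stop("no PulSA-labelled events")
  x <- events$cer_a[sel]
  is_i <- labels$pulsa[sel] == "i"
  rng <- stats::quantile(x, c(0.005, 0.995), names = FALSE)
  rng[1] <- max(rng[1], .Machine$double.eps)
  edges <- 10^seq(log10(rng[1]), log10(rng[2]), length.out = n_bins + 1)
  bin <- cut(x, edges, include.lowest = TRUE, labels = FALSE)
  keep <- !is.na(bin)
  bin <- bin[keep]; is_i <- is_i[keep]
  cnt <- tabulate(bin, nbins = n_bins)
  inc <- tabulate(bin[is_i], nbins = n_bins)
  ci <- t(vapply(seq_len(n_bins),
                 function(b) wilson_interval(inc[b], cnt[b]), numeric(2)))
  data.frame(
    bin = seq_len(n_bins),
    lower_edge = edges[-(n_bins + 1)], upper_edge = edges[-1],
    count = cnt, n_inclusion = inc,
    i_fraction = ifelse(cnt > 0, inc / cnt, NA_real_),
    ci_lower = ci[, 1], ci_upper = ci[, 2],
    flagged = cnt < min_count
  )
}

#' Gated death-rate statistic
#'
#' Estimates the total fraction of dead cells from the gated populations by
#' summing SYTOX-reactive events, additional SYTOX-negative leached ghosts
#' (L) and SYTOX-negative free-inclusion debris (D), each D event counting
#' as the remnant of one cell. Subpopulation scopes attribute D events to
#' the inclusion-bearing (i) scope and L events to the no-inclusion (ni)
#' scope:
#' \describe{
#'   \item{all}{numerator |SYTOX+| + |SYTOX- in L| + |SYTOX- in D|,
#'     denominator |M| + |L| + |D|;}
#'   \item{i}{numerator |SYTOX+ in i| + |SYTOX- in D|, denominator
#'     |i| + |D|;}
#'   \item{ni}{numerator |SYTOX+ in ni| + |SYTOX- in L|, denominator
#'     |ni| + |L|.}
#' }
#' The numerator components are disjoint by construction (SYTOX+ events are
#' excluded from the SYTOX- terms); this is asserted on every call.
#'
#' @param labels Label table from [apply_gates()].
#' @param scope One of "all", "i", "ni".
#' @return List of class `aggflux_deathrate` with the component counts,
#'   denominator and `rate`.
#' @examples
#' # 850 M cells (50 SYTOX+), 100 L (20+), 50 D (5+) -> rate 0.200
#' @export
death_rate <- function(labels, scope = c("all", "i", "ni")) {
  scope <- match.arg(scope)
  t <- labels[labels$transfected & !is.na(labels$mdl), , drop = FALSE]
  sy_pos <- t$sytox == "+"
  if (scope == "all") {
    n_sytox_pos <- sum(sy_pos)
    n_leached_sytox_neg <- sum(!sy_pos & t$mdl == "L")
    n_debris_sytox_neg <- sum(!sy_pos & t$mdl == "D")
    denominator <- nrow(t)
  } else if (scope == "i") {
    n_sytox_pos <- sum(sy_pos & t$pulsa %in% "i")
    n_leached_sytox_neg <- 0L
    n_debris_sytox_neg <- sum(!sy_pos & t$mdl == "D")
    denominator <- sum(t$pulsa %in% "i") + sum(t$mdl == "D")
  } else {
    n_sytox_pos <- sum(sy_pos & t$pulsa %in% "ni")
    n_leached_sytox_neg <- sum(!sy_pos & t$mdl == "L")
    n_debris_sytox_neg <- 0L
    denominator <- sum(t$pulsa %in% "ni") + sum(t$mdl == "L")
  }
  if (denominator == 0) stop("zero denominator for scope '", scope, "'")
  numerator <- n_sytox_pos + n_leached_sytox_neg + n_debris_sytox_neg
  # disjointness: components partition the counted events
  stopifnot(numerator <= denominator)
  structure(list(scope = scope,
                 n_sytox_pos = n_sytox_pos,
                 n_leached_sytox_neg = n_leached_sytox_neg,
                 n_debris_sytox_neg = n_debris_sytox_neg,
                 denominator = denominator,
                 rate = numerator / denominator),
            class = "aggflux_deathrate")
}

#' Mean mKate2/Cerulean reporter ratio of live M cells
#'
#' @param events Event table.
#' @param labels Label table.
#' @param scope "i" or "ni" (PulSA subpopulation of live M cells).
#' @return List with `mean`, `median`, `n`.
#' @export
reporter_ratio <- function(events, labels, scope = c("ni", "i")) {
  scope <- match.arg(scope)
  sel <- labels$transfected & labels$mdl %in% "M" & labels$sytox %in% "-" &
    labels$pulsa %in% scope
  if (!any(sel)) stop("no live M events in scope '", scope, "'")
  r <- events$mk_a[sel] / pmax(events$cer_a[sel], .Machine$double.eps)
  list(mean = mean(r), median = stats::median(r), n = sum(sel))
}

#' Log-spaced intensity histogram
#'
#' @param events Event table.
#' @param labels Label table; the histogram is over live transfected M cells.
#' @param channel Column name, e.g. `"cer_a"` or `"mk_a"`.
#' @param n_bins Number of log-spaced bins.
#' @param breaks Optional fixed bin edges (for comparing arms/replicates).
#' @return Data frame with bin edges, centres, counts and density.
#' @export
intensity_histogram <- function(events, labels, channel = "cer_a",
                                n_bins = 40, breaks = NULL) {
  sel <- labels$transfected & labels$mdl %in% "M" & labels$sytox %in% "-"
  x <- events[[channel]][sel]
  x <- x[x > 0]
  if (!length(x)) stop("no events for intensity histogram")
  if (is.null(breaks))
    breaks <- 10^seq(log10(min(x)), log10(max(x)), length.out = n_bins + 1)
  h <- graphics::hist(x[x >= breaks[1] & x <= breaks[length(breaks)]],
                      breaks = breaks, plot = FALSE)
  data.frame(lower_edge = utils::head(h$breaks, -1),
             upper_edge = h$breaks[-1],
             mid = h$mids, count = h$counts, density = h$density)
}

#' Relative transfected-cell density
#'
#' Cell counts per unit acquired volume (a proxy of culture growth), as the
#' cytometer's count rate at a standard flow rate measures it, normalized to
#' a reference arm.
#'
#' @param counts Transfected event counts per sample.
#' @param volumes Acquired volumes (or duration x flow rate) per sample.
#' @param arms Arm labels per sample.
#' @param reference Reference arm (default "alone").
#' @return Data frame with per-sample density and density relative to the
#'   reference arm mean.
#' @export
cell_density <- function(counts, volumes, arms, reference = "alone") {
  if (!reference %in% arms) stop("reference arm '", reference, "' missing")
  density <- counts / volumes
  rel <- density / mean(density[arms == reference])
  data.frame(arm = arms, density = density, relative_density = rel)
}

#' Fraction of transfected cells that are PFR and lack an inclusion
#'
#' Cells that are poor-FlAsH-reactive yet have no inclusion are enriched
#' with self-aggregated oligomeric Httex1 -- an intermediate stage between
#' dispersed monomer and inclusion.
#'
#' @param labels Label table from [apply_gates()].
#' @return List with `n_pfr_ni`, `n_transfected`, `fraction` and Wilson
#'   interval bounds.
#' @export
pfr_ni_fraction <- function(labels) {
  n_t <- sum(labels$transfected)
  if (n_t == 0) stop("no transfected events")
  n_pn <- sum(labels$transfected & labels$flash %in% "PFR" &
                labels$pulsa %in% "ni")
  ci <- wilson_interval(n_pn, n_t)
  list(n_pfr_ni = n_pn, n_transfected = n_t, fraction = n_pn / n_t,
       ci_lower = ci[[1]], ci_upper = ci[[2]])
}

#' Holm-Sidak step-down adjustment
#'
#' Sorts the raw p-values ascending and sets
#' `adj_p(j) = max over j' <= j of 1 - (1 - p(j'))^(k - j' + 1)`, clipped at
#' 1, returning the adjusted values in the original order.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values (same order as input).
#' @examples
#' holm_sidak_adjust(c(0.01, 0.03, 0.04))  # 0.0297 0.0591 0.0591
#' @export
holm_sidak_adjust <- function(p) {
  k <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- pmin(cummax(1 - (1 - ps)^(k - seq_len(k) + 1)), 1)
  out <- numeric(k)
  out[o] <- adj
  out
}

#' Fixed-effects ANOVA with Holm-Sidak comparisons against a control arm
#'
#' One-way (treatment arm only) or three-way (arm x polyQ x time, with all
#' interactions) fixed-effects analysis of variance by the standard
#' sums-of-squares decomposition, followed by pairwise comparisons of every
#' treatment arm against the control arm using the pooled residual variance,
#' adjusted by the Holm-Sidak step-down.
#'
#' @param data Data frame of replicate-level values.
#' @param value Name of the response column.
#' @param design "one-way" or "three-way".
#' @param arm,polyQ,time Names of the factor columns.
#' @param control Control arm label (default "alone").
#' @return List with `omnibus` (per-factor F and p), `pairwise` (arm,
#'   difference, raw and adjusted p) and the residual degrees of freedom.
#' @export
anova_holm_sidak <- function(data, value = "value",
                             design = c("one-way", "three-way"),
                             arm = "arm", polyQ = "polyQ", time = "time",
                             control = "alone") {
  design <- match.arg(design)
  data[[arm]] <- factor(data[[arm]])
  if (!control %in% levels(data[[arm]]))
    stop("control arm '", control, "' not present")
  if (design == "three-way") {
    data[[polyQ]] <- factor(data[[polyQ]])
    data[[time]] <- factor(data[[time]])
    cells <- table(data[[arm]], data[[polyQ]], data[[time]])
    if (any(cells == 0))
      stop("unbalanced three-way design: empty cells")
    if (any(cells < 2))
      stop("at least 2 replicates per design cell are required")
    form <- stats::as.formula(paste(value, "~", arm, "*", polyQ, "*", time))
    factors <- c(arm, polyQ, time)
  } else {
    if (any(table(data[[arm]]) < 2))
      stop("at least 2 replicates per arm are required")
    form <- stats::as.formula(paste(value, "~", arm))
    factors <- arm
  }
  fit <- stats::aov(form, data = data)
  tab <- summary(fit)[[1]]
  rn <- trimws(rownames(tab))
  mse <- tab["Residuals", "Mean Sq"]
  df_res <- tab["Residuals", "Df"]
  if (!is.finite(mse) || mse <= 1e-12 * max(mean(data[[value]]^2), 1e-300))
    stop("degenerate input: zero residual variance, F undefined")
  omnibus <- data.frame(factor = rn[rn != "Residuals"],
                        F = tab[rn != "Residuals", "F value"],
                        p = tab[rn != "Residuals", "Pr(>F)"])
  # pairwise arm-vs-control on marginal means, pooled residual variance
  arms <- setdiff(levels(data[[arm]]), control)
  y <- data[[value]]
  g <- data[[arm]]
  diff <- se <- numeric(length(arms))
  for (j in seq_along(arms)) {
    a <- arms[j]
    n1 <- sum(g == a); n0 <- sum(g == control)
    diff[j] <- mean(y[g == a]) - mean(y[g == control])
    se[j] <- sqrt(mse * (1 / n1 + 1 / n0))
  }
  p_raw <- 2 * stats::pt(abs(diff / se), df_res, lower.tail = FALSE)
  pairwise <- data.frame(arm = arms, difference = diff, se = se,
                         p_raw = p_raw,
                         p_adjusted = holm_sidak_adjust(p_raw))
  list(design = design, omnibus = omnibus, pairwise = pairwise,
       df_residual = df_res)
}
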