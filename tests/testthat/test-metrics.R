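# build a label table directly (counts in, labels out)
make_labels <- function(nM, nM_pos, nL, nL_pos, nD, nD_pos,
                        n_i = 0, n_i_pos = 0) {
  n <- nM + nL + nD
  mdl <- rep(c("M", "L", "D"), c(nM, nL, nD))
  sytox <- rep("-", n)
  sytox[seq_len(nM_pos)] <- "+"
  sytox[nM + seq_len(nL_pos)] <- "+"
  sytox[nM + nL + seq_len(nD_pos)] <- "+"
  pulsa <- rep(NA_character_, n)
  pulsa[seq_len(nM)] <- "ni"
  if (n_i > 0) {
    # i cells placed first among M; overlap n_i_pos of them with SYTOX+
    pulsa[seq_len(n_i)] <- "i"
  }
  data.frame(pregate = TRUE, transfected = TRUE,
             mdl = factor(mdl, levels = c("M", "D", "L")),
             sytox = factor(sytox, levels = c("+", "-")),
             pulsa = factor(pulsa, levels = c("i", "ni")),
             flash = factor(NA_character_, levels = c("PFR", "high")))
}

test_that("death rate reproduces the hand-countable gated sum", {
  lab <- make_labels(850, 50, 100, 20, 50, 5)
  dr <- death_rate(lab, "all")
  expect_identical(dr$rate, 0.200)
  expect_identical(dr$n_sytox_pos, 75L)
  expect_identical(dr$n_leached_sytox_neg, 80L)
  expect_identical(dr$n_debris_sytox_neg, 45L)
  expect_identical(dr$denominator, 1000L)
  # no SYTOX+, no L, no D
  lab0 <- make_labels(500, 0, 0, 0, 0, 0)
  expect_equal(death_rate(lab0, "all")$rate, 0)
  expect_error(death_rate(lab0[0, ], "all"), "zero denominator")
  # subpopulation scopes: D -> i, L -> ni
  lab_i <- make_labels(850, 50, 100, 20, 50, 5, n_i = 200)
  dri <- death_rate(lab_i, "i")
  expect_identical(dri$denominator, 250L)   # |i| + |D|
  expect_identical(dri$n_debris_sytox_neg, 45L)
  drn <- death_rate(lab_i, "ni")
  expect_identical(drn$denominator, 750L)   # |ni| + |L|
  expect_identical(drn$n_leached_sytox_neg, 80L)
  # row-permutation invariance
  perm <- lab_i[sample.int(nrow(lab_i)), ]
  expect_identical(death_rate(perm, "all")$rate,
                   death_rate(lab_i, "all")$rate)
})

test_that("expression-binned inclusion curve behaves as specified", {
  # all ni -> all zero fractions
  ev <- data.frame(cer_a = stats::rlnorm(500, 6, 1))
  lab <- data.frame(pulsa = factor(rep("ni", 500), levels = c("i", "ni")))
  b <- bin_by_expression(ev, lab)
  expect_true(all(b$i_fraction[b$count > 0] == 0))
  # one event per bin, alternating labels: extreme fractions, all flagged
  ev1 <- data.frame(cer_a = 10^seq(1, 4.5, by = 0.5))
  lab1 <- data.frame(pulsa = factor(rep(c("i", "ni"), 4),
                                    levels = c("i", "ni")))
  b1 <- bin_by_expression(ev1, lab1, n_bins = 8)
  expect_true(all(b1$flagged))
  expect_true(all(b1$i_fraction[b1$count > 0] %in% c(0, 1)))
  # simulated expanded-polyQ run: fraction rises with expression bin
  q72 <- q72_fixture()
  b2 <- bin_by_expression(q72$events, q72$labels)
  ok <- !b2$flagged
  expect_gt(sum(ok), 4)
  fr <- b2$i_fraction[ok]
  expect_gt(fr[length(fr)], fr[1])
  expect_gt(stats::cor(seq_along(fr), fr, method = "spearman"), 0.7)
  expect_equal(sum(b2$count), sum(!is.na(q72$labels$pulsa) &
                                    q72$events$cer_a >= min(b2$lower_edge) &
                                    q72$events$cer_a <= max(b2$upper_edge)))
})

test_that("reporter ratio and intensity histogram basics", {
  ev <- data.frame(cer_a = c(10, 20, 40), mk_a = c(20, 40, 80))
  lab <- data.frame(pregate = TRUE, transfected = TRUE,
                    mdl = factor("M", levels = c("M", "D", "L")),
                    sytox = factor("-", levels = c("+", "-")),
                    pulsa = factor("ni", levels = c("i", "ni")),
                    flash = factor(NA, levels = c("PFR", "high")))
  lab <- lab[rep(1, 3), ]
  expect_equal(reporter_ratio(ev, lab, "ni")$mean, 2.0)
  expect_error(reporter_ratio(ev, lab, "i"), "no live M events")
  evh <- data.frame(cer_a = rep(100, 50), mk_a = rep(100, 50))
  h <- intensity_histogram(evh, lab[rep(1, 50), ], "cer_a", n_bins = 10)
  expect_equal(sum(h$count > 0), 1)
  expect_error(intensity_histogram(evh[0, ], lab[0, ]), "no events")
})

test_that("chaperone combination lowers Httex1 and raises the reporter ratio", {
  alone <- gate_arm(46, "alone", 4000, seed = 71)
  combo <- gate_arm(46, "hsp40+hsp70", 4000, seed = 73)
  rr_a <- reporter_ratio(alone$events, alone$labels, "ni")$mean
  rr_c <- reporter_ratio(combo$events, combo$labels, "ni")$mean
  expect_gt(rr_c, rr_a)
  # Cerulean abundance distribution shifts down (same fixed bins)
  br <- 10^seq(1, 6, length.out = 41)
  h_a <- intensity_histogram(alone$events, alone$labels, "cer_a", breaks = br)
  h_c <- intensity_histogram(combo$events, combo$labels, "cer_a", breaks = br)
  loc <- function(h) sum(h$count * log10(h$mid)) / sum(h$count)
  expect_lt(loc(h_c), loc(h_a) - 0.05)
  mode_bin <- function(h) which.max(h$count)
  expect_lte(mode_bin(h_c), mode_bin(h_a))
})

test_that("cell density normalizes counts per acquired volume", {
  d <- cell_density(c(1000, 1000), c(1, 1), c("alone", "hsp40"))
  expect_equal(d$relative_density, c(1, 1))
  d2 <- cell_density(c(1000, 1000), c(1, 0.5), c("alone", "hsp40"))
  expect_equal(d2$relative_density[2], 2)
  expect_error(cell_density(1, 1, "hsp40"), "reference arm")
  # chaperone arms accumulate at least as many transfected cells
  alone <- gate_arm(46, "alone", 4000, seed = 71)
  h40 <- gate_arm(46, "hsp40", 4000, seed = 75)
  d3 <- cell_density(c(sum(alone$labels$transfected),
                       sum(h40$labels$transfected)),
                     c(1, 1), c("alone", "hsp40"))
  expect_gte(d3$relative_density[2], 1)
})

test_that("PFR,ni fraction counts oligomer-enriched intermediates", {
  lab <- data.frame(pregate = TRUE, transfected = TRUE,
                    mdl = factor("M", levels = c("M", "D", "L")),
                    sytox = factor("-", levels = c("+", "-")),
                    pulsa = factor("ni", levels = c("i", "ni")),
                    flash = factor("high", levels = c("PFR", "high")))
  lab <- lab[rep(1, 100), ]
  expect_equal(pfr_ni_fraction(lab)$fraction, 0)
  lab$flash[] <- "PFR"
  expect_equal(pfr_ni_fraction(lab)$fraction, 1)
  expect_error(pfr_ni_fraction(lab[0, ]), "no transfected")
})

test_that("Holm-Sidak step-down matches the closed form and is monotone", {
  expect_equal(round(holm_sidak_adjust(c(0.01, 0.03, 0.04)), 4),
               c(0.0297, 0.0591, 0.0591))
  expect_equal(holm_sidak_adjust(0.2), 0.2)
  set.seed(81)
  for (i in 1:20) {
    p <- stats::runif(sample(2:8, 1))
    adj <- holm_sidak_adjust(p)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
    expect_true(all(adj <= 1))
  }
})

test_that("ANOVA with Holm-Sidak comparisons against the control arm", {
  set.seed(91)
  d <- expand.grid(arm = c("alone", "hsp40", "hsp70"), rep = 1:6)
  d$value <- stats::rnorm(nrow(d), ifelse(d$arm == "hsp40", 3, 0))
  out <- anova_holm_sidak(d, design = "one-way")
  expect_lt(out$omnibus$p[1], 0.01)
  expect_setequal(out$pairwise$arm, c("hsp40", "hsp70"))
  expect_lt(out$pairwise$p_adjusted[out$pairwise$arm == "hsp40"], 0.01)
  expect_true(all(out$pairwise$p_adjusted >= out$pairwise$p_raw - 1e-12))
  # two groups: F equals the square of the equal-variance t statistic
  d2 <- d[d$arm %in% c("alone", "hsp40"), ]
  d2$arm <- droplevels(factor(d2$arm))
  out2 <- anova_holm_sidak(d2, design = "one-way")
  tt <- stats::t.test(value ~ arm, data = d2, var.equal = TRUE)
  expect_equal(out2$omnibus$F[1], unname(tt$statistic)^2, tolerance = 1e-9)
  # degenerate zero-variance input is an error
  d3 <- d; d3$value <- 1
  expect_error(anova_holm_sidak(d3, design = "one-way"), "degenerate")
  # three-way design demands filled cells
  d4 <- expand.grid(arm = c("alone", "hsp40"), polyQ = c(46, 72),
                    time = c(30, 46), rep = 1:3)
  d4$value <- stats::rnorm(nrow(d4))
  out4 <- anova_holm_sidak(d4, design = "three-way")
  expect_setequal(out4$omnibus$factor[1:3], c("arm", "polyQ", "time"))
  expect_error(anova_holm_sidak(d4[d4$polyQ == 46 | d4$arm == "alone", ],
                                design = "three-way"), "empty cells")
})
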