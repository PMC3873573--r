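test_that("pre-gate removes background particles and doublets, keeps cells", {
  q72 <- q72_fixture()
  ev <- q72$events
  pg <- pregate(ev)
  particles <- ev$truth_class == "particle"
  doublets <- ev$truth_class == "doublet"
  cells <- ev$truth_class == "cell"
  expect_gte(mean(!pg$mask[particles]), 0.95)
  expect_gte(mean(!pg$mask[doublets]), 0.90)
  expect_lte(mean(!pg$mask[cells]), 0.01)
  # exclusive lower bound at the size floor
  probe <- ev[rep(which(cells)[1], 2), ]
  probe$ssc_h <- c(pg$size_floor - 1e-9, pg$size_floor)
  probe$ssc_a <- probe$ssc_h  # ratio 1, below any doublet bound
  m <- pregate(probe, pg$size_floor, pg$doublet_ratio)$mask
  expect_identical(m, c(FALSE, TRUE))
  # identical in-range events all pass under derived bounds
  same <- ev[rep(which(cells)[1], 20), ]
  expect_true(all(pregate(same)$mask))
  expect_error(pregate(ev[0, ]), "empty")
})

test_that("transfection gate references the untransfected control", {
  ctl <- ctl_fixture()
  q72 <- q72_fixture()
  tf <- transfection_gate(q72$events, ctl$untransfected)
  live <- q72$events$truth_class == "cell" &
    q72$events$truth_status == "live"
  untr <- q72$events$truth_class == "untransfected"
  expect_gte(mean(tf$mask[live]), 0.99)
  expect_lte(mean(tf$mask[untr]), 0.002)
  # constant reference: threshold equals the constant, pass strictly above
  ref <- data.frame(cer_a = rep(100, 1000), mk_a = rep(50, 1000))
  probe <- data.frame(cer_a = c(101, 100, 0), mk_a = c(0, 0, 101))
  tf2 <- transfection_gate(probe, ref)
  expect_equal(tf2$threshold, 100)
  expect_identical(tf2$mask, c(TRUE, FALSE, TRUE))  # either-channel rule
  # mislabeled controls (reference ~ sample) are rejected
  expect_error(transfection_gate(q72$events, q72$events), "mislabeled")
})

test_that("M/D/L classification is a partition with the stated geometry", {
  ctl <- ctl_fixture()
  q72 <- q72_fixture()
  lab <- q72$labels
  ti <- lab$transfected
  expect_true(all(!is.na(lab$mdl[ti])))
  expect_equal(sum(ti), sum(lab$mdl == "M", na.rm = TRUE) +
                 sum(lab$mdl == "D", na.rm = TRUE) +
                 sum(lab$mdl == "L", na.rm = TRUE))
  # an all-live diffuse population is almost entirely M
  live_ev <- cells_to_events(ctl$cells[ctl$cells$status == "live", ],
                             ctl$panel, seed = 41)
  mdl <- classify_MDL(live_ev, q72$gateset$transfection_threshold)
  expect_gte(mean(mdl$labels == "M"), 0.98)
  # far-off-band constructed events follow the region rules
  thr <- q72$gateset$transfection_threshold
  fit <- q72$gateset$mdl_fit
  probe <- live_ev[1:2, ]
  probe$cer_a[1] <- 100 * 10^(fit$intercept +
                                fit$slope * log10(probe$mk_a[1] + 1))
  probe$cer_a[2] <- 0.5 * thr
  probe$mk_a[2] <- 10 * thr
  lab2 <- classify_MDL(probe, thr, fit = fit)
  expect_identical(as.character(lab2$labels), c("D", "L"))
  expect_error(classify_MDL(live_ev[1:10, ], thr), "too few")
  # truth-leached cells funnel into L, truth-debris into D
  ev <- q72$events
  lch <- ev$truth_status == "leached" & ti
  deb <- ev$truth_status == "lysed_debris" & ti
  expect_gte(mean(lab$mdl[lch] == "L"), 0.9)
  expect_gte(mean(lab$mdl[deb] == "D"), 0.9)
})

test_that("SYTOX gate separates dead-intact cells from leached ghosts", {
  q72 <- q72_fixture()
  ref <- data.frame(sytox_a = stats::runif(1000, 0, 50))
  sg <- sytox_gate(data.frame(sytox_a = c(60, 10)), ref)
  expect_identical(as.character(sg$labels), c("+", "-"))
  lab <- q72$labels
  ev <- q72$events
  di <- ev$truth_status == "dead_intact" & lab$transfected
  lch <- ev$truth_status == "leached" & lab$transfected
  expect_gte(mean(lab$sytox[di] == "+"), 0.95)
  expect_gt(mean(lab$sytox[lch] == "-"), 0.5)
})

test_that("PulSA gate separates inclusion-bearing from diffuse cells", {
  ctl <- ctl_fixture()
  q72 <- q72_fixture()
  env <- q72$gateset$pulsa_envelope
  # synthetic probes at the extremes of punctate share
  set.seed(51)
  A <- stats::rlnorm(1000, log(2000), 0.3)
  diam <- stats::rlnorm(1000, log(12), 0.05)
  mk_ev <- function(share) {
    p <- synthesize_pulse(A * (1 - share), A * share, diam, noise_sd = 1)
    data.frame(cer_h = p$height, cer_w = p$width)
  }
  lab0 <- pulsa_gate(mk_ev(0), envelope = env)$labels
  lab9 <- pulsa_gate(mk_ev(0.9), envelope = env)$labels
  expect_lte(mean(lab0 == "i"), 0.05)
  expect_lte(mean(lab9 == "ni"), 0.05)
  # boundary is monotone: reducing width at fixed height never flips i -> ni
  probe <- mk_ev(0.5)
  lab_a <- pulsa_gate(probe, envelope = env)$labels
  probe$cer_w <- probe$cer_w * 0.5
  lab_b <- pulsa_gate(probe, envelope = env)$labels
  expect_false(any(lab_a == "i" & lab_b == "ni"))
  expect_error(pulsa_gate(mk_ev(0), calibration = ctl$events[1:100, ]),
               "at least 500")
})

test_that("FlAsH gate flags poor reactivity against the monomer reference", {
  ctl <- ctl_fixture()
  q72 <- q72_fixture()
  env <- q72$gateset$flash_envelope
  panel <- ctl$panel
  set.seed(61)
  E <- stats::rlnorm(500, log(2000), 0.3)
  mk_ev <- function(f_mono) {
    ln <- function() stats::rlnorm(500, 0, panel$noise_cv)
    data.frame(cer_a = E * ln(), fl_a = panel$b_flash * f_mono * E * ln())
  }
  expect_gte(mean(flash_gate(mk_ev(1), envelope = env)$labels == "high"),
             0.99)
  expect_gte(mean(flash_gate(mk_ev(0.05), envelope = env)$labels == "PFR"),
             0.95)
  # the reference population itself sits almost fully above its envelope
  lab_ctl <- apply_gates(ctl$events, q72$gateset)
  pfr_ctl <- mean(lab_ctl$flash == "PFR", na.rm = TRUE)
  expect_lte(pfr_ctl, 0.015)
})

test_that("gating is a pure function of the gate set", {
  q72 <- q72_fixture()
  lab1 <- apply_gates(q72$events, q72$gateset)
  lab2 <- apply_gates(q72$events, q72$gateset)
  expect_identical(lab1, lab2)
  p <- tempfile(fileext = ".json")
  write_gateset(q72$gateset, p)
  gs2 <- read_gateset(p)
  lab3 <- apply_gates(q72$events, gs2)
  expect_identical(lab1$mdl, lab3$mdl)
  expect_identical(lab1$pulsa, lab3$pulsa)
  expect_identical(lab1$flash, lab3$flash)
})
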