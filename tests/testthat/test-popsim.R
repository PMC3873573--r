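test_that("configuration validation rejects invalid hazards and fates", {
  expect_error(sim_config(mu_i = -1), "hazards")
  expect_error(sim_config(k_nuc = Inf), "hazards")
  expect_error(sim_config(p_leach = 0.7, p_debris = 0.5), "p_leach")
  expect_error(sim_config(arm = "nonsense"), "unknown arm")
  expect_error(sim_config(time_points = c(18.3), dt = 0.5), "multiples")
  expect_error(
    simulate_population(sim_config(mu_ni = 1, dt = 0.5, n_cells = 10,
                                   time_points = 1)),
    "exceeds 0.2")
})

test_that("non-pathogenic polyQ never nucleates and k_nuc = 0 switches it off", {
  expect_equal(q_gain(25), 0)
  expect_true(all(q_gain(c(25, 46, 72, 97)) == cummax(q_gain(c(25, 46, 72, 97)))))
  cells25 <- simulate_population(sim_config(polyQ_length = 25, n_cells = 800,
                                            seed = 1))
  expect_false(any(cells25$has_inclusion))
  expect_false(any(cells25$status == "lysed_debris"))  # debris needs inclusions
  cells0 <- simulate_population(sim_config(polyQ_length = 97, n_cells = 800,
                                           k_nuc = 0, k_olig = 0, seed = 2))
  expect_false(any(cells0$has_inclusion))
  expect_true(all(cells0$f_mono == 1))
})

test_that("inclusion formation is time- and expression-dependent (97Q)", {
  cells <- simulate_population(sim_config(polyQ_length = 97, n_cells = 10000,
                                          time_points = c(18, 25, 30, 46),
                                          seed = 42))
  s18 <- cells[cells$time == 18, ]
  s46 <- cells[cells$time == 46, ]
  pt <- prop.test(c(sum(s46$has_inclusion), sum(s18$has_inclusion)),
                  c(nrow(s46), nrow(s18)))
  expect_gt(mean(s46$has_inclusion), mean(s18$has_inclusion))
  expect_lt(pt$p.value, 1e-3)
  # expression dependence: top vs bottom quartile of initial expression
  qt <- stats::quantile(s46$E_htt0, c(0.25, 0.75))
  top <- s46[s46$E_htt0 >= qt[2], ]
  bot <- s46[s46$E_htt0 <= qt[1], ]
  pt2 <- prop.test(c(sum(top$has_inclusion), sum(bot$has_inclusion)),
                   c(nrow(top), nrow(bot)))
  expect_gt(mean(top$has_inclusion), mean(bot$has_inclusion))
  expect_lt(pt2$p.value, 1e-3)
  # per-quartile inclusion fraction is monotone in expression at every time;
  # among founder cells (no dilution by newborn daughters) inclusion
  # formation is absorbing, so it is also monotone in time exactly
  frac_q <- sapply(c(18, 25, 30, 46), function(tp) {
    s <- cells[cells$time == tp, ]
    qq <- cut(s$E_htt0, stats::quantile(s$E_htt0, 0:4 / 4),
              include.lowest = TRUE, labels = FALSE)
    tapply(s$has_inclusion, qq, mean)
  })
  expect_true(all(apply(frac_q, 2, function(f) all(diff(f) >= 0))))
  founders <- cells[cells$id <= 10000, ]
  frac_f <- sapply(c(18, 25, 30, 46), function(tp) {
    s <- founders[founders$time == tp, ]
    qq <- cut(s$E_htt0, stats::quantile(s$E_htt0, 0:4 / 4),
              include.lowest = TRUE, labels = FALSE)
    tapply(s$has_inclusion, qq, mean)
  })
  expect_true(all(apply(frac_f, 1, function(f) all(diff(f) >= 0))))
})

test_that("population accounting balances at every step", {
  cells <- simulate_population(sim_config(polyQ_length = 72, n_cells = 1000,
                                          seed = 7))
  acc <- attr(cells, "accounting")
  expect_true(all(acc$n_after == acc$n_before + acc$births))
  final <- cells[cells$time == max(cells$time), ]
  expect_equal(nrow(final), 1000 + sum(acc$births))
  expect_true(all(final$status %in% c("live", "dead_intact", "leached",
                                      "lysed_debris")))
})

test_that("per-cell state is a valid molecular partition", {
  cells <- simulate_population(sim_config(polyQ_length = 97, n_cells = 2000,
                                          seed = 9))
  expect_true(all(abs(cells$f_mono + cells$f_olig + cells$f_inc - 1) < 1e-9))
  expect_true(all(cells$f_mono >= 0 & cells$f_olig >= 0 & cells$f_inc >= 0))
  expect_true(all(cells$f_mono <= 1 & cells$f_olig <= 1 & cells$f_inc <= 1))
  expect_identical(cells$has_inclusion, cells$f_inc > 0)
})

test_that("arms with unit modifiers are statistically indistinguishable", {
  mods <- default_arm_modifiers()
  expect_true(all(unlist(mods$alone) == 1))
  mods$null_arm <- mods$alone
  rejections <- 0
  for (sd_ in 1:20) {
    s1 <- simulate_population(sim_config(72, n_cells = 1500, time_points = 46,
                                         seed = sd_))
    s2 <- simulate_population(sim_config(72, n_cells = 1500, time_points = 46,
                                         arm = "null_arm",
                                         chaperone_mods = mods,
                                         seed = 100 + sd_))
    # founder cells only: daughters share their parent's state, so the
    # two-proportion test's independence assumption holds for founders
    s1 <- s1[s1$id <= 1500, ]; s2 <- s2[s2$id <= 1500, ]
    p <- prop.test(c(sum(s1$has_inclusion), sum(s2$has_inclusion)),
                   c(nrow(s1), nrow(s2)))$p.value
    if (p < 0.01) rejections <- rejections + 1
  }
  expect_lte(rejections, 1)
})

test_that("lysate pooling matches the brute-force summation oracle", {
  two <- data.frame(E_htt = c(1, 1), f_mono = c(1, 0), f_olig = c(0, 0),
                    f_inc = c(0, 1), status = "live")
  expect_equal(pool_lysate(two)$p_inc, 0.5)
  one <- data.frame(E_htt = 2, f_mono = 1, f_olig = 0, f_inc = 0,
                    status = "live")
  expect_equal(unlist(pool_lysate(one)[c("p_mono", "p_olig", "p_inc")]),
               c(p_mono = 1, p_olig = 0, p_inc = 0))
  cells <- simulate_population(sim_config(polyQ_length = 46, n_cells = 1000,
                                          time_points = 30, seed = 13))
  lys <- pool_lysate(cells)
  expect_equal(c(lys$p_mono, lys$p_olig, lys$p_inc), pool_oracle(cells),
               tolerance = 1e-12)
  expect_equal(lys$p_mono + lys$p_olig + lys$p_inc, 1, tolerance = 1e-9)
  # leached cells contribute nothing
  leach <- data.frame(E_htt = c(1, 5), f_mono = c(1, 0), f_olig = c(0, 0),
                      f_inc = c(0, 1), status = c("live", "leached"))
  expect_equal(pool_lysate(leach)$p_inc, 0)
  expect_error(pool_lysate(data.frame()), "empty")
  dead0 <- data.frame(E_htt = 0, f_mono = 1, f_olig = 0, f_inc = 0,
                      status = "live")
  expect_error(pool_lysate(dead0), "all-zero")
})
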