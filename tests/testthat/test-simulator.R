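test_that("euler_step is exact on its closed forms and guards its inputs", {
  st <- c(a = 1, b = 2)
  expect_equal(euler_step(st, c(a = 0, b = 0), 0.1), st)
  # linear decay, one step
  expect_equal(euler_step(c(c = 2), c(c = -0.3 * 2), 0.5)[["c"]],
               2 * (1 - 0.3 * 0.5))
  expect_error(euler_step(st, c(a = NaN, b = 0), 0.1), "non-finite.*a")
  expect_warning(out <- euler_step(c(x = 1), c(x = -3), 1), "clamped")
  expect_equal(out[["x"]], 0)
})

test_that("batch growth hits the yield-limited biomass ceiling", {
  traj <- simulate_growth(batch_config())
  final <- tail(traj$c_x_total, 1)
  # both substrate ceilings coincide: min(30*0.17, 3*1.7) = 5.1 above c_x0
  expect_equal(final, 0.21 + 5.1, tolerance = 0.02)
  # biomass formed tracks glucose consumed exactly through the yield
  expect_equal(final - 0.21, 0.17 * (30 - tail(traj$c_gluc, 1)),
               tolerance = 0.005)
  expect_true(all(traj$c_gluc >= 0 & traj$c_nano3 >= 0))
})

test_that("a sterile reactor stays sterile", {
  traj <- simulate_growth(batch_config(c_x0 = 0))
  expect_true(all(traj$c_x_total == 0))
  expect_equal(tail(traj$c_gluc, 1), 30)
})

test_that("volume bookkeeping is exact across feed types", {
  for (nm in c("b2", "fb1", "fb2", "fb4")) {
    traj <- simulate_process(mel_scenario(nm))
    v <- fed_volumes(traj)
    expect_equal(v$V_final,
                 v$V0 + v$medium_l + v$oil_bolus_l + v$oil_continuous_l,
                 tolerance = 1e-9)
  }
})

test_that("bolus oil addition is instantaneous perfect mixing", {
  cfg <- production_only_config(
    handover_V = 4,
    oil_feeds = list(oil_feed(0, volume_ml = 240, oil_density = 0.92)),
    t_end = 10
  )
  handover <- list(t = 0, V_L = 4, c_x = 0, c_gluc = 0, c_nano3 = 0)
  traj <- simulate_production(cfg, handover)
  expect_equal(traj$c_oil[1], 220.8 / 4.24, tolerance = 1e-9)
  expect_equal(traj$V_L[1], 4.24)
  # sterile handover: nothing reacts
  expect_equal(tail(traj$c_oil, 1), 220.8 / 4.24, tolerance = 1e-9)
  expect_equal(max(traj$c_mel), 0)
})

test_that("without oil no MEL is formed", {
  cfg <- process_config(V0 = 4, t_growth_end = 24, t_end = 60,
                        c_gluc0 = 10, c_nano30 = 1)
  traj <- simulate_process(cfg)
  expect_equal(max(traj$c_mel), 0)
  expect_equal(max(traj$c_oil), 0)
})

test_that("growth-only processes return a growth trajectory", {
  traj <- simulate_process(batch_config(t_end = 48))
  expect_true(all(traj$phase == "growth"))
})

test_that("trajectories have strictly increasing time and one transition", {
  traj <- simulate_process(mel_scenario("b2"))
  expect_true(all(diff(traj$t_h) > 0))
  expect_equal(sum(diff(as.integer(factor(traj$phase,
                                          c("growth", "production")))) != 0), 1)
  expect_true(all(as.matrix(traj[, c("c_x_free", "c_x_incl", "c_oil",
                                     "c_fa", "c_mel")]) >= 0))
})

test_that("oil events before the hand-over are rejected", {
  expect_error(
    process_config(V0 = 4, t_growth_end = 48, t_end = 100,
                   oil_feeds = list(oil_feed(20, frac_vv = 6,
                                             reference_volume = 4))),
    "growth phase ends"
  )
})

test_that("Euler endpoint error shrinks first order in the step size", {
  run <- function(dtg, dtp) {
    cfg <- mel_scenario("toy")
    cfg$dt_growth <- dtg
    cfg$dt_production <- dtp
    traj <- simulate_process(cfg)
    unlist(tail(traj[, c("c_x_total", "c_oil", "c_fa", "c_mel")], 1))
  }
  e1 <- run(0.1, 0.4); e2 <- run(0.05, 0.2); e3 <- run(0.025, 0.1)
  shift1 <- max(abs(e1 - e2)); shift2 <- max(abs(e2 - e3))
  expect_gt(shift1 / shift2, 1.5)  # ~2 for a first-order scheme
  expect_lt(shift1 / shift2, 3)
})

test_that("the growth hand-over seeds the production phase correctly", {
  traj <- simulate_process(mel_scenario("b1"))
  h <- attr(traj, "handover")
  first_prod <- traj[traj$phase == "production", ][1, ]
  # biomass pools: all hand-over biomass starts lipid-free (diluted by bolus)
  expect_equal(first_prod$c_x_free,
               h$c_x * h$V_L / first_prod$V_L, tolerance = 1e-9)
  expect_equal(first_prod$c_x_incl, 0)
})
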