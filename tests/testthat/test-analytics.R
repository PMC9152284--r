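test_that("growth rate estimation is exact on exponential data", {
  d <- tibble::tibble(t_h = seq(0, 18, 2), c_x = 0.4 * exp(0.1 * seq(0, 18, 2)))
  expect_equal(estimate_growth_rate(d, c(0, 18))$estimate, 0.1,
               tolerance = 1e-10)
  expect_equal(estimate_growth_rate(d, c(0, 18), method = "two_point")$estimate,
               0.1, tolerance = 1e-10)
  flat <- tibble::tibble(t_h = 0:5, c_x = 3)
  expect_equal(estimate_growth_rate(flat, c(0, 5))$estimate, 0)
  bad <- tibble::tibble(t_h = 0:2, c_x = c(1, 0, 2))
  expect_error(estimate_growth_rate(bad, c(0, 2)), "positive")
})

test_that("consumption estimators return the classical ratios and identity", {
  d <- tibble::tibble(t_h = c(0, 10), c_x = c(0.5, 5.6),
                      c_gluc = c(30, 0), c_nano3 = c(3, 0))
  g <- estimate_consumption(d, "c_gluc", c(0, 10), method = "two_point")
  expect_equal(g$yield, 5.1 / 30)
  expect_equal(g$r_s, 3)
  n <- estimate_consumption(d, "c_nano3", c(0, 10), method = "two_point")
  expect_equal(n$yield, 1.7)
  # q_S * Y_X/S = mu, exactly, with the two-point estimators
  mu <- estimate_growth_rate(d, c(0, 10), method = "two_point")$estimate
  expect_equal(g$q_s * g$yield, mu, tolerance = 1e-12)
  expect_equal(n$q_s * n$yield, mu, tolerance = 1e-12)
  expect_error(estimate_consumption(tibble::tibble(t_h = c(0, 1), c_x = c(1, 2),
                                                   c_gluc = c(5, 5)),
                                    "c_gluc", c(0, 1)), "undefined")
})

test_that("simulated batch growth round-trips through the estimators", {
  traj <- simulate_growth(batch_config())
  d <- tibble::tibble(t_h = traj$t_h, c_x = traj$c_x_total,
                      c_gluc = traj$c_gluc)
  est <- estimate_consumption(d, "c_gluc", c(2, 30), method = "two_point")
  expect_equal(est$yield, 0.17, tolerance = 0.01)
  mu <- estimate_growth_rate(d, c(5, 25))$estimate
  expect_equal(mu, 0.11, tolerance = 0.05)
})

test_that("off-gas balance gives zero respiration for identical streams", {
  rec <- tibble::tibble(y_o2_in = 0.2095, y_co2_in = 4e-4,
                        y_o2_out = 0.2095, y_co2_out = 4e-4,
                        q_air_lph = 168, p_pa = 101325, t_k = 303.15, v_l = 4)
  r <- off_gas_rates(rec)
  expect_equal(r$our, 0, tolerance = 1e-12)
  expect_equal(r$cer, 0, tolerance = 1e-12)
  expect_true(is.na(r$rq))
})

test_that("off-gas round trip recovers the generating rates", {
  out <- invert_off_gas(24.9, 34.6)
  rec <- tibble::tibble(y_o2_in = 0.2095, y_co2_in = 4e-4,
                        y_o2_out = out$y_o2_out, y_co2_out = out$y_co2_out,
                        q_air_lph = 168, p_pa = 101325, t_k = 303.15, v_l = 4)
  r <- off_gas_rates(rec)
  expect_equal(r$our, 24.9, tolerance = 1e-9)
  expect_equal(r$cer, 34.6, tolerance = 1e-9)
  expect_equal(r$rq, 34.6 / 24.9, tolerance = 1e-9)
})

test_that("rates are insensitive to the inert dilution level of the streams", {
  # same true OUR/CER seen through inlets with different inert padding
  for (k in c(1, 0.9, 0.7)) {
    y_in <- 0.2095 * k; c_in <- 4e-4 * k
    out <- invert_off_gas(20, 12, y_o2_in = y_in, y_co2_in = c_in)
    rec <- tibble::tibble(y_o2_in = y_in, y_co2_in = c_in,
                          y_o2_out = out$y_o2_out, y_co2_out = out$y_co2_out,
                          q_air_lph = 168, p_pa = 101325, t_k = 303.15,
                          v_l = 4)
    r <- off_gas_rates(rec)
    expect_equal(r$our, 20, tolerance = 1e-9)
    expect_equal(r$cer, 12, tolerance = 1e-9)
  }
})

test_that("invalid gas fractions are rejected", {
  rec <- tibble::tibble(y_o2_in = 0.2095, y_co2_in = 4e-4,
                        y_o2_out = 0.6, y_co2_out = 0.5,
                        q_air_lph = 168, p_pa = 101325, t_k = 303.15, v_l = 4)
  expect_error(off_gas_rates(rec), "inert")
})

test_that("specific oxygen uptake divides OUR by the window biomass", {
  d <- tibble::tibble(t_h = c(0, 4), c_x = c(5.8, 5.8), our = c(25, 25))
  est <- estimate_o2_uptake(d, c(0, 4))
  expect_equal(est$q_o2, 25 / 5.8, tolerance = 1e-9)
  expect_error(estimate_o2_uptake(
    tibble::tibble(t_h = c(0, 4), c_x = c(0, 0), our = c(25, 25)), c(0, 4)
  ), "positive")
})

test_that("oil and MEL window rates match the two-point arithmetic", {
  d <- tibble::tibble(t_h = c(48, 168), c_oil = c(52, 2), c_mel = c(0, 11.2))
  est <- estimate_production_rates(d, c(48, 168), c_x_growth = 4.2,
                                   total_oil_added = 49.6,
                                   method = "two_point")
  expect_equal(est$r_mel, 11.2 / 120, tolerance = 1e-9)
  expect_equal(est$y_mel_total_oil, 11.2 / 49.6, tolerance = 1e-9)
  # yield per total oil matches the reported 0.226 g/g
  expect_equal(round(est$y_mel_total_oil, 3), 0.226)
  flat <- tibble::tibble(t_h = c(0, 10), c_oil = c(30, 20), c_mel = c(5, 5))
  expect_equal(estimate_production_rates(flat, c(0, 10), 4)$r_mel, 0)
})

test_that("extract purity is a scale-invariant mass fraction", {
  expect_equal(round(100 * x_mel(11.2, 13.9 - 11.2, 0)), 81)
  expect_equal(x_mel(5, 0, 0), 1)
  expect_equal(x_mel(0, 3, 2), 0)
  expect_equal(x_mel(7, 2, 1), x_mel(70, 20, 10))
  expect_error(x_mel(0, 0, 0), "undefined")
  expect_error(x_mel(-1, 1, 1), "non-negative")
})

test_that("OD and backscatter calibrations are the printed linear factors", {
  expect_equal(od_to_biomass(0.6), 0.21)
  expect_equal(od_to_biomass(0), 0)
  expect_equal(backscatter_to_od(1.4), 10)
  expect_equal(backscatter_to_biomass(1.4), 3.5)
  expect_equal(biomass_to_od(0.21), 0.6)
})
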