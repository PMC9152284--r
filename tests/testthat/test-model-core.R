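test_that("specific growth rate follows dual-substrate minimum kinetics", {
  p <- mel_params()
  expect_equal(specific_growth_rate(0, 3), 0)
  # glucose at half saturation, nitrate in excess: the minimum operator
  # selects the glucose term exactly
  expect_equal(specific_growth_rate(1, 1000), 0.055)
  # nitrate at half saturation limits despite abundant glucose
  expect_equal(specific_growth_rate(30, 0.01), 0.055)
  expect_error(specific_growth_rate(-1, 3), "non-negative")
})

test_that("mu and specific rates are bounded over admissible inputs", {
  p <- mel_params()
  grid <- expand.grid(a = c(0, 0.1, 1, 5, 50, 1e4), b = c(0, 0.01, 1, 20, 1e4))
  mu <- specific_growth_rate(grid$a, grid$b)
  expect_true(all(mu >= 0 & mu <= p$mu_max))
  qh <- hydrolysis_rate(grid$a, grid$b)
  expect_true(all(qh >= 0 & qh <= p$q_max_hyd))
  expect_true(all(mel_rate(grid$a) <= p$q_max_mel))
  expect_true(all(inclusion_rate(grid$a) <= p$q_max_incl))
})

test_that("derived maximum consumption rates match the tabulated constants", {
  q <- q_max_derived()
  expect_equal(q$q_max[q$substrate == "glucose"], 0.647, tolerance = 0.01)
  expect_equal(q$q_max[q$substrate == "nano3"], 0.065, tolerance = 0.01)
})

test_that("growth RHS reproduces the saturation and degenerate limits", {
  st0 <- c(V_L = 4, c_x = 1, c_gluc = 0, c_nano3 = 0)
  expect_equal(unname(growth_rhs(st0)), rep(0, 4))
  # both substrates far above their K: mu -> mu_max
  st <- c(V_L = 4, c_x = 1, c_gluc = 1e6, c_nano3 = 1e6)
  d <- growth_rhs(st)
  expect_equal(d[["c_x"]], 0.11, tolerance = 1e-5)
  expect_equal(d[["c_gluc"]], -0.11 / 0.17, tolerance = 1e-5)
  expect_equal(d[["c_nano3"]], -0.11 / 1.7, tolerance = 1e-5)
  # sterile feed: no biomass change, substrates relax toward the feed
  feed <- exponential_feed(0, 10, 0.08, V0 = 3, cx0 = 7.6)
  ds <- growth_rhs(c(V_L = 3, c_x = 0, c_gluc = 10, c_nano3 = 50),
                   F_in = 0.02, feed = feed)
  expect_equal(ds[["c_x"]], 0)
  expect_gt(ds[["c_gluc"]], 0)   # feed at 300 g/L pulls glucose up
  expect_lt(ds[["c_nano3"]], 0)  # feed at 30 g/L pulls nitrate down
  expect_error(growth_rhs(c(V_L = 0, c_x = 1, c_gluc = 1, c_nano3 = 1)),
               "volume")
})

test_that("exponential feed law evaluates as specified", {
  feed <- exponential_feed(44.5, 55, mu_set = 0.08, V0 = 3, cx0 = 7.6,
                           Y_x_gluc_feed = 0.25, c_gluc_feed = 300)
  expect_equal(exponential_feed_rate(40, feed), 0)
  expect_equal(exponential_feed_rate(60, feed), 0)
  # direct evaluation at feed start: (3*7.6*0.08)/(0.25*300)
  expect_equal(exponential_feed_rate(44.5, feed), 0.02432, tolerance = 1e-6)
  # pure exponential shape inside the window
  r <- exponential_feed_rate(50, feed) / exponential_feed_rate(44.5, feed)
  expect_equal(r, exp(0.08 * 5.5), tolerance = 1e-12)
  expect_error(exponential_feed_rate(45, feed, c_gluc = 300), "diverges")
})

test_that("feed totals integrate the law and convert mass to substrate", {
  feed <- exponential_feed(44.5, 55, mu_set = 0.08, V0 = 3, cx0 = 7.6)
  tot <- feed_totals(feed)
  # closed form: F0 (e^{mu tau} - 1)/mu
  expect_equal(tot$volume_l, 0.02432 * (exp(0.08 * 10.5) - 1) / 0.08,
               tolerance = 1e-6)
  expect_equal(tot$glucose_g / tot$nano3_g, 10)
  d <- feed_delivery(460, feed)
  expect_equal(d$glucose_g, 138)
  expect_equal(d$nano3_g, 13.8)
})

test_that("hydrolysis rate shows saturation and fatty-acid inhibition", {
  expect_equal(hydrolysis_rate(0, 10), 0)
  expect_equal(hydrolysis_rate(5, 0), 0.05)          # oil at K_m
  expect_equal(hydrolysis_rate(5, 20), 0.1 * 5 / 15) # FA at K_i
  # monotone: increasing in oil, decreasing in FA
  oils <- seq(0, 60, by = 5); fas <- seq(0, 60, by = 5)
  for (cf in fas) expect_true(all(diff(hydrolysis_rate(oils, cf)) >= 0))
  for (co in oils[-1]) expect_true(all(diff(hydrolysis_rate(co, fas)) <= 0))
})

test_that("MEL and inclusion rates are Michaelis-Menten in fatty acids", {
  expect_equal(mel_rate(0), 0)
  expect_equal(mel_rate(5), 0.01)
  expect_equal(mel_rate(45), 0.02 * 45 / 50)
  expect_equal(inclusion_rate(0), 0)
  expect_equal(inclusion_rate(1), 0.035)
  expect_equal(inclusion_rate(9), 0.07 * 9 / 10)
})

test_that("production RHS reproduces the printed limits", {
  base <- c(V_L = 4, c_x_free = 10, c_x_incl = 0, c_oil = 0, c_fa = 0,
            c_mel = 0, c_x_growth = 10)
  expect_equal(unname(production_rhs(base))[1:6], rep(0, 6))
  # saturating oil, no fatty acids: pure hydrolysis flux
  st <- base; st["c_oil"] <- 1e7
  d <- production_rhs(st)
  expect_equal(d[["c_oil"]], -1.0, tolerance = 1e-5)
  expect_equal(d[["c_fa"]], 0.957, tolerance = 1e-5)
  expect_equal(d[["c_mel"]], 0)
  # fatty acids alone: MEL formation at the Monod factor 50/55
  st2 <- base; st2["c_fa"] <- 50
  expect_equal(production_rhs(st2)[["c_mel"]], 10 * 0.02 * 50 / 55,
               tolerance = 1e-12)
  expect_error(production_rhs(replace(base, 1, 0)), "volume")
})

test_that("fatty-acid flux bookkeeping balances term by term", {
  p <- mel_params()
  set.seed(42)
  for (i in 1:25) {
    st <- c(V_L = runif(1, 1, 6), c_x_free = runif(1, 0, 12),
            c_x_incl = runif(1, 0, 20), c_oil = runif(1, 0, 80),
            c_fa = runif(1, 0, 60), c_mel = runif(1, 0, 40),
            c_x_growth = runif(1, 1, 15))
    d <- production_rhs(st, F_in = 0)
    hyd_flux <- hydrolysis_rate(st[["c_oil"]], st[["c_fa"]]) * st[["c_x_growth"]]
    mel_flux <- mel_rate(st[["c_fa"]]) * st[["c_x_growth"]]
    incl_flux <- inclusion_rate(st[["c_fa"]]) * st[["c_x_free"]]
    expect_equal(
      d[["c_fa"]] + p$Y_fa_mel * mel_flux + p$Y_fa_incl * incl_flux -
        p$Y_fa_oil * hyd_flux,
      0, tolerance = 1e-14
    )
    # the MEL and inclusion-biomass equations carry exactly those fluxes
    expect_equal(d[["c_mel"]], mel_flux, tolerance = 1e-14)
    expect_equal(d[["c_x_incl"]], incl_flux, tolerance = 1e-14)
    expect_equal(d[["c_x_free"]], -p$Y_x_free_incl * incl_flux,
                 tolerance = 1e-14)
  }
})

test_that("parameter set validates and rejects unknown or invalid values", {
  expect_error(mel_params(q_max_mel = -1), "positive")
  expect_error(mel_params(nonsense = 1), "unknown parameter")
  expect_equal(mel_params(q_max_mel = 0.03)$q_max_mel, 0.03)
})
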