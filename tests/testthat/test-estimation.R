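test_that("direct yield regression recovers the generating constants", {
  cfg <- batch_config()
  obs <- generate_observations(cfg, noiseless(offline_interval = 4))
  est <- fit_yields(obs, exp_window = c(4, 28), batch_window = c(0, 40))
  get <- function(p) est$estimate[est$parameter == p]
  expect_equal(get("Y_x_gluc"), 0.17, tolerance = 0.01)
  expect_equal(get("Y_x_nano3"), 1.7, tolerance = 0.01)
  expect_equal(get("mu_max"), 0.11, tolerance = 0.05)
  expect_equal(get("q_max_gluc"), 0.647, tolerance = 0.1)
  expect_equal(get("q_max_nano3"), 0.0647, tolerance = 0.1)
})

test_that("noisy yields are recovered within the stated band", {
  cfg <- batch_config()
  obs <- generate_observations(cfg, noise_model(rel_sd = 0.05,
                                                offline_interval = 4,
                                                seed = 11))
  est <- fit_yields(obs, exp_window = c(4, 28), batch_window = c(0, 40))
  y <- est$estimate[est$parameter == "Y_x_gluc"]
  expect_equal(y, 0.17, tolerance = 0.10)
})

test_that("a fit with no free parameters is the forward-simulation SSE", {
  cfg <- mel_scenario("toy")
  obs <- generate_observations(cfg, noiseless())
  fit <- fit_model(obs, cfg, fit_spec(character(0)))
  expect_true(fit$convergence)
  expect_lt(fit$objective, 1e-16)  # simulation interpolates its own samples
  expect_equal(nrow(tidy(fit)), 0)
  expect_equal(glance(fit)$objective, fit$objective)
})

test_that("a singly-freed parameter is recovered from noiseless data", {
  cfg <- mel_scenario("toy")
  obs <- generate_observations(cfg, noiseless())
  fit <- fit_model(obs, cfg, fit_spec("q_max_mel"))
  expect_equal(tidy(fit)$estimate, 0.02, tolerance = 0.05)
  expect_true(fit$convergence)
})

test_that("the objective profile dips at the generating value", {
  cfg <- mel_scenario("toy")
  obs <- generate_observations(cfg, noiseless())
  grid <- c(0.005, 0.01, 0.02, 0.04, 0.08)
  prof <- profile_objective(obs, cfg, "q_max_mel", grid)
  expect_equal(prof$value[which.min(prof$objective)], 0.02)
  # monotone away from the optimum on either side
  i0 <- which(grid == 0.02)
  expect_true(all(diff(prof$objective[1:i0]) <= 0))
  expect_true(all(diff(prof$objective[i0:length(grid)]) >= 0))
})

test_that("a structurally inert parameter gives a flat profile", {
  # no oil anywhere: fatty acids stay zero, K_i_hyd cannot matter
  cfg <- process_config(V0 = 2, c_gluc0 = 10, c_nano30 = 1,
                        t_growth_end = 16, t_end = 40)
  obs <- generate_observations(cfg, noiseless())
  prof <- profile_objective(obs, cfg, "K_i_hyd", c(5, 20, 80))
  expect_equal(diff(range(prof$objective)), 0, tolerance = 1e-12)
})

test_that("fits are bit-reproducible given the seed", {
  cfg <- mel_scenario("toy")
  obs <- generate_observations(cfg, noise_model(seed = 5))
  spec <- fit_spec(c("q_max_mel", "K_m_mel"), n_starts = 2, maxit = 60,
                   seed = 9)
  f1 <- fit_model(obs, cfg, spec)
  f2 <- fit_model(obs, cfg, spec)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$objective, f2$objective)
})

test_that("unknown free parameters and bad windows are rejected", {
  expect_error(fit_spec("not_a_param"), "unknown parameter")
  expect_error(profile_objective(tibble::tibble(t_h = 1), batch_config(),
                                 "nope", 1:3), "unknown parameter")
  d <- tibble::tibble(t_h = c(0, 8), c_x = c(1, 2), c_gluc = c(10, 5),
                      c_nano3 = c(1, 0.5))
  expect_error(fit_yields(d, c(0, 8)), ">= 3 samples")
})
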