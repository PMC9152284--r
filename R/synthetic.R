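#' Measurement noise model for synthetic observation tables
#'
#' Describes the statistical structure of the emulated bioreactor
#' measurements: sparse offline samples (concentrations, OD) with
#' multiplicative lognormal noise, and a continuous off-gas stream with
#' small additive mole-fraction noise. Lognormal multiplicative noise is
#' used so noisy concentrations can never go negative; species that are
#' exactly zero instead receive a half-normal draw at the absolute floor sd.
#'
#' @param rel_sd relative (lognormal sdlog) noise, recycled over species or
#'   a named vector per species; default 5%.
#' @param floor_sd named absolute floor sd (g/L) used for species at zero.
#' @param offgas_sd absolute sd of outlet mole fractions; default 2e-4.
#' @param offline_interval spacing of offline samples (h); default 8.
#' @param offgas_interval spacing of off-gas records (h); default 0.2.
#' @param seed integer seed.
#' @return An object of class `mel_noise`.
#' @export
noise_model <- function(rel_sd = 0.05,
                        floor_sd = c(od625 = 0.05, c_x = 0.02, c_gluc = 0.05,
                                     c_nano3 = 0.01, c_oil = 0.1, c_fa = 0.1,
                                     c_mel = 0.1),
                        offgas_sd = 2e-4,
                        offline_interval = 8, offgas_interval = 0.2,
                        seed = 1L) {
  species <- c("od625", "c_x", "c_gluc", "c_nano3", "c_oil", "c_fa", "c_mel")
  if (is.null(names(rel_sd))) {
    rel_sd <- setNames(rep_len(rel_sd, length(species)), species)
  } else {
    full <- setNames(rep(0.05, length(species)), species)
    full[names(rel_sd)] <- rel_sd
    rel_sd <- full
  }
  if (any(rel_sd < 0) || any(floor_sd < 0) || offgas_sd < 0) {
    abort("noise standard deviations must be non-negative")
  }
  structure(
    list(rel_sd = rel_sd, floor_sd = floor_sd, offgas_sd = offgas_sd,
         offline_interval = offline_interval,
         offgas_interval = offgas_interval, seed = as.integer(seed)),
    class = "mel_noise"
  )
}

#' Off-gas generation settings
#'
#' Conventions used to synthesise the respiration signal from a simulated
#' trajectory. During growth the specific oxygen uptake follows the growth
#' rate, `q_O2 = mu / Y_X/O2`, with `Y_X/O2` fixed implicitly so that
#' `q_O2 = q_o2_at_mu_max` at `mu_max`; during production a constant
#' specific uptake `q_o2_production` acts on the frozen catalytic biomass.
#' The respiratory quotient is phase-specific (oxidative lipid metabolism
#' pushes it well below 1 during production).
#'
#' @param q_o2_at_mu_max growth-phase specific O2 uptake at `mu_max`
#'   (mmol/g/h); default 4.3.
#' @param q_o2_production production-phase specific O2 uptake (mmol/g/h).
#' @param rq_growth,rq_production phase respiratory quotients (1.4 / 0.52).
#' @param vvm aeration rate (gas volumes per initial liquid volume per
#'   minute); default 0.7.
#' @param y_o2_in,y_co2_in inlet dry-gas mole fractions.
#' @param p_pa,t_k pressure (Pa) and temperature (K).
#' @return A named list of settings.
#' @export
off_gas_settings <- function(q_o2_at_mu_max = 4.3, q_o2_production = 1.5,
                             rq_growth = 1.4, rq_production = 0.52,
                             vvm = 0.7, y_o2_in = 0.2095, y_co2_in = 4e-4,
                             p_pa = 101325, t_k = 303.15) {
  list(q_o2_at_mu_max = q_o2_at_mu_max, q_o2_production = q_o2_production,
       rq_growth = rq_growth, rq_production = rq_production, vvm = vvm,
       y_o2_in = y_o2_in, y_co2_in = y_co2_in, p_pa = p_pa, t_k = t_k)
}

interp_cols <- function(traj, times, cols) {
  out <- lapply(cols, function(cl) {
    approx(traj$t_h, traj[[cl]], xout = times, rule = 2)$y
  })
  names(out) <- cols
  as_tibble(out)
}

#' Generate a synthetic observation table
#'
#' Simulates a process with known parameters, samples it on the offline and
#' off-gas grids of the noise model, and applies measurement noise. The OD
#' column is derived from the noiseless biomass (biomass / 0.35) before
#' noising. Outlet gas fractions are constructed by inverting the off-gas
#' balance from the model-implied OUR and CER, so the analytics estimators
#' applied to a zero-noise table recover the generating rates exactly.
#'
#' @param config a [process_config()].
#' @param noise a [noise_model()]; set all sds to zero for noiseless tables.
#' @param gas [off_gas_settings()].
#' @param seed seed for the noise draws; defaults to the noise model's.
#' @return A tibble of class `mel_observations` on the off-gas time grid:
#'   offline columns (`od625`, `c_x`, `c_gluc`, `c_nano3`, `c_oil`, `c_fa`,
#'   `c_mel`) are `NA` except at offline sampling times; off-gas columns
#'   (`y_o2_in`, `y_co2_in`, `y_o2_out`, `y_co2_out`, `q_air_lph`, `p_pa`,
#'   `t_k`, `v_l`) are filled on every row. The generating trajectory and
#'   config are attached as attributes `truth` and `config`.
#' @examples
#' obs <- generate_observations(mel_scenario("toy"),
#'                              noise_model(rel_sd = 0, offgas_sd = 0))
#' @export
generate_observations <- function(config, noise = noise_model(),
                                  gas = off_gas_settings(),
                                  seed = noise$seed) {
  stopifnot(inherits(config, "mel_config"), inherits(noise, "mel_noise"))
  set.seed(seed)
  traj <- simulate_process(config)
  p <- config$params
  t_gas <- seq(0, config$t_end, by = noise$offgas_interval)
  t_off <- seq(0, config$t_end, by = noise$offline_interval)

  sim <- interp_cols(traj, t_gas, c(
    "V_L", "c_x_total", "c_gluc", "c_nano3", "c_oil", "c_fa", "c_mel", "mu"
  ))
  growth_phase <- t_gas <= config$t_growth_end
  cx_growth <- attr(traj, "handover")$c_x %||% tail(traj$c_x_total, 1)

  q_o2 <- ifelse(growth_phase,
                 gas$q_o2_at_mu_max * sim$mu / p$mu_max,
                 gas$q_o2_production)
  cx_eff <- ifelse(growth_phase, sim$c_x_total, cx_growth)
  our <- q_o2 * cx_eff
  rq <- ifelse(growth_phase, gas$rq_growth, gas$rq_production)
  cer <- rq * our
  q_air <- gas$vvm * config$V0 * 60
  outlet <- invert_off_gas(our, cer, y_o2_in = gas$y_o2_in,
                           y_co2_in = gas$y_co2_in, q_air_lph = q_air,
                           p_pa = gas$p_pa, t_k = gas$t_k, v_l = sim$V_L)
  y_o2_out <- outlet$y_o2_out + rnorm(length(t_gas), 0, noise$offgas_sd)
  y_co2_out <- outlet$y_co2_out + rnorm(length(t_gas), 0, noise$offgas_sd)

  obs <- tibble(
    t_h = t_gas,
    od625 = NA_real_, c_x = NA_real_, c_gluc = NA_real_, c_nano3 = NA_real_,
    c_oil = NA_real_, c_fa = NA_real_, c_mel = NA_real_,
    y_o2_in = gas$y_o2_in, y_co2_in = gas$y_co2_in,
    y_o2_out = pmin(pmax(y_o2_out, 0), 0.9999),
    y_co2_out = pmin(pmax(y_co2_out, 0), 0.9999),
    q_air_lph = q_air, p_pa = gas$p_pa, t_k = gas$t_k, v_l = sim$V_L
  )

  idx <- match(round(t_off, 9), round(t_gas, 9))
  keep <- !is.na(idx)
  idx <- idx[keep]
  clean <- tibble(
    od625 = sim$c_x_total[idx] / .OD_TO_CX,
    c_x = sim$c_x_total[idx],
    c_gluc = sim$c_gluc[idx], c_nano3 = sim$c_nano3[idx],
    c_oil = sim$c_oil[idx], c_fa = sim$c_fa[idx], c_mel = sim$c_mel[idx]
  )
  for (sp in names(clean)) {
    v <- clean[[sp]]
    rel <- noise$rel_sd[[sp]]
    fl <- noise$floor_sd[[sp]]
    noisy <- ifelse(v > 0, v * exp(rnorm(length(v), 0, rel)),
                    abs(rnorm(length(v), 0, fl)))
    obs[[sp]][idx] <- noisy
  }

  structure(obs,
    class = c("mel_observations", class(tibble())),
    config = config, truth = traj, noise = noise, gas = gas,
    c_x_growth = cx_growth
  )
}

# back-calculate the pump-program biomass (V cx)_0 that makes the feed-law
# integral reproduce a printed total feed mass
cx0_from_total_mass <- function(total_mass_g, mu_set, t_start, t_end, V0,
                                Y = 0.25, c_gluc_feed = 300, density = 1) {
  total_l <- total_mass_g / (density * 1000)
  dur <- t_end - t_start
  F0 <- total_l * mu_set / (exp(mu_set * dur) - 1)
  F0 * Y * c_gluc_feed / (mu_set * V0)
}

#' Shipped process scenario library
#'
#' Reconstructions of the six reported bioreactor runs (two two-stage batch
#' processes B1 and B2, four fed-batch processes FB1-FB4) plus a fast `toy`
#' scenario for smoke tests. Batch processes start from 4 L of medium with
#' 30 g/L glucose and 3 g/L NaNO3; fed-batch processes start from 3 L and
#' add an exponential medium feed (300 g/L glucose, 30 g/L NaNO3, unit
#' density) before the oil-fed production phase. Oil is rapeseed oil at
#' 0.92 g/mL. For FB2-FB4 the pump-program biomass behind the feeding law is
#' not reported and is back-calculated from the printed total feed mass;
#' those values are reconstructions, not measurements.
#'
#' @param name one of `"toy"`, `"b1"`, `"b2"`, `"fb1"`, `"fb2"`, `"fb3"`,
#'   `"fb4"`.
#' @param ... overrides passed to nothing currently; reserved.
#' @return A [process_config()] (`mel_scenario()`), or a named list of all
#'   of them (`mel_scenarios()`).
#' @examples
#' mel_scenario("b2")
#' names(mel_scenarios())
#' @export
mel_scenario <- function(name = c("toy", "b1", "b2", "fb1", "fb2", "fb3", "fb4"),
                         ...) {
  name <- match.arg(name)
  switch(name,
    toy = process_config(
      V0 = 1, c_gluc0 = 10, c_nano30 = 1, t_growth_end = 16, t_end = 40,
      oil_feeds = list(oil_feed(16, frac_vv = 5, reference_volume = 1)),
      name = "toy"
    ),
    b1 = process_config(
      V0 = 4, t_growth_end = 48, t_end = 240,
      oil_feeds = list(oil_feed(48, frac_vv = 6, reference_volume = 4)),
      name = "b1"
    ),
    b2 = process_config(
      V0 = 4, t_growth_end = 48, t_end = 333,
      oil_feeds = c(
        list(oil_feed(48, frac_vv = 6, reference_volume = 4)),
        lapply(c(118, 165, 215, 286), oil_feed, frac_vv = 4,
               reference_volume = 4)
      ),
      name = "b2"
    ),
    fb1 = process_config(
      V0 = 3, t_growth_end = 55, t_end = 310,
      feed = exponential_feed(
        44.5, 55, mu_set = 0.08, V0 = 3,
        cx0 = cx0_from_total_mass(460, 0.08, 44.5, 55, 3)
      ),
      oil_feeds = lapply(c(55, 142, 190, 242), oil_feed, frac_vv = 6),
      name = "fb1"
    ),
    fb2 = process_config(
      V0 = 3, t_growth_end = 54, t_end = 310,
      feed = exponential_feed(
        42.5, 54, mu_set = 0.09, V0 = 3,
        cx0 = cx0_from_total_mass(612, 0.09, 42.5, 54, 3)
      ),
      oil_feeds = list(
        oil_feed(54, frac_vv = 6),
        oil_feed(72, 140, kind = "continuous", rate_ml_h = 11)
      ),
      name = "fb2"
    ),
    fb3 = process_config(
      V0 = 3, t_growth_end = 51, t_end = 231,
      feed = exponential_feed(
        40, 51, mu_set = 0.09, V0 = 3,
        cx0 = cx0_from_total_mass(708, 0.09, 40, 51, 3)
      ),
      oil_feeds = list(oil_feed(51, frac_vv = 6), oil_feed(72, frac_vv = 6)),
      name = "fb3"
    ),
    fb4 = process_config(
      V0 = 3, c_gluc0 = 20, c_nano30 = 2, t_growth_end = 44.5, t_end = 307,
      feed = exponential_feed(
        27, 43.9, mu_set = 0.08, V0 = 3,
        cx0 = cx0_from_total_mass(701, 0.08, 27, 43.9, 3)
      ),
      oil_feeds = list(
        oil_feed(44.5, frac_vv = 6),
        oil_feed(52, 82, kind = "continuous", rate_ml_h = 8)
      ),
      name = "fb4"
    )
  )
}

#' @rdname mel_scenario
#' @export
mel_scenarios <- function() {
  nm <- c("toy", "b1", "b2", "fb1", "fb2", "fb3", "fb4")
  setNames(lapply(nm, mel_scenario), nm)
}
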