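#' Process configuration for a two-phase fermentation
#'
#' Fully defines one simulated fermentation: initial state, kinetic
#' parameters, the optional exponential medium feed, the oil feed schedule,
#' phase boundary and integrator step sizes.
#'
#' @param V0 initial liquid volume (L).
#' @param c_x0 initial dry biomass (g/L); default 0.21 g/L, i.e. inoculation
#'   to OD625 = 0.6 converted with the 0.35 g/L-per-OD correlation.
#' @param c_gluc0,c_nano30 initial glucose and NaNO3 (g/L).
#' @param params a [mel_params()] set.
#' @param feed optional [exponential_feed()] for the fed-batch growth part.
#' @param oil_feeds list of [oil_feed()] events for the production phase.
#' @param t_growth_end time of the growth-to-production hand-over (h).
#' @param t_end end of the simulated process (h); equal to `t_growth_end`
#'   for a growth-only simulation.
#' @param dt_growth,dt_production explicit-Euler step sizes (h); published
#'   scheme uses 0.05 h (growth) and 0.2 h (production).
#' @param use_total_biomass see [production_rhs()].
#' @param seed integer seed recorded for downstream synthetic-data use.
#' @param name optional scenario label.
#' @return An object of class `mel_config`.
#' @export
process_config <- function(V0, c_x0 = 0.21, c_gluc0 = 30, c_nano30 = 3,
                           params = mel_params(), feed = NULL,
                           oil_feeds = list(), t_growth_end, t_end,
                           dt_growth = 0.05, dt_production = 0.2,
                           use_total_biomass = FALSE, seed = 1L,
                           name = NULL) {
  if (dt_growth <= 0 || dt_production <= 0) abort("step sizes must be positive")
  if (t_end < t_growth_end) abort("t_end must be >= t_growth_end")
  if (V0 <= 0) abort("initial volume must be positive")
  if (min(c_x0, c_gluc0, c_nano30) < 0) abort("concentrations must be non-negative")
  if (!is.null(feed)) stopifnot(inherits(feed, "mel_feed"))
  if (inherits(oil_feeds, "mel_oil_feed")) oil_feeds <- list(oil_feeds)
  for (ev in oil_feeds) {
    stopifnot(inherits(ev, "mel_oil_feed"))
    if (ev$t_start < t_growth_end) {
      abort("oil feed events must not start before the growth phase ends")
    }
  }
  structure(
    list(
      V0 = V0, c_x0 = c_x0, c_gluc0 = c_gluc0, c_nano30 = c_nano30,
      params = params, feed = feed, oil_feeds = oil_feeds,
      t_growth_end = t_growth_end, t_end = t_end,
      dt_growth = dt_growth, dt_production = dt_production,
      use_total_biomass = use_total_biomass, seed = as.integer(seed),
      name = name
    ),
    class = "mel_config"
  )
}

#' @export
print.mel_config <- function(x, ...) {
  cat(sprintf(
    "<mel_config>%s V0 %.2g L, growth 0-%g h (dt %g), production to %g h (dt %g)\n",
    if (is.null(x$name)) "" else paste0(" [", x$name, "]"),
    x$V0, x$t_growth_end, x$dt_growth, x$t_end, x$dt_production
  ))
  if (!is.null(x$feed)) print(x$feed)
  for (ev in x$oil_feeds) print(ev)
  invisible(x)
}

#' One explicit Euler step with non-negativity clamp
#'
#' Advances a state vector by `state + dt * deriv`, then clamps negative
#' components to zero (explicit Euler can undershoot near substrate
#' exhaustion). A warning reports any component that undershoots below
#' -1e-6 before clamping.
#'
#' @param state named numeric state vector.
#' @param deriv derivative vector, same names/order.
#' @param dt step size (h).
#' @return Updated state vector.
#' @export
euler_step <- function(state, deriv, dt) {
  if (dt <= 0) abort("dt must be positive")
  if (!all(is.finite(deriv))) {
    bad <- names(deriv)[!is.finite(deriv)]
    abort(paste0("non-finite derivative for: ", paste(bad, collapse = ", ")))
  }
  out <- state + dt * deriv
  if (any(out < -1e-6)) {
    bad <- names(out)[out < -1e-6]
    warn(paste0("Euler undershoot clamped to zero for: ",
                paste(bad, collapse = ", ")))
  }
  pmax(out, 0)
}

# Build the unified trajectory tibble from a record matrix.
as_trajectory <- function(mat, phase, config, handover = NULL, fed = list()) {
  out <- as_tibble(as.data.frame(mat))
  out$phase <- phase
  out <- out[, c(
    "t_h", "phase", "V_L", "c_x_free", "c_x_incl", "c_x_total",
    "c_gluc", "c_nano3", "c_oil", "c_fa", "c_mel", "F_in",
    "mu", "q_hyd", "q_mel", "q_incl"
  )]
  structure(out,
    class = c("mel_trajectory", class(out)),
    config = config, handover = handover, fed_volumes = fed
  )
}

#' Simulate the growth phase
#'
#' Integrates the growth model (batch, then fed-batch if a feed is
#' configured) with the explicit Euler scheme from time 0 to
#' `t_growth_end`.
#'
#' @param config a [process_config()].
#' @return A `mel_trajectory` tibble (one row per Euler grid point) with a
#'   `handover` attribute holding the end-of-growth state.
#' @examples
#' cfg <- process_config(V0 = 4, t_growth_end = 48, t_end = 48)
#' traj <- simulate_growth(cfg)
#' tail(traj$c_x_total, 1)  # yield-limited final biomass, ~5.3 g/L
#' @export
simulate_growth <- function(config) {
  stopifnot(inherits(config, "mel_config"))
  p <- config$params
  feed <- config$feed
  dt <- config$dt_growth
  n <- floor(config$t_growth_end / dt + 1e-9) + 1L
  times <- (seq_len(n) - 1L) * dt
  # last grid point may fall short of t_growth_end if not a multiple of dt
  rec <- matrix(0, nrow = n, ncol = 16,
                dimnames = list(NULL, c(
                  "t_h", "V_L", "c_x_free", "c_x_incl", "c_x_total",
                  "c_gluc", "c_nano3", "c_oil", "c_fa", "c_mel", "F_in",
                  "mu", "q_hyd", "q_mel", "q_incl", "phase_dummy")))
  V <- config$V0; cx <- config$c_x0
  cg <- config$c_gluc0; cn <- config$c_nano30
  fed_medium <- 0
  mu_max <- p$mu_max; Kg <- p$K_gluc; Kn <- p$K_nano3
  qg <- p$mu_max / p$Y_x_gluc; qn <- p$mu_max / p$Y_x_nano3
  F0 <- 0; cg_feed <- 0; cn_feed <- 0
  if (!is.null(feed)) {
    F0 <- exponential_feed_rate(feed$t_start, feed)
    cg_feed <- feed$c_gluc_feed; cn_feed <- feed$c_nano3_feed
  }
  undershoot <- FALSE
  for (i in seq_len(n)) {
    t <- times[i]
    F_in <- 0
    if (!is.null(feed) && t >= feed$t_start && t < feed$t_end) {
      F_in <- F0 * exp(feed$mu_set * (t - feed$t_start))
    }
    mu <- mu_max * min(cg / (Kg + cg), cn / (Kn + cn))
    rec[i, 1:15] <- c(t, V, cx, 0, cx, cg, cn, 0, 0, 0, F_in, mu, 0, 0, 0)
    if (i == n) break
    D <- F_in / V
    cx1 <- cx + dt * (-D * cx + mu * cx)
    cg1 <- cg + dt * (D * (cg_feed - cg) - (mu / p$Y_x_gluc) * cx)
    cn1 <- cn + dt * (D * (cn_feed - cn) - (mu / p$Y_x_nano3) * cx)
    if (min(cx1, cg1, cn1) < -1e-6) undershoot <- TRUE
    cx <- max(cx1, 0); cg <- max(cg1, 0); cn <- max(cn1, 0)
    V <- V + dt * F_in
    fed_medium <- fed_medium + dt * F_in
  }
  if (undershoot) warn("Euler undershoot clamped to zero during growth phase")
  handover <- list(t = times[n], V_L = V, c_x = cx, c_gluc = cg, c_nano3 = cn)
  as_trajectory(rec[, 1:16, drop = FALSE], "growth", config,
                handover = handover, fed = list(medium_l = fed_medium))
}

#' Simulate the production phase
#'
#' Integrates the production model from the growth hand-over state to
#' `t_end` with the explicit Euler scheme, applying oil feed events. Bolus
#' additions are applied at the nearest Euler grid time at or before the
#' event time as instantaneous perfect mixing: all concentrations are scaled
#' by `V_old/V_new` and the oil concentration gains `added mass / V_new`.
#' Continuous oil feeds enter through the feed term with an oil feed
#' concentration of `1000 * oil_density` g/L.
#'
#' The catalytic biomass `c_x_growth` is frozen at the hand-over biomass;
#' the lipid-free pool starts there and the inclusion pool at zero.
#'
#' @param config a [process_config()] with at least one oil feed event for a
#'   productive run.
#' @param handover either a growth `mel_trajectory` (its `handover`
#'   attribute is used) or a list with `t`, `V_L`, `c_x`, `c_gluc`,
#'   `c_nano3`.
#' @return A `mel_trajectory` tibble covering `[t_growth_end, t_end]`.
#' @export
simulate_production <- function(config, handover) {
  stopifnot(inherits(config, "mel_config"))
  if (inherits(handover, "mel_trajectory")) {
    handover <- attr(handover, "handover")
  }
  p <- config$params
  dt <- config$dt_production
  t0 <- config$t_growth_end
  n <- floor((config$t_end - t0) / dt + 1e-9) + 1L
  times <- t0 + (seq_len(n) - 1L) * dt
  cx_growth <- handover$c_x
  V <- handover$V_L
  use_total <- isTRUE(config$use_total_biomass)

  # resolve oil events against the hand-over volume
  boluses <- list(); cont <- list()
  for (ev in config$oil_feeds) {
    vol_ml <- oil_feed_volume_ml(ev, V)
    if (ev$kind == "bolus") {
      idx <- findInterval(ev$t_start + 1e-9, times)
      if (idx < 1L) abort("bolus event before the production phase start")
      boluses[[length(boluses) + 1L]] <-
        list(idx = idx, mass_g = vol_ml * ev$oil_density, vol_l = vol_ml / 1000)
    } else {
      cont[[length(cont) + 1L]] <- list(
        t_start = ev$t_start, t_end = ev$t_end,
        rate_l_h = vol_ml / 1000 / (ev$t_end - ev$t_start),
        c_oil_feed = 1000 * ev$oil_density
      )
    }
  }
  bolus_idx <- vapply(boluses, `[[`, 0, "idx")

  rec <- matrix(0, nrow = n, ncol = 16,
                dimnames = list(NULL, c(
                  "t_h", "V_L", "c_x_free", "c_x_incl", "c_x_total",
                  "c_gluc", "c_nano3", "c_oil", "c_fa", "c_mel", "F_in",
                  "mu", "q_hyd", "q_mel", "q_incl", "phase_dummy")))
  cxf <- cx_growth; cxi <- 0; co <- 0; cf <- 0; cm <- 0
  cg <- handover$c_gluc; cn <- handover$c_nano3
  fed_bolus <- 0; fed_cont <- 0
  undershoot <- FALSE
  for (i in seq_len(n)) {
    t <- times[i]
    # pending boluses at this grid time: instantaneous perfect mixing
    for (b in boluses[bolus_idx == i]) {
      V_new <- V + b$vol_l
      sc <- V / V_new
      cxf <- cxf * sc; cxi <- cxi * sc; cf <- cf * sc; cm <- cm * sc
      cg <- cg * sc; cn <- cn * sc
      co <- co * sc + b$mass_g / V_new
      V <- V_new
      fed_bolus <- fed_bolus + b$vol_l
    }
    F_in <- 0; oil_mass_rate <- 0
    for (cw in cont) {
      if (t >= cw$t_start && t < cw$t_end) {
        F_in <- F_in + cw$rate_l_h
        oil_mass_rate <- oil_mass_rate + cw$rate_l_h * cw$c_oil_feed
      }
    }
    cx_cat <- if (use_total) cxf + cxi else cx_growth
    q_h <- p$q_max_hyd * co / (co + p$K_m_hyd * (1 + cf / p$K_i_hyd))
    q_m <- p$q_max_mel * cf / (cf + p$K_m_mel)
    q_i <- p$q_max_incl * cf / (cf + p$K_m_incl)
    rec[i, 1:15] <- c(t, V, cxf, cxi, cxf + cxi, cg, cn, co, cf, cm, F_in,
                      0, q_h, q_m, q_i)
    if (i == n) break
    D <- F_in / V
    cxf1 <- cxf + dt * (-D * cxf - p$Y_x_free_incl * q_i * cxf)
    cxi1 <- cxi + dt * (-D * cxi + q_i * cxf)
    co1 <- co + dt * (if (F_in > 0) (oil_mass_rate - F_in * co) / V else 0) -
      dt * q_h * cx_cat
    cf1 <- cf + dt * (-D * cf + (p$Y_fa_oil * q_h - p$Y_fa_mel * q_m) * cx_cat -
                        p$Y_fa_incl * q_i * cxf)
    cm1 <- cm + dt * (-D * cm + q_m * cx_cat)
    cg <- cg - dt * D * cg
    cn <- cn - dt * D * cn
    if (min(cxf1, cxi1, co1, cf1, cm1) < -1e-6) undershoot <- TRUE
    cxf <- max(cxf1, 0); cxi <- max(cxi1, 0)
    co <- max(co1, 0); cf <- max(cf1, 0); cm <- max(cm1, 0)
    V <- V + dt * F_in
    fed_cont <- fed_cont + dt * F_in
  }
  if (undershoot) warn("Euler undershoot clamped to zero during production phase")
  as_trajectory(rec, "production", config,
                handover = handover,
                fed = list(oil_bolus_l = fed_bolus, oil_continuous_l = fed_cont))
}

#' Simulate a full two-phase process
#'
#' Chains [simulate_growth()] and [simulate_production()] with the correct
#' hand-over: the production phase starts from the end-of-growth state, with
#' the catalytic biomass frozen there. When `t_end == t_growth_end` the
#' result is the growth trajectory alone.
#'
#' @param config a [process_config()].
#' @return A `mel_trajectory` tibble with a single growth-to-production
#'   phase transition, strictly increasing time, and attributes `handover`
#'   (end-of-growth state) and `fed_volumes` (feed bookkeeping in L).
#' @examples
#' traj <- simulate_process(mel_scenario("toy"))
#' dplyr::filter(traj, t_h == max(t_h))
#' @export
simulate_process <- function(config) {
  stopifnot(inherits(config, "mel_config"))
  growth <- simulate_growth(config)
  if (config$t_end <= config$t_growth_end) return(growth)
  production <- simulate_production(config, growth)
  # keep strictly increasing time: production owns the hand-over instant
  g <- growth[growth$t_h < config$t_growth_end, ]
  out <- dplyr::bind_rows(g, production)
  structure(out,
    class = c("mel_trajectory", class(tibble())),
    config = config,
    handover = attr(growth, "handover"),
    fed_volumes = c(attr(growth, "fed_volumes"), attr(production, "fed_volumes"))
  )
}

#' Feed-volume bookkeeping of a trajectory
#'
#' @param traj a `mel_trajectory`.
#' @return A tibble with the initial volume, the volumes added by medium
#'   feed, oil boluses and continuous oil feeds, and the final volume.
#' @export
fed_volumes <- function(traj) {
  stopifnot(inherits(traj, "mel_trajectory"))
  fed <- attr(traj, "fed_volumes")
  cfg <- attr(traj, "config")
  tibble(
    V0 = cfg$V0,
    medium_l = fed$medium_l %||% 0,
    oil_bolus_l = fed$oil_bolus_l %||% 0,
    oil_continuous_l = fed$oil_continuous_l %||% 0,
    V_final = tail(traj$V_L, 1)
  )
}
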