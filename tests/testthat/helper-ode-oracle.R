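# Independent reference integrator: adaptive high-order solution (lsoda via
# deSolve) of the same two-phase model, with bolus events applied as state
# jumps. Used only as an oracle against the package's explicit Euler scheme.

ode_reference <- function(config) {
  p <- config$params
  feed <- config$feed

  growth_rhs_ode <- function(t, y, parms) {
    F_in <- 0
    if (!is.null(feed) && t >= feed$t_start && t < feed$t_end) {
      F_in <- exponential_feed_rate(t, feed)
    }
    mu <- p$mu_max * min(y["cg"] / (p$K_gluc + y["cg"]),
                         y["cn"] / (p$K_nano3 + y["cn"]))
    D <- F_in / y["V"]
    cg_feed <- if (is.null(feed)) 0 else feed$c_gluc_feed
    cn_feed <- if (is.null(feed)) 0 else feed$c_nano3_feed
    list(c(
      V = F_in,
      cx = -D * y["cx"] + mu * y["cx"],
      cg = D * (cg_feed - y["cg"]) - (mu / p$Y_x_gluc) * y["cx"],
      cn = D * (cn_feed - y["cn"]) - (mu / p$Y_x_nano3) * y["cx"]
    ))
  }
  y0 <- c(V = config$V0, cx = config$c_x0, cg = config$c_gluc0,
          cn = config$c_nano30)
  gt <- seq(0, config$t_growth_end, length.out = 201)
  g <- deSolve::ode(y0, gt, growth_rhs_ode, NULL, method = "lsoda",
                    rtol = 1e-9, atol = 1e-10)
  gend <- g[nrow(g), ]
  handover <- list(V_L = unname(gend["V"]), c_x = max(unname(gend["cx"]), 0),
                   c_gluc = max(unname(gend["cg"]), 0),
                   c_nano3 = max(unname(gend["cn"]), 0))
  if (config$t_end <= config$t_growth_end) {
    return(list(growth = g, handover = handover, endpoint = handover))
  }

  cx_growth <- handover$c_x
  boluses <- list(); cont <- list()
  for (ev in config$oil_feeds) {
    vol_ml <- melkin:::oil_feed_volume_ml(ev, handover$V_L)
    if (ev$kind == "bolus") {
      boluses[[length(boluses) + 1]] <-
        list(t = ev$t_start, vol_l = vol_ml / 1000,
             mass_g = vol_ml * ev$oil_density)
    } else {
      cont[[length(cont) + 1]] <- list(
        t_start = ev$t_start, t_end = ev$t_end,
        rate_l_h = vol_ml / 1000 / (ev$t_end - ev$t_start),
        c_feed = 1000 * ev$oil_density
      )
    }
  }
  # match the package's grid semantics: boluses land on the Euler grid point
  # at or before the event time
  snap <- function(t) {
    config$t_growth_end +
      floor((t - config$t_growth_end) / config$dt_production + 1e-9) *
        config$dt_production
  }
  bolus_times <- vapply(boluses, function(b) snap(b$t), 0)

  prod_rhs_ode <- function(t, y, parms) {
    F_in <- 0; oil_rate <- 0
    for (cw in cont) {
      if (t >= cw$t_start && t < cw$t_end) {
        F_in <- F_in + cw$rate_l_h
        oil_rate <- oil_rate + cw$rate_l_h * cw$c_feed
      }
    }
    co <- max(y["co"], 0); cf <- max(y["cf"], 0)
    q_h <- p$q_max_hyd * co / (co + p$K_m_hyd * (1 + cf / p$K_i_hyd))
    q_m <- p$q_max_mel * cf / (cf + p$K_m_mel)
    q_i <- p$q_max_incl * cf / (cf + p$K_m_incl)
    cx_cat <- if (isTRUE(config$use_total_biomass)) y["cxf"] + y["cxi"]
      else cx_growth
    D <- F_in / y["V"]
    list(c(
      V = F_in,
      cxf = -D * y["cxf"] - p$Y_x_free_incl * q_i * y["cxf"],
      cxi = -D * y["cxi"] + q_i * y["cxf"],
      co = (if (F_in > 0) (oil_rate - F_in * y["co"]) / y["V"] else 0) -
        q_h * cx_cat,
      cf = -D * y["cf"] + (p$Y_fa_oil * q_h - p$Y_fa_mel * q_m) * cx_cat -
        p$Y_fa_incl * q_i * y["cxf"],
      cm = -D * y["cm"] + q_m * cx_cat
    ))
  }
  eventfun <- function(t, y, parms) {
    for (k in seq_along(bolus_times)) {
      if (abs(t - bolus_times[k]) < 1e-8) {
        b <- boluses[[k]]
        Vn <- y["V"] + b$vol_l
        sc <- y["V"] / Vn
        y[c("cxf", "cxi", "cf", "cm")] <- y[c("cxf", "cxi", "cf", "cm")] * sc
        y["co"] <- y["co"] * sc + b$mass_g / Vn
        y["V"] <- Vn
      }
    }
    y
  }
  y0p <- c(V = handover$V_L, cxf = cx_growth, cxi = 0, co = 0, cf = 0, cm = 0)
  pt <- sort(unique(c(seq(config$t_growth_end, config$t_end, length.out = 301),
                      bolus_times,
                      unlist(lapply(cont, function(cw) c(cw$t_start, cw$t_end))))))
  pt <- pt[pt >= config$t_growth_end & pt <= config$t_end]
  pr <- deSolve::ode(y0p, pt, prod_rhs_ode, NULL, method = "lsoda",
                     rtol = 1e-9, atol = 1e-10,
                     events = list(func = eventfun, time = bolus_times))
  pend <- pr[nrow(pr), ]
  list(
    growth = g, handover = handover, production = pr,
    endpoint = list(V_L = unname(pend["V"]),
                    c_x_total = unname(pend["cxf"] + pend["cxi"]),
                    c_oil = unname(pend["co"]), c_fa = unname(pend["cf"]),
                    c_mel = unname(pend["cm"]))
  )
}
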