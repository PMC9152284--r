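#' Specific growth rate under dual substrate limitation
#'
#' Monod kinetics on glucose and sodium nitrate as two non-complementary
#' limiting substrates; growth is dominated by the most limiting compound via
#' a minimum operator:
#' \deqn{\mu = \mu_{max}\,\min\left\{\frac{c_{gluc}}{K_{gluc}+c_{gluc}},\;
#'   \frac{c_{NaNO_3}}{K_{NaNO_3}+c_{NaNO_3}}\right\}}
#'
#' @param c_gluc glucose concentration (g/L); vectorised.
#' @param c_nano3 sodium nitrate concentration (g/L); vectorised.
#' @param params a [mel_params()] set.
#' @return Specific growth rate (1/h), bounded by `[0, mu_max]`.
#' @examples
#' specific_growth_rate(30, 3)          # unlimited: ~mu_max
#' specific_growth_rate(1, 1000)        # glucose at K: mu_max/2
#' @export
specific_growth_rate <- function(c_gluc, c_nano3, params = mel_params()) {
  if (any(c_gluc < 0) || any(c_nano3 < 0)) {
    abort("substrate concentrations must be non-negative")
  }
  params$mu_max * pmin(
    c_gluc / (params$K_gluc + c_gluc),
    c_nano3 / (params$K_nano3 + c_nano3)
  )
}

#' Growth-phase ODE right-hand side
#'
#' Time derivatives of liquid volume, biomass, glucose and nitrate during the
#' growth phase. Each substrate carries a dilution/feed term
#' \eqn{(F_{in}/V_L)(c_{feed} - c)} and a consumption term
#' \eqn{-(\mu/Y_{X/S}) c_x}; biomass is diluted and grows at \eqn{\mu c_x};
#' volume increases with the feed.
#'
#' @param state named numeric vector or list with `V_L`, `c_x`, `c_gluc`,
#'   `c_nano3` (time is not needed by the autonomous part).
#' @param F_in volumetric feed rate (L/h).
#' @param feed an [exponential_feed()] (supplies feed concentrations); may be
#'   `NULL` when `F_in = 0`.
#' @param params a [mel_params()] set.
#' @return Named numeric vector of derivatives `(V_L, c_x, c_gluc, c_nano3)`.
#' @export
growth_rhs <- function(state, F_in = 0, feed = NULL, params = mel_params()) {
  s <- as.list(state)
  if (s$V_L <= 0) abort("liquid volume must be positive")
  if (F_in < 0) abort("feed rate must be non-negative")
  cg_feed <- if (is.null(feed)) 0 else feed$c_gluc_feed
  cn_feed <- if (is.null(feed)) 0 else feed$c_nano3_feed
  mu <- specific_growth_rate(s$c_gluc, s$c_nano3, params)
  D <- F_in / s$V_L
  c(
    V_L = F_in,
    c_x = -D * s$c_x + mu * s$c_x,
    c_gluc = D * (cg_feed - s$c_gluc) - (mu / params$Y_x_gluc) * s$c_x,
    c_nano3 = D * (cn_feed - s$c_nano3) - (mu / params$Y_x_nano3) * s$c_x
  )
}

#' Exponential feed rate
#'
#' Evaluates the open-loop exponential feeding law at time `t`. Outside the
#' feed window the rate is zero. By default the broth glucose term in the
#' denominator is the feed's fixed reference (`c_gluc_ref`, usually 0 g/L);
#' an explicit `c_gluc` overrides it.
#'
#' @param t process time (h); vectorised.
#' @param feed an [exponential_feed()] specification.
#' @param c_gluc broth glucose concentration used in the denominator (g/L);
#'   default the feed's `c_gluc_ref`.
#' @return Volumetric feed rate (L/h).
#' @examples
#' f <- exponential_feed(44.5, 55, 0.08, V0 = 3, cx0 = 7.6)
#' exponential_feed_rate(44.5, f)  # 0.02432 L/h
#' @export
exponential_feed_rate <- function(t, feed, c_gluc = feed$c_gluc_ref) {
  stopifnot(inherits(feed, "mel_feed"))
  if (c_gluc >= feed$c_gluc_feed) {
    abort("broth glucose at or above the feed concentration: feed law diverges")
  }
  F0 <- feed$V0 * feed$cx0 * feed$mu_set /
    (feed$Y_x_gluc_feed * (feed$c_gluc_feed - c_gluc))
  ifelse(t >= feed$t_start & t <= feed$t_end,
         F0 * exp(feed$mu_set * (t - feed$t_start)), 0)
}

#' Specific oil hydrolysis rate
#'
#' Michaelis-Menten kinetics in the oil concentration with competitive-type
#' product inhibition by free fatty acids:
#' \deqn{q_{hyd} = q_{max,hyd}\frac{c_{oil}}
#'   {c_{oil} + K_{m,hyd}\,(1 + c_{FA}/K_{i,hyd})}}
#'
#' @param c_oil oil (triglyceride) concentration (g/L); vectorised.
#' @param c_fa free fatty acid concentration (g/L); vectorised.
#' @param params a [mel_params()] set.
#' @return Specific hydrolysis rate (g oil/g biomass/h).
#' @examples
#' hydrolysis_rate(5, 0)    # half saturation: q_max/2
#' hydrolysis_rate(5, 20)   # inhibited
#' @export
hydrolysis_rate <- function(c_oil, c_fa, params = mel_params()) {
  if (any(c_oil < 0) || any(c_fa < 0)) abort("concentrations must be non-negative")
  params$q_max_hyd * c_oil /
    (c_oil + params$K_m_hyd * (1 + c_fa / params$K_i_hyd))
}

#' Specific MEL formation rate
#'
#' Single "black-box" Michaelis-Menten conversion of free fatty acids into
#' MEL: \eqn{q_{MEL} = q_{max,MEL}\, c_{FA}/(c_{FA} + K_{m,MEL})}.
#'
#' @param c_fa free fatty acid concentration (g/L); vectorised.
#' @param params a [mel_params()] set.
#' @return Specific MEL formation rate (g MEL/g biomass/h).
#' @export
mel_rate <- function(c_fa, params = mel_params()) {
  if (any(c_fa < 0)) abort("concentrations must be non-negative")
  params$q_max_mel * c_fa / (c_fa + params$K_m_mel)
}

#' Specific lipid-inclusion rate
#'
#' Michaelis-Menten uptake of free fatty acids into intracellular storage
#' lipids: \eqn{q_{incl} = q_{max,incl}\, c_{FA}/(c_{FA} + K_{m,incl})}.
#'
#' @inheritParams mel_rate
#' @return Specific inclusion rate (g/g/h).
#' @export
inclusion_rate <- function(c_fa, params = mel_params()) {
  if (any(c_fa < 0)) abort("concentrations must be non-negative")
  params$q_max_incl * c_fa / (c_fa + params$K_m_incl)
}

#' Production-phase ODE right-hand side
#'
#' Time derivatives of volume, the two biomass pools, oil, fatty acids and
#' MEL during the production phase. All substrate/product reaction fluxes
#' (hydrolysis, MEL formation, inclusion) are scaled by the catalytic biomass
#' `c_x_growth` frozen at the end of the growth phase; optionally
#' (`use_total_biomass = TRUE`) by the current total measurable biomass
#' `c_x_free + c_x_incl` for sensitivity analysis. The biomass pool
#' equations convert lipid-free biomass into inclusion biomass at
#' `q_incl * c_x_free`, with the lipid-free pool decreasing by
#' `Y_x_free_incl` times that flux; the fatty acid stored away by inclusion
#' is `Y_fa_incl` times the same flux (`q_incl * c_x_free`), so the
#' inclusion bookkeeping balances exactly: 1.128 g fatty acid disappear per
#' g of inclusion biomass formed. Every species carries a dilution term
#' `(F_in/V_L) (c_feed - c)`, with zero feed concentration for fatty acids,
#' MEL and both biomass pools.
#'
#' @param state named numeric vector or list with `V_L`, `c_x_free`,
#'   `c_x_incl`, `c_oil`, `c_fa`, `c_mel`, `c_x_growth`.
#' @param F_in volumetric feed rate (L/h), e.g. a continuous oil feed.
#' @param c_oil_feed oil concentration of the feed stream (g/L); for a neat
#'   oil feed this is `1000 * oil_density`.
#' @param params a [mel_params()] set.
#' @param use_total_biomass scale reaction fluxes by current total biomass
#'   instead of the frozen `c_x_growth`.
#' @return Named numeric vector of derivatives
#'   `(V_L, c_x_free, c_x_incl, c_oil, c_fa, c_mel)`.
#' @export
production_rhs <- function(state, F_in = 0, c_oil_feed = 0,
                           params = mel_params(), use_total_biomass = FALSE) {
  s <- as.list(state)
  if (s$V_L <= 0) abort("liquid volume must be positive")
  if (F_in < 0) abort("feed rate must be non-negative")
  cx_cat <- if (use_total_biomass) s$c_x_free + s$c_x_incl else s$c_x_growth
  q_h <- hydrolysis_rate(s$c_oil, s$c_fa, params)
  q_m <- mel_rate(s$c_fa, params)
  q_i <- inclusion_rate(s$c_fa, params)
  D <- F_in / s$V_L
  c(
    V_L = F_in,
    c_x_free = D * (0 - s$c_x_free) -
      params$Y_x_free_incl * q_i * s$c_x_free,
    c_x_incl = D * (0 - s$c_x_incl) + q_i * s$c_x_free,
    c_oil = D * (c_oil_feed - s$c_oil) - q_h * cx_cat,
    c_fa = D * (0 - s$c_fa) + params$Y_fa_oil * q_h * cx_cat -
      params$Y_fa_mel * q_m * cx_cat - params$Y_fa_incl * q_i * s$c_x_free,
    c_mel = D * (0 - s$c_mel) + q_m * cx_cat
  )
}
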