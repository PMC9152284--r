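#' Kinetic parameter set for the two-phase MEL fermentation model
#'
#' Builds the full set of rate and yield constants used by both partial
#' models: dual-substrate Monod growth on glucose and sodium nitrate, and the
#' production phase coupling oil (triglyceride) hydrolysis, fatty-acid-to-MEL
#' conversion and intracellular lipid inclusion. Defaults are the published
#' model calibration for *Moesziomyces aphidis*; any subset can be overridden
#' by name.
#'
#' Growth parameters:
#' \describe{
#'   \item{mu_max}{maximum specific growth rate (1/h)}
#'   \item{K_gluc, K_nano3}{Monod half-saturation constants for glucose and
#'     NaNO3 (g/L)}
#'   \item{Y_x_gluc, Y_x_nano3}{biomass yields from glucose and NaNO3 (g/g)}
#' }
#' The maximum specific consumption rates are derived, not stored:
#' `q_max_gluc = mu_max / Y_x_gluc` and `q_max_nano3 = mu_max / Y_x_nano3`.
#'
#' Production parameters:
#' \describe{
#'   \item{q_max_hyd, K_m_hyd, K_i_hyd}{maximum specific oil hydrolysis rate
#'     (g oil/g biomass/h), oil affinity (g/L) and fatty-acid product
#'     inhibition constant (g/L) of the lipase term}
#'   \item{Y_fa_oil}{fatty acid released per oil hydrolysed (g/g), from
#'     triolein stoichiometry}
#'   \item{q_max_mel, K_m_mel}{maximum specific MEL formation rate
#'     (g MEL/g biomass/h) and fatty-acid affinity (g/L)}
#'   \item{Y_fa_mel}{fatty acid consumed per MEL formed (g/g)}
#'   \item{q_max_incl, K_m_incl}{maximum specific lipid-inclusion rate
#'     (g/g/h) and fatty-acid affinity (g/L)}
#'   \item{Y_x_free_incl}{lipid-free biomass converted per unit of
#'     inclusion-forming flux (g/g)}
#'   \item{Y_fa_incl}{fatty acid stored per unit of inclusion biomass formed
#'     (g/g)}
#' }
#'
#' @param ... named overrides of individual parameters.
#' @return An object of class `mel_params`: a named list with the 16
#'   parameters above.
#' @examples
#' p <- mel_params()
#' p$mu_max
#' mel_params(q_max_mel = 0.03)$q_max_mel
#' @export
mel_params <- function(...) {
  p <- list(
    # growth
    mu_max    = 0.11,
    K_gluc    = 1,
    K_nano3   = 0.01,
    Y_x_gluc  = 0.17,
    Y_x_nano3 = 1.7,
    # production: hydrolysis
    q_max_hyd = 0.1,
    K_m_hyd   = 5,
    K_i_hyd   = 20,
    Y_fa_oil  = 0.957,
    # production: MEL formation
    q_max_mel = 0.02,
    K_m_mel   = 5,
    Y_fa_mel  = 1.667,
    # production: lipid inclusion
    q_max_incl    = 0.07,
    K_m_incl      = 1,
    Y_x_free_incl = 0.203,
    Y_fa_incl     = 1.128
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad) || is.null(names(over)) || any(names(over) == "")) {
      abort(paste0("unknown parameter(s): ", paste(bad, collapse = ", ")))
    }
    p[names(over)] <- over
  }
  validate_mel_params(structure(p, class = "mel_params"))
}

validate_mel_params <- function(p) {
  vals <- unlist(p[setdiff(names(p), "class")])
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    abort("all kinetic parameters must be finite and strictly positive")
  }
  p
}

#' @export
print.mel_params <- function(x, ...) {
  cat("<mel_params> two-phase MEL fermentation kinetic parameters\n")
  df <- tibble(parameter = names(x), value = unlist(x))
  print(as.data.frame(df), row.names = FALSE)
  cat(sprintf(
    "derived: q_max_gluc = %.3f g/g/h, q_max_nano3 = %.4f g/g/h\n",
    x$mu_max / x$Y_x_gluc, x$mu_max / x$Y_x_nano3
  ))
  invisible(x)
}

#' Derived maximum specific substrate consumption rates
#'
#' The growth model stores yields, not consumption rates; the maximum
#' specific glucose and nitrate consumption rates follow as
#' `mu_max / Y_x_s`.
#'
#' @param params a [mel_params()] set.
#' @return A tibble with columns `substrate` and `q_max` (g/g/h).
#' @export
q_max_derived <- function(params = mel_params()) {
  tibble(
    substrate = c("glucose", "nano3"),
    q_max = c(params$mu_max / params$Y_x_gluc, params$mu_max / params$Y_x_nano3)
  )
}

#' Exponential medium-feed specification
#'
#' Defines the open-loop exponential feeding law used during the fed-batch
#' part of the growth phase. The volumetric feed rate is
#' \deqn{F_{in}(t) = \frac{(V_L c_x)_0\, \mu_{set}}
#'   {Y_{X/gluc}\,(c_{gluc,Feed} - c_{gluc})} e^{\mu_{set} (t - t_{start})}}
#' with \eqn{(V_L c_x)_0} the volume-biomass product at feed start. The
#' glucose concentration entering the denominator is a fixed reference
#' (default 0 g/L, i.e. glucose-limited conditions), so the law stays
#' open-loop.
#'
#' @param t_start,t_end feed window (h).
#' @param mu_set target specific growth rate (1/h).
#' @param V0 liquid volume at feed start (L).
#' @param cx0 biomass concentration assumed at feed start (g/L); this is the
#'   pump-program value, not necessarily the simulated state.
#' @param Y_x_gluc_feed biomass yield assumed by the feed law (g/g).
#' @param c_gluc_feed,c_nano3_feed feed solution concentrations (g/L).
#' @param feed_density feed solution density (g/mL); 1 by convention.
#' @param c_gluc_ref reference broth glucose concentration in the
#'   denominator (g/L).
#' @return An object of class `mel_feed`.
#' @examples
#' exponential_feed(44.5, 55, mu_set = 0.08, V0 = 3, cx0 = 7.6)
#' @export
exponential_feed <- function(t_start, t_end, mu_set, V0, cx0,
                             Y_x_gluc_feed = 0.25,
                             c_gluc_feed = 300, c_nano3_feed = 30,
                             feed_density = 1, c_gluc_ref = 0) {
  if (t_end <= t_start) abort("t_end must exceed t_start")
  if (mu_set <= 0) abort("mu_set must be positive")
  if (c_gluc_feed <= 0) abort("c_gluc_feed must be positive")
  if (c_gluc_ref >= c_gluc_feed) {
    abort("reference glucose must be below the feed concentration")
  }
  structure(
    list(
      t_start = t_start, t_end = t_end, mu_set = mu_set,
      V0 = V0, cx0 = cx0, Y_x_gluc_feed = Y_x_gluc_feed,
      c_gluc_feed = c_gluc_feed, c_nano3_feed = c_nano3_feed,
      feed_density = feed_density, c_gluc_ref = c_gluc_ref
    ),
    class = "mel_feed"
  )
}

#' @export
print.mel_feed <- function(x, ...) {
  cat(sprintf(
    "<mel_feed> exponential feed %.1f-%.1f h, mu_set %.3g 1/h, (V cx)0 = %.3g g\n",
    x$t_start, x$t_end, x$mu_set, x$V0 * x$cx0
  ))
  invisible(x)
}

#' Cumulative delivery of an exponential feed
#'
#' Integrates the feeding law analytically from feed start to `t` and
#' converts the fed volume into solution mass and substrate masses.
#'
#' @param feed an [exponential_feed()] specification.
#' @param t time (h) at which to evaluate the cumulative totals; defaults to
#'   the feed end.
#' @return A tibble with `volume_l`, `mass_g` (volume times density),
#'   `glucose_g` and `nano3_g`.
#' @examples
#' feed_totals(exponential_feed(44.5, 55, 0.08, V0 = 3, cx0 = 7.6))
#' @export
feed_totals <- function(feed, t = feed$t_end) {
  stopifnot(inherits(feed, "mel_feed"))
  tau <- min(max(t, feed$t_start), feed$t_end) - feed$t_start
  F0 <- exponential_feed_rate(feed$t_start, feed)
  vol <- F0 * (exp(feed$mu_set * tau) - 1) / feed$mu_set
  tibble(
    volume_l = vol,
    mass_g = vol * feed$feed_density * 1000,
    glucose_g = vol * feed$c_gluc_feed,
    nano3_g = vol * feed$c_nano3_feed
  )
}

#' Substrate content of a weighed amount of feed solution
#'
#' Converts a mass of feed solution into the substrate masses it carries,
#' using the feed's density and composition (460 g of a 300 g/L glucose feed
#' at unit density carry 138 g glucose).
#'
#' @param mass_g feed solution mass (g).
#' @param feed an [exponential_feed()] specification.
#' @return A tibble with `volume_l`, `glucose_g`, `nano3_g`.
#' @export
feed_delivery <- function(mass_g, feed) {
  stopifnot(inherits(feed, "mel_feed"))
  vol <- mass_g / (feed$feed_density * 1000)
  tibble(volume_l = vol, glucose_g = vol * feed$c_gluc_feed,
         nano3_g = vol * feed$c_nano3_feed)
}

#' Oil feed event
#'
#' A single addition of plant oil to the production phase, either as an
#' instantaneous bolus or as a continuous feed over a window. Amounts can be
#' given as an absolute volume (`volume_ml`), as a percentage of a reference
#' broth volume (`frac_vv`, % v/v), or — for continuous feeds — as a rate
#' (`rate_ml_h`).
#'
#' @param t_start event time (h); for continuous feeds, window start.
#' @param t_end window end (h); equals `t_start` for a bolus.
#' @param kind `"bolus"` or `"continuous"`.
#' @param volume_ml absolute oil volume (mL).
#' @param frac_vv oil volume as % v/v of `reference_volume`.
#' @param rate_ml_h continuous feed rate (mL/h).
#' @param reference_volume reference broth volume (L) for `frac_vv`; `NA`
#'   means "broth volume at the start of the production phase".
#' @param oil_density oil density (g/mL); rapeseed oil default 0.92.
#' @return An object of class `mel_oil_feed`.
#' @examples
#' oil_feed(48, frac_vv = 6, reference_volume = 4)
#' oil_feed(72, 140, kind = "continuous", rate_ml_h = 11)
#' @export
oil_feed <- function(t_start, t_end = t_start, kind = c("bolus", "continuous"),
                     volume_ml = NULL, frac_vv = NULL, rate_ml_h = NULL,
                     reference_volume = NA_real_, oil_density = 0.92) {
  kind <- match.arg(kind)
  if (kind == "bolus") {
    if (t_end != t_start) abort("a bolus has t_end == t_start")
    if (is.null(volume_ml) && is.null(frac_vv)) {
      abort("a bolus needs volume_ml or frac_vv")
    }
  } else {
    if (t_end <= t_start) abort("a continuous feed needs t_end > t_start")
    if (is.null(rate_ml_h) && is.null(volume_ml) && is.null(frac_vv)) {
      abort("a continuous feed needs rate_ml_h, volume_ml or frac_vv")
    }
  }
  amounts <- c(!is.null(volume_ml), !is.null(frac_vv), !is.null(rate_ml_h))
  if (sum(amounts) != 1) abort("give exactly one of volume_ml, frac_vv, rate_ml_h")
  amt <- c(volume_ml, frac_vv, rate_ml_h)
  if (amt <= 0) abort("oil amount must be positive")
  structure(
    list(
      kind = kind, t_start = t_start, t_end = t_end,
      volume_ml = volume_ml, frac_vv = frac_vv, rate_ml_h = rate_ml_h,
      reference_volume = reference_volume, oil_density = oil_density
    ),
    class = "mel_oil_feed"
  )
}

# Resolve an oil event to an absolute volume (mL), given the production-start
# broth volume used when reference_volume is NA.
oil_feed_volume_ml <- function(event, handover_volume) {
  if (!is.null(event$volume_ml)) return(event$volume_ml)
  if (!is.null(event$frac_vv)) {
    ref <- event$reference_volume
    if (is.na(ref)) ref <- handover_volume
    return(event$frac_vv / 100 * ref * 1000)
  }
  event$rate_ml_h * (event$t_end - event$t_start)
}

#' @export
print.mel_oil_feed <- function(x, ...) {
  amt <- if (!is.null(x$volume_ml)) sprintf("%g mL", x$volume_ml)
    else if (!is.null(x$frac_vv)) sprintf("%g %% v/v", x$frac_vv)
    else sprintf("%g mL/h", x$rate_ml_h)
  cat(sprintf("<mel_oil_feed> %s at %g h: %s (rho %.2f g/mL)\n",
              x$kind, x$t_start, amt, x$oil_density))
  invisible(x)
}
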