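#' @section Window estimators:
#' The rate and yield estimators operate on a window `(t0, t1)` of a
#' time-series data frame. Two methods are available: `"regression"`
#' (default; a linear fit over all points in the window, matching how the
#' published rates were derived) and `"two_point"` (the difference quotient
#' between the window ends). Whenever a biomass-specific quantity needs a
#' single representative biomass for the window, the logarithmic mean of the
#' endpoint biomasses is used; this makes the identity
#' `q_S * Y_X/S = mu` exact in two-point mode and exact for noiseless
#' exponential growth.
#' @name window-estimators
#' @keywords internal
NULL

window_slice <- function(data, window, t_col) {
  if (length(window) != 2 || window[2] <= window[1]) {
    abort("window must be c(t0, t1) with t1 > t0")
  }
  d <- data[data[[t_col]] >= window[1] & data[[t_col]] <= window[2], ]
  if (nrow(d) < 2) abort("need at least 2 observations in the window")
  d[order(d[[t_col]]), ]
}

log_mean <- function(a, b) {
  if (a <= 0 || b <= 0) abort("biomass must be positive")
  if (abs(a - b) < 1e-12 * max(a, b)) return((a + b) / 2)
  (b - a) / (log(b) - log(a))
}

# slope with stderr/r2; two-point falls out of lm with 2 points (r2 = 1)
window_fit <- function(t, y, method) {
  if (method == "two_point") {
    n <- length(t)
    slope <- (y[n] - y[1]) / (t[n] - t[1])
    return(list(slope = slope, stderr = NA_real_, r_squared = NA_real_))
  }
  fit <- lm(y ~ t)
  sm <- suppressWarnings(summary(fit))
  list(slope = unname(coef(fit)[2]),
       stderr = unname(sm$coefficients[2, 2]),
       r_squared = sm$r.squared)
}

#' Specific growth rate from observed biomass
#'
#' Estimates mu over a window from offline biomass samples as the slope of
#' `ln(c_x)` versus time (regression mode), or from the two window-end
#' samples (two-point mode, where the difference quotient is divided by the
#' logarithmic-mean biomass — exactly the log-slope between two points).
#'
#' @param data a data frame of observations.
#' @param window numeric `c(t0, t1)` in hours.
#' @param t,biomass column names (strings) for time and dry biomass.
#' @param method `"regression"` or `"two_point"`.
#' @return A one-row tibble: `t0`, `t1`, `estimate` (1/h), `stderr`,
#'   `r_squared`, `method`, `n`.
#' @examples
#' d <- tibble::tibble(t_h = 0:10, c_x = 0.5 * exp(0.1 * (0:10)))
#' estimate_growth_rate(d, c(0, 10))
#' @export
estimate_growth_rate <- function(data, window, t = "t_h", biomass = "c_x",
                                 method = c("regression", "two_point")) {
  method <- match.arg(method)
  d <- window_slice(data, window, t)
  cx <- d[[biomass]]
  if (any(cx <= 0)) abort("biomass must be positive for growth-rate estimation")
  f <- window_fit(d[[t]], log(cx), method)
  tibble(t0 = window[1], t1 = window[2], estimate = f$slope,
         stderr = f$stderr, r_squared = f$r_squared,
         method = method, n = nrow(d))
}

#' Substrate consumption rate, yield and specific rate over a window
#'
#' Implements the classical window estimators: the volumetric consumption
#' rate `r_S = -dc_S/dt` (positive when the substrate is consumed), the
#' biomass yield `Y_X/S = dc_x / (-dc_S)`, and the biomass-specific rate
#' `q_S = r_S / c_x` with the logarithmic-mean window biomass. In two-point
#' mode the identity `q_S * Y_X/S = mu` (with [estimate_growth_rate()]'s
#' two-point mu) holds exactly.
#'
#' @inheritParams estimate_growth_rate
#' @param substrate column name of the substrate concentration.
#' @return A one-row tibble with `r_s` (g/L/h), `yield` (g/g), `q_s`
#'   (g/g/h), window metadata and regression diagnostics for the substrate
#'   slope.
#' @export
estimate_consumption <- function(data, substrate, window, t = "t_h",
                                 biomass = "c_x",
                                 method = c("regression", "two_point")) {
  method <- match.arg(method)
  d <- window_slice(data, window, t)
  fs <- window_fit(d[[t]], d[[substrate]], method)
  fx <- window_fit(d[[t]], d[[biomass]], method)
  if (abs(fs$slope) < 1e-12 * (abs(mean(d[[substrate]])) + 1)) {
    abort("no substrate change in window: yield undefined")
  }
  cx_bar <- log_mean(head(d[[biomass]], 1), tail(d[[biomass]], 1))
  r_s <- -fs$slope
  tibble(t0 = window[1], t1 = window[2],
         r_s = r_s, yield = fx$slope / (-fs$slope), q_s = r_s / cx_bar,
         stderr = fs$stderr, r_squared = fs$r_squared,
         method = method, n = nrow(d))
}

#' Oxygen uptake, carbon dioxide emission and respiratory quotient
#'
#' Computes OUR, CER and RQ from dry-gas mole fractions at the inlet and
#' exhaust using the inert-gas balance: the nitrogen flow through the vessel
#' is conserved, so the outlet molar flow equals the inlet flow scaled by
#' the ratio of inert fractions,
#' \deqn{OUR = \frac{Q_{air}\, p_{air}}{V_L R T}\left(y_{O_2}^{in} -
#'   \frac{1 - y_{O_2}^{in} - y_{CO_2}^{in}}
#'        {1 - y_{O_2}^{out} - y_{CO_2}^{out}}\, y_{O_2}^{out}\right)}
#' and analogously for CER with the CO2 fractions swapped. With `Q_air` in
#' L/h, `p_air` in Pa, `V_L` in L and `T` in K the result is in mmol/L/h.
#'
#' @param data a data frame with columns `y_o2_in`, `y_co2_in`, `y_o2_out`,
#'   `y_co2_out`, `q_air_lph`, `p_pa`, `t_k`, `v_l` (one off-gas record per
#'   row).
#' @return `data` with columns `our`, `cer` (mmol/L/h) and `rq` appended;
#'   `rq` is `NA` where OUR is not positive.
#' @examples
#' rec <- tibble::tibble(y_o2_in = 0.2095, y_co2_in = 4e-4,
#'                       y_o2_out = 0.19, y_co2_out = 0.02,
#'                       q_air_lph = 168, p_pa = 101325, t_k = 303.15,
#'                       v_l = 4)
#' off_gas_rates(rec)
#' @export
off_gas_rates <- function(data) {
  need <- c("y_o2_in", "y_co2_in", "y_o2_out", "y_co2_out",
            "q_air_lph", "p_pa", "t_k", "v_l")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste0("missing off-gas columns: ", paste(missing_cols, collapse = ", ")))
  }
  inert_in <- 1 - data$y_o2_in - data$y_co2_in
  inert_out <- 1 - data$y_o2_out - data$y_co2_out
  if (any(inert_in <= 0) || any(inert_out <= 0)) {
    abort("mole fractions must leave a positive inert balance (sum < 1)")
  }
  flow <- data$q_air_lph * data$p_pa / (data$v_l * .R_GAS * data$t_k) # mmol/L/h basis
  ratio <- inert_in / inert_out
  our <- flow * (data$y_o2_in - ratio * data$y_o2_out)
  cer <- flow * (ratio * data$y_co2_out - data$y_co2_in)
  rq <- ifelse(our > 0, cer / our, NA_real_)
  dplyr::mutate(as_tibble(data), our = our, cer = cer, rq = rq)
}

#' Outlet gas fractions implied by known OUR and CER
#'
#' Algebraic inverse of [off_gas_rates()]: given volumetric oxygen uptake
#' and carbon dioxide emission rates, reconstructs the dry exhaust mole
#' fractions consistent with the inert-gas balance. Used by the
#' synthetic-data generator and as a round-trip oracle.
#'
#' @param our,cer volumetric rates (mmol/L/h); vectorised.
#' @param y_o2_in,y_co2_in inlet dry-gas mole fractions.
#' @param q_air_lph inlet airflow (L/h).
#' @param p_pa pressure (Pa).
#' @param t_k temperature (K).
#' @param v_l broth volume (L).
#' @return A tibble with `y_o2_out` and `y_co2_out`.
#' @export
invert_off_gas <- function(our, cer, y_o2_in = 0.2095, y_co2_in = 4e-4,
                           q_air_lph = 168, p_pa = 101325, t_k = 303.15,
                           v_l = 4) {
  flow <- q_air_lph * p_pa / (v_l * .R_GAS * t_k)
  inert_in <- 1 - y_o2_in - y_co2_in
  a <- y_o2_in - our / flow       # = ratio * y_o2_out
  b <- y_co2_in + cer / flow      # = ratio * y_co2_out
  if (any(a < 0)) abort("OUR exceeds the oxygen supplied: no physical outlet")
  ratio <- a + b + inert_in       # ratio * (sum of outlet fractions) = ratio
  tibble(y_o2_out = a / ratio, y_co2_out = b / ratio)
}

#' Specific oxygen uptake rate and biomass yield from oxygen
#'
#' `q_O2 = OUR / c_x` evaluated with the logarithmic-mean biomass over the
#' window and the mean OUR in the window; `Y_X/O2` is the biomass formed per
#' oxygen consumed (slope of biomass against cumulative O2 uptake).
#'
#' @param data a data frame holding both an `our` column (mmol/L/h, e.g.
#'   from [off_gas_rates()]) and a biomass column on the same time base.
#' @inheritParams estimate_growth_rate
#' @param our column name of the OUR series.
#' @return A one-row tibble with `q_o2` (mmol/g/h), `y_x_o2` (g/mmol) and
#'   window metadata.
#' @export
estimate_o2_uptake <- function(data, window, t = "t_h", biomass = "c_x",
                               our = "our",
                               method = c("regression", "two_point")) {
  method <- match.arg(method)
  d <- window_slice(data, window, t)
  cx <- d[[biomass]]
  if (any(cx <= 0)) abort("biomass must be positive")
  cx_bar <- log_mean(head(cx, 1), tail(cx, 1))
  q_o2 <- mean(d[[our]]) / cx_bar
  # cumulative O2 uptake by trapezoid; yield = dc_x / d(O2 consumed)
  tt <- d[[t]]
  o2 <- cumsum(c(0, diff(tt) * (head(d[[our]], -1) + tail(d[[our]], -1)) / 2))
  f <- window_fit(o2, cx, method)
  tibble(t0 = window[1], t1 = window[2], q_o2 = q_o2, y_x_o2 = f$slope,
         method = method, n = nrow(d))
}

#' Oil consumption and MEL formation rates and yields
#'
#' Window estimates of the volumetric oil consumption rate `r_oil`, MEL
#' formation rate `r_MEL`, their biomass-specific counterparts relative to
#' the frozen end-of-growth biomass `c_x,growth`, the differential yield
#' `Y_MEL/oil = dc_MEL / (-dc_oil)`, and — when `total_oil_added` is given —
#' the integral yield relative to the total oil mass added per volume.
#'
#' @inheritParams estimate_growth_rate
#' @param oil,mel column names for oil and MEL concentrations.
#' @param c_x_growth biomass at end of growth (g/L), the catalytic biomass.
#' @param total_oil_added total oil added up to `t1`, as g per L of broth;
#'   optional.
#' @return A one-row tibble with `r_oil`, `q_oil`, `r_mel`, `q_mel`,
#'   `y_mel_oil` and `y_mel_total_oil` (NA if `total_oil_added` missing).
#' @export
estimate_production_rates <- function(data, window, c_x_growth,
                                      t = "t_h", oil = "c_oil", mel = "c_mel",
                                      total_oil_added = NULL,
                                      method = c("regression", "two_point")) {
  method <- match.arg(method)
  if (c_x_growth <= 0) abort("c_x_growth must be positive")
  d <- window_slice(data, window, t)
  fo <- window_fit(d[[t]], d[[oil]], method)
  fm <- window_fit(d[[t]], d[[mel]], method)
  dmel <- tail(d[[mel]], 1) - head(d[[mel]], 1)
  y_diff <- if (abs(fo$slope) < .Machine$double.eps) NA_real_
    else fm$slope / (-fo$slope)
  tibble(
    t0 = window[1], t1 = window[2],
    r_oil = -fo$slope, q_oil = -fo$slope / c_x_growth,
    r_mel = fm$slope, q_mel = fm$slope / c_x_growth,
    y_mel_oil = y_diff,
    y_mel_total_oil = if (is.null(total_oil_added)) NA_real_
      else dmel / total_oil_added,
    method = method, n = nrow(d)
  )
}

#' Share of MEL in the crude lipid extract
#'
#' The crude lipid extract pools everything the solvent extraction recovers:
#' MEL, residual oil and free fatty acids. Its MEL mass fraction
#' \deqn{X_{MEL} = \frac{c_{MEL}}{c_{oil} + c_{FA} + c_{MEL}}}
#' is both a substrate-conversion indicator and the purity the first
#' downstream extraction step would deliver.
#'
#' @param c_mel,c_oil,c_fa concentrations (g/L); vectorised.
#' @return Fraction in `[0, 1]` (multiply by 100 for %).
#' @examples
#' x_mel(11.2, 1.7, 1.0)  # ~0.81
#' @export
x_mel <- function(c_mel, c_oil = 0, c_fa = 0) {
  if (any(c(c_mel, c_oil, c_fa) < 0)) abort("concentrations must be non-negative")
  total <- c_mel + c_oil + c_fa
  if (any(total <= 0)) abort("crude extract is empty: X_MEL undefined")
  c_mel / total
}

#' Optical density and backscatter conversions to dry biomass
#'
#' Linear calibration of offline OD625 readings (0.35 g/L dry biomass per OD
#' unit) and of microcultivation backscatter at gain 5 (0.14 backscatter
#' units per OD unit).
#'
#' @param od OD625 reading; vectorised.
#' @param backscatter backscatter (gain 5) reading; vectorised.
#' @return Dry biomass (g/L), or OD625 for `backscatter_to_od()`.
#' @examples
#' od_to_biomass(0.6)          # 0.21 g/L
#' backscatter_to_od(1.4)      # OD 10
#' @export
od_to_biomass <- function(od) {
  if (any(od < 0)) abort("OD must be non-negative")
  .OD_TO_CX * od
}

#' @rdname od_to_biomass
#' @param c_x dry biomass (g/L); vectorised.
#' @export
biomass_to_od <- function(c_x) c_x / .OD_TO_CX

#' @rdname od_to_biomass
#' @export
backscatter_to_od <- function(backscatter) {
  if (any(backscatter < 0)) abort("backscatter must be non-negative")
  backscatter / .BS_TO_OD
}

#' @rdname od_to_biomass
#' @export
backscatter_to_biomass <- function(backscatter) {
  od_to_biomass(backscatter_to_od(backscatter))
}
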