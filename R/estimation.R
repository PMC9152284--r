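.GROWTH_PARS <- c("mu_max", "K_gluc", "K_nano3", "Y_x_gluc", "Y_x_nano3")

#' Direct regression estimates of growth yields and rates
#'
#' Recovers the growth-model constants the way they were derived from
#' experimental data: yields as regression slopes of biomass against
#' substrate over the batch window, `mu_max` as the log-biomass slope over
#' an exponential window, and the maximum specific consumption rates from a
#' through-the-origin regression of per-interval consumption rates against
#' the interval's (logarithmic-mean) biomass.
#'
#' @param data observation table with offline columns `t_h`, `c_x`,
#'   `c_gluc`, `c_nano3` (rows with `NA` biomass are dropped).
#' @param exp_window window `c(t0, t1)` inside the exponential growth part.
#' @param batch_window window covering the substrate consumption; defaults
#'   to `exp_window`.
#' @return A tibble with columns `parameter` and `estimate` for
#'   `mu_max`, `Y_x_gluc`, `Y_x_nano3`, `q_max_gluc`, `q_max_nano3`.
#' @export
fit_yields <- function(data, exp_window, batch_window = exp_window) {
  d <- data[!is.na(data$c_x), c("t_h", "c_x", "c_gluc", "c_nano3")]
  if (nrow(window_slice(d, exp_window, "t_h")) < 3) {
    abort(sprintf("need >= 3 samples in window [%g, %g]",
                  exp_window[1], exp_window[2]))
  }
  mu_max <- estimate_growth_rate(d, exp_window)$estimate
  b <- window_slice(d, batch_window, "t_h")
  y_gluc <- -unname(coef(lm(c_x ~ c_gluc, data = b))[2])
  y_nano3 <- -unname(coef(lm(c_x ~ c_nano3, data = b))[2])
  # specific rates regress interval consumption against the interval's
  # logarithmic-mean biomass, restricted to the exponential window where
  # consumption is active
  e <- window_slice(d, exp_window, "t_h")
  q_spec <- function(substrate) {
    r <- -diff(e[[substrate]]) / diff(e$t_h)
    cx_bar <- mapply(log_mean, head(e$c_x, -1), tail(e$c_x, -1))
    unname(coef(lm(r ~ 0 + cx_bar))[1])
  }
  tibble(
    parameter = c("mu_max", "Y_x_gluc", "Y_x_nano3", "q_max_gluc", "q_max_nano3"),
    estimate = c(mu_max, y_gluc, y_nano3, q_spec("c_gluc"), q_spec("c_nano3"))
  )
}

#' Specification of a simulation-based parameter fit
#'
#' Names the kinetic parameters to free, their (positive, finite) box
#' bounds, the observed species entering the weighted least-squares
#' objective, and the optimiser settings. Species residuals are normalised
#' by a per-species scale (default: the species' observed maximum), so
#' concentrations of very different magnitude contribute comparably.
#'
#' @param free character vector of parameter names from [mel_params()];
#'   may be empty (degenerate fit: the objective is just evaluated).
#' @param lower,upper named bound vectors; defaults are a factor of 10
#'   around the default parameter values.
#' @param species observed species to fit (columns of the observation
#'   table); default all concentration species present.
#' @param weights named per-species weights (default 1).
#' @param scales named per-species normalisation scales; default observed
#'   maxima.
#' @param n_starts number of optimiser starts (multi-start for >= 2 free
#'   parameters); deterministic given `seed`.
#' @param maxit,reltol optimiser control.
#' @param seed integer seed for start-point sampling.
#' @return An object of class `mel_fit_spec`.
#' @export
fit_spec <- function(free, lower = NULL, upper = NULL, species = NULL,
                     weights = NULL, scales = NULL, n_starts = 5,
                     maxit = 500, reltol = 1e-10, seed = 1L) {
  defaults <- unlist(mel_params())
  bad <- setdiff(free, names(defaults))
  if (length(bad)) abort(paste0("unknown parameter(s): ", paste(bad, collapse = ", ")))
  lo <- defaults[free] / 10
  hi <- defaults[free] * 10
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  if (length(free) && (any(lo <= 0) || any(!is.finite(hi)) || any(hi <= lo))) {
    abort("bounds must be finite, positive, with upper > lower")
  }
  structure(
    list(free = free, lower = lo, upper = hi, species = species,
         weights = weights, scales = scales, n_starts = n_starts,
         maxit = maxit, reltol = reltol, seed = as.integer(seed)),
    class = "mel_fit_spec"
  )
}

.SIM_COLS <- c(c_x = "c_x_total", c_gluc = "c_gluc", c_nano3 = "c_nano3",
               c_oil = "c_oil", c_fa = "c_fa", c_mel = "c_mel")

# Weighted, scale-normalised SSE between a simulated trajectory and the
# observation table, restricted to rows where the species is observed.
make_objective <- function(obs, config, species, weights, scales) {
  obs_by_species <- lapply(species, function(sp) {
    rows <- !is.na(obs[[sp]])
    list(t = obs$t_h[rows], y = obs[[sp]][rows])
  })
  names(obs_by_species) <- species
  if (is.null(scales)) {
    scales <- vapply(obs_by_species, function(o) max(abs(o$y), 1e-8), 0)
  }
  w <- setNames(rep(1, length(species)), species)
  if (!is.null(weights)) w[names(weights)] <- weights

  growth_cached <- NULL
  function(par_overrides) {
    params <- mel_params()
    params[names(par_overrides)] <- par_overrides
    params <- validate_mel_params(params)
    cfg <- config
    cfg$params <- params
    if (!any(names(par_overrides) %in% .GROWTH_PARS)) {
      if (is.null(growth_cached)) {
        gcfg <- config
        growth_cached <<- simulate_growth(gcfg)
      }
      traj <- if (cfg$t_end > cfg$t_growth_end) {
        dplyr::bind_rows(
          growth_cached[growth_cached$t_h < cfg$t_growth_end, ],
          simulate_production(cfg, growth_cached)
        )
      } else {
        growth_cached
      }
    } else {
      traj <- simulate_process(cfg)
    }
    sse <- 0
    for (sp in species) {
      o <- obs_by_species[[sp]]
      if (!length(o$t)) next
      sim <- approx(traj$t_h, traj[[.SIM_COLS[[sp]]]], xout = o$t, rule = 2)$y
      sse <- sse + w[[sp]] * sum(((sim - o$y) / scales[[sp]])^2)
    }
    sse
  }
}

#' Fit kinetic parameters to an observation table by simulation
#'
#' Minimises the weighted, scale-normalised sum of squared deviations
#' between simulated and observed species over the freed parameters, using
#' derivative-free local search on log-transformed parameters (Brent line
#' search for one free parameter, Nelder-Mead with deterministic
#' multi-start otherwise). The growth trajectory is cached when no growth
#' parameter is freed.
#'
#' @param obs an observation table (e.g. from [generate_observations()] or
#'   [read_observations()]).
#' @param config the [process_config()] describing the experiment.
#' @param spec a [fit_spec()].
#' @return An object of class `mel_fit` with elements `estimates` (tibble
#'   of freed parameters and fitted values), `objective`, `convergence`
#'   (TRUE if the optimiser reported convergence), `residuals` (per-species
#'   RMS summaries), `trajectory` (simulation at the optimum) and `spec`.
#'   Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @export
fit_model <- function(obs, config, spec) {
  stopifnot(inherits(spec, "mel_fit_spec"), inherits(config, "mel_config"))
  species <- spec$species
  if (is.null(species)) {
    species <- names(.SIM_COLS)[vapply(names(.SIM_COLS), function(sp) {
      sp %in% names(obs) && any(!is.na(obs[[sp]]))
    }, TRUE)]
  }
  missing_sp <- setdiff(species, names(obs))
  if (length(missing_sp)) {
    abort(paste0("observed species not in table: ", paste(missing_sp, collapse = ", ")))
  }
  objective <- make_objective(obs, config, species, spec$weights, spec$scales)

  free <- spec$free
  if (!length(free)) {
    value <- objective(list())
    return(new_mel_fit(list(), value, TRUE, obs, config, spec, species, objective))
  }

  fn_log <- function(theta_log) {
    th <- exp(theta_log)
    th <- pmin(pmax(th, spec$lower), spec$upper)
    objective(as.list(setNames(th, free)))
  }
  lo <- log(spec$lower); hi <- log(spec$upper)
  defaults <- unlist(mel_params())[free]

  if (length(free) == 1L) {
    opt <- optimize(fn_log, lower = lo, upper = hi, tol = 1e-9)
    best <- list(par = opt$minimum, value = opt$objective, convergence = 0L)
  } else {
    set.seed(spec$seed)
    starts <- rbind(
      log(defaults),
      matrix(runif((spec$n_starts - 1) * length(free), rep(lo, each = spec$n_starts - 1),
                   rep(hi, each = spec$n_starts - 1)),
             ncol = length(free), byrow = FALSE)
    )
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      o <- optim(starts[i, ], fn_log, method = "Nelder-Mead",
                 control = list(maxit = spec$maxit, reltol = spec$reltol))
      if (is.null(best) || o$value < best$value) best <- o
    }
  }
  est <- pmin(pmax(exp(best$par), spec$lower), spec$upper)
  est <- setNames(as.numeric(est), free)
  new_mel_fit(as.list(est), best$value, best$convergence == 0L,
              obs, config, spec, species, objective)
}

new_mel_fit <- function(estimates, value, converged, obs, config, spec,
                        species, objective) {
  params <- mel_params()
  params[names(estimates)] <- estimates
  cfg <- config
  cfg$params <- validate_mel_params(params)
  traj <- simulate_process(cfg)
  resid <- purrr::map_dfr(species, function(sp) {
    rows <- !is.na(obs[[sp]])
    if (!any(rows)) return(tibble())
    sim <- approx(traj$t_h, traj[[.SIM_COLS[[sp]]]],
                  xout = obs$t_h[rows], rule = 2)$y
    r <- sim - obs[[sp]][rows]
    tibble(species = sp, n = sum(rows), rmse = sqrt(mean(r^2)),
           bias = mean(r))
  })
  structure(
    list(estimates = tibble(parameter = names(estimates),
                            estimate = as.numeric(estimates)),
         objective = value, convergence = converged,
         residuals = resid, trajectory = traj, params = cfg$params,
         config = config, spec = spec, obs = obs, species = species),
    class = "mel_fit"
  )
}

#' @export
print.mel_fit <- function(x, ...) {
  cat(sprintf("<mel_fit> %d free parameter(s), objective %.6g, %s\n",
              nrow(x$estimates), x$objective,
              if (x$convergence) "converged" else "NOT converged"))
  if (nrow(x$estimates)) print(as.data.frame(x$estimates), row.names = FALSE)
  invisible(x)
}

#' @importFrom generics tidy
#' @method tidy mel_fit
#' @export
tidy.mel_fit <- function(x, ...) x$estimates

#' @importFrom generics glance
#' @method glance mel_fit
#' @export
glance.mel_fit <- function(x, ...) {
  tibble(objective = x$objective, convergence = x$convergence,
         n_free = nrow(x$estimates),
         n_obs = sum(x$residuals$n))
}

#' Objective profile along one parameter
#'
#' Evaluates the fit objective over a grid of values of a single kinetic
#' parameter with everything else held at its default, exposing the
#' identifiability of that parameter for the given data.
#'
#' @inheritParams fit_model
#' @param parameter a parameter name from [mel_params()].
#' @param grid numeric vector of parameter values.
#' @param species,weights,scales as in [fit_spec()].
#' @return A tibble with columns `value` and `objective`.
#' @export
profile_objective <- function(obs, config, parameter, grid, species = NULL,
                              weights = NULL, scales = NULL) {
  if (!parameter %in% names(mel_params())) {
    abort(paste0("unknown parameter: ", parameter))
  }
  if (is.null(species)) {
    species <- names(.SIM_COLS)[vapply(names(.SIM_COLS), function(sp) {
      sp %in% names(obs) && any(!is.na(obs[[sp]]))
    }, TRUE)]
  }
  objective <- make_objective(obs, config, species, weights, scales)
  tibble(
    value = grid,
    objective = vapply(grid, function(v) {
      objective(setNames(list(v), parameter))
    }, 0)
  )
}
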