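#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point facet_wrap
#'   labs geom_vline theme_bw vars
NULL

.PLOT_SPECIES <- c("c_x_total", "c_gluc", "c_nano3", "c_oil", "c_fa", "c_mel")

#' Plot a simulated trajectory
#'
#' Faceted time courses of the main state variables, with the
#' growth-to-production hand-over marked.
#'
#' @param object a `mel_trajectory`.
#' @param species columns to show.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot mel_trajectory
#' @export
autoplot.mel_trajectory <- function(object, species = .PLOT_SPECIES, ...) {
  cfg <- attr(object, "config")
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("t_h", species)],
    -"t_h", names_to = "species", values_to = "value"
  )
  long$species <- factor(long$species, levels = species)
  ggplot(long, aes(x = .data$t_h, y = .data$value)) +
    geom_line(colour = "steelblue") +
    geom_vline(xintercept = cfg$t_growth_end, linetype = "dashed",
               colour = "grey50") +
    facet_wrap(vars(.data$species), scales = "free_y") +
    labs(x = "time (h)", y = "concentration (g/L)") +
    theme_bw()
}

#' Plot an observation table
#'
#' Offline samples as points (off-gas columns are omitted; see
#' [plot_off_gas()]).
#'
#' @param object a `mel_observations` table.
#' @param species columns to show.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot mel_observations
#' @export
autoplot.mel_observations <- function(object,
                                      species = c("c_x", "c_gluc", "c_nano3",
                                                  "c_oil", "c_fa", "c_mel"),
                                      ...) {
  species <- intersect(species, names(object))
  d <- as_tibble(object)[, c("t_h", species)]
  long <- tidyr::pivot_longer(d, -"t_h", names_to = "species",
                              values_to = "value")
  long <- long[!is.na(long$value), ]
  ggplot(long, aes(x = .data$t_h, y = .data$value)) +
    geom_point(size = 1, colour = "firebrick") +
    facet_wrap(vars(.data$species), scales = "free_y") +
    labs(x = "time (h)", y = "measured concentration (g/L)") +
    theme_bw()
}

#' Plot off-gas rates
#'
#' Computes OUR and CER with [off_gas_rates()] and plots them against time.
#'
#' @param data a data frame with the off-gas record columns.
#' @return A ggplot object.
#' @export
plot_off_gas <- function(data) {
  r <- off_gas_rates(data)
  long <- tidyr::pivot_longer(r[, c("t_h", "our", "cer")], -"t_h",
                              names_to = "rate", values_to = "value")
  ggplot(long, aes(x = .data$t_h, y = .data$value, colour = .data$rate)) +
    geom_line() +
    labs(x = "time (h)", y = "rate (mmol/L/h)", colour = NULL) +
    theme_bw()
}

#' Plot a fitted model against its observations
#'
#' Simulated trajectory at the fitted parameters (lines) with the fitted
#' observations overlaid (points).
#'
#' @param object a `mel_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot mel_fit
#' @export
autoplot.mel_fit <- function(object, ...) {
  traj <- object$trajectory
  sim_long <- tidyr::pivot_longer(
    as_tibble(traj)[, c("t_h", unname(.SIM_COLS[object$species]))],
    -"t_h", names_to = "column", values_to = "value"
  )
  lut <- setNames(names(.SIM_COLS), .SIM_COLS)
  sim_long$species <- lut[sim_long$column]
  obs <- as_tibble(object$obs)
  obs_long <- tidyr::pivot_longer(
    obs[, c("t_h", object$species)], -"t_h",
    names_to = "species", values_to = "value"
  )
  obs_long <- obs_long[!is.na(obs_long$value), ]
  ggplot(sim_long, aes(x = .data$t_h, y = .data$value)) +
    geom_line(colour = "steelblue") +
    geom_point(data = obs_long, size = 1, colour = "firebrick") +
    facet_wrap(vars(.data$species), scales = "free_y") +
    labs(x = "time (h)", y = "concentration (g/L)") +
    theme_bw()
}
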