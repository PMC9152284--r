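## Fixed CSV schemas. Column orders are part of the package contract.

.TRAJ_COLS <- c("t_h", "phase", "V_L", "c_x_free", "c_x_incl", "c_x_total",
                "c_gluc", "c_nano3", "c_oil", "c_fa", "c_mel", "F_in")

.OBS_REQUIRED <- "t_h"
.OBS_OPTIONAL <- c("od625", "c_x", "c_gluc", "c_nano3", "c_oil", "c_fa",
                   "c_mel", "y_o2_in", "y_co2_in", "y_o2_out", "y_co2_out",
                   "q_air_lph", "p_pa", "t_k", "v_l")
.OBS_CONC <- c("c_x", "c_gluc", "c_nano3", "c_oil", "c_fa", "c_mel", "od625")

#' Write / read a trajectory as tidy CSV
#'
#' The trajectory CSV carries exactly the columns
#' `t_h, phase, V_L, c_x_free, c_x_incl, c_x_total, c_gluc, c_nano3, c_oil,
#' c_fa, c_mel, F_in` in this order, decimal-point dialect, UTF-8.
#'
#' @param traj a `mel_trajectory`.
#' @param path file path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns a tibble.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "mel_trajectory"))
  write.csv(as.data.frame(traj)[, .TRAJ_COLS], path, row.names = FALSE,
            quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(.TRAJ_COLS, names(d))
  if (length(missing_cols)) {
    abort(paste0("trajectory file lacks columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  as_tibble(d[, .TRAJ_COLS])
}

#' Write / read an observation table as CSV
#'
#' Observation tables require a `t_h` column; the optional columns are the
#' offline species (`od625`, `c_x`, `c_gluc`, `c_nano3`, `c_oil`, `c_fa`,
#' `c_mel`) and the off-gas record fields (`y_o2_in`, `y_co2_in`,
#' `y_o2_out`, `y_co2_out`, `q_air_lph`, `p_pa`, `t_k`, `v_l`). Unknown
#' columns and negative concentrations are rejected with the offending
#' rows named.
#'
#' @param obs a data frame of observations.
#' @param path file path.
#' @return `read_observations()` returns a `mel_observations` tibble.
#' @export
write_observations <- function(obs, path) {
  keep <- intersect(c(.OBS_REQUIRED, .OBS_OPTIONAL), names(obs))
  write.csv(as.data.frame(obs)[, keep], path, row.names = FALSE,
            quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!.OBS_REQUIRED %in% names(d)) abort("observation file lacks column t_h")
  unknown <- setdiff(names(d), c(.OBS_REQUIRED, .OBS_OPTIONAL))
  if (length(unknown)) {
    abort(paste0("unknown observation columns: ", paste(unknown, collapse = ", ")))
  }
  for (cl in intersect(.OBS_CONC, names(d))) {
    bad <- which(!is.na(d[[cl]]) & d[[cl]] < 0)
    if (length(bad)) {
      abort(sprintf("negative %s at data row(s) %s", cl,
                    paste(bad, collapse = ", ")))
    }
  }
  structure(as_tibble(d), class = c("mel_observations", class(tibble())))
}

## --- YAML process configuration -------------------------------------------

.CFG_KEYS <- c("name", "V0", "c_x0", "c_gluc0", "c_nano30", "t_growth_end",
               "t_end", "dt_growth", "dt_production", "use_total_biomass",
               "seed", "params", "feed", "oil_feeds")
.FEED_KEYS <- c("t_start", "t_end", "mu_set", "V0", "cx0", "Y_x_gluc_feed",
                "c_gluc_feed", "c_nano3_feed", "feed_density", "c_gluc_ref")
.OIL_KEYS <- c("kind", "t_start", "t_end", "volume_ml", "frac_vv",
               "rate_ml_h", "reference_volume", "oil_density")

check_keys <- function(x, allowed, what) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    abort(sprintf("unknown %s key(s): %s", what, paste(unknown, collapse = ", ")))
  }
}

#' Load / save a process configuration as YAML
#'
#' A scenario file is a human-editable YAML map with the
#' [process_config()] fields, an optional `params` map of kinetic-parameter
#' overrides (anything unset keeps the shipped defaults), an optional
#' `feed` map ([exponential_feed()] fields) and an `oil_feeds` list
#' ([oil_feed()] fields). Unknown keys are rejected; a missing phase
#' boundary is an error. `save_config()` followed by `load_config()`
#' round-trips a configuration.
#'
#' @param path YAML file path.
#' @return A [process_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  y <- yaml::read_yaml(path)
  check_keys(y, .CFG_KEYS, "config")
  for (k in c("V0", "t_growth_end", "t_end")) {
    if (is.null(y[[k]])) abort(paste0("config key missing: ", k))
  }
  params <- mel_params()
  if (!is.null(y$params)) {
    check_keys(y$params, names(params), "params")
    params <- do.call(mel_params, y$params)
  }
  feed <- NULL
  if (!is.null(y$feed)) {
    check_keys(y$feed, .FEED_KEYS, "feed")
    feed <- do.call(exponential_feed, y$feed)
  }
  oil_feeds <- lapply(y$oil_feeds %||% list(), function(ev) {
    check_keys(ev, .OIL_KEYS, "oil feed")
    ev$reference_volume <- ev$reference_volume %||% NA_real_
    do.call(oil_feed, ev)
  })
  args <- y[intersect(names(y), c("name", "V0", "c_x0", "c_gluc0", "c_nano30",
                                  "t_growth_end", "t_end", "dt_growth",
                                  "dt_production", "use_total_biomass",
                                  "seed"))]
  do.call(process_config,
          c(args, list(params = params, feed = feed, oil_feeds = oil_feeds)))
}

#' @rdname load_config
#' @param config a [process_config()] to serialise.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "mel_config"))
  defaults <- unlist(mel_params())
  pv <- unlist(config$params)
  over <- as.list(pv[pv != defaults])
  y <- list(
    name = config$name, V0 = config$V0, c_x0 = config$c_x0,
    c_gluc0 = config$c_gluc0, c_nano30 = config$c_nano30,
    t_growth_end = config$t_growth_end, t_end = config$t_end,
    dt_growth = config$dt_growth, dt_production = config$dt_production,
    use_total_biomass = config$use_total_biomass, seed = config$seed
  )
  if (length(over)) y$params <- over
  if (!is.null(config$feed)) y$feed <- unclass(config$feed)
  if (length(config$oil_feeds)) {
    y$oil_feeds <- lapply(config$oil_feeds, function(ev) {
      ev <- unclass(ev)
      ev[!vapply(ev, is.null, TRUE)]
    })
  }
  y <- y[!vapply(y, is.null, TRUE)]
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records what produced a set of outputs: the command, the configuration
#' (hashed and echoed), the seed, the package version and the output file
#' list, so deterministic runs can be replayed bit-for-bit.
#'
#' @param path manifest file path (JSON).
#' @param command command label, e.g. `"simulate"`.
#' @param config the [process_config()] used (optional).
#' @param seed seed used.
#' @param outputs character vector of output files.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, config = NULL, seed = NA_integer_,
                           outputs = character()) {
  cfg_hash <- NULL
  cfg_echo <- NULL
  if (!is.null(config)) {
    tmp <- tempfile(fileext = ".yaml")
    on.exit(unlink(tmp), add = TRUE)
    save_config(config, tmp)
    cfg_hash <- unname(tools::md5sum(tmp))
    cfg_echo <- yaml::read_yaml(tmp)
  }
  jsonlite::write_json(
    list(
      command = command,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      package = "melkin",
      version = as.character(packageVersion("melkin")),
      seed = seed,
      config_md5 = cfg_hash,
      config = cfg_echo,
      outputs = outputs
    ),
    path, auto_unbox = TRUE, pretty = TRUE, null = "null", digits = NA
  )
  invisible(path)
}
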