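# Shared fixtures: tiny configs built in code, plus an error metric for
# comparing integrator endpoints across species of very different scale.

batch_config <- function(t_end = 48, ...) {
  process_config(V0 = 4, t_growth_end = t_end, t_end = t_end, ...)
}

# production-only config: growth phase of zero length via a prepared handover
production_only_config <- function(handover_V = 4, oil_feeds = list(),
                                   t_end = 100, ...) {
  process_config(V0 = handover_V, c_x0 = 0, c_gluc0 = 0, c_nano30 = 0,
                 t_growth_end = 0, t_end = t_end, oil_feeds = oil_feeds, ...)
}

# relative endpoint error with a floor so near-zero species (exhausted
# substrates) do not blow up the relative scale
endpoint_error <- function(a, b, scale) {
  abs(a - b) / pmax(abs(b), 0.01 * scale, 1e-6)
}

noiseless <- function(...) {
  noise_model(rel_sd = 0, floor_sd = c(od625 = 0, c_x = 0, c_gluc = 0,
                                       c_nano3 = 0, c_oil = 0, c_fa = 0,
                                       c_mel = 0),
              offgas_sd = 0, ...)
}
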