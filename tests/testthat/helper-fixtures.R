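# Shared fixtures: the three solvent regimes of the two-component decay
# model (tau ps / amplitude %), and small channel grids that keep test
# fits fast while spanning >= 10 of the longest lifetime.

solvent_regimes <- list(
  PBS  = list(tau = c(332, 788), amp = c(88, 12)),
  EtOH = list(tau = c(287, 862), amp = c(45, 55)),
  MeOH = list(tau = c(464, 943), amp = c(71, 29))
)

small_irf <- function(n_channels = 1024, channel_width = 14,
                      center = 500, fwhm = 100) {
  gen_irf(irf_spec(center = center, fwhm = fwhm), n_channels, channel_width)
}

# delta "IRF" trace: all weight in channel 1
delta_irf <- function(n_channels = 512, channel_width = 10) {
  tt <- (seq_len(n_channels) - 0.5) * channel_width
  decay_trace(tt, c(1, numeric(n_channels - 1)))
}

# full-frame single-region FLIM scene
uniform_scene <- function(tau_ps, side = 40, photons = 5000,
                          tau_jitter_sd = 0, background = 0,
                          n_channels = 512, channel_width = 25) {
  flim_scene(side, side,
             regions = list(list(
               mask = matrix(TRUE, side, side),
               params = decay_params(tau_ps, rep(100 / length(tau_ps),
                                                 length(tau_ps)),
                                     background = background),
               tau_jitter_sd = tau_jitter_sd)),
             photons_per_pixel = photons,
             n_channels = n_channels, channel_width = channel_width)
}
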