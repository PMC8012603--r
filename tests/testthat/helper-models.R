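# Shared builders for the simulation-study conditions: two spectrally
# identical pairs, one photochromic donor (rho0 = 0.3) and one photostatic
# (rho0 = 1.0), equal brightness, gamma = 1.

two_pair_specs <- function(n = 4000, rho0 = c(0.3, 1.0), gamma = 1) {
  list(pair_sim_spec(n, rho0[1], gamma = gamma),
       pair_sim_spec(n, rho0[2], gamma = gamma))
}

two_pair_models <- function(rho0 = c(0.3, 1.0), gamma = 1,
                            valid_range = c(0, 0.6)) {
  list(power_law_pair("pair1", rho0[1], gamma = gamma, valid_range = valid_range),
       power_law_pair("pair2", rho0[2], gamma = gamma, valid_range = valid_range))
}

# Noise-free forward acquisition for given ground truths.
noiseless_acq <- function(thetas, n = 4000, rho0 = c(0.3, 1.0), gamma = 1) {
  simulate_acquisition(two_pair_specs(n, rho0, gamma), thetas, noise = FALSE)
}
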