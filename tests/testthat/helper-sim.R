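# shared simulator configurations for the test-suite
no_noise <- list(pressure_sd_bar = 0, od_sd = 0, gc_sd = 0,
                 nh4_sd_mmol_l = 0, aa_sd_umol_l = 0)

noiseless_config <- function(...) {
  sim_config(noise = no_noise, gassing_loss_bar = 0, ...)
}

# run_config matched to the simulator defaults (nominal 7:1:1 feed)
sim_run_config <- function(...) {
  run_config(initial_n2_fraction = 1 / 9, ...)
}
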