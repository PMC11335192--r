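# Shared fixtures built in code: the default study-condition generators.

h_protocol <- function(...) voltage_step_protocol(...)

h_cm <- function(...) charge_movement_params(...)

h_cell <- function(...) cell_params(...)

# Simulate a matched (test, blocker) pair of recording sets.
h_pss_pair <- function(cm = h_cm(), noise_sd = 0, seed = NULL,
                       gaba_uM = 0, betaine_mM = 0,
                       transport = two_substrate_params(),
                       protocol = h_protocol(), cell = h_cell()) {
  conds <- list(
    list(label = "blocker", blocker = TRUE),
    list(label = "test", gaba_uM = gaba_uM, betaine_mM = betaine_mM)
  )
  simulate_condition_set(protocol, cm, cell, transport, conds,
                         noise = noise_spec(noise_sd, seed))
}

# Noise-free competition grid records from the documented model.
h_competition_records <- function(transport, gaba_levels, betaine_levels,
                                  n_cells = 3, noise_sd = 0, seed = NULL) {
  simulate_competition_records(transport, gaba_levels, betaine_levels,
                               n_cells = n_cells,
                               noise = noise_spec(noise_sd, seed))
}
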