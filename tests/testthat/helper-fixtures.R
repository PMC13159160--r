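# Small builders shared across test files. Everything is generated in code;
# sizes are kept small so the unit suite stays fast.

# a compact field: few neurons, few trials, short session
small_config <- function(n_neurons = 40, ...) {
  population_config(n_neurons = n_neurons, ...)
}

small_protocol <- function(modality = "ultrasound", pressure = 450,
                           n_trials = 9) {
  stimulus_protocol(peak_negative_pressure = pressure, modality = modality,
                    n_trials = n_trials)
}

quick_session <- function(protocols = small_protocol(),
                          config = small_config(), seed = 7) {
  synthesize_traces(protocols, config, seed = seed)
}

# build an epoch tensor directly from a neurons x trials x frames array
manual_epochs <- function(values, units = "dff", sampling_rate = 3,
                          config = analysis_config()) {
  et <- sonotrace:::new_epoch_tensor(values, units, config, sampling_rate,
                                     condition = "manual")
  et
}

# one-neuron one-trial epoch from a 90-frame vector
one_epoch <- function(x, units = "dff") {
  manual_epochs(array(x, c(1, 1, length(x))), units = units)
}
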