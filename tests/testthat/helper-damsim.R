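# memoized default runs shared across test files (deterministic, so safe)
.cache <- new.env(parent = emptyenv())

default_traj <- function() {
  if (is.null(.cache$traj)) .cache$traj <- simulate_dam()
  .cache$traj
}

default_amps <- function() {
  if (is.null(.cache$amps)) .cache$amps <- periodic_amplitudes(default_traj())
  .cache$amps
}

amp_of <- function(amps, pool) amps$amplitude[amps$pool == pool]
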