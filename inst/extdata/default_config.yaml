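# Full default configuration: the published driver and flux constants of
# the four-pool beta-cell model, written out explicitly. Loading this file
# is equivalent to loading an empty one; it exists as a reference profile
# to copy and edit.
driver:
  k0_ca: 22
  k1_ca: 15
  k2_ca: 10
  t1: 0.25
  t2: 0.5
  T0: 1
  A0: 0
  A1: 0.5
  tau_nadh: 0
  tau_atp: 0
  ca_init: 0
model:
  k0_p0: 0.1
  k0A: 0.2
  k01: 7
  k12: 1
  k13: 2
  k32: 1
init:
  p1: 0.4
  p2: 0.6
  p3: 0.5
n_periods: 10
n_discard: 5
tol: 1.0e-10
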