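# SYNTHETIC stand-in values for the two external plug-in models.
# The ritonavir population PK model and the IV paclitaxel model are
# literature models whose parameter values are user-supplied
# configuration; the values below are representative synthetic
# placeholders (chosen to give low-dose ritonavir exposure in the
# clinically reported range) so that examples, tests and simulations
# run self-contained. Replace this file with literature estimates for
# any real comparison.
ritonavir:
  clearance: 20               # L/h (apparent)
  vc: 60                      # L
  q_inter: 6                  # L/h
  vp: 40                      # L
  bioavailable_fraction: 1
  mean_absorption_time: 2     # h
  input_shape: 0.5            # relative variance of the IG input
iv_paclitaxel:
  vc: 10                      # L
  vp1: 30                     # L
  vp2: 275                    # L
  q1: 15                      # L/h
  q2: 15                      # L/h
  elimination: saturable
  vmax: 30000                 # ug/h
  km: 500                     # ng/mL
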