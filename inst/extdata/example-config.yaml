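# Example configuration: ratio-10 populations, signal preset 3, mild
# stochastic resistance, activation delayed until the tumor holds 20% of
# the membrane.  Unstated keys take the documented defaults.
ratio: 10
signal_set: 3
ignore_prob: 0.25
activation_volume_frac: 0.2
max_steps: 400
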