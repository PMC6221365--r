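# Example configuration: a driver unit excites a quiet follower through
# synapse port 2. Run with:
#   spikesim simulate two_unit_network.yaml --out runs/demo
duration: 5000
dt: 1
seed: 7
tau_syn: 10
units:
  - id: driver
    mode: 1
    stimulus: {kind: square, rate: 2, duty: 0.5, amplitude: 8}
    stimulus_route: analog
  - id: follower
    mode: 1
    dials: {static_current: 2}
wiring:
  - {src: driver, dst: follower, port: 2, gain: 6}
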