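# Agent simulation profiles.
# "wt": indifferent explorer (no avoidance).
# "ko": sound-avoider; avoidance_strength and onset_latency_s are tuned so
# that mean silent-quadrant occupancy over the 30-min exposure lands in the
# mid-40s percent range, with the preference emerging only after the onset
# latency has elapsed.
wt:
  mean_speed_cm_s: 4
  speed_shape: 2
  turn_sd_rad: 0.3
  avoidance_strength: 0.0
  onset_latency_s: 0
ko:
  mean_speed_cm_s: 4
  speed_shape: 2
  turn_sd_rad: 0.3
  avoidance_strength: 0.2
  onset_latency_s: 300
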