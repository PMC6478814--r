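# Example simulation config: a PC unit driven by a 100 Hz sinusoid whose
# amplitude sits above the unit's neural threshold.
type: PC
seed: 1
n_units: 2
grid:
  dt_s: 1.0e-4
  duration_s: 0.5
stimulus:
  type: sinusoid
  freq_hz: 100
  amp_mm: 0.01
noise:
  enabled: false
write_waveforms: true
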