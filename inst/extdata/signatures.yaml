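# Default synthetic call signatures, one per vocalization class.
# These are deliberately stylized: each class gets a distinct, mutually
# separable time-frequency structure (carrier, pulse rate, FM, repetition
# pattern), not a bioacoustically faithful model of the species.
# carrier_freq Hz, am_rate Hz, call_duration s, fm_sweep Hz/s,
# rel_amplitude in (0, 1].
ec_standard:          # pulsed advertisement trill
  carrier_freq: 1500
  am_rate: 18
  call_duration: 1.2
  n_repeats: 2
  fm_sweep: 0
  harmonics: 2
  rel_amplitude: 0.80
ec_chorus:            # several desynchronized, detuned trills superposed
  carrier_freq: 1500
  am_rate: 18
  call_duration: 2.5
  n_repeats: 1
  fm_sweep: 0
  harmonics: 2
  rel_amplitude: 0.90
  n_voices: 4
ec_amplexus:          # quiet, slow-pulsed low tone
  carrier_freq: 700
  am_rate: 6
  call_duration: 1.0
  n_repeats: 1
  fm_sweep: 0
  harmonics: 1
  rel_amplitude: 0.35
ao_standard:          # short repeated whistle
  carrier_freq: 1000
  am_rate: 0
  call_duration: 0.15
  n_repeats: 8
  fm_sweep: 0
  harmonics: 1
  rel_amplitude: 0.80
ao_distress:          # rising frequency-modulated sweep
  carrier_freq: 1800
  am_rate: 0
  call_duration: 1.5
  n_repeats: 1
  fm_sweep: 1500
  harmonics: 1
  rel_amplitude: 0.90
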