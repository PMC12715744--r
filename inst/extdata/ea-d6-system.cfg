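# Two nascent protons of ethyl acetate-d6 at the polarizer field.
# Shifts in ppm, couplings in Hz.

[field]
b0_t = 0.4454
ref_freq_hz = 18717000
coupling = scalar

[spins]
CH3 = 1.26
OCH2 = 4.12

[couplings]
CH3 OCH2 = 7.1
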