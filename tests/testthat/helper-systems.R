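# Shared fixture builders; everything is generated in code.

two_spin_weak <- function(j = 7.1, shifts = c(0, 0)) {
  build_spin_system(shifts, matrix(c(0, j, j, 0), 2),
                    b0 = 0.4454, ref_freq = 18.717e6, coupling = "weak")
}

single_spin <- function(shift = 0) {
  build_spin_system(shift, NULL, b0 = 0.4454, ref_freq = 18.717e6)
}

# Deviation state rho = E/2^N + dev, built from the system's own operators
deviation_state <- function(sys, dev) {
  phiptools:::.new_state(diag(sys$dim) / sys$dim + dev, sys)
}

# Nutation-curve fixture parameters used throughout (h = 20 mm conditions)
NUT_PERIOD <- 90.30e-6
NUT_K <- 369.7
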