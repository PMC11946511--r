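# Canonical Cu2+-histidine study conditions used across the suite.
fld3316 <- field_conditions(3316)

sys_15N <- function(count = 1, A_iso = 2.8, T_dip = -0.4)
  his_15N_system(count, A_iso, T_dip)

sys_14N <- function() his_14N_system()

# short timings for engine-agreement tests
tim_short <- pulse_timing_3p(210, 12, 16, 64)

# processed magnitude spectrum with the package's default chain
process_1d <- function(trace, window = "chebyshev", zerofill = 2048)
  to_spectrum(subtract_background(normalize_trace(trace), model = "polynomial"),
              window = window, zerofill = zerofill)

process_2d <- function(trace, window = "chebyshev", zerofill = 1024)
  to_spectrum(subtract_background(normalize_trace(trace), model = "polynomial"),
              window = window, zerofill = zerofill)

rel_rms <- function(a, b) sqrt(mean((a - b)^2)) / sqrt(mean(b^2))

# Independent oracle: 2x2 manifold Hamiltonians for I = 1/2 built directly
# from the secular/pseudosecular geometry, diagonalized numerically.
oracle_freqs_12 <- function(A_iso, T_dip, theta, nu_nz) {
  A <- A_iso + T_dip * (3 * cos(theta)^2 - 1)
  B <- 3 * T_dip * sin(theta) * cos(theta)
  gaps <- sapply(c(0.5, -0.5), function(ms) {
    H <- ms * (A * matrix(c(0.5, 0, 0, -0.5), 2) +
                 B * matrix(c(0, 0.5, 0.5, 0), 2)) -
      nu_nz * matrix(c(0.5, 0, 0, -0.5), 2)
    diff(range(eigen(H, symmetric = TRUE)$values))
  })
  sort(gaps)
}
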