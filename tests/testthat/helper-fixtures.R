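# Shared fixtures: the study conditions of the rosmarinic-acid (RA) runs.
# Void marker elutes at 0.298 min; binding runs at 0.6 mL/min, 10 uL
# injections; RA concentration grid 0.3-1.1 mM.

ra_column <- function() column_system(t0 = 0.298, flow_rate = 0.6)

ra_conc <- function() seq(0.3, 1.1, by = 0.1) * 1e-3  # mol/L

ra_truth <- function(...) {
  simulation_truth(K_A = 7.268e5, n_a = 1.237e-8, column = ra_column(), ...)
}

# Independent EMG oracle: the closed-form density, maximized on a fine grid
# (never via the package's own mode finder).
emg_oracle <- function(t, mu, sigma, tau) {
  erfc <- function(x) 2 * pnorm(x * sqrt(2), lower.tail = FALSE)
  if (tau <= 0) return(dnorm(t, mu, sigma))
  (1 / (2 * tau)) * exp(sigma^2 / (2 * tau^2) - (t - mu) / tau) *
    erfc((sigma / tau - (t - mu) / sigma) / sqrt(2))
}

# Independent quadratic oracle for the overload capacity factor: positive
# real root via polyroot of V_m k^2 + (V_m + nb K_A - na K_A) k - na K_A.
apparent_k_oracle <- function(K_A, n_a, V_m, n_b) {
  vapply(n_b, function(nb) {
    roots <- polyroot(c(-n_a * K_A, V_m + nb * K_A - n_a * K_A, V_m))
    real <- Re(roots[abs(Im(roots)) < 1e-8])
    real[real > 0]
  }, numeric(1))
}
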