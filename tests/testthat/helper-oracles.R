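# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the solver oracle uses stats::uniroot on the raw
# conservation equation, and curve values are recomputed from first
# principles where asserted.

# Brute-force root of M + 2M^2/K1 + 4M^4/(K1^2 K2) = C_tot on [0, C_tot].
oracle_monomer <- function(K1, K2, C_tot) {
  f <- function(M) M + 2 * M^2 / K1 + 4 * M^4 / (K1^2 * K2) - C_tot
  stats::uniroot(f, c(0, C_tot), tol = 1e-18 * C_tot)$root
}

oracle_species <- function(K1, K2, C_tot) {
  M <- oracle_monomer(K1, K2, C_tot)
  D <- M^2 / K1
  list(M = M, D = D, T = D^2 / K2)
}

# Operational Hill curve (agonist only), written independently of
# omam_response.
oracle_operational_hill <- function(S, E_max, K_S, tau, n) {
  E_max * (tau * S)^n / ((S + K_S)^n + (tau * S)^n)
}

# Study-system defaults used as generator truth throughout the suite.
truth_params <- function() equilibrium_params()
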