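#' Solve the monomer-dimer-tetramer mass-action equilibrium
#'
#' For the stepwise assembly 2M = D, 2D = T with dissociation constants
#' `K1 = M^2/D` and `K2 = D^2/T`, the free monomer concentration is the unique
#' non-negative root of the conservation equation
#' `M + 2 M^2/K1 + 4 M^4/(K1^2 K2) = C_tot`.
#' The conservation function is strictly increasing in `M`, so the root is
#' bracketed by `[0, C_tot]` and located by bisection (200 iterations), which
#' converges unconditionally and leaves no seed or initialization sensitivity.
#'
#' @param K1 Monomer-monomer dissociation constant (molar).
#' @param K2 Dimer-dimer dissociation constant (molar).
#' @param C_tot Total protein concentration in monomer equivalents (molar).
#' @return An object of class `species_concentrations`: list with molar
#'   particle concentrations `M`, `D`, `T` and the input `C_tot`.
#' @examples
#' sp <- solve_equilibrium(12.6e-9, 9.6e-6, 50e-9)
#' sp$M + 2 * sp$D + 4 * sp$T  # = 50e-9
#' @export
solve_equilibrium <- function(K1, K2, C_tot) {
  check_positive(K1, "K1")
  check_positive(K2, "K2")
  check_positive(C_tot, "C_tot")
  excess <- function(M) M + 2 * M^2 / K1 + 4 * M^4 / (K1^2 * K2) - C_tot
  lo <- 0
  hi <- C_tot
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    if (excess(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < 1e-12 * C_tot && hi - lo < 1e-18) break
  }
  M <- (lo + hi) / 2
  D <- M^2 / K1
  T_ <- D^2 / K2
  res <- abs(M + 2 * D + 4 * T_ - C_tot) / C_tot
  structure(list(M = M, D = D, T = T_, C_tot = C_tot, residual = res),
            class = "species_concentrations")
}

#' Effective interface constants under substrate/inhibitor linkage
#'
#' Maps a condition (substrate concentration `S`, inhibitor concentration `B`)
#' onto effective dissociation constants for both interfaces. Substrate-site
#' occupancy follows the allosteric ternary-complex expression raised to a
#' Hill form,
#' `theta = s / (1 + s + b + alpha*s*b)` with `s = (S/K_S)^n_link` and
#' `b = B/K_B`, and the effective constants interpolate log-linearly between
#' the substrate-free and substrate-saturated endpoints:
#' `log K2_eff = (1-theta) log K2_0 + theta log K2_S` (likewise for K1), plus
#' an inhibitor dimer-destabilization term `phi_B * log gamma_D` on K1, where
#' `phi_B = b (1 + alpha*s) / (1 + s + b + alpha*s*b)` is the fractional
#' inhibitor occupancy.
#'
#' @param params An [equilibrium_params()] object.
#' @param inh An [inhibitor_model()] or `NULL` for no inhibitor.
#' @param cond An [assay_condition()].
#' @return List with `K1_eff`, `K2_eff` (molar), substrate occupancy `theta`
#'   and inhibitor occupancy `phi_B`.
#' @export
effective_constants <- function(params, inh = NULL, cond) {
  stopifnot(inherits(params, "equilibrium_params"),
            inherits(cond, "assay_condition"))
  s <- if (cond$S > 0) (cond$S / params$K_S)^params$n_link else 0
  if (!is.null(inh)) {
    stopifnot(inherits(inh, "inhibitor_model"))
    b <- cond$B / inh$K_B
    alpha <- inh$alpha
    log_gamma <- log(inh$gamma_D)
  } else {
    b <- 0
    alpha <- 0
    log_gamma <- 0
  }
  denom <- 1 + s + b + alpha * s * b
  theta <- s / denom
  phi_B <- b * (1 + alpha * s) / denom
  if (theta == 0 && phi_B == 0) {  # unliganded limit, exact
    return(list(K1_eff = params$K1_0, K2_eff = params$K2_0,
                theta = 0, phi_B = 0))
  }
  log_K2 <- (1 - theta) * log(params$K2_0) + theta * log(params$K2_S)
  log_K1 <- (1 - theta) * log(params$K1_0) + theta * log(params$K1_S) +
    phi_B * log_gamma
  list(K1_eff = exp(log_K1), K2_eff = exp(log_K2),
       theta = theta, phi_B = phi_B)
}

#' Law-of-mass-action dissociation constants from species concentrations
#'
#' Computes the interface constants directly from measured (or solved)
#' species concentrations: `Kd_MM_calc = M^2 / D` and `Kd_DD_calc = D^2 / T`.
#' A zero denominator yields `NA` with the corresponding `defined` flag set to
#' `FALSE` rather than an error, since vanishing dimer or tetramer populations
#' are legitimate dilute-limit outcomes.
#'
#' @param conc A `species_concentrations` object or list with `M`, `D`, `T`.
#' @return List with `Kd_MM_calc`, `Kd_DD_calc` (molar, `NA` when undefined)
#'   and a logical vector `defined`.
#' @export
mass_action_kd <- function(conc) {
  M <- conc$M
  D <- conc$D
  T_ <- conc$T
  check_nonnegative(M, "M")
  check_nonnegative(D, "D")
  check_nonnegative(T_, "T")
  mm_ok <- D > 0
  dd_ok <- T_ > 0
  list(Kd_MM_calc = if (mm_ok) M^2 / D else NA_real_,
       Kd_DD_calc = if (dd_ok) D^2 / T_ else NA_real_,
       defined = c(MM = mm_ok, DD = dd_ok))
}

#' Hill-modified operational model of allosterically modulated agonism
#'
#' Response (% of total protein in the tetramer, in this application) of a
#' system driven by an agonist/substrate at concentration `S` in the presence
#' of an allosteric-competitive modulator at concentration `B`:
#' `E = E_max * A^n / (C^n + A^n)` with
#' `A = tau_S * S * (K_B + alpha*beta*B) + tau_I * B * K_S` and
#' `C = S*K_B + K_S*K_B + K_S*B + alpha*S*B`.
#' At `B = 0` this reduces to the two-parameter operational Hill curve
#' `E_max * (tau_S S)^n / ((S + K_S)^n + (tau_S S)^n)`.
#'
#' @param S Substrate concentration(s), molar. Vectorized.
#' @param B Inhibitor concentration(s), molar. Vectorized (recycled).
#' @param p An [omam_params()] object.
#' @return Response in percent.
#' @export
omam_response <- function(S, B, p) {
  stopifnot(inherits(p, "omam_params"))
  check_nonnegative(S, "S")
  check_nonnegative(B, "B")
  A <- p$tau_S * S * (p$K_B + p$alpha * p$beta * B) + p$tau_I * B * p$K_S
  C <- S * p$K_B + p$K_S * p$K_B + p$K_S * B + p$alpha * S * B
  An <- A^p$n
  p$E_max * An / (C^p$n + An)
}

#' Model-predicted oligomer fractions for a condition
#'
#' Convenience wrapper: effective constants -> equilibrium -> concentration
#' (monomer-equivalent) fractions. This is the noise-free expectation of what
#' the measurement pipeline estimates from event lists.
#'
#' @inheritParams effective_constants
#' @return List with `f_M`, `f_D`, `f_T` (concentration fractions, summing to
#'   1), the `species_concentrations`, and the effective constants.
#' @export
predict_fractions <- function(params, inh = NULL, cond) {
  eff <- effective_constants(params, inh, cond)
  sp <- solve_equilibrium(eff$K1_eff, eff$K2_eff, cond$C_tot)
  list(f_M = sp$M / cond$C_tot,
       f_D = 2 * sp$D / cond$C_tot,
       f_T = 4 * sp$T / cond$C_tot,
       species = sp, effective = eff)
}
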