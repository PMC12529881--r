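#' Convert an IC50 into an inhibitor dissociation constant Ki
#'
#' Three explicit conversion modes, recorded in the result:
#' \describe{
#'   \item{classical}{`Ki = IC50 / (1 + S/K_S)`, the Cheng-Prusoff relation
#'     for competition with a substrate at concentration `S`.}
#'   \item{hill}{`Ki = IC50 / (1 + S/K_S)^n`, the competition factor raised
#'     to the Hill exponent, for cooperative assays.}
#'   \item{empirical_lambda}{`Ki = IC50 / lambda` with a factor calibrated
#'     from matched IC50/Ki pairs (see [calibrate_lambda()]); appropriate
#'     when the assay-specific conversion is known only empirically.}
#' }
#'
#' @param IC50 Half-maximal inhibitory concentration(s), molar.
#' @param cfg A [pharmacology_config()].
#' @return List with `Ki` (molar, same length as `IC50`), the `mode` and the
#'   conversion `factor` applied.
#' @export
ic50_to_ki <- function(IC50, cfg) {
  stopifnot(inherits(cfg, "pharmacology_config"))
  check_positive(IC50, "IC50")
  factor <- switch(cfg$mode,
    classical = 1 + cfg$S / cfg$K_S,
    hill = (1 + cfg$S / cfg$K_S)^cfg$n,
    empirical_lambda = {
      if (is.null(cfg$lambda)) {
        stop("mode 'empirical_lambda' requires a calibrated `lambda`",
             call. = FALSE)
      }
      cfg$lambda
    })
  list(Ki = IC50 / factor, mode = cfg$mode, factor = factor)
}

#' Calibrate the empirical IC50/Ki conversion factor lambda
#'
#' `lambda` is the geometric mean of the per-pair ratios `IC50 / Ki`. The
#' residual report flags the calibration as inconsistent when any per-pair
#' ratio deviates from `lambda` by more than 10%, i.e. when the pairs do not
#' share a single conversion factor.
#'
#' @param ic50,ki Matched vectors of IC50 and Ki values (molar or any common
#'   unit), all positive.
#' @return List with `lambda`, per-pair `ratios`, relative `residuals`
#'   (`ratio/lambda - 1`) and the logical `consistent`.
#' @export
calibrate_lambda <- function(ic50, ki) {
  if (length(ic50) != length(ki) || length(ic50) < 1) {
    stop("need at least one matched IC50/Ki pair", call. = FALSE)
  }
  check_positive(ic50, "ic50")
  check_positive(ki, "ki")
  ratios <- ic50 / ki
  lambda <- exp(mean(log(ratios)))
  residuals <- ratios / lambda - 1
  list(lambda = lambda, ratios = ratios, residuals = residuals,
       consistent = max(abs(residuals)) <= 0.10)
}

#' Linear Schild analysis of EC50 concentration ratios
#'
#' Concentration ratios `CR = EC50(B) / EC50(0)` are transformed into a
#' Schild plot, `log10(CR - 1)` against `log10(B)`, and the linear region is
#' fitted by least squares. For a purely competitive antagonist
#' `CR = 1 + B/K_B`, giving slope 1 and x-intercept `log10(K_B)`; the
#' apparent affinity is reported as `K_B_app = 10^(x-intercept)`.
#'
#' @param ec50_by_B Data frame with columns `B` (antagonist concentration,
#'   molar, `> 0`) and `EC50` (molar).
#' @param ec50_control EC50 without antagonist (molar).
#' @param linear_region `NULL` for automatic selection (all B with
#'   `CR - 1 > 0.2`), or a length-2 numeric giving B bounds.
#' @return Object of class `schild_result`: `points` (B, CR), `slope`,
#'   `K_B_app`, `r_squared`, `linear_region` (range of B used), `n_used`.
#' @export
schild_analysis <- function(ec50_by_B, ec50_control, linear_region = NULL) {
  stopifnot(is.data.frame(ec50_by_B), all(c("B", "EC50") %in% names(ec50_by_B)))
  check_positive(ec50_control, "ec50_control")
  check_positive(ec50_by_B$B, "B")
  CR <- ec50_by_B$EC50 / ec50_control
  points <- data.frame(B = ec50_by_B$B, CR = CR)
  usable <- CR > 1
  if (!any(usable)) {
    stop("no-effect region only: no concentration ratios above 1",
         call. = FALSE)
  }
  if (is.null(linear_region)) {
    in_region <- usable & (CR - 1 > 0.2)
  } else {
    stopifnot(length(linear_region) == 2)
    in_region <- usable & ec50_by_B$B >= linear_region[1] &
      ec50_by_B$B <= linear_region[2]
  }
  if (sum(in_region) < 2) {
    stop("need at least 2 usable points (CR > 1) in the linear region",
         call. = FALSE)
  }
  lx <- log10(ec50_by_B$B[in_region])
  ly <- log10(CR[in_region] - 1)
  fit <- stats::lm(ly ~ lx)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  x_int <- -intercept / slope
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(list(points = points, slope = slope,
                 K_B_app = 10^x_int, r_squared = r2,
                 linear_region = range(ec50_by_B$B[in_region]),
                 n_used = sum(in_region)),
            class = "schild_result")
}

#' @export
print.schild_result <- function(x, ...) {
  cat(sprintf(
    "schild_result: slope = %.3f, K_B_app = %.4g M, R2 = %.3f (%d points)\n",
    x$slope, x$K_B_app, x$r_squared, x$n_used))
  invisible(x)
}

#' Allosteric (nonlinear) Schild fit
#'
#' Fits the allosteric ternary complex model concentration-ratio relation
#' `CR = (1 + B/K_B) / (1 + alpha * B/K_B)` by least squares on `log CR`.
#' With `alpha = 0` this reduces to linear Schild behavior (slope 1);
#' `alpha = 1` gives `CR = 1` for all B and is unidentifiable, which is
#' flagged rather than fitted.
#'
#' @param ec50_by_B Data frame with columns `B` and `EC50` (molar).
#' @param ec50_control EC50 without antagonist (molar).
#' @return List with `alpha`, `K_B`, `converged`, `flagged` and the fitted
#'   `points`.
#' @export
schild_nonlinear <- function(ec50_by_B, ec50_control) {
  stopifnot(is.data.frame(ec50_by_B), all(c("B", "EC50") %in% names(ec50_by_B)))
  check_positive(ec50_control, "ec50_control")
  CR <- ec50_by_B$EC50 / ec50_control
  B <- ec50_by_B$B
  keep <- B > 0
  B <- B[keep]
  CR <- CR[keep]
  if (length(B) < 3) stop("need at least 3 usable antagonist concentrations",
                          call. = FALSE)
  if (max(abs(CR - 1)) < 0.05) {
    return(list(alpha = NA_real_, K_B = NA_real_, converged = FALSE,
                flagged = TRUE, reason = "CR == 1 throughout: unidentifiable",
                points = data.frame(B = B, CR = CR)))
  }
  resid_fn <- function(p) {
    kb <- 10^p[["logK"]]
    log(CR) - log((1 + B / kb) / (1 + p[["alpha"]] * B / kb))
  }
  start <- c(logK = log10(stats::median(B)), alpha = 0.1)
  fit <- minpack.lm::nls.lm(par = start,
                            lower = c(logK = log10(min(B)) - 6, alpha = 0),
                            upper = c(logK = log10(max(B)) + 6, alpha = 10),
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-14, ptol = 1e-14))
  converged <- fit$info %in% 1:4
  list(alpha = unname(fit$par[["alpha"]]), K_B = unname(10^fit$par[["logK"]]),
       converged = converged, flagged = !converged,
       points = data.frame(B = B, CR = CR))
}

#' Global fit of the Hill-modified operational model (OMAM)
#'
#' Fits a single shared parameter set to substrate-response curves measured
#' at several inhibitor concentrations, minimizing the (optionally weighted)
#' sum of squared errors of [omam_response()] across all curves. `E_max` and
#' `K_S` are fixed from prior analysis; `K_B`, `tau_S`, `tau_I`, `alpha`,
#' `beta` and `n` are free. The objective is multi-modal, so `n_starts`
#' log-uniform starting points (fixed seed) are run through
#' Levenberg-Marquardt and the best final SSE is kept.
#'
#' The data must include a `B = 0` control curve. If only `B = 0` data is
#' supplied, `tau_S` and `n` are fitted from the control curve and the
#' inhibitor-side parameters are returned as `NA` and flagged unidentifiable.
#'
#' @param data Data frame with columns `S`, `B` (molar), `y` (response, %),
#'   and optionally `y_err`.
#' @param E_max,K_S Fixed maximal response (%) and substrate affinity (molar).
#' @param n_starts Number of multi-start draws (>= 1).
#' @param seed Seed for the start draws (default 12345).
#' @param bounds Named list overriding default box bounds.
#' @return Object of class `omam_fit`: `params` ([omam_params()]), `sse`,
#'   `r_squared`, `converged`, `flagged`, `at_bounds` (parameters pinned at a
#'   box bound, a sign of misspecification), `unidentifiable` (character
#'   vector of parameter names, empty when all are identifiable), `n_starts`.
#' @export
omam_global_fit <- function(data, E_max = 68.3, K_S = 34.6e-6,
                            n_starts = 12, seed = 12345, bounds = list()) {
  stopifnot(is.data.frame(data), all(c("S", "B", "y") %in% names(data)))
  if (!any(data$B == 0)) {
    stop("identifiability: a B = 0 control curve is required", call. = FALSE)
  }
  w <- if ("y_err" %in% names(data) && all(data$y_err > 0, na.rm = TRUE) &&
           !anyNA(data$y_err)) 1 / data$y_err^2 else rep(1, nrow(data))
  b0_only <- all(data$B == 0)

  lo <- list(logKB = -12, logtauS = -3, logtauI = -8, alpha = 0, beta = 0,
             n = 0.2)
  hi <- list(logKB = -2, logtauS = 3, logtauI = 3, alpha = 100, beta = 100,
             n = 5)
  for (nm in names(bounds)) {
    lo[[nm]] <- bounds[[nm]][1]
    hi[[nm]] <- bounds[[nm]][2]
  }

  if (b0_only) {
    # only the operational Hill curve is constrained: fit tau_S and n
    resid_fn <- function(p) {
      pars <- omam_params(E_max, K_S, 1e-6, 10^p[["logtauS"]], 0, 0, 0,
                          p[["n"]])
      sqrt(w) * (data$y - omam_response(data$S, data$B, pars))
    }
    fit <- minpack.lm::nls.lm(par = c(logtauS = 0.5, n = 1),
                              lower = c(lo$logtauS, lo$n),
                              upper = c(hi$logtauS, hi$n), fn = resid_fn)
    pars <- omam_params(E_max, K_S, 1e-6, 10^fit$par[["logtauS"]], 0, 0, 0,
                        fit$par[["n"]])
    pars$K_B <- NA_real_
    pars$tau_I <- NA_real_
    pars$alpha <- NA_real_
    pars$beta <- NA_real_
    return(structure(list(params = pars, sse = fit$deviance,
                          r_squared = NA_real_,
                          converged = fit$info %in% 1:4, flagged = TRUE,
                          unidentifiable = c("K_B", "tau_I", "alpha", "beta"),
                          n_starts = 1),
                     class = "omam_fit"))
  }

  par_names <- c("logKB", "logtauS", "logtauI", "alpha", "beta", "n")
  lower <- unlist(lo[par_names])
  upper <- unlist(hi[par_names])
  resid_fn <- function(p) {
    pars <- omam_params(E_max, K_S, 10^p[["logKB"]], 10^p[["logtauS"]],
                        10^p[["logtauI"]], p[["alpha"]], p[["beta"]],
                        p[["n"]])
    sqrt(w) * (data$y - omam_response(data$S, data$B, pars))
  }
  starts <- with_seed(seed, {
    lapply(seq_len(max(1, n_starts)), function(i) {
      c(logKB = stats::runif(1, -9, -4),
        logtauS = stats::runif(1, -1, 2),
        logtauI = stats::runif(1, -4, 1),
        alpha = 10^stats::runif(1, -3, 1),
        beta = 10^stats::runif(1, -3, 1),
        n = stats::runif(1, 0.5, 2))
    })
  })
  best <- NULL
  for (st in starts) {
    fit <- try(minpack.lm::nls.lm(par = st, lower = lower, upper = upper,
                                  fn = resid_fn,
                                  control = minpack.lm::nls.lm.control(
                                    maxiter = 1000, ftol = 1e-14,
                                    ptol = 1e-14)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(params = NULL, sse = NA_real_, r_squared = NA_real_,
                          converged = FALSE, flagged = TRUE,
                          unidentifiable = character(0),
                          n_starts = n_starts),
                     class = "omam_fit"))
  }
  p <- best$par
  pars <- omam_params(E_max, K_S, 10^p[["logKB"]], 10^p[["logtauS"]],
                      10^p[["logtauI"]], p[["alpha"]], p[["beta"]], p[["n"]])
  ss_tot <- sum(w * (data$y - stats::weighted.mean(data$y, w))^2)
  # a parameter pinned at a box bound signals a degenerate direction
  # (typically model misspecification); the zero lower bounds of alpha/beta
  # are legitimate estimates and not treated as pinning
  span <- upper - lower
  at_upper <- abs(p - upper) < 1e-6 * span
  at_lower <- abs(p - lower) < 1e-6 * span & !(names(p) %in% c("alpha", "beta"))
  at_bounds <- names(p)[at_upper | at_lower]
  structure(list(params = pars, sse = best$deviance,
                 r_squared = if (ss_tot > 0) 1 - best$deviance / ss_tot
                             else NA_real_,
                 converged = best$info %in% 1:4,
                 flagged = !(best$info %in% 1:4),
                 at_bounds = at_bounds,
                 unidentifiable = character(0), n_starts = n_starts),
            class = "omam_fit")
}

#' @export
print.omam_fit <- function(x, ...) {
  if (is.null(x$params)) {
    cat("omam_fit: no convergent start\n")
    return(invisible(x))
  }
  p <- x$params
  cat(sprintf(
    paste0("omam_fit%s: tau_S = %.3g, tau_I = %.3g, alpha = %.3g, ",
           "beta = %.3g, K_B = %.4g M, n = %.3g (SSE %.4g)\n"),
    if (x$flagged) " (flagged)" else "", p$tau_S, p$tau_I, p$alpha, p$beta,
    p$K_B, p$n, x$sse))
  invisible(x)
}
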