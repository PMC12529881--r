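#' Hill-logistic dose-response function
#'
#' `y = bottom + (top - bottom) * x^n / (K^n + x^n)`. Decreasing curves are
#' obtained with `top < bottom`. At `x = K` the response is the midpoint
#' `(bottom + top)/2`; at `x = 0` it is `bottom` and for `x -> Inf` it tends
#' to `top`.
#'
#' @param x Concentration(s), `>= 0`.
#' @param bottom,top Asymptotes (response units, typically percent).
#' @param K Midpoint concentration (same units as `x`), `> 0`.
#' @param n Hill coefficient, `> 0`.
#' @return Response values.
#' @export
hill_logistic <- function(x, bottom, top, K, n) {
  check_positive(K, "K")
  check_positive(n, "n")
  check_nonnegative(x, "x")
  xn <- ifelse(x == 0, 0, exp(n * log(x)))
  bottom + (top - bottom) * xn / (K^n + xn)
}

#' A titration series (one response curve)
#'
#' @param x Concentration axis (molar), `>= 0`.
#' @param y Response (fraction in percent).
#' @param y_err Optional standard deviations of `y`.
#' @param axis_kind What the x axis is: protein, free monomer, free dimer,
#'   substrate, or inhibitor concentration.
#' @return Object of class `titration_series`.
#' @export
titration_series <- function(x, y, y_err = NULL,
                             axis_kind = c("protein", "free_monomer",
                                           "free_dimer", "substrate",
                                           "inhibitor")) {
  axis_kind <- match.arg(axis_kind)
  check_nonnegative(x, "x")
  stopifnot(length(x) == length(y))
  if (!is.null(y_err)) stopifnot(length(y_err) == length(y))
  structure(list(x = x, y = y, y_err = y_err, axis_kind = axis_kind),
            class = "titration_series")
}

#' Fit a Hill-logistic curve to a titration series
#'
#' Weighted least squares (weights `1/sigma^2` when `y_err` is supplied) via
#' Levenberg-Marquardt, with the midpoint fitted on a log scale. Plateau
#' constraints follow the convention of constraining fits to approximate
#' plateau values: a supplied `bottom`/`top` is either fixed exactly
#' (`plateau_halfwidth = 0`) or boxed within `+/- plateau_halfwidth` response
#' units (default 5). The Hill coefficient can be fixed with `fix_n`.
#'
#' The fit is flagged (`flagged = TRUE`) when the optimizer does not
#' converge or when the fitted midpoint falls outside the concentration range
#' of the data by more than a factor of 100.
#'
#' @param series A [titration_series()] (or list with `x`, `y`, `y_err`).
#' @param fix_n Fix the Hill coefficient at this value (`NULL` = free).
#' @param bottom,top Optional plateau constraint centers.
#' @param plateau_halfwidth Half-width of the plateau box in response units.
#' @param n_bounds Bounds for a free Hill coefficient.
#' @param min_span Minimum observed response range (response units) for the
#'   series to count as covering a transition; flatter series are flagged.
#' @return Object of class `hill_fit`: `estimates` (bottom, top, K, n), `se`,
#'   `r_squared`, `converged`, `flagged`, `constraints`, `orientation`.
#' @export
fit_hill <- function(series, fix_n = NULL, bottom = NULL, top = NULL,
                     plateau_halfwidth = 5, n_bounds = c(0.2, 6),
                     min_span = 5) {
  x <- series$x
  y <- series$y
  if (length(x) < 4) stop("need at least 4 points spanning the transition",
                          call. = FALSE)
  w <- if (!is.null(series$y_err) && all(series$y_err > 0)) {
    1 / series$y_err^2
  } else {
    rep(1, length(y))
  }
  xpos <- x[x > 0]
  if (length(xpos) < 2) stop("need at least 2 positive concentrations",
                             call. = FALSE)
  y_lo_end <- mean(y[x <= stats::quantile(x, 0.25)])
  y_hi_end <- mean(y[x >= stats::quantile(x, 0.75)])

  # parameter bookkeeping: full vector (bottom, top, logK, n), some fixed
  start <- c(bottom = bottom %||% y_lo_end, top = top %||% y_hi_end,
             logK = log10(exp(mean(log(range(xpos))))),
             n = fix_n %||% 1)
  lower <- c(bottom = -Inf, top = -Inf,
             logK = log10(min(xpos)) - 4, n = n_bounds[1])
  upper <- c(bottom = Inf, top = Inf,
             logK = log10(max(xpos)) + 4, n = n_bounds[2])
  fixed <- c(bottom = FALSE, top = FALSE, logK = FALSE, n = !is.null(fix_n))
  if (!is.null(bottom)) {
    if (plateau_halfwidth == 0) fixed["bottom"] <- TRUE
    lower["bottom"] <- bottom - plateau_halfwidth
    upper["bottom"] <- bottom + plateau_halfwidth
  }
  if (!is.null(top)) {
    if (plateau_halfwidth == 0) fixed["top"] <- TRUE
    lower["top"] <- top - plateau_halfwidth
    upper["top"] <- top + plateau_halfwidth
  }
  free <- names(start)[!fixed]
  resid_fn <- function(p) {
    full <- start
    full[free] <- p
    sqrt(w) * (y - hill_logistic(x, full[["bottom"]], full[["top"]],
                                 10^full[["logK"]], full[["n"]]))
  }
  fit <- minpack.lm::nls.lm(par = start[free], lower = lower[free],
                            upper = upper[free], fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-12, ptol = 1e-12))
  full <- start
  full[free] <- fit$par
  est <- c(bottom = unname(full[["bottom"]]), top = unname(full[["top"]]),
           K = unname(10^full[["logK"]]), n = unname(full[["n"]]))
  # standard errors on the free parameters (delta method for K = 10^logK)
  se <- c(bottom = NA_real_, top = NA_real_, K = NA_real_, n = NA_real_)
  dof <- length(y) - length(free)
  if (dof > 0 && fit$info %in% 1:4) {
    cov_try <- try(solve(fit$hessian) * fit$deviance / dof, silent = TRUE)
    if (!inherits(cov_try, "try-error")) {
      d <- sqrt(pmax(diag(cov_try), 0))
      names(d) <- free
      if ("bottom" %in% free) se["bottom"] <- d["bottom"]
      if ("top" %in% free) se["top"] <- d["top"]
      if ("logK" %in% free) se["K"] <- d["logK"] * log(10) * est["K"]
      if ("n" %in% free) se["n"] <- d["n"]
    }
  }
  fitted_y <- hill_logistic(x, est["bottom"], est["top"], est["K"], est["n"])
  ss_res <- sum(w * (y - fitted_y)^2)
  ss_tot <- sum(w * (y - stats::weighted.mean(y, w))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  converged <- fit$info %in% 1:4
  k_in_range <- est["K"] >= min(xpos) / 100 && est["K"] <= max(xpos) * 100
  spans_transition <- diff(range(y)) >= min_span
  structure(list(estimates = est, se = se, r_squared = r2,
                 converged = converged,
                 flagged = !converged || !k_in_range || !spans_transition,
                 constraints = list(fix_n = fix_n, bottom = bottom, top = top,
                                    plateau_halfwidth = plateau_halfwidth),
                 orientation = if (est["top"] >= est["bottom"]) "increasing"
                               else "decreasing",
                 n_points = length(y)),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "hill_fit (%s%s): bottom = %.3g, top = %.3g, K = %.4g, n = %.3g, R2 = %.4f\n",
    x$orientation, if (x$flagged) ", flagged" else "",
    x$estimates["bottom"], x$estimates["top"], x$estimates["K"],
    x$estimates["n"], x$r_squared))
  invisible(x)
}

#' Free monomer and dimer concentrations from oligomer fractions
#'
#' Converts concentration fractions into the free-species concentration axes
#' used for the binding plots: `M_free = f_M * C_tot` (molar monomer) and
#' `D_free = f_D * C_tot / 2` (molar dimer particles).
#'
#' @param fractions An `oligomer_fractions` object, or a numeric vector of
#'   concentration fractions named `f_M`, `f_D`, `f_T`.
#' @param C_tot Total protein concentration (molar, monomer equivalents).
#' @return List with `M_free` and `D_free` (molar).
#' @export
free_species_concentrations <- function(fractions, C_tot) {
  cf <- if (inherits(fractions, "oligomer_fractions")) {
    fractions$conc_fractions
  } else {
    fractions
  }
  check_positive(C_tot, "C_tot")
  list(M_free = unname(cf[["f_M"]] * C_tot),
       D_free = unname(cf[["f_D"]] * C_tot / 2))
}

#' Assembly interface affinities from a dilution-series fractions table
#'
#' Estimates the monomer-monomer and dimer-dimer dissociation constants from
#' per-condition oligomer fractions. For each interface the conversion
#' fraction local to that interface is fitted against the free partner
#' concentration with a Hill-logistic curve:
#' \itemize{
#'   \item M:M -- fraction of (M + D) protein residing in dimers,
#'     `f_D / (f_M + f_D)`, against free monomer `M_free`;
#'   \item D:D -- fraction of (D + T) protein residing in tetramers,
#'     `f_T / (f_D + f_T)`, against free dimer `D_free`.
#' }
#' Under stepwise mass action each of these is an exact hyperbola in the free
#' partner with midpoint `K/2`, so the interface constant is reported as
#' twice the fitted midpoint. (The total-protein fractions, e.g. the monomer
#' fraction of all protein, are contaminated by the third species and bias
#' the midpoint; they are retained for plotting via `convention = "total"`.)
#'
#' When the series was measured at a fixed substrate concentration `S > 0`,
#' the fitted constants are effective constants at that occupancy. If
#' `params` is supplied, they are additionally extrapolated to substrate
#' saturation by inverting the log-linear linkage
#' `log K_eff = (1 - theta) log K_0 + theta log K_sat` at
#' `theta = (S/K_S)^n_link / (1 + (S/K_S)^n_link)`.
#'
#' @param fractions_table Data frame with columns `c_tot`, `conc_f_M`,
#'   `conc_f_D`, `conc_f_T` (fractions as proportions), e.g. rows from
#'   [quantify_events()]. Replicate rows per condition are allowed and
#'   used to weight the fit by the replicate standard deviation.
#' @param S Substrate concentration of the design (molar; 0 = none).
#' @param params An [equilibrium_params()] carrying `K_S`, `n_link` and the
#'   substrate-free constants, required for saturation extrapolation.
#' @param convention `"interface"` (default, unbiased) or `"total"`
#'   (total-protein fractions, plotting convention).
#' @return List with `Kd_MM`, `Kd_DD` (molar; `NA` when flagged), the
#'   underlying `hill_fit`s, and -- when `S > 0` and `params` is given --
#'   `Kd_MM_sat`, `Kd_DD_sat` extrapolated to saturating substrate.
#' @export
fit_assembly_affinities <- function(fractions_table, S = 0, params = NULL,
                                    convention = c("interface", "total")) {
  convention <- match.arg(convention)
  tab <- fractions_table
  req <- c("c_tot", "conc_f_M", "conc_f_D", "conc_f_T")
  if (!all(req %in% names(tab))) {
    stop("fractions table must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  tab$M_free <- tab$conc_f_M * tab$c_tot
  tab$D_free <- tab$conc_f_D * tab$c_tot / 2
  if (convention == "interface") {
    tab$y_MM <- 100 * tab$conc_f_D / (tab$conc_f_M + tab$conc_f_D)
    tab$y_DD <- 100 * tab$conc_f_T / (tab$conc_f_D + tab$conc_f_T)
  } else {
    tab$y_MM <- 100 * (1 - tab$conc_f_M)  # protein no longer monomeric
    tab$y_DD <- 100 * tab$conc_f_T
  }
  agg <- function(xcol, ycol) {
    sp <- split(tab, tab$c_tot)
    x <- vapply(sp, function(d) mean(d[[xcol]]), numeric(1))
    y <- vapply(sp, function(d) mean(d[[ycol]]), numeric(1))
    yerr <- vapply(sp, function(d)
      if (nrow(d) > 1) stats::sd(d[[ycol]]) else NA_real_, numeric(1))
    if (any(is.na(yerr)) || any(yerr == 0)) yerr <- NULL
    ord <- order(x)
    titration_series(x[ord], y[ord],
                     y_err = if (!is.null(yerr)) yerr[ord],
                     axis_kind = if (xcol == "M_free") "free_monomer"
                                 else "free_dimer")
  }
  fit_one <- function(xcol, ycol) {
    ser <- agg(xcol, ycol)
    fit <- fit_hill(ser, bottom = 0, top = 100, plateau_halfwidth = 0)
    kd <- if (fit$flagged) NA_real_ else unname(2 * fit$estimates["K"])
    list(fit = fit, Kd = kd)
  }
  mm <- fit_one("M_free", "y_MM")
  dd <- fit_one("D_free", "y_DD")
  out <- list(Kd_MM = mm$Kd, Kd_DD = dd$Kd,
              fits = list(MM = mm$fit, DD = dd$fit),
              convention = convention, S = S)
  if (S > 0 && !is.null(params)) {
    theta <- (S / params$K_S)^params$n_link /
      (1 + (S / params$K_S)^params$n_link)
    invert <- function(K_eff, K_0) {
      if (is.na(K_eff)) return(NA_real_)
      exp((log(K_eff) - (1 - theta) * log(K_0)) / theta)
    }
    out$theta <- theta
    out$Kd_MM_sat <- invert(mm$Kd, params$K1_0)
    out$Kd_DD_sat <- invert(dd$Kd, params$K2_0)
  }
  out
}
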