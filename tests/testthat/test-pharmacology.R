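table1_ic50 <- c(C5 = 19.7e-6, C13 = 19.4e-6, C15 = 3.1e-6)
table1_ki <- c(C5 = 517.2e-9, C13 = 508.3e-9, C15 = 82.6e-9)

test_that("ic50_to_ki: the three conversion modes behave as documented", {
  cfg <- pharmacology_config("classical", S = 100e-6, K_S = 34.6e-6)
  # constructed identity: IC50 = (1 + S/K_S) * 1 uM
  out <- ic50_to_ki((1 + 100 / 34.6) * 1e-6, cfg)
  expect_equal(out$Ki, 1e-6, tolerance = 1e-6)
  expect_identical(out$mode, "classical")

  # no-substrate limit
  cfg0 <- pharmacology_config("classical", S = 0, K_S = 34.6e-6)
  expect_equal(ic50_to_ki(5e-6, cfg0)$Ki, 5e-6)

  # hill mode equals classical at n = 1
  cfg_h1 <- pharmacology_config("hill", S = 100e-6, K_S = 34.6e-6, n = 1)
  expect_equal(ic50_to_ki(5e-6, cfg_h1)$Ki, ic50_to_ki(5e-6, cfg)$Ki)
  cfg_h <- pharmacology_config("hill", S = 100e-6, K_S = 34.6e-6, n = 1.3)
  expect_equal(ic50_to_ki(5e-6, cfg_h)$factor, (1 + 100 / 34.6)^1.3)

  # empirical mode requires lambda
  expect_error(ic50_to_ki(5e-6, pharmacology_config("empirical_lambda")),
               "lambda")
  cfg_l <- pharmacology_config("empirical_lambda", lambda = 37.9)
  expect_equal(ic50_to_ki(3.1e-6, cfg_l)$Ki, 3.1e-6 / 37.9)
})

test_that("lambda calibration reproduces a single consistent factor from the potency table", {
  cal <- calibrate_lambda(table1_ic50, table1_ki)
  # per-pair ratios: 38.1, 38.2, 37.5 -- oracle by direct division
  expect_equal(unname(cal$ratios), unname(table1_ic50 / table1_ki))
  expect_equal(cal$lambda, 37.9, tolerance = 0.01)
  expect_true(cal$consistent)
  expect_lt(max(abs(cal$residuals)), 0.02)

  # the calibrated factor reproduces each printed Ki from its printed IC50
  cfg <- pharmacology_config("empirical_lambda", lambda = cal$lambda)
  expect_equal(ic50_to_ki(table1_ic50, cfg)$Ki, table1_ki, tolerance = 0.02)

  expect_equal(calibrate_lambda(2, 1)$lambda, 2)
  expect_false(calibrate_lambda(c(2, 200), c(1, 1))$consistent)
  expect_error(calibrate_lambda(c(2, -1), c(1, 1)), "positive")
})

test_that("competitive concentration ratios give Schild slope 1 and K_B at the intercept", {
  K_B <- 0.7e-6
  B <- c(0.8, 2, 5, 10) * 1e-6
  ec50 <- (1 + B / K_B) * 1e-6
  sch <- schild_analysis(data.frame(B = B, EC50 = ec50), 1e-6)
  expect_equal(sch$slope, 1, tolerance = 1e-9)
  expect_equal(sch$K_B_app, K_B, tolerance = 1e-9)
  expect_equal(sch$r_squared, 1, tolerance = 1e-9)

  # property: exact for any K_B over three decades
  for (kb in 10^seq(-8, -5, length.out = 7)) {
    Bk <- kb * c(2, 5, 20, 100)
    s <- schild_analysis(data.frame(B = Bk, EC50 = (1 + Bk / kb) * 1e-6),
                         1e-6)
    expect_equal(s$slope, 1, tolerance = 1e-8)
    expect_equal(s$K_B_app, kb, tolerance = 1e-6)
  }
})

test_that("allosteric saturation flattens the high-B Schild slope below 1", {
  kb <- 25.2e-9
  alpha <- 0.02
  B <- 10^seq(-7, -3, length.out = 9)
  CR <- (1 + B / kb) / (1 + alpha * B / kb)  # brute-force ATCM oracle
  sch <- schild_analysis(data.frame(B = B, EC50 = CR * 1e-6), 1e-6,
                         linear_region = c(1e-5, 1e-3))
  expect_lt(sch$slope, 1)
})

test_that("schild_analysis rejects unusable inputs informatively", {
  expect_error(schild_analysis(data.frame(B = 1e-6, EC50 = 2e-6), 1e-6),
               "at least 2")
  expect_error(
    schild_analysis(data.frame(B = c(1e-6, 2e-6), EC50 = c(1e-6, 9e-7)),
                    1e-6),
    "no-effect")
})

test_that("nonlinear Schild fit recovers ATCM parameters and flags the null modulator", {
  kb <- 25.2e-9
  alpha <- 0.02
  B <- 10^seq(-8.5, -4, length.out = 10)
  CR <- (1 + B / kb) / (1 + alpha * B / kb)
  fit <- schild_nonlinear(data.frame(B = B, EC50 = CR * 1e-6), 1e-6)
  expect_false(fit$flagged)
  expect_equal(fit$K_B, kb, tolerance = 1e-4)
  expect_equal(fit$alpha, alpha, tolerance = 1e-4)

  # alpha = 1 -> CR == 1 everywhere: unidentifiable
  null_fit <- schild_nonlinear(data.frame(B = B, EC50 = rep(1e-6, 10)), 1e-6)
  expect_true(null_fit$flagged)
  expect_true(is.na(null_fit$K_B))

  # alpha = 0 -> pure competition: linear Schild slope 1 on the same CR
  CR0 <- 1 + B / kb
  fit0 <- schild_nonlinear(data.frame(B = B, EC50 = CR0 * 1e-6), 1e-6)
  expect_equal(fit0$alpha, 0, tolerance = 1e-6)
  sch0 <- schild_analysis(data.frame(B = B, EC50 = CR0 * 1e-6), 1e-6)
  expect_equal(sch0$slope, 1, tolerance = 1e-8)
})

omam_truth <- function() {
  omam_params(E_max = 68.3, K_S = 34.6e-6, K_B = 25.2e-9, tau_S = 17.6,
              tau_I = 0.02, alpha = 0.02, beta = 0, n = 1.3)
}

omam_grid <- function() {
  expand.grid(S = 800e-6 / 2^(13:0),
              B = c(0, 2e-8, 2e-7, 8e-7, 2e-6, 1e-5))
}

test_that("OMAM global fit is self-consistent on noise-free curves", {
  truth <- omam_truth()
  d <- omam_grid()
  d$y <- omam_response(d$S, d$B, truth)
  fit <- omam_global_fit(d, E_max = 68.3, K_S = 34.6e-6)
  expect_false(fit$flagged)
  expect_equal(fit$params$tau_S, truth$tau_S, tolerance = 0.05)
  expect_equal(fit$params$tau_I, truth$tau_I, tolerance = 0.05)
  expect_equal(fit$params$alpha, truth$alpha, tolerance = 0.05)
  expect_equal(fit$params$K_B, truth$K_B, tolerance = 0.05)
  expect_equal(fit$params$n, truth$n, tolerance = 0.05)
  expect_lt(fit$params$beta, 0.05)

  # idempotence: refitting the fit's own predictions returns the same
  # parameters
  d2 <- d
  d2$y <- omam_response(d2$S, d2$B, fit$params)
  fit2 <- omam_global_fit(d2, E_max = 68.3, K_S = 34.6e-6)
  expect_equal(fit2$params$tau_S, fit$params$tau_S, tolerance = 1e-4)
  expect_equal(fit2$params$K_B, fit$params$K_B, tolerance = 1e-3)
})

test_that("OMAM identifiability contracts: control curve required, B=0-only flagged", {
  truth <- omam_truth()
  d <- omam_grid()
  d$y <- omam_response(d$S, d$B, truth)
  expect_error(omam_global_fit(d[d$B > 0, ], E_max = 68.3, K_S = 34.6e-6),
               "B = 0")

  d0 <- d[d$B == 0, ]
  fit0 <- omam_global_fit(d0, E_max = 68.3, K_S = 34.6e-6)
  expect_true(fit0$flagged)
  expect_setequal(fit0$unidentifiable, c("K_B", "tau_I", "alpha", "beta"))
  expect_equal(fit0$params$tau_S, truth$tau_S, tolerance = 0.05)
  expect_true(is.na(fit0$params$K_B))
})

test_that("OMAM fit tolerates replicate measurement noise", {
  truth <- omam_truth()
  d <- omam_grid()
  mu <- omam_response(d$S, d$B, truth)
  set.seed(55)
  reps <- replicate(3, mu * (1 + rnorm(length(mu), 0, 0.05)))
  d$y <- rowMeans(reps)
  d$y_err <- pmax(apply(reps, 1, sd), 0.1)
  fit <- omam_global_fit(d, E_max = 68.3, K_S = 34.6e-6)
  expect_false(fit$flagged)
  expect_equal(fit$params$tau_S, truth$tau_S, tolerance = 0.25)
})
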