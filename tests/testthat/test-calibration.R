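test_that("MLE recovers parameters from an overdispersed simulation", {
  des <- spikein_design()
  truth <- default_truth()
  obs <- simulate_calibration_data(des, truth, t_read = 1e6, seed = 7)
  fit <- fit_read_model(obs, t_read = 1e6)
  expect_true(fit$converged)
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  expect_true(all(is.finite(se)) && all(se > 0))
  # truth inside the 95% Wald interval of each parameter
  expect_true(all(abs(cf - c(0.7, 1.5, 1.3)) <= 1.96 * se))
  # covariance symmetric PSD
  V <- vcov(fit)
  expect_equal(V, t(V))
  expect_true(min(eigen(V, symmetric = TRUE)$values) > -1e-12)
  # the optimum beats every initialisation point
  expect_true(fit$logLik >= max(fit$start_logLik) - 1e-8)
})

test_that("Poisson-truth data yields a near-Poisson fit", {
  des <- spikein_design()
  obs <- simulate_calibration_data(des, read_model_params(0.5, 0, 1),
                                   t_read = 1e6, seed = 3)
  fit <- fit_read_model(obs, t_read = 1e6)
  expect_lte(coef(fit)[["eta"]], 0.05)
  expect_gt(coef(fit)[["r_e"]], 0.45)
  expect_lt(coef(fit)[["r_e"]], 0.55)
})

test_that("degenerate calibration inputs are rejected", {
  one_tier <- data.frame(f_samp = rep(1e-3, 30),
                         c_read = rpois(30, 500))
  expect_error(fit_read_model(one_tier, t_read = 1e6), "distinct f_samp")
  zeros <- data.frame(f_samp = rep(c(1e-6, 1e-5, 1e-4), each = 5),
                      c_read = 0L)
  expect_error(fit_read_model(zeros, t_read = 1e6), "zero")
  bad <- data.frame(f_samp = c(0, 1e-4, 1e-3), c_read = c(1L, 2L, 3L))
  expect_error(fit_read_model(bad, t_read = 1e6), "f_samp")
})

test_that("r_e bias shrinks as replicates grow", {
  truth <- default_truth()
  bias <- sapply(c(6, 60), function(nrep) {
    des <- spikein_design(n_replicates = nrep)
    mean(sapply(1:5, function(s) {
      obs <- simulate_calibration_data(des, truth, t_read = 1e6,
                                       seed = 100 + s)
      coef(fit_read_model(obs, t_read = 1e6))[["r_e"]] - 0.7
    }))
  })
  expect_lt(abs(bias[2]), abs(bias[1]) + 0.005)
})

test_that("detection limit matches the Poisson closed form", {
  p <- read_model_params(1, 0, 1)
  dl <- detection_limit(p, alpha = 0.95, t_read = 1e6, c_thresh = 0)
  # 1 - exp(-f * 1e6) = 0.95  =>  f = log(20) / 1e6
  expect_equal(dl$f_samp95, log(20) / 1e6, tolerance = 1e-5)
  expect_equal(dl$achieved, 0.95, tolerance = 1e-4)
})

test_that("detection limit is monotone in its drivers", {
  p <- read_model_params(0.7, 1.5, 1.3)
  base <- detection_limit(p, 0.95, t_read = 1e6)$f_samp95
  expect_gte(detection_limit(p, 0.99, t_read = 1e6)$f_samp95, base)
  expect_gte(detection_limit(p, 0.95, t_read = 1e6,
                             c_thresh = 18)$f_samp95, base)
  expect_lte(detection_limit(p, 0.95, t_read = 1e7)$f_samp95, base)
  p_hi <- read_model_params(0.9, 1.5, 1.3)
  expect_lte(detection_limit(p_hi, 0.95, t_read = 1e6)$f_samp95, base)
  # detection probability at the limit equals alpha
  mu <- base * 0.7 * 1e6
  size <- mu^(2 - 1.3) / 1.5
  expect_equal(pnbinom(0, size = size, mu = mu, lower.tail = FALSE), 0.95,
               tolerance = 1e-4)
})

test_that("unreachable alpha reports the maximum achievable probability", {
  p <- read_model_params(1e-6, 0, 1)
  expect_error(detection_limit(p, alpha = 0.95, t_read = 100),
               "unreachable")
})

test_that("bootstrap detection-limit interval behaves", {
  des <- spikein_design()
  obs <- simulate_calibration_data(des, default_truth(), t_read = 1e6,
                                   seed = 11)
  fit <- fit_read_model(obs, t_read = 1e6)
  dl1 <- detection_limit_ci(fit, seed = 5, n_boot = 200)
  dl2 <- detection_limit_ci(fit, seed = 5, n_boot = 200)
  expect_identical(dl1$ci_low, dl2$ci_low)  # seeded determinism
  expect_lte(dl1$ci_low, dl1$f_samp95)
  expect_gte(dl1$ci_high, dl1$f_samp95)
  # interval is tight relative to the limit for this design
  expect_lt((dl1$ci_high - dl1$ci_low) / dl1$f_samp95, 0.5)
  # zero parameter uncertainty collapses the interval
  fit0 <- fit
  fit0$vcov[] <- 0
  dl0 <- detection_limit_ci(fit0, seed = 1, n_boot = 50)
  expect_equal(dl0$ci_low, dl0$f_samp95)
  expect_equal(dl0$ci_high, dl0$f_samp95)
  # Wald alternative brackets the point estimate too
  dlw <- detection_limit_ci(fit, method = "wald")
  expect_lt(dlw$ci_low, dl1$f_samp95)
  expect_gt(dlw$ci_high, dl1$f_samp95)
})

test_that("fit methods are coherent", {
  des <- spikein_design(n_replicates = 3)
  obs <- simulate_calibration_data(des, default_truth(), t_read = 1e6,
                                   seed = 2)
  fit <- fit_read_model(obs, t_read = 1e6)
  expect_s3_class(fit, "readmodel_fit")
  expect_named(coef(fit), c("r_e", "eta", "lambda"))
  expect_equal(attr(logLik(fit), "nobs"), nrow(obs))
  pr <- predict(fit, newdata = data.frame(f_samp = c(1e-4, 1e-3)),
                interval = "prediction")
  expect_equal(pr$mu, c(1e-4, 1e-3) * coef(fit)[["r_e"]] * 1e6)
  expect_true(all(pr$lwr <= pr$mu & pr$mu <= pr$upr))
  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sim), c(nrow(obs), 2L))
  expect_true(all(sim >= 0))
  r <- residuals(fit)
  expect_lt(abs(mean(r)), 0.5)  # pearson residuals roughly centred
  expect_output(print(summary(fit)), "read-count model")
})
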