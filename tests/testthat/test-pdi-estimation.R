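test_that("per-subject OLS matches the normal equations", {
  # collinear points: exact recovery
  fit <- fit_subject_lr(data.frame(t_days = c(0, 500, 1000),
                                   egfr = c(25, 19.5, 14)))
  expect_equal(fit$intercept, 25)
  expect_equal(fit$slope, -0.011)

  # non-collinear 3-point fixture against the closed-form oracle
  t <- c(0, 100, 200); y <- c(26, 24, 25)
  fit <- fit_subject_lr(data.frame(t_days = t, egfr = y))
  cf <- oracle_ols(t, y)
  expect_equal(fit$intercept, cf[1])
  expect_equal(fit$slope, cf[2])
  expect_equal(fit$intercept, 25.5)
  expect_equal(fit$slope, -0.005)
})

test_that("per-subject OLS preconditions are enforced", {
  expect_error(fit_subject_lr(data.frame(t_days = c(0, 100),
                                         egfr = c(25, 24))),
               "at least 3")
  expect_error(fit_subject_lr(data.frame(t_days = c(5, 5, 5),
                                         egfr = c(25, 24, 26))),
               "identical")
})

test_that("LR PDI estimation composes the fit and the crossing", {
  d <- data.frame(subject_id = 1, t_days = c(0, 500, 1000),
                  egfr = c(25, 19.5, 14))
  est <- estimate_pdi_lr(d, threshold = 10)
  expect_equal(est$pdi_day, (10 - 25) / (-0.011))
  expect_true(est$valid)

  # a flat subject has no crossing
  d2 <- rbind(d, data.frame(subject_id = 2, t_days = c(0, 300, 600),
                            egfr = c(20, 20, 20)))
  est2 <- estimate_pdi_lr(d2, threshold = 10)
  expect_false(est2$valid[est2$subject_id == 2])
  expect_true(is.na(est2$pdi_day[est2$subject_id == 2]))

  # subjects with < 3 records are excluded, with count
  d3 <- rbind(d, data.frame(subject_id = 3, t_days = c(0, 200),
                            egfr = c(24, 23)))
  est3 <- suppressMessages(estimate_pdi_lr(d3, threshold = 10))
  expect_false(3 %in% est3$subject_id)
  expect_equal(attr(est3, "n_excluded"), 1L)
  expect_error(estimate_pdi_lr(d[0, ], 10), "empty")
})

test_that("crossing time is shift-invariant in (intercept, threshold)", {
  set.seed(8)
  for (i in 1:20) {
    a <- runif(1, 15, 35); b <- runif(1, -0.03, -0.001); c <- runif(1, -5, 5)
    expect_equal(pdi_from_line(a + c, b, 10 + c), pdi_from_line(a, b, 10))
  }
})

test_that("the mixed model recovers a noiseless population line", {
  set.seed(12)
  params <- pop_params(sigma1 = 1e-4, sigma2 = 1e-8, sigma_e = 1e-4)
  co <- simulate_cohort(params, visit_schedule(), 40)
  fit <- suppressWarnings(fit_lme(co$data))
  expect_equal(fit$beta0_hat, 25, tolerance = 1e-3)
  expect_equal(fit$beta1_hat, -0.011, tolerance = 1e-5)
  expect_lt(max(abs(fit$blups$b0_hat)), 1e-2)
  est <- suppressWarnings(estimate_pdi_lme(fit, 10))
  expect_equal(est$pdi_day, rep((10 - 25) / (-0.011), 40), tolerance = 1e-3)
})

test_that("BLUPs satisfy the closed-form mixed-model identity", {
  co <- default_cohort(150, seed = 21)
  fit <- fit_lme(co$data)
  expect_true(fit$converged)
  Sigma <- matrix(c(fit$sigma1_hat^2,
                    fit$rho_hat * fit$sigma1_hat * fit$sigma2_hat,
                    fit$rho_hat * fit$sigma1_hat * fit$sigma2_hat,
                    fit$sigma2_hat^2), 2)
  beta <- c(fit$beta0_hat, fit$beta1_hat)
  for (id in co$truth$subject_id) {
    d <- co$data[co$data$subject_id == id, ]
    b <- oracle_blup(d$t_days, d$egfr, beta, Sigma, fit$sigma_e_hat)
    expect_equal(fit$blups$b0_hat[fit$blups$subject_id == id], b[1],
                 tolerance = 1e-6)
    expect_equal(fit$blups$b1_hat[fit$blups$subject_id == id], b[2],
                 tolerance = 1e-6)
  }
})

test_that("variance components are recovered on a large cohort", {
  co <- default_cohort(4000, seed = 31)
  fit <- fit_lme(co$data)
  expect_true(fit$converged)
  expect_equal(fit$sigma1_hat, 6.3, tolerance = 0.05)
  expect_equal(fit$sigma_e_hat, 2, tolerance = 0.03)
  expect_equal(fit$rho_hat, 0.6, tolerance = 0.25)
  expect_equal(fit$sigma2_hat, 0.001, tolerance = 0.2)
  expect_equal(fit$beta0_hat, 25, tolerance = 0.02)
  expect_equal(fit$beta1_hat, -0.011, tolerance = 0.05)
})

test_that("LME PDI uses fixed effect plus BLUP per subject", {
  fit <- structure(
    list(beta0_hat = 25, beta1_hat = -0.011,
         blups = tibble::tibble(subject_id = 1:3,
                                b0_hat = c(0, 6.3, 0),
                                b1_hat = c(0, 0, 0.011)),
         converged = TRUE),
    class = "pdi_lme")
  est <- estimate_pdi_lme(fit, 10)
  expect_equal(est$pdi_day[1], 1363.6364, tolerance = 1e-6)
  expect_equal(est$pdi_day[2], (10 - 31.3) / (-0.011), tolerance = 1e-6)
  expect_equal(est$pdi_day[2], 1936.3636, tolerance = 1e-6)
  # subject 3: slope exactly zero -> no crossing
  expect_false(est$valid[3])
})

test_that("BLUP lines approach per-subject OLS lines as noise vanishes", {
  set.seed(41)
  params <- pop_params(sigma_e = 0.01)
  co <- simulate_cohort(params, visit_schedule(), 60)
  fit <- suppressWarnings(fit_lme(co$data))
  ols <- suppressMessages(fit_subject_lines(co$data))
  lme_int <- fit$beta0_hat + fit$blups$b0_hat
  lme_slo <- fit$beta1_hat + fit$blups$b1_hat
  expect_lt(max(abs(lme_int - ols$intercept)), 0.05)
  expect_lt(max(abs(lme_slo - ols$slope)), 1e-4)
})

test_that("BLUPs shrink to zero as the random-effect covariance vanishes", {
  co <- default_cohort(30, seed = 51)
  beta <- c(25, -0.011)
  tiny <- diag(c(1e-8, 1e-12))
  for (id in co$truth$subject_id[1:10]) {
    d <- co$data[co$data$subject_id == id, ]
    b <- oracle_blup(d$t_days, d$egfr, beta, tiny, 2)
    expect_lt(abs(b[1]), 1e-4)
    expect_lt(abs(b[2]), 1e-6)
  }
})

test_that("tidy and glance expose the fit in broom style", {
  co <- default_cohort(60, seed = 61)
  fit <- suppressWarnings(fit_lme(co$data))
  td <- tidy(fit)
  expect_equal(td$term,
               c("beta0", "beta1", "sigma1", "sigma2", "rho", "sigma_e"))
  expect_true(all(is.finite(td$estimate)))
  gl <- glance(fit)
  expect_equal(gl$n_subjects, 60)
  expect_type(gl$converged, "logical")
})
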