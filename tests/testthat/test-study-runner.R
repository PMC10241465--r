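test_that("mean absolute deviation behaves as an error summary", {
  expect_equal(as.numeric(pdi_mad(c(3, 4, 5), c(3, 4, 5))), 0)
  expect_equal(as.numeric(pdi_mad(c(0, 10), c(5, 5))), 5)
  m <- pdi_mad(c(0, 10, 20), c(5, NA, 25))
  expect_equal(as.numeric(m), 5)
  expect_equal(attr(m, "n_dropped"), 1L)
  expect_error(pdi_mad(c(1, 2), c(NA, NA)), "no valid")
})

test_that("replicates are deterministic given the master seed and index", {
  cfg <- study_config(n_subjects = 80, n_datasets = 3, master_seed = 7L)
  a <- suppressWarnings(run_replicate(cfg, 2))
  b <- suppressWarnings(run_replicate(cfg, 2))
  expect_identical(a, b)
  c1 <- suppressWarnings(run_replicate(cfg, 1))
  expect_false(isTRUE(all.equal(a$mad_lr, c1$mad_lr)))
})

test_that("running replicates out of order matches a sequential study", {
  cfg <- study_config(n_subjects = 60, n_datasets = 3, master_seed = 5L)
  study <- run_study(cfg)
  r3 <- suppressWarnings(run_replicate(cfg, 3))
  expect_equal(study$mad_lme[3], r3$mad_lme)
  expect_equal(study$mad_lr[3], r3$mad_lr)
})

test_that("a noiseless study yields essentially zero MAD for both methods", {
  pop <- pop_params(sigma1 = 1e-4, sigma2 = 1e-8, sigma_e = 1e-4)
  cfg <- study_config(population = pop, n_subjects = 50, n_datasets = 1,
                      master_seed = 2L)
  r <- suppressWarnings(run_replicate(cfg, 1))
  expect_lt(r$mad_lr, 0.5)
  expect_lt(r$mad_lme, 0.5)
})

test_that("replicate bookkeeping tracks visits and validity", {
  cfg <- study_config(n_subjects = 120, n_datasets = 1, master_seed = 9L)
  r <- suppressWarnings(run_replicate(cfg, 1))
  expect_gte(r$visit_min, 6)
  expect_lte(r$visit_max, 13)
  expect_lte(r$visit_min, r$visit_median)
  expect_lte(r$visit_median, r$visit_max)
  expect_gte(r$mad_lr, 0)
  expect_gte(r$mad_lme, 0)
})

test_that("study summaries follow the stated quantile and SD conventions", {
  # linear-interpolation quartiles on {1,2,3,4}
  q <- quantile(1:4, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  expect_equal(q, c(1.75, 2.5, 3.25))

  fake <- tibble::tibble(
    replicate = 1:4, mad_lr = c(1, 2, 3, 4), mad_lme = c(2, 2, 2, 2),
    visit_min = 6, visit_median = 9, visit_max = 12,
    n_lr_excluded = 0L, n_invalid_lr = 0L, n_invalid_lme = 0L,
    lme_converged = TRUE)
  s <- summarize_study(fake)
  lr <- s$mad[s$mad$method == "LR", ]
  expect_equal(lr$q1, 1.75)
  expect_equal(lr$median, 2.5)
  expect_equal(lr$q3, 3.25)
  expect_equal(lr$mean, 2.5)
  expect_equal(lr$sd, sd(c(1, 2, 3, 4)))
  lme <- s$mad[s$mad$method == "LME", ]
  expect_equal(lme$sd, 0)
  expect_equal(lme$min, lme$max)

  # single replicate: the seven numbers collapse
  s1 <- summarize_study(fake[1, ])
  lr1 <- s1$mad[s1$mad$method == "LR", ]
  expect_equal(unlist(lr1[, c("min", "q1", "median", "mean", "q3", "max")],
                      use.names = FALSE),
               rep(1, 6))
  expect_true(is.na(lr1$sd) || lr1$sd == 0)
})

test_that("non-converged replicates are dropped from summaries", {
  fake <- tibble::tibble(
    replicate = 1:3, mad_lr = c(1, 2, 100), mad_lme = c(1, 2, 100),
    visit_min = 6, visit_median = 9, visit_max = 12,
    n_lr_excluded = 0L, n_invalid_lr = 0L, n_invalid_lme = 0L,
    lme_converged = c(TRUE, TRUE, FALSE))
  s <- summarize_study(fake)
  expect_equal(s$n_replicates, 2)
  expect_equal(s$n_flagged, 1)
  expect_equal(max(s$mad$max), 2)
  fake$lme_converged <- FALSE
  expect_error(summarize_study(fake), "non-converged")
})

test_that("halving the residual noise decreases both MADs", {
  base <- study_config(n_subjects = 400, n_datasets = 2, master_seed = 13L)
  quiet <- study_config(population = pop_params(sigma_e = 1),
                        n_subjects = 400, n_datasets = 2, master_seed = 13L)
  rb <- summarize_study(run_study(base))
  rq <- summarize_study(run_study(quiet))
  expect_lt(rq$mad[rq$mad$method == "LR", ]$mean,
            rb$mad[rb$mad$method == "LR", ]$mean)
  expect_lt(rq$mad[rq$mad$method == "LME", ]$mean,
            rb$mad[rb$mad$method == "LME", ]$mean)
})

test_that("survival-enabled replicates report follow-up diagnostics", {
  cfg <- study_config(survival = survival_config(),
                      n_subjects = 300, n_datasets = 1, master_seed = 17L)
  r <- suppressWarnings(run_replicate(cfg, 1))
  expect_true(all(c("revkm_median_true", "revkm_median_est",
                    "sup_est_vs_truth", "sup_est_vs_true_pdi") %in% names(r)))
  expect_gte(r$sup_est_vs_truth, 0)
  expect_lte(r$sup_est_vs_truth, 1)
  expect_gte(r$n_surv_excluded, 0)
})
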