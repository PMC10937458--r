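test_that("noiseless LQ data is recovered essentially exactly", {
  truth <- survival_params_lq(0.3, 0.03)
  dat <- simulate_survival_data(truth, noise_sigma = 0, seed = 11)
  fit <- fit_survival_model(dat, "lq")
  expect_equal(fit$params$alpha, 0.3, tolerance = 1e-6)
  expect_equal(fit$params$beta, 0.03, tolerance = 1e-6)
  expect_lt(fit$see, 1e-10)
})

test_that("noiseless USC data recovers the generating parameters within 1%", {
  truth <- scc_params()
  dat <- simulate_survival_data(truth, noise_sigma = 0, seed = 11)
  fit <- fit_survival_model(dat, "usc")
  for (f in c("alpha", "beta", "D0", "Dq")) {
    expect_lt(abs(fit$params[[f]] / truth[[f]] - 1), 0.01, label = f)
  }
  # derived quantities respect the smooth-join constraints
  p <- fit$params
  expect_equal(p$DT, 2 * p$Dq / (1 - p$alpha * p$D0), tolerance = 1e-9)
  expect_equal(p$beta, (1 - p$alpha * p$D0)^2 / (4 * p$Dq * p$D0),
               tolerance = 1e-9)
})

test_that("fitting is idempotent on model-generated predictions", {
  dat <- simulate_survival_data(noise_sigma = 0.1, seed = 23)
  fit1 <- fit_survival_model(dat, "usc")
  clean <- data.frame(dose_Gy = dat$dose_Gy,
                      survival_fraction = pmin(survival_fraction(fit1$params,
                                                                 dat$dose_Gy), 1))
  fit2 <- fit_survival_model(clean, "usc")
  for (f in c("alpha", "beta", "D0", "Dq")) {
    expect_equal(fit2$params[[f]], fit1$params[[f]], tolerance = 1e-4,
                 label = f)
  }
})

test_that("standard error of the estimate matches its closed form", {
  # perfect fit -> 0
  truth <- survival_params_lq(0.25, 0.02)
  dat <- simulate_survival_data(truth, noise_sigma = 0, seed = 3)
  expect_equal(standard_error_of_estimate(dat, "lq", truth), 0,
               tolerance = 1e-14)
  # residuals (+r, -r, 0) with N - p = 1 give r*sqrt(2)
  r <- 0.2
  d <- c(5, 10, 15)
  p0 <- survival_params_lq(0.1, 0)
  s <- exp(ln_survival(p0, d) + c(r, -r, 0))
  dat2 <- data.frame(dose_Gy = d, survival_fraction = s)
  expect_equal(standard_error_of_estimate(dat2, "lq", p0), r * sqrt(2),
               tolerance = 1e-12)
  # N <= p undefined
  expect_error(standard_error_of_estimate(dat2[1:2, ], "lq", p0), "undefined")
})

test_that("LQ fits USC-generated data worse than USC does", {
  dat <- simulate_survival_data(noise_sigma = 0.05, seed = 31)
  see_usc <- fit_survival_model(dat, "usc")$see
  see_lq <- fit_survival_model(dat, "lq")$see
  expect_gt(see_lq, see_usc)
})

test_that("compare_models ranks deterministically with principled tie-breaks", {
  # pure LQ data: LQ and USC tie at ~0; LQ wins on fewer free parameters
  dat <- simulate_survival_data(survival_params_lq(0.3, 0.03),
                                noise_sigma = 0, seed = 7)
  tab <- compare_models(dat)
  expect_equal(tab$model[[1L]], "lq")
  expect_lt(abs(tab$see[tab$model == "lq"] - tab$see[tab$model == "usc"]), 1e-6)
  # insufficient points is an error, not a silent rank
  tiny <- simulate_survival_data(dose_grid = c(1, 4, 8), noise_sigma = 0,
                                 seed = 1)
  expect_error(fit_survival_model(tiny, "usc"), "at least")
})

test_that("survival data IO round-trips and validates", {
  dat <- simulate_survival_data(noise_sigma = 0.1, seed = 13)
  path <- withr::local_tempfile(fileext = ".csv")
  write_survival_data(dat, path)
  back <- read_survival_data(path)
  expect_equal(back$dose_Gy, dat$dose_Gy)
  expect_equal(back$survival_fraction, dat$survival_fraction, tolerance = 1e-12)
  # tab-delimited with comments also accepted
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# clonogenic assay", "dose_Gy\tsurvival_fraction",
               "0\t1", "2\t0.5", "4\t0.1"), path2)
  expect_equal(nrow(read_survival_data(path2)), 3L)
  # S outside (0, 1] rejected
  bad <- dat
  bad$survival_fraction[[1L]] <- 1.2
  expect_error(read_survival_data(write_survival_data(bad, path)))
})
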