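test_that("DVH construction validates and renormalizes", {
  h <- dvh(c(10, 20, 30), c(0.2, 0.5, 0.3))
  expect_s3_class(h, "dvh")
  expect_equal(sum(h$volume), 1)
  # 1% rounding slack renormalized
  expect_message(h2 <- dvh(c(10, 20), c(0.7, 0.295)), "renormalizing")
  expect_equal(sum(h2$volume), 1)
  # outside the slack is an error
  expect_error(dvh(c(10, 20), c(0.6, 0.3)), "outside")
  expect_error(dvh(c(10, 10), c(0.5, 0.5)), "strictly increasing")
  expect_error(dvh(c(20, 10), c(0.5, 0.5)), "strictly increasing")
  # cumulative must be non-increasing from 1
  expect_error(dvh(c(10, 20), c(0.8, 1), kind = "cumulative"), "non-increasing")
  h3 <- dvh(c(10, 20, 30), c(1, 0.8, 0.3), kind = "cumulative")
  expect_equal(h3$volume[[1L]], 1)
})

test_that("DVH text IO round-trips with line-numbered errors", {
  h <- dvh(c(10, 20, 30), c(0.2, 0.5, 0.3), target = "GTV1")
  path <- withr::local_tempfile(fileext = ".txt")
  write_dvh(h, path)
  back <- read_dvh(path)
  expect_equal(back$dose, h$dose)
  expect_equal(back$volume, h$volume, tolerance = 1e-9)
  expect_equal(back$kind, "differential")
  expect_equal(back$target, "GTV1")
  # cumulative file
  path2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# kind=cumulative unit=Gy-w target=t", "dose,volume",
               "10,1.0", "20,0.8", "30,0.3"), path2)
  expect_equal(read_dvh(path2)$kind, "cumulative")
  # volumes summing to 0.90 rejected with location info
  path3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# kind=differential unit=Gy-w target=t",
               "10,0.2", "20,0.4", "30,0.3"), path3)
  expect_error(read_dvh(path3), "line")
  # bad header
  path4 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("10,0.2", "20,0.8"), path4)
  expect_error(read_dvh(path4), "header")
  # packaged example parses
  ex <- read_dvh(system.file("extdata", "example_dvh.txt", package = "bnctcp"))
  expect_equal(sum(ex$volume), 1, tolerance = 1e-9)
})

test_that("differential/cumulative conversion is an exact involution", {
  cum <- dvh(c(10, 20, 30), c(1.0, 0.8, 0.3), kind = "cumulative")
  diff_ <- to_differential(cum)
  expect_equal(diff_$volume, c(0.2, 0.5, 0.3), tolerance = 1e-12)
  expect_equal(to_cumulative(diff_)$volume, cum$volume, tolerance = 1e-12)
  # single bin
  expect_equal(to_differential(dvh(15, 1, kind = "cumulative"))$volume, 1)
  # property: round trip identity on random DVHs
  set.seed(404)
  for (i in 1:25) {
    h <- random_dvh()
    expect_equal(to_differential(to_cumulative(h))$volume, h$volume,
                 tolerance = 1e-12)
  }
})

test_that("dose metrics match hand arithmetic", {
  u <- dvh(20, 1)
  expect_equal(min_dose(u), 20)
  expect_equal(max_dose(u), 20)
  expect_equal(mean_dose(u), 20)
  h <- dvh(c(10, 15, 30), c(0, 0.5, 0.5))
  expect_equal(min_dose(h), 15)   # zero-volume bin ignored
  expect_equal(max_dose(h), 30)
  expect_equal(mean_dose(h), 22.5)
  h2 <- dvh(c(9.4, 20), c(0.02, 0.98))
  expect_equal(min_dose(h2), 9.4)
})

test_that("volume_fraction_below is a strict-threshold CDF", {
  h <- dvh(c(10, 20), c(0.15, 0.85))
  expect_equal(volume_fraction_below(h, 5), 0)
  expect_equal(volume_fraction_below(h, 18.5), 0.15)
  expect_equal(volume_fraction_below(h, 10), 0)     # strict inequality
  expect_equal(volume_fraction_below(h, 25), 1)
  # non-decreasing in the threshold
  set.seed(99)
  hh <- random_dvh()
  ts <- seq(0, 110, by = 5)
  vals <- vapply(ts, function(t) volume_fraction_below(hh, t), 0)
  expect_true(all(diff(vals) >= 0))
})

test_that("dose_at_volume interpolates the cumulative curve", {
  u <- dvh(20, 1)
  expect_equal(dose_at_volume(u, 0.8), 20)
  cum <- dvh(c(10, 20, 30), c(1.0, 0.8, 0.3), kind = "cumulative")
  expect_equal(dose_at_volume(cum, 0.8), 20)    # exact node
  expect_equal(dose_at_volume(cum, 0.55), 25)   # linear interpolation
  expect_equal(dose_at_volume(cum, 1), 10)
  expect_equal(dose_at_volume(cum, 0.1), 30)    # below the last cumulative point
  expect_error(dose_at_volume(cum, 0), "volume_fraction")
  expect_error(dose_at_volume(cum, 1.5), "volume_fraction")
})

test_that("min <= mean <= max on random DVHs", {
  set.seed(2024)
  for (i in 1:25) {
    h <- random_dvh()
    expect_lte(min_dose(h), mean_dose(h) + 1e-12)
    expect_lte(mean_dose(h), max_dose(h) + 1e-12)
  }
})
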