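test_that("spectrum constructor enforces grid and value invariants", {
  expect_error(spectrum(c(500, 500, 600), c(1, 1, 1)), "strictly increasing")
  expect_error(spectrum(c(500, 450), c(1, 1)), "strictly increasing")
  expect_error(spectrum(c(400, 500), c(1, -0.1)), "non-negative")
  expect_error(spectrum(c(400, 500), c(1, NA)), "finite")
  expect_error(spectrum(400:402, c(1, 1)), "length")
  expect_error(spectrum(c(400, 500), c(0.5, 1.2), "fraction"), "<= 1")
  # relative radiance may exceed 1 (measured sparks do)
  expect_silent(spectrum(c(400, 500), c(0.5, 2.15), "relative"))
})

test_that("resample interpolates linearly, preserves constants, refuses to extrapolate", {
  s <- spectrum(c(400, 700), c(0, 3), "relative")
  expect_equal(resample(s, 500)$value, 1.0)
  const <- flat_spec(1.0)
  for (grid in list(seq(400, 700, 50), c(433, 433.7, 691.2), 400:700))
    expect_equal(resample(const, grid)$value, rep(1.0, length(grid)))
  full <- spectrum(seq(400, 700, 10), runif(31), "relative")
  expect_equal(resample(full, full$wl), full)     # identity on own grid
  expect_equal(resample(resample(full, 400:700), 400:700),
               resample(full, 400:700))           # idempotent
  expect_error(resample(s, c(399, 500)), "399")
  expect_error(resample(s, 701), "701")
  expect_identical(resample(s, 500)$unit, s$unit)
})

test_that("to_photon_units applies lambda/(hc) and is linear", {
  z <- spectrum(c(400, 500), c(0, 1), "energy_radiance")
  p <- to_photon_units(z)
  expect_equal(p$value[1L], 0)
  expect_identical(p$unit, "photon_radiance")
  # 1 W sr^-1 m^-2 nm^-1 at 500 nm, lambda/(hc) with CODATA constants
  expect_equal(p$value[2L], 2.5170583e18, tolerance = 1e-7)
  # conversion factor is proportional to lambda: 700 vs 350 gives exactly 2
  ee <- spectrum(c(350, 700), c(1, 1), "energy_radiance")
  pp <- to_photon_units(ee)
  expect_equal(pp$value[2L] / pp$value[1L], 2)
  # linearity: to_photon(a * s) = a * to_photon(s)
  s <- spectrum(400:700, runif(301), "energy_radiance")
  for (a in c(0.25, 3, 1e4))
    expect_equal(to_photon_units(spectrum(s$wl, a * s$value,
                                          "energy_radiance"))$value,
                 a * to_photon_units(s)$value)
  expect_error(to_photon_units(flat_spec(1, "relative")), "energy_radiance")
})

test_that("band_mean is a width-normalised trapezoidal integral", {
  expect_equal(band_mean(flat_spec(1.34), 400, 700), 1.34)
  ones <- flat_spec(1.0)
  for (band in list(c(400, 700), c(450, 550), c(400.5, 699.5)))
    expect_equal(band_mean(ones, band[1], band[2]), 1.0)
  ramp <- spectrum(c(400, 700), c(0, 2), "relative")
  expect_equal(band_mean(ramp, 400, 700), 1.0)
  expect_error(band_mean(ones, 500, 500), "lo < hi")
  expect_error(band_mean(ones, 300, 500), "outside")
})

test_that("spectrum CSV I/O round-trips and rejects malformed files", {
  cfg <- synth_config(seed = 11)
  rho <- generate_spark(cfg)$rho          # 301-point synthetic spark
  p <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(rho, p)
  back <- read_spectrum_csv(p, unit = "relative")
  expect_equal(back$wl, rho$wl, tolerance = 1e-12)
  expect_equal(back$value, rho$value, tolerance = 1e-12)

  writeLines(c("wavelength_nm,value", "450,0.5", "460,0.7"), p)
  two <- read_spectrum_csv(p)
  expect_length(two$wl, 2L)

  writeLines(c("wl,val", "450,0.5"), p)
  expect_error(read_spectrum_csv(p), "line 1")
  writeLines(c("wavelength_nm,value", "450,0.5", "440,0.7"), p)
  expect_error(read_spectrum_csv(p), "line 3")
  writeLines(c("wavelength_nm,value", "450,-0.5"), p)
  expect_error(read_spectrum_csv(p), "line 2")
  writeLines(c("wavelength_nm,value", "399,0.5", "450,0.5"), p)
  expect_error(read_spectrum_csv(p), "399")
  expect_silent(read_spectrum_csv(p, enforce_range = FALSE))
})
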