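test_that("ambient eye radiance is the non-coaxial reflection of the shaded side light", {
  lf <- flat_lf(L = 1, sigma = 0.2)
  expect_equal(eye_radiance_ambient(lf, flat_gamm(Rnc = 0))$value,
               rep(0, 301))
  full <- eye_radiance_ambient(flat_lf(sigma = 1, shading = "weak"),
                               flat_gamm(Rnc = 1, Rcx = 1))
  expect_equal(full$value, lf$L_dw$value)    # perfect white in full light
  expect_equal(eye_radiance_ambient(lf, flat_gamm(Rnc = 0.05))$value,
               rep(0.01, 301))
  g_short <- gammarid_optics(0.0625, flat_spec(0.3, grid = 450:500),
                             flat_spec(0.05, grid = 450:500), 6,
                             flat_spec(0.05), flat_spec(0.6, "fraction"))
  expect_error(eye_radiance_ambient(lf, g_short), "grids")
})

test_that("spark increment follows the closed-form round-trip first leg", {
  lf <- flat_lf()
  g <- flat_gamm(Rcx = 0.3)
  off <- spark_model(0.16, flat_spec(0))
  expect_equal(spark_increment(lf, off, g, 20)$value, rep(0, 301))
  # flat chain: dL = Rcx * rho * Omega/pi, Omega = 2pi(1 - 20/sqrt(400.0256))
  sp <- spark_model(0.16, flat_spec(1.34))
  dl <- spark_increment(lf, sp, g, 20, point_receiver = TRUE)
  expect_equal(dl$value, rep(0.3 * 1.34 * 2.0105228e-4 / pi, 301),
               tolerance = 1e-7)
  # receiver-averaged default is within 0.1 % of the point value here
  dl2 <- spark_increment(lf, sp, g, 20)
  expect_equal(dl2$value, dl$value, tolerance = 1e-3)
  # single-leg inverse square in the far field
  r1 <- spark_increment(lf, sp, g, 30, point_receiver = TRUE)$value[1]
  r2 <- spark_increment(lf, sp, g, 60, point_receiver = TRUE)$value[1]
  expect_equal(r1 / r2, 4, tolerance = 1e-4)
  expect_error(spark_increment(lf, sp, g, 0), "distance")
})

test_that("pupil flux is linear in radiance and pupil area", {
  v <- viewer_optics(0.78)
  zero <- flux_at_pupil(flat_spec(0, "photon_radiance"), 0.0625, 10, v)
  expect_equal(zero$value, rep(0, 301))
  # at fixed target solid angle, flux is exactly linear in pupil area
  L <- flat_spec(2, "photon_radiance")
  f1 <- flux_at_pupil(L, 0.0625, 10, v, point_receiver = TRUE)
  f2 <- flux_at_pupil(L, 0.0625, 10, viewer_optics(0.78 * sqrt(2)),
                      point_receiver = TRUE)
  expect_equal(f2$value, 2 * f1$value, tolerance = 1e-9)
  expect_error(flux_at_pupil(L, 0.0625, -5, v), "distance")
})

test_that("round-trip increment flux at the pupil falls 16-fold per distance doubling", {
  lf <- flat_lf()
  g <- flat_gamm()
  sp <- spark_model(0.25, flat_spec(1.34))
  v <- viewer_optics()
  inc_flux <- function(d) {
    dl <- spark_increment(lf, sp, g, d, point_receiver = TRUE)
    sum(flux_at_pupil(dl, g$eye_radius_mm, d, v, point_receiver = TRUE)$value)
  }
  expect_equal(inc_flux(30) / inc_flux(60), 16, tolerance = 1e-3)
  # log-log slope of the increment flux vs distance is -4 on 30-45 mm,
  # with the extended pupil receiver engaged
  d <- 30:45
  phi <- vapply(d, function(di) {
    dl <- spark_increment(lf, sp, g, di)
    sum(flux_at_pupil(dl, g$eye_radius_mm, di, v)$value)
  }, numeric(1))
  slope <- coef(lm(log(phi) ~ log(d)))[[2]]
  expect_equal(slope, -4, tolerance = 0.01)
})

test_that("body radiance combines reflection and transmitted substrate light", {
  lf <- flat_lf(sigma = 0.2)
  sub <- flat_spec(0.1)
  opaque_black <- flat_gamm(Rbody = 0, Tbody = 0)
  expect_equal(body_radiance(lf, opaque_black, sub)$value, rep(0, 301))
  window <- flat_gamm(Rbody = 0, Tbody = 1)
  expect_equal(body_radiance(lf, window, sub)$value, rep(0.1, 301))
  g <- flat_gamm(Rbody = 0.05, Tbody = 0.6)
  # substrate lit by the shaded sidewelling field: 0.05*0.2 + 0.6*0.1*0.2
  expect_equal(body_radiance(lf, g, sub,
                             substrate_lighting = "sidewelling")$value,
               rep(0.022, 301))
  # default: substrate backing stays in downwelling light
  expect_equal(body_radiance(lf, g, sub)$value,
               rep(0.05 * 0.2 + 0.6 * 0.1, 301))
  sp <- spark_model(0.16, flat_spec(1.34))
  with_sp <- body_radiance(lf, g, sub, sp, 10, with_spark = TRUE)
  expect_true(all(with_sp$value > body_radiance(lf, g, sub)$value))
  expect_error(body_radiance(lf, g, sub, with_spark = TRUE), "spark")
})

test_that("all radiances and fluxes are elementwise linear in the ambient light", {
  g <- flat_gamm()
  sp <- spark_model(0.2, flat_spec(1.5))
  v <- viewer_optics()
  lf1 <- flat_lf(L = 1)
  lf2 <- flat_lf(L = 2)
  expect_equal(eye_radiance_ambient(lf2, g)$value,
               2 * eye_radiance_ambient(lf1, g)$value)
  expect_equal(spark_increment(lf2, sp, g, 15)$value,
               2 * spark_increment(lf1, sp, g, 15)$value)
  # with-spark flux dominates without-spark flux at every wavelength
  L0 <- eye_radiance_ambient(lf1, g)
  L1 <- photoloc:::spec_add(L0, spark_increment(lf1, sp, g, 15))
  f0 <- flux_at_pupil(L0, g$eye_radius_mm, 15, v)
  f1 <- flux_at_pupil(L1, g$eye_radius_mm, 15, v)
  expect_true(all(f1$value >= f0$value))
})
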