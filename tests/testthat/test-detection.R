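test_that("contrast curves decay with distance and vanish without a spark", {
  lf <- flat_lf()
  g <- flat_gamm()
  off <- spark_model(0.16, flat_spec(0))
  cc <- contrast_curve(lf, g, off, distances_mm = seq(5, 45, 10))
  expect_equal(cc$contrast, rep(0, 5))
  ccj <- contrast_curve(lf, g, off, distances_mm = seq(5, 45, 10),
                        channel = "chromatic")
  expect_equal(ccj$contrast, rep(0, 5))
  on <- spark_model(0.16, flat_spec(1.34))
  cc <- contrast_curve(lf, g, on)
  expect_true(all(diff(cc$contrast) < 0))
})

test_that("flat-spectrum Michelson curve equals dL / (2 L0 + dL)", {
  sigma <- 0.2; Rnc <- 0.05; Rcx <- 0.3; rho <- 1.34; r_spark <- 0.16
  lf <- flat_lf(sigma = sigma)
  g <- flat_gamm(Rcx = Rcx, Rnc = Rnc)
  sp <- spark_model(r_spark, flat_spec(rho))
  cc <- contrast_curve(lf, g, sp)
  d <- cc$distance_mm
  dl <- Rcx * rho * (2 * pi * (1 - d / sqrt(d^2 + r_spark^2))) / pi
  l0 <- Rnc * sigma
  expect_equal(cc$contrast, dl / (2 * l0 + dl), tolerance = 1e-3)
  # flat spark on flat ambient carries no chromatic signal at all
  ccj <- contrast_curve(lf, g, sp, visual = flat_vs(), channel = "chromatic")
  expect_equal(ccj$contrast, rep(0, 41), tolerance = 1e-9)
})

test_that("max detection distance is the far-end threshold crossing", {
  curve <- data.frame(distance_mm = 5:45, contrast = 0.5 / (5:45)^2)
  expect_identical(max_detection_distance(curve, 1), NA_real_)    # never
  expect_equal(max_detection_distance(curve, 1e-6), 45)           # cap
  expect_equal(max_detection_distance(curve, 0.5 / 30.5^2), 30)
  wobble <- data.frame(distance_mm = 1:5, contrast = c(5, 3, 4, 2, 1))
  expect_warning(res <- max_detection_distance(wobble, 3.5),
                 "non-increasing")
  expect_equal(res, 3)
})

test_that("a constructed flat scenario crosses threshold exactly between 20 and 21 mm", {
  lf <- flat_lf(sigma = 0.2)
  g <- flat_gamm()
  sp <- spark_model(0.16, flat_spec(1.34))
  cc <- contrast_curve(lf, g, sp)
  m <- function(d) {
    dl <- 0.3 * 1.34 * (2 * pi * (1 - d / sqrt(d^2 + 0.16^2))) / pi
    dl / (2 * 0.05 * 0.2 + dl)
  }
  thr <- sqrt(m(20) * m(21))    # closed form puts the crossing inside (20, 21)
  expect_equal(max_detection_distance(cc, thr), 20)
})

test_that("a degenerate 1x1x1x1 sweep reduces to a single scenario's distance", {
  cfg <- synth_config(seed = 2)
  inputs <- build_inputs(cfg)
  sc <- sweep_config(spark_radii_mm = 0.16, spark_radiance_means = 1.34,
                     ratios = 4.09, shadings = "average",
                     channels = "achromatic_optimistic", seed = 2)
  map <- run_sweep(sc, inputs)
  expect_equal(nrow(map), 1L)
  sp <- spark_model(0.16, photoloc:::scale_to_band_mean(inputs$spark_shape,
                                                        1.34))
  cc <- contrast_curve(inputs$light_fields$average,
                       inputs$gammarids[["4.09"]], sp,
                       inputs$viewer, inputs$visual)
  expect_equal(map$max_distance_mm, max_detection_distance(cc, 0.008))
})

test_that("detection maps are monotone in spark radiance and ordered across thresholds", {
  cfg <- synth_config(seed = 2)
  inputs <- build_inputs(cfg)
  sc <- sweep_config(spark_radii_mm = 0.16,
                     spark_radiance_means = c(0.63, 1.34, 2.09),
                     ratios = 4.09, shadings = c("weak", "average"),
                     channels = c("achromatic_optimistic",
                                  "achromatic_conservative"), seed = 2)
  map <- run_sweep(sc, inputs)
  for (sh in unique(map$shading)) for (ch in unique(map$channel)) {
    sub <- map[map$shading == sh & map$channel == ch, ]
    sub <- sub[order(sub$spark_radiance_mean), ]
    expect_true(all(diff(dist0(sub$max_distance_mm)) >= 0))
  }
  wide <- merge(map[map$channel == "achromatic_optimistic", ],
                map[map$channel == "achromatic_conservative", ],
                by = c("spark_radius_mm", "spark_radiance_mean", "ratio",
                       "shading"))
  expect_true(all(dist0(wide$max_distance_mm.x) >=
                    dist0(wide$max_distance_mm.y)))
  expect_error(sweep_config(shadings = character(0)), "at least one")
})

test_that("the gammarid body is not a viable photolocation target", {
  cfg <- synth_config(seed = 2)
  inputs <- build_inputs(cfg)
  sc <- sweep_config(spark_radii_mm = c(0.09, 0.25),
                     spark_radiance_means = c(0.63, 2.09),
                     channels = "achromatic_optimistic", seed = 2)
  body_map <- run_sweep(sc, inputs, target = "body")
  expect_true(all(is.na(body_map$max_distance_mm) |
                    body_map$max_distance_mm <= 5))
})
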