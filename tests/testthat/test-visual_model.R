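test_that("cone template peaks at lambda_max and matches an independent transcription", {
  for (lmax in c(468, 517, 530)) {
    s <- cone_template(lmax)
    expect_equal(max(s$value), 1)
    expect_equal(s$wl[which.max(s$value)], lmax)
  }
  s468 <- cone_template(468)
  expect_lt(s468$value[s468$wl == 700], s468$value[s468$wl == 500])
  # frozen oracle: independent numpy transcription of the two-band template
  s517 <- cone_template(517)
  expect_equal(s517$value[s517$wl == 480], 0.7392493, tolerance = 1e-6)
  expect_equal(s517$value[s517$wl == 517], 1.0, tolerance = 1e-6)
  expect_equal(s517$value[s517$wl == 560], 0.5680308, tolerance = 1e-6)
  expect_error(cone_template(300), "lambda_max")
  expect_error(cone_template(700), "lambda_max")
})

test_that("quantum catches integrate flux against ocular media and cone sensitivities", {
  vs <- flat_vs()
  zero <- quantum_catch(flat_spec(0, "photon_radiance"), vs)
  expect_equal(zero$q_single, 0)
  expect_equal(zero$q_double, 0)
  # flat flux, transparent media: catch equals the trapezoid of each cone
  # curve (computed here independently of the package's integrator)
  tr <- function(y) sum((y[-1] + y[-length(y)]) / 2)
  q <- quantum_catch(flat_spec(1, "photon_radiance"), vs)
  expect_equal(q$q_single, tr(vs$single$value), tolerance = 1e-12)
  expect_equal(q$q_double, tr(vs$double_members[[1]]$value) +
                 tr(vs$double_members[[2]]$value), tolerance = 1e-12)
  # linearity
  q2 <- quantum_catch(flat_spec(2, "photon_radiance"), vs)
  expect_equal(q2$q_single, 2 * q$q_single)
  expect_equal(q2$q_double, 2 * q$q_double)
  expect_error(quantum_catch(flat_spec(1, "energy_radiance"), vs),
               "photon")
})

test_that("chromatic JND follows the receptor-noise-limited closed form", {
  vs <- viewer_visual_system()      # weber 0.05, densities 1:4
  expect_equal(chromatic_jnd(make_qc(2, 3), make_qc(2, 3), vs), 0)
  # pure intensity change is invisible to the chromatic channel
  expect_equal(chromatic_jnd(make_qc(5, 8), make_qc(0.5, 0.8), vs), 0,
               tolerance = 1e-12)
  # q_s ratio 1.10, q_d ratio 1.00: |ln 1.1| / sqrt(0.1^2 + 0.05^2)
  expect_equal(chromatic_jnd(make_qc(1.10, 1), make_qc(1, 1), vs),
               0.8524802, tolerance = 1e-6)
  expect_error(chromatic_jnd(make_qc(0, 1), make_qc(1, 1), vs), "positive")
  # symmetric under swapping stimuli
  a <- make_qc(1.3, 0.9); b <- make_qc(1.1, 1.2)
  expect_equal(chromatic_jnd(a, b, vs), chromatic_jnd(b, a, vs))
})

test_that("Michelson contrast is bounded, zero at equality, antisymmetric", {
  expect_equal(michelson(make_qc(1, 2), make_qc(9, 2)), 0)
  expect_equal(michelson(make_qc(1, 1), make_qc(1, 0)), 1)
  expect_equal(michelson(make_qc(1, 1.05), make_qc(1, 1.00)), 0.0243902,
               tolerance = 1e-5)
  for (q in list(c(0.3, 0.7), c(2, 1e-4), c(5, 5))) {
    m <- michelson(make_qc(1, q[1]), make_qc(1, q[2]))
    expect_gte(m, -1); expect_lte(m, 1)
    expect_equal(michelson(make_qc(1, q[2]), make_qc(1, q[1])), -m)
  }
  expect_error(michelson(make_qc(1, 0), make_qc(1, 0)), "zero")
})

test_that("contrasts are invariant to uniform rescaling of both stimuli", {
  vs <- viewer_visual_system()
  cfg <- synth_config(seed = 5)
  lf <- photoloc:::as_photon_light_field(generate_light_field(cfg,
                                                              shading = "average"))
  g <- generate_gammarid(cfg)
  sp <- generate_spark(cfg)
  L0 <- eye_radiance_ambient(lf, g)
  L1 <- photoloc:::spec_add(L0, spark_increment(lf, sp, g, 10))
  base_j <- base_m <- NULL
  for (k in c(1e-2, 1, 1e2)) {
    q0 <- quantum_catch(spectrum(L0$wl, k * L0$value, L0$unit), vs)
    q1 <- quantum_catch(spectrum(L1$wl, k * L1$value, L1$unit), vs)
    j <- chromatic_jnd(q1, q0, vs); m <- michelson(q1, q0)
    if (is.null(base_j)) { base_j <- j; base_m <- m }
    expect_equal(j, base_j, tolerance = 1e-9)
    expect_equal(m, base_m, tolerance = 1e-9)
  }
  expect_gt(base_m, 0)    # the spark increment raises the achromatic catch
})
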