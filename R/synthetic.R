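#' Configuration for the synthetic input generator
#'
#' Defines the seeded emulation of every measured input the pipeline
#' needs. Summary statistics that were reported from the measurements are
#' used as generator constraints: spark relative radiance peaking at 472 nm
#' at 2.15 with a 400--700 nm band mean of 1.34 (range 0.63--2.09),
#' coaxial:non-coaxial eye-reflectance ratio categories 2.68 / 4.09 / 9.87,
#' gammarid eye radius 0.0625 mm, and the 10 m downwelling profile as the
#' fixed light field. Sidewelling and shading fractions were measured but
#' never reported as numbers, so the defaults (band-mean
#' sidewelling:downwelling 0.20 unshaded, then 0.08 / 0.03 / 0.01 for
#' weak / average / strong shade) are free parameters of the emulation,
#' chosen to be plausible for complex rocky substrate and documented as
#' non-measured.
#'
#' @param seed Integer seed; every generated spectrum is a deterministic
#'   function of it.
#' @param depth_m Depth of the emulated light field (m).
#' @param surface_spectrum_shape `"daylight_like"` (broad smooth maximum
#'   near 560 nm) or `"flat"`.
#' @param attenuation_m1 Diffuse attenuation K (m^-1): a scalar for a flat
#'   profile or a vector on the canonical grid. Default is a coastal-water
#'   profile rising monotonically from 0.08 at 400 nm to 0.60 at 700 nm.
#' @param sidewelling_fraction Band-mean sidewelling:downwelling ratio for
#'   unshaded conditions.
#' @param shading_fractions Named vector `c(weak=, average=, strong=)`,
#'   each below `sidewelling_fraction`, strictly decreasing.
#' @param spark_peak_nm,spark_peak_rel,spark_band_mean Spark constraints.
#' @param spark_radius_mm Spark radius equivalent (mm).
#' @param eye_ratio Coaxial:non-coaxial band-mean reflectance ratio.
#' @param eye_noncoaxial_level Band-mean non-coaxial eye reflectance.
#' @param eye_radius_mm Gammarid eye radius (mm).
#' @param body_reflectance_level,body_transmittance_level Band means of the
#'   gammarid body spectra.
#' @return Validated list of class `"synth_config"`.
#' @export
synth_config <- function(seed = 1L, depth_m = 10,
                         surface_spectrum_shape = c("daylight_like", "flat"),
                         attenuation_m1 = NULL,
                         sidewelling_fraction = 0.20,
                         shading_fractions = c(weak = 0.08, average = 0.03,
                                               strong = 0.01),
                         spark_peak_nm = 472, spark_peak_rel = 2.15,
                         spark_band_mean = 1.34, spark_radius_mm = 0.16,
                         eye_ratio = 4.09, eye_noncoaxial_level = 0.04,
                         eye_radius_mm = 0.0625,
                         body_reflectance_level = 0.05,
                         body_transmittance_level = 0.6) {
  surface_spectrum_shape <- match.arg(surface_spectrum_shape)
  grid <- canonical_grid()
  if (is.null(attenuation_m1))
    attenuation_m1 <- 0.08 + 0.52 * ((grid - 400) / 300)^2
  if (length(attenuation_m1) == 1L)
    attenuation_m1 <- rep(attenuation_m1, length(grid))
  if (length(attenuation_m1) != length(grid) || any(attenuation_m1 <= 0))
    stop("attenuation must be positive, scalar or on the canonical grid",
         call. = FALSE)
  if (!all(c("weak", "average", "strong") %in% names(shading_fractions)))
    stop("shading_fractions needs 'weak', 'average', 'strong'",
         call. = FALSE)
  sf <- shading_fractions[c("weak", "average", "strong")]
  if (!(sidewelling_fraction > sf[["weak"]] && sf[["weak"]] > sf[["average"]] &&
        sf[["average"]] > sf[["strong"]] && sf[["strong"]] > 0))
    stop("shading fractions must satisfy none > weak > average > strong > 0",
         call. = FALSE)
  if (eye_ratio <= 1)
    stop("eye_ratio must exceed 1 (coaxial reflectance is the stronger one)",
         call. = FALSE)
  if (spark_band_mean <= 0 || spark_band_mean >= spark_peak_rel)
    stop("spark_band_mean must lie in (0, spark_peak_rel)", call. = FALSE)
  structure(list(seed = as.integer(seed), depth_m = depth_m,
                 surface_spectrum_shape = surface_spectrum_shape,
                 attenuation_m1 = attenuation_m1,
                 sidewelling_fraction = sidewelling_fraction,
                 shading_fractions = sf,
                 spark_peak_nm = spark_peak_nm,
                 spark_peak_rel = spark_peak_rel,
                 spark_band_mean = spark_band_mean,
                 spark_radius_mm = spark_radius_mm,
                 eye_ratio = eye_ratio,
                 eye_noncoaxial_level = eye_noncoaxial_level,
                 eye_radius_mm = eye_radius_mm,
                 body_reflectance_level = body_reflectance_level,
                 body_transmittance_level = body_transmittance_level,
                 grid = grid),
            class = "synth_config")
}

# Surface (just-below-surface) downwelling radiance proxy, energy scale.
surface_spectrum <- function(cfg) {
  grid <- cfg$grid
  v <- if (cfg$surface_spectrum_shape == "flat") rep(1, length(grid))
       else 1 - 0.25 * ((grid - 560) / 160)^2
  spectrum(grid, pmax(v, 0.05), "energy_radiance")
}

#' Generate an ambient light-field scenario
#'
#' Beer-Lambert attenuation of the surface spectrum,
#' `L_dw(lambda, z) = L_surface(lambda) * exp(-K(lambda) z)`, with
#' sidewelling and shaded-sidewelling fields expressed as flat fractions of
#' downwelling light (the shading categories). Deterministic given the
#' config.
#'
#' @param cfg A [synth_config()].
#' @param depth_m Depth (m), >= 0; defaults to `cfg$depth_m`.
#' @param shading Shading category of the prey's micro-habitat.
#' @return A [light_field_scenario()] on the canonical grid (energy units).
#' @export
generate_light_field <- function(cfg, depth_m = cfg$depth_m,
                                 shading = c("none", "weak", "average",
                                             "strong")) {
  stopifnot(inherits(cfg, "synth_config"))
  shading <- match.arg(shading)
  if (depth_m < 0) stop("depth must be >= 0", call. = FALSE)
  surf <- surface_spectrum(cfg)
  L_dw <- spectrum(cfg$grid, surf$value * exp(-cfg$attenuation_m1 * depth_m),
                   "energy_radiance")
  L_sw <- spectrum(cfg$grid, L_dw$value * cfg$sidewelling_fraction,
                   "energy_radiance")
  frac <- if (shading == "none") cfg$sidewelling_fraction
          else cfg$shading_fractions[[shading]]
  sigma <- spectrum(cfg$grid, rep(frac, length(cfg$grid)), "fraction")
  light_field_scenario(depth_m, L_dw, L_sw, shading, sigma)
}

#' Generate an ocular-spark model
#'
#' Builds a unimodal relative-radiance spectrum: a Gaussian bump centred at
#' `spark_peak_nm` with peak value `spark_peak_rel` on a flat pedestal,
#' with the pedestal (or, when the requested band mean is too low for any
#' pedestal, the bump width) solved analytically so the 400--700 nm band
#' mean equals `spark_band_mean` exactly.
#'
#' @param cfg A [synth_config()].
#' @param band_mean_target Override for the band mean (the swept axis).
#' @param radius_mm Override for the spark radius.
#' @return A [spark_model()].
#' @export
generate_spark <- function(cfg, band_mean_target = cfg$spark_band_mean,
                           radius_mm = cfg$spark_radius_mm) {
  stopifnot(inherits(cfg, "synth_config"))
  peak <- cfg$spark_peak_rel
  if (band_mean_target <= 0 || band_mean_target >= peak)
    stop("spark band mean must lie strictly between 0 and the peak value (",
         peak, ")", call. = FALSE)
  grid <- cfg$grid
  bump_mean <- function(w) {
    g <- exp(-(grid - cfg$spark_peak_nm)^2 / (2 * w^2))
    band_mean(spectrum(grid, g, "relative"), 400, 700)
  }
  w0 <- 60
  m <- bump_mean(w0)
  pedestal <- (band_mean_target - peak * m) / (1 - m)
  if (pedestal >= 0) {
    w <- w0
  } else {
    # narrow the bump until the pedestal-free curve hits the target mean
    pedestal <- 0
    w <- stats::uniroot(function(w) peak * bump_mean(w) - band_mean_target,
                        c(1, w0), tol = 1e-12)$root
  }
  g <- exp(-(grid - cfg$spark_peak_nm)^2 / (2 * w^2))
  rho <- spectrum(grid, pedestal + (peak - pedestal) * g, "relative")
  spark_model(radius_mm, rho)
}

# Seeded smooth positive spectrum with an exact band mean: a gentle tilt
# plus low-amplitude random-phase sinusoids, renormalised.
smooth_random_spectrum <- function(cfg, level, seed_offset, tilt = 0.3,
                                   wiggle = 0.05, unit = "relative") {
  grid <- cfg$grid
  u <- (grid - 400) / 300
  ph <- with_local_seed(cfg$seed + seed_offset, stats::runif(3, 0, 2 * pi))
  v <- 1 + tilt * (u - 0.5)
  for (k in 1:3) v <- v + wiggle / k * sin(2 * pi * k * u + ph[k])
  v <- pmax(v, 0.05)
  s <- spectrum(grid, v, "relative")
  spectrum(grid, v * level / band_mean(s, 400, 700), unit)
}

#' Generate gammarid optics
#'
#' Smooth, low-amplitude reflectance and transmittance spectra with exact
#' configured band means. Coaxial eye reflectance is the non-coaxial
#' spectrum scaled by `eye_ratio`, so the band-mean ratio is exact by
#' construction (the measured directionality enters the model only through
#' this ratio).
#'
#' @param cfg A [synth_config()].
#' @param eye_ratio Override for the coaxial:non-coaxial ratio.
#' @return A [gammarid_optics()].
#' @export
generate_gammarid <- function(cfg, eye_ratio = cfg$eye_ratio) {
  stopifnot(inherits(cfg, "synth_config"))
  if (eye_ratio <= 1)
    stop("eye_ratio must exceed 1", call. = FALSE)
  R_nc <- smooth_random_spectrum(cfg, cfg$eye_noncoaxial_level, 101L)
  R_cx <- spectrum(R_nc$wl, R_nc$value * eye_ratio, "relative")
  R_body <- smooth_random_spectrum(cfg, cfg$body_reflectance_level, 202L)
  T_body <- if (cfg$body_transmittance_level == 0)
    spectrum(cfg$grid, rep(0, length(cfg$grid)), "fraction")
  else
    smooth_random_spectrum(cfg, cfg$body_transmittance_level, 303L,
                           tilt = 0.1, wiggle = 0.02, unit = "fraction")
  gammarid_optics(cfg$eye_radius_mm, R_cx, R_nc, eye_ratio, R_body, T_body)
}

#' Generate a brown-algae-like substrate reflectance
#'
#' Low reflectance through 400--500 nm rising logistically toward 600 nm,
#' the qualitative shape of brown macroalgae such as the *Halopteris*
#' foraging substrate.
#'
#' @param cfg A [synth_config()].
#' @return Reflectance [spectrum()] (unit `relative`).
#' @export
generate_substrate <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  grid <- cfg$grid
  v <- 0.02 + 0.10 / (1 + exp(-(grid - 560) / 30))
  spectrum(grid, v, "relative")
}

#' Assemble the full synthetic input bundle for a sweep
#'
#' Generates, from one seed, every input [run_sweep()] needs: one light
#' field per shading category, one gammarid-optics set per reflectance
#' ratio, the reference spark spectrum, the substrate, and default viewer
#' optics and visual system.
#'
#' @param cfg A [synth_config()].
#' @return List with elements `light_fields`, `gammarids`, `spark_shape`,
#'   `substrate`, `viewer`, `visual`, and `config`.
#' @export
build_inputs <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  shadings <- c("none", "weak", "average", "strong")
  lfs <- lapply(shadings, function(sh) generate_light_field(cfg, shading = sh))
  names(lfs) <- shadings
  ratios <- c(2.68, 4.09, 9.87)
  gs <- lapply(ratios, function(r) generate_gammarid(cfg, eye_ratio = r))
  names(gs) <- as.character(ratios)
  list(light_fields = lfs, gammarids = gs,
       spark_shape = generate_spark(cfg)$rho,
       substrate = generate_substrate(cfg),
       viewer = viewer_optics(),
       visual = viewer_visual_system(),
       config = cfg)
}

#' Write a complete CSV fixture set
#'
#' Exports every generated spectrum as `wavelength_nm,value` CSV plus a
#' YAML manifest echoing the seed and configuration, so a pipeline run can
#' be reproduced from files alone.
#'
#' @param cfg A [synth_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
generate_fixture_set <- function(cfg, dir) {
  stopifnot(inherits(cfg, "synth_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- build_inputs(cfg)
  wr <- function(s, name) write_spectrum_csv(s, file.path(dir, name))
  for (sh in names(inputs$light_fields)) {
    lf <- inputs$light_fields[[sh]]
    wr(lf$sigma, paste0("sigma_", sh, ".csv"))
  }
  lf0 <- inputs$light_fields[["none"]]
  wr(lf0$L_dw, "downwelling.csv")
  wr(lf0$L_sw_unshaded, "sidewelling_unshaded.csv")
  g <- inputs$gammarids[[as.character(cfg$eye_ratio)]]
  if (is.null(g)) g <- generate_gammarid(cfg)
  wr(g$R_cx, "eye_reflectance_coaxial.csv")
  wr(g$R_nc, "eye_reflectance_noncoaxial.csv")
  wr(g$R_body, "body_reflectance.csv")
  wr(g$T_body, "body_transmittance.csv")
  wr(inputs$spark_shape, "spark_relative_radiance.csv")
  wr(inputs$substrate, "substrate_reflectance.csv")
  wr(inputs$visual$T_om, "ocular_media_transmission.csv")
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(
    generator = "photoloc synthetic fixture set (emulated spectra)",
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), c("grid", "attenuation_m1"))],
    attenuation_m1_range = range(cfg$attenuation_m1),
    files = list.files(dir, pattern = "\\.csv$")), manifest)
  invisible(manifest)
}
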