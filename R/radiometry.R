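#' Ambient light-field scenario
#'
#' Bundles the white-standard radiance proxies that define the ambient light
#' around predator and prey at one depth: downwelling radiance `L_dw`, the
#' unshaded sidewelling radiance, and the effective sidewelling-to-
#' downwelling ratio `sigma` for the prey's shading category. The predator
#' is always assumed fully exposed to downwelling light; only the prey is
#' shaded.
#'
#' @param depth_m Depth in metres.
#' @param L_dw Downwelling radiance proxy ([spectrum()], energy or photon
#'   units).
#' @param L_sw_unshaded Unshaded sidewelling radiance proxy, same grid and
#'   unit.
#' @param shading One of `"none"`, `"weak"`, `"average"`, `"strong"`.
#' @param sigma Effective sidewelling/downwelling ratio for the chosen
#'   shading ([spectrum()], unit `fraction`, values in (0, 1]). For
#'   `shading = "none"` this must equal `L_sw_unshaded / L_dw` elementwise.
#' @return An object of class `"light_field_scenario"`.
#' @export
light_field_scenario <- function(depth_m, L_dw, L_sw_unshaded, shading, sigma) {
  shading <- match.arg(shading, c("none", "weak", "average", "strong"))
  stopifnot(is_spectrum(L_dw), is_spectrum(L_sw_unshaded), is_spectrum(sigma))
  check_same_grid(L_dw, L_sw_unshaded)
  check_same_grid(L_dw, sigma)
  if (sigma$unit != "fraction")
    stop("sigma must have unit 'fraction'", call. = FALSE)
  if (any(sigma$value <= 0))
    stop("sigma must be strictly positive", call. = FALSE)
  if (shading == "none") {
    implied <- L_sw_unshaded$value / L_dw$value
    if (max(abs(sigma$value - implied)) > 1e-9)
      stop("for shading = 'none', sigma must equal L_sw_unshaded / L_dw",
           call. = FALSE)
  }
  structure(list(depth_m = depth_m, L_dw = L_dw,
                 L_sw_unshaded = L_sw_unshaded,
                 shading = shading, sigma = sigma),
            class = "light_field_scenario")
}

#' Ocular spark model
#'
#' The emitter: a disc of radius `radius_mm` on the predator's iris whose
#' radiance, relative to a diffuse white standard in the same downwelling
#' light, is the spectrum `rho`. Measured sparks have band-mean relative
#' radiance 0.63--2.09 (mean 1.34) and radius equivalents 0.09--0.25 mm.
#'
#' @param radius_mm Spark disc radius (mm), in \[0.09, 0.25\] for the
#'   empirical range.
#' @param rho Relative radiance [spectrum()] (unit `relative`; band mean may
#'   exceed 1 -- the spark is brighter than a white standard).
#' @return An object of class `"spark_model"`.
#' @export
spark_model <- function(radius_mm, rho) {
  stopifnot(is_spectrum(rho))
  if (radius_mm <= 0) stop("spark radius must be > 0", call. = FALSE)
  if (rho$unit != "relative")
    stop("spark rho must have unit 'relative'", call. = FALSE)
  structure(list(radius_mm = radius_mm, rho = rho), class = "spark_model")
}

#' Optical properties of the gammarid target
#'
#' The prey-side optics: eye radius, coaxial (epi-illuminated) and
#' non-coaxial (45 degree) relative eye reflectance, and body reflectance
#' and transmittance. Gammarid inter-ommatidial reflectors are strongly
#' directional: coaxial reflectance exceeds non-coaxial by a factor of
#' 2.68--9.87 (mean 4.09).
#'
#' @param eye_radius_mm Eye radius (mm); empirical mean 0.0625.
#' @param R_cx Coaxial relative reflectance [spectrum()].
#' @param R_nc Non-coaxial relative reflectance [spectrum()]; must not
#'   exceed `R_cx` anywhere.
#' @param ratio Band-level coaxial:non-coaxial factor carried for reporting
#'   (one of 2.68, 4.09, 9.87 in the empirical categories).
#' @param R_body Body relative reflectance [spectrum()].
#' @param T_body Body transmittance [spectrum()], unit `fraction`.
#' @return An object of class `"gammarid_optics"`.
#' @export
gammarid_optics <- function(eye_radius_mm = 0.0625, R_cx, R_nc, ratio,
                            R_body, T_body) {
  stopifnot(is_spectrum(R_cx), is_spectrum(R_nc),
            is_spectrum(R_body), is_spectrum(T_body))
  if (eye_radius_mm <= 0) stop("eye radius must be > 0", call. = FALSE)
  check_same_grid(R_cx, R_nc)
  if (any(R_cx$value < R_nc$value - 1e-12))
    stop("coaxial reflectance must be >= non-coaxial at every wavelength",
         call. = FALSE)
  if (T_body$unit != "fraction")
    stop("T_body must have unit 'fraction'", call. = FALSE)
  structure(list(eye_radius_mm = eye_radius_mm, R_cx = R_cx, R_nc = R_nc,
                 ratio = ratio, R_body = R_body, T_body = T_body),
            class = "gammarid_optics")
}

#' Viewer receiving optics
#'
#' @param pupil_radius_mm Pupil radius (mm); the triplefin mean is 0.78.
#' @return Object of class `"viewer_optics"` with the derived pupil area
#'   (mm^2).
#' @export
viewer_optics <- function(pupil_radius_mm = 0.78) {
  if (pupil_radius_mm <= 0) stop("pupil radius must be > 0", call. = FALSE)
  structure(list(pupil_radius_mm = pupil_radius_mm,
                 pupil_area_mm2 = pi * pupil_radius_mm^2),
            class = "viewer_optics")
}

#' Ambient radiance of the prey eye (spark off)
#'
#' Without the spark the gammarid eye is lit by the sidewelling light of its
#' (possibly shaded) micro-habitat and reflects it non-coaxially:
#' `L_eye0 = R_nc * sigma * L_dw`. Independent of viewing distance.
#'
#' @param lf A [light_field_scenario()].
#' @param g A [gammarid_optics()].
#' @return Radiance [spectrum()] in the unit of `lf$L_dw`.
#' @export
eye_radiance_ambient <- function(lf, g) {
  stopifnot(inherits(lf, "light_field_scenario"),
            inherits(g, "gammarid_optics"))
  spec_product(g$R_nc, lf$sigma, lf$L_dw, unit = lf$L_dw$unit)
}

#' Spark-induced radiance increment of the prey eye
#'
#' First leg of the round trip. The spark radiates
#' `L_spark = rho * L_dw` (relative radiance times the white-standard
#' proxy); at distance `d_mm` it delivers irradiance
#' `E = L_spark * Omega_spark(d)` onto the prey eye, where `Omega_spark` is
#' the solid angle of the spark disc seen from the eye. Dividing by pi
#' converts that irradiance to the white-standard-equivalent radiance scale
#' on which the coaxial reflectance `R_cx` is defined (a Lambertian white
#' standard under irradiance E has radiance E/pi), so
#' `dL = R_cx * rho * L_dw * Omega_spark(d) / pi`.
#'
#' @param lf A [light_field_scenario()].
#' @param spark A [spark_model()].
#' @param g A [gammarid_optics()] (supplies `R_cx` and the receiver radius
#'   for the solid angle).
#' @param d_mm Spark-to-prey distance (mm), > 0.
#' @param point_receiver If `TRUE`, treat the prey eye as a point when
#'   computing the spark solid angle (receiver-averaging is negligible for
#'   the 0.0625 mm eye but is on by default for fidelity).
#' @return Radiance increment [spectrum()] in the unit of `lf$L_dw`.
#' @export
spark_increment <- function(lf, spark, g, d_mm, point_receiver = FALSE) {
  stopifnot(inherits(lf, "light_field_scenario"),
            inherits(spark, "spark_model"),
            inherits(g, "gammarid_optics"))
  if (d_mm <= 0) stop("distance must be > 0", call. = FALSE)
  recv <- if (point_receiver) 0 else g$eye_radius_mm
  omega <- solid_angle_cached(spark$radius_mm, d_mm, recv)
  spec_product(g$R_cx, spark$rho, lf$L_dw, omega / pi, unit = lf$L_dw$unit)
}

#' Spectral photon (or energy) flux entering the viewer's pupil
#'
#' Second leg: a target of radius `target_radius_mm` with radiance
#' `L_target` subtends solid angle `Omega_target(d)` at the viewer, and the
#' pupil of area `A` collects `Phi = L_target * Omega_target(d) * A` per
#' nm. Units follow the input radiance (photons/s/nm for photon radiance;
#' distances in mm, pupil area in mm^2, so the absolute scale is
#' arbitrary-but-consistent -- all contrasts are scale-invariant).
#'
#' @param L_target Radiance [spectrum()].
#' @param target_radius_mm Radius of the emitting disc (mm).
#' @param d_mm Target-to-pupil distance (mm), > 0.
#' @param v A [viewer_optics()].
#' @param point_receiver If `TRUE`, treat the pupil as a point receiver.
#' @return Flux [spectrum()] (unit tag inherited from `L_target`).
#' @export
flux_at_pupil <- function(L_target, target_radius_mm, d_mm, v,
                          point_receiver = FALSE) {
  stopifnot(is_spectrum(L_target), inherits(v, "viewer_optics"))
  if (d_mm <= 0) stop("distance must be > 0", call. = FALSE)
  recv <- if (point_receiver) 0 else v$pupil_radius_mm
  omega <- solid_angle_cached(target_radius_mm, d_mm, recv)
  spec_product(L_target, omega * v$pupil_area_mm2, unit = L_target$unit)
}

#' Radiance of the gammarid body (negative control)
#'
#' The translucent body both reflects the ambient sidewelling field and
#' transmits the radiance of the substrate behind it. With the default
#' `substrate_lighting = "downwelling"`,
#' `L_body = R_body * sigma * L_dw + T_body * R_substrate * L_dw`:
#' shading dims the horizontal light field that the body surface (and the
#' eye's reflectors) return, but the substrate backing the body stays lit
#' by downwelling light, so the translucent body remains bright in shade.
#' This asymmetry is what makes the dark, directionally reflective eye --
#' and not the body -- the high-contrast target for the spark.
#' `substrate_lighting = "sidewelling"` instead applies `sigma` to the
#' transmitted term as well. With `with_spark = TRUE` the spark increment
#' is added with `R_body` playing the coaxial-reflector role -- the
#' control asks whether the spark also lights up the body, which would
#' spoil the eye-specific cue.
#'
#' @param lf A [light_field_scenario()].
#' @param g A [gammarid_optics()].
#' @param substrate_R Substrate relative reflectance [spectrum()].
#' @param spark A [spark_model()] (used only if `with_spark`).
#' @param d_mm Distance (mm); used only if `with_spark`.
#' @param with_spark Add the spark-induced increment?
#' @param substrate_lighting Light field illuminating the substrate seen
#'   through the body: `"downwelling"` (default) or `"sidewelling"`.
#' @return Radiance [spectrum()] in the unit of `lf$L_dw`.
#' @export
body_radiance <- function(lf, g, substrate_R, spark = NULL, d_mm = NULL,
                          with_spark = FALSE,
                          substrate_lighting = c("downwelling",
                                                 "sidewelling")) {
  stopifnot(inherits(lf, "light_field_scenario"),
            inherits(g, "gammarid_optics"), is_spectrum(substrate_R))
  substrate_lighting <- match.arg(substrate_lighting)
  refl <- spec_product(g$R_body, lf$sigma, lf$L_dw, unit = lf$L_dw$unit)
  trans <- if (substrate_lighting == "downwelling")
    spec_product(g$T_body, substrate_R, lf$L_dw, unit = lf$L_dw$unit)
  else
    spec_product(g$T_body, substrate_R, lf$sigma, lf$L_dw,
                 unit = lf$L_dw$unit)
  out <- spec_add(refl, trans)
  if (with_spark) {
    if (is.null(spark) || is.null(d_mm))
      stop("with_spark = TRUE needs 'spark' and 'd_mm'", call. = FALSE)
    if (d_mm <= 0) stop("distance must be > 0", call. = FALSE)
    omega <- solid_angle_cached(spark$radius_mm, d_mm, g$eye_radius_mm)
    inc <- spec_product(g$R_body, spark$rho, lf$L_dw, omega / pi,
                        unit = lf$L_dw$unit)
    out <- spec_add(out, inc)
  }
  out
}
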