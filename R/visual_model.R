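#' Vertebrate A1 photoreceptor sensitivity template
#'
#' Spectral sensitivity of a vitamin-A1 visual pigment with peak absorbance
#' at `lambda_max_nm`, built from the standard two-band vertebrate template:
#' an alpha band `1 / (exp(A(a - x)) + exp(B(b - x)) + exp(C(c - x)) + D)`
#' with `x = lambda_max / lambda`, `A = 69.7`, `B = 28`, `C = -14.9`,
#' `D = 0.674`, `b = 0.922`, `c = 1.104`,
#' `a = 0.8795 + 0.0459 exp(-(lambda_max - 300)^2 / 11940)`, plus a beta
#' band `0.26 exp(-((lambda - m) / w)^2)` with `m = 189 + 0.315 lambda_max`
#' and `w = -40.5 + 0.195 lambda_max`. The sum is renormalised so the
#' maximum on the grid is exactly 1.
#'
#' @param lambda_max_nm Peak wavelength (nm), in \[400, 650\].
#' @param grid Wavelength grid (nm); defaults to [canonical_grid()].
#' @return Peak-normalised sensitivity [spectrum()] (unit `relative`).
#' @examples
#' s <- cone_template(468)
#' s$value[s$wl == 468]  # 1 at the peak
#' @export
cone_template <- function(lambda_max_nm, grid = canonical_grid()) {
  if (lambda_max_nm < 400 || lambda_max_nm > 650)
    stop("lambda_max must be within [400, 650] nm", call. = FALSE)
  x <- lambda_max_nm / grid
  a <- 0.8795 + 0.0459 * exp(-(lambda_max_nm - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                  exp(-14.9 * (1.104 - x)) + 0.674)
  m <- 189 + 0.315 * lambda_max_nm
  w <- -40.5 + 0.195 * lambda_max_nm
  beta <- 0.26 * exp(-((grid - m) / w)^2)
  s <- alpha + beta
  spectrum(grid, s / max(s), "relative")
}

#' Synthetic ocular-media transmission
#'
#' A smooth logistic short-wavelength cut-on (centre 410 nm, scale 8 nm,
#' plateau 1) used as the default stand-in for a measured species curve;
#' replace via the `T_om` argument of [viewer_visual_system()] or a CSV
#' spectrum.
#'
#' @param grid Wavelength grid (nm).
#' @param centre_nm,scale_nm Logistic midpoint and scale.
#' @return Transmission [spectrum()] (unit `fraction`).
#' @export
ocular_media_default <- function(grid = canonical_grid(), centre_nm = 410,
                                 scale_nm = 8) {
  spectrum(grid, 1 / (1 + exp(-(grid - centre_nm) / scale_nm)), "fraction")
}

#' The viewer's visual system
#'
#' Cone set, ocular media, and noise/threshold parameters of the receiving
#' fish. Defaults are the triplefin values: single cone peaking at 468 nm,
#' double cone with members at 517 and 530 nm, single:double density 1:4,
#' Weber fraction 0.05 on the most abundant (double) channel, chromatic
#' threshold 1 JND, and Michelson achromatic thresholds 0.008 (optimistic,
#' behaviourally measured) and 0.024 (conservative, three times larger and
#' typical of other teleosts).
#'
#' @param single_peak_nm Single-cone peak (nm).
#' @param double_peaks_nm Two double-cone member peaks (nm).
#' @param T_om Ocular-media transmission [spectrum()] (unit `fraction`);
#'   default [ocular_media_default()].
#' @param density_single,density_double Relative cone densities (1 and 4).
#' @param weber Weber fraction of the double-cone channel.
#' @param jnd_threshold Chromatic detection threshold in JND.
#' @param michelson_thresholds Named numeric
#'   `c(optimistic = 0.008, conservative = 0.024)`; must be ordered
#'   optimistic < conservative.
#' @param grid Wavelength grid (nm).
#' @return Object of class `"viewer_visual_system"` with cone sensitivity
#'   spectra on `grid`.
#' @export
viewer_visual_system <- function(single_peak_nm = 468,
                                 double_peaks_nm = c(517, 530),
                                 T_om = NULL,
                                 density_single = 1, density_double = 4,
                                 weber = 0.05, jnd_threshold = 1,
                                 michelson_thresholds = c(optimistic = 0.008,
                                                          conservative = 0.024),
                                 grid = canonical_grid()) {
  if (is.null(T_om)) T_om <- ocular_media_default(grid)
  stopifnot(is_spectrum(T_om), length(double_peaks_nm) == 2L)
  if (weber <= 0) stop("weber fraction must be > 0", call. = FALSE)
  if (density_single <= 0 || density_double <= 0)
    stop("cone densities must be > 0", call. = FALSE)
  if (!all(c("optimistic", "conservative") %in% names(michelson_thresholds)))
    stop("michelson_thresholds needs 'optimistic' and 'conservative'",
         call. = FALSE)
  if (michelson_thresholds[["optimistic"]] >=
        michelson_thresholds[["conservative"]])
    stop("optimistic threshold must be below the conservative one",
         call. = FALSE)
  T_om <- resample(T_om, grid)
  structure(list(
    single = cone_template(single_peak_nm, grid),
    double_members = lapply(double_peaks_nm, cone_template, grid = grid),
    single_peak_nm = single_peak_nm, double_peaks_nm = double_peaks_nm,
    T_om = T_om,
    density_single = density_single, density_double = density_double,
    weber = weber, jnd_threshold = jnd_threshold,
    michelson_thresholds = michelson_thresholds,
    grid = grid), class = "viewer_visual_system")
}

#' Quantum catches of the viewer's cone channels
#'
#' Integrates the photon flux against ocular-media transmission and each
#' cone sensitivity (trapezoid on the grid):
#' `q_i = integral Phi(lambda) T_om(lambda) S_i(lambda) dlambda`. The
#' double-cone catch is the sum over both members (the achromatic channel
#' pools them; for Michelson contrast sum vs mean is immaterial).
#'
#' @param flux Photon-flux [spectrum()]; must carry the photon unit tag --
#'   convert energy-scale spectra with [to_photon_units()] first.
#' @param vs A [viewer_visual_system()].
#' @return List of class `"quantum_catches"` with `q_single` and `q_double`.
#' @export
quantum_catch <- function(flux, vs) {
  stopifnot(is_spectrum(flux), inherits(vs, "viewer_visual_system"))
  if (flux$unit != "photon_radiance")
    stop("quantum_catch() needs photon-unit flux; use to_photon_units()",
         call. = FALSE)
  check_same_grid(flux, vs$T_om)
  base <- flux$value * vs$T_om$value
  q_s <- trapz(flux$wl, base * vs$single$value)
  q_d <- sum(vapply(vs$double_members,
                    function(m) trapz(flux$wl, base * m$value), numeric(1)))
  structure(list(q_single = q_s, q_double = q_d), class = "quantum_catches")
}

#' Receptor-noise-limited chromatic distance
#'
#' Dichromatic RNL model with log receptor signals: for each channel
#' `df_i = ln(q_i(c1) / q_i(c2))`; channel noise follows the density rule
#' with the Weber fraction anchored on the abundant double-cone channel,
#' `e_double = weber`, `e_single = weber * sqrt(density_double /
#' density_single)`; the chromatic distance is
#' `|df_single - df_double| / sqrt(e_single^2 + e_double^2)` in JND.
#' Intensity-invariant: scaling both stimuli equally changes nothing.
#'
#' @param c1,c2 [quantum_catch()] results; all catches must be > 0.
#' @param vs A [viewer_visual_system()].
#' @return Chromatic distance in JND (>= 0).
#' @export
chromatic_jnd <- function(c1, c2, vs) {
  stopifnot(inherits(c1, "quantum_catches"), inherits(c2, "quantum_catches"),
            inherits(vs, "viewer_visual_system"))
  qs <- c(c1$q_single, c2$q_single, c1$q_double, c2$q_double)
  if (any(qs <= 0))
    stop("chromatic_jnd needs strictly positive quantum catches",
         call. = FALSE)
  df_s <- log(c1$q_single / c2$q_single)
  df_d <- log(c1$q_double / c2$q_double)
  e_d <- vs$weber
  e_s <- vs$weber * sqrt(vs$density_double / vs$density_single)
  abs(df_s - df_d) / sqrt(e_s^2 + e_d^2)
}

#' Michelson achromatic contrast
#'
#' `(Q1 - Q2) / (Q1 + Q2)` on the double-cone (achromatic) channel; lies in
#' \[-1, 1\], zero for identical stimuli, antisymmetric under swapping.
#'
#' @param c1,c2 [quantum_catch()] results.
#' @return Michelson contrast.
#' @export
michelson <- function(c1, c2) {
  stopifnot(inherits(c1, "quantum_catches"), inherits(c2, "quantum_catches"))
  tot <- c1$q_double + c2$q_double
  if (tot <= 0)
    stop("michelson contrast undefined: both double-cone catches are zero",
         call. = FALSE)
  (c1$q_double - c2$q_double) / tot
}
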