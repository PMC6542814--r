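#' Wavelength-indexed spectrum
#'
#' The basic container shared by every pipeline stage: a strictly increasing
#' wavelength grid (nm) with one non-negative value per wavelength and a
#' declared unit. Units distinguish instrument-scale radiance
#' (`energy_radiance`, W sr^-1 m^-2 nm^-1), photon-scale radiance
#' (`photon_radiance`, photons s^-1 sr^-1 m^-2 nm^-1), radiance or
#' reflectance relative to a diffuse white standard (`relative`, may exceed
#' 1, as measured ocular sparks do), and dimensionless transmittance or
#' shading fractions (`fraction`, constrained to \[0, 1\]).
#'
#' @param wavelengths_nm Strictly increasing numeric vector of wavelengths
#'   in nm.
#' @param values Non-negative finite numeric vector, same length.
#' @param unit One of `"energy_radiance"`, `"photon_radiance"`,
#'   `"relative"`, `"fraction"`.
#' @return An object of class `"spectrum"`.
#' @examples
#' s <- spectrum(canonical_grid(), rep(1, 301), "relative")
#' band_mean(s, 400, 700)
#' @export
spectrum <- function(wavelengths_nm, values,
                     unit = c("energy_radiance", "photon_radiance",
                              "relative", "fraction")) {
  unit <- match.arg(unit)
  wavelengths_nm <- as.numeric(wavelengths_nm)
  values <- as.numeric(values)
  if (length(wavelengths_nm) < 1L)
    stop("spectrum needs at least one wavelength", call. = FALSE)
  if (length(wavelengths_nm) != length(values))
    stop("wavelengths and values differ in length (",
         length(wavelengths_nm), " vs ", length(values), ")", call. = FALSE)
  if (anyNA(wavelengths_nm) || any(!is.finite(wavelengths_nm)))
    stop("wavelengths must be finite", call. = FALSE)
  if (any(diff(wavelengths_nm) <= 0))
    stop("wavelengths must be strictly increasing (no duplicates)",
         call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("spectrum values must be finite", call. = FALSE)
  if (any(values < 0))
    stop("spectrum values must be non-negative", call. = FALSE)
  if (unit == "fraction" && any(values > 1 + 1e-9))
    stop("unit 'fraction' requires values <= 1; max is ",
         format(max(values)), call. = FALSE)
  structure(list(wl = wavelengths_nm, value = values, unit = unit),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, %.6g-%.6g nm, unit = %s\n",
              length(x$wl), min(x$wl), max(x$wl), x$unit))
  cat(sprintf("  values: min %.4g, max %.4g, band mean %.4g\n",
              min(x$value), max(x$value),
              band_mean(x, min(x$wl), max(x$wl))))
  invisible(x)
}

#' @export
as.data.frame.spectrum <- function(x, ...) {
  data.frame(wavelength_nm = x$wl, value = x$value)
}

is_spectrum <- function(x) inherits(x, "spectrum")

# Grids must be identical for elementwise arithmetic; fail loudly otherwise.
check_same_grid <- function(a, b) {
  if (length(a$wl) != length(b$wl) || any(a$wl != b$wl))
    stop("spectra are on different wavelength grids; resample first",
         call. = FALSE)
  invisible(TRUE)
}

# Elementwise product of spectra/scalars with an explicit result unit.
# Relative reflectances and fractions are dimensionless multipliers, so the
# caller states what scale the product lives on.
spec_product <- function(..., unit) {
  parts <- list(...)
  specs <- Filter(is_spectrum, parts)
  if (length(specs) == 0L) stop("no spectrum among factors", call. = FALSE)
  for (s in specs[-1L]) check_same_grid(specs[[1L]], s)
  v <- Reduce(`*`, lapply(parts, function(p) if (is_spectrum(p)) p$value else p))
  spectrum(specs[[1L]]$wl, v, unit)
}

spec_add <- function(a, b) {
  check_same_grid(a, b)
  if (a$unit != b$unit)
    stop("cannot add spectra with units '", a$unit, "' and '", b$unit, "'",
         call. = FALSE)
  spectrum(a$wl, a$value + b$value, a$unit)
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation; no extrapolation. Linear (rather than spline)
#' interpolation is monotone and cannot overshoot, which matters for
#' reflectance spectra that must stay non-negative.
#'
#' @param s A [spectrum()].
#' @param grid Strictly increasing wavelengths (nm), all within the range of
#'   `s`'s grid.
#' @return A [spectrum()] on `grid`, unit preserved.
#' @export
resample <- function(s, grid = canonical_grid()) {
  stopifnot(is_spectrum(s))
  grid <- as.numeric(grid)
  bad <- grid < min(s$wl) | grid > max(s$wl)
  if (any(bad))
    stop("resample would extrapolate at ", grid[which(bad)[1L]],
         " nm (spectrum covers ", min(s$wl), "-", max(s$wl), " nm)",
         call. = FALSE)
  v <- stats::approx(s$wl, s$value, xout = grid, method = "linear")$y
  spectrum(grid, v, s$unit)
}

#' Convert energy radiance to photon radiance
#'
#' Photon energy is hc/lambda, so a per-nm energy radiance converts to a
#' per-nm photon radiance by multiplying with lambda/(hc) (lambda in
#' metres). Quantum catches must be computed on the photon scale.
#'
#' @param s A [spectrum()] with unit `energy_radiance`.
#' @return A [spectrum()] with unit `photon_radiance`.
#' @export
to_photon_units <- function(s) {
  stopifnot(is_spectrum(s))
  if (s$unit != "energy_radiance")
    stop("to_photon_units() requires unit 'energy_radiance', got '",
         s$unit, "'", call. = FALSE)
  lambda_m <- s$wl * 1e-9
  spectrum(s$wl, s$value * lambda_m / (.PLANCK_H * .LIGHT_C),
           "photon_radiance")
}

#' Band mean of a spectrum
#'
#' Trapezoidal integral over \[lo, hi\] divided by the band width. The band
#' mean of the all-ones relative spectrum is 1 on any sub-band, so this is
#' the "mean area under the curve" scale on which spark radiance is
#' reported (a diffuse white standard scores 1).
#'
#' @param s A [spectrum()].
#' @param lo,hi Band limits in nm, `lo < hi`, within the grid range.
#' @return Scalar band mean.
#' @export
band_mean <- function(s, lo = 400, hi = 700) {
  stopifnot(is_spectrum(s))
  if (lo >= hi) stop("band_mean requires lo < hi", call. = FALSE)
  if (lo < min(s$wl) || hi > max(s$wl))
    stop("band [", lo, ", ", hi, "] outside spectrum range [",
         min(s$wl), ", ", max(s$wl), "]", call. = FALSE)
  grid <- sort(unique(c(lo, hi, s$wl[s$wl > lo & s$wl < hi])))
  v <- stats::approx(s$wl, s$value, xout = grid)$y
  trapz(grid, v) / (hi - lo)
}

# Trapezoidal rule on an irregular grid.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1L] + y[-n]) * diff(x)) / 2
}

#' Read a spectrum from CSV
#'
#' Expects a UTF-8, comma-separated file with header `wavelength_nm,value`.
#' Malformed files are rejected with the offending line number.
#'
#' @param path File path.
#' @param unit Unit to stamp on the result (the file stores bare numbers).
#' @param enforce_range If `TRUE` (default), wavelengths outside
#'   \[400, 700\] nm are rejected; the modelling band is 400--700 nm.
#' @return A [spectrum()].
#' @export
read_spectrum_csv <- function(path, unit = "relative", enforce_range = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  if (!identical(trimws(header), "wavelength_nm,value"))
    stop("line 1 of ", path, ": expected header 'wavelength_nm,value', got '",
         header, "'", call. = FALSE)
  d <- utils::read.csv(path, header = TRUE)
  if (nrow(d) < 1L) stop("line 2 of ", path, ": no data rows", call. = FALSE)
  wl <- suppressWarnings(as.numeric(d$wavelength_nm))
  v <- suppressWarnings(as.numeric(d$value))
  bad <- which(!is.finite(wl) | !is.finite(v))
  if (length(bad))
    stop("line ", bad[1L] + 1L, " of ", path, ": non-numeric entry",
         call. = FALSE)
  if (any(diff(wl) <= 0)) {
    i <- which(diff(wl) <= 0)[1L]
    stop("line ", i + 2L, " of ", path, ": wavelengths not strictly ",
         "increasing (", wl[i], " then ", wl[i + 1L], ")", call. = FALSE)
  }
  if (any(v < 0))
    stop("line ", which(v < 0)[1L] + 1L, " of ", path, ": negative value",
         call. = FALSE)
  if (enforce_range && (min(wl) < 400 || max(wl) > 700)) {
    i <- which(wl < 400 | wl > 700)[1L]
    stop("line ", i + 1L, " of ", path, ": wavelength ", wl[i],
         " nm outside the 400-700 nm modelling band", call. = FALSE)
  }
  spectrum(wl, v, unit)
}

#' Write a spectrum to CSV
#'
#' Inverse of [read_spectrum_csv()]: `read(write(s))` reproduces `s` to at
#' least 12 significant digits.
#'
#' @param s A [spectrum()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(s, path) {
  stopifnot(is_spectrum(s))
  lines <- c("wavelength_nm,value",
             paste(format(s$wl, digits = 15, trim = TRUE, scientific = FALSE),
                   format(s$value, digits = 15, trim = TRUE),
                   sep = ","))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
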