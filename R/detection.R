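#' Contrast between the prey eye with and without the ocular spark
#'
#' Runs the full chain at each viewing distance: ambient target radiance,
#' spark-induced increment, flux through the viewer's pupil with and
#' without the spark, quantum catches, and either the Michelson achromatic
#' contrast (`channel = "achromatic"`) or the receptor-noise-limited
#' chromatic distance in JND (`channel = "chromatic"`). With
#' `target = "body"` the same machinery is applied to the translucent
#' gammarid body as a negative control (requires `substrate`).
#'
#' Ambient radiance does not depend on distance; only the spark term does,
#' via the product of the two solid angles, which is what produces the
#' inverse-fourth-power decay of the returned flux increment.
#'
#' @param lf A [light_field_scenario()].
#' @param g A [gammarid_optics()].
#' @param spark A [spark_model()].
#' @param viewer A [viewer_optics()].
#' @param visual A [viewer_visual_system()].
#' @param distances_mm Distance grid (mm), each > 0; default 5--45 mm in
#'   1 mm steps.
#' @param channel `"achromatic"` (Michelson) or `"chromatic"` (JND).
#' @param target `"eye"` or `"body"`.
#' @param substrate Substrate reflectance [spectrum()]; needed for
#'   `target = "body"`.
#' @return `data.frame` with columns `distance_mm` and `contrast`.
#' @export
contrast_curve <- function(lf, g, spark, viewer = viewer_optics(),
                           visual = viewer_visual_system(),
                           distances_mm = 5:45,
                           channel = c("achromatic", "chromatic"),
                           target = c("eye", "body"), substrate = NULL) {
  channel <- match.arg(channel)
  target <- match.arg(target)
  if (any(distances_mm <= 0)) stop("distances must be > 0", call. = FALSE)
  lf <- as_photon_light_field(lf)
  if (target == "eye") {
    L0 <- eye_radiance_ambient(lf, g)
  } else {
    if (is.null(substrate))
      stop("target = 'body' requires a substrate spectrum", call. = FALSE)
    L0 <- body_radiance(lf, g, substrate)
  }
  contrast <- vapply(distances_mm, function(d) {
    if (target == "eye") {
      dL <- spark_increment(lf, spark, g, d)
      L1 <- spec_add(L0, dL)
    } else {
      L1 <- body_radiance(lf, g, substrate, spark, d, with_spark = TRUE)
    }
    q0 <- quantum_catch(flux_at_pupil(L0, g$eye_radius_mm, d, viewer), visual)
    q1 <- quantum_catch(flux_at_pupil(L1, g$eye_radius_mm, d, viewer), visual)
    if (channel == "achromatic") michelson(q1, q0)
    else chromatic_jnd(q1, q0, visual)
  }, numeric(1))
  data.frame(distance_mm = as.numeric(distances_mm), contrast = contrast)
}

# Light fields enter on the instrument (energy) scale; catches need the
# photon scale. Converts L_dw and L_sw once, leaving sigma untouched.
as_photon_light_field <- function(lf) {
  if (lf$L_dw$unit == "photon_radiance") return(lf)
  light_field_scenario(lf$depth_m,
                       to_photon_units(lf$L_dw),
                       to_photon_units(lf$L_sw_unshaded),
                       lf$shading, lf$sigma)
}

#' Maximum distance at which a contrast curve clears a threshold
#'
#' Scans the curve from the far end and returns the largest grid distance
#' whose contrast equals or exceeds `threshold` -- the maximum discernable
#' distance. Contrast decays with distance while the ambient baseline is
#' constant, so the curve is expected to be non-increasing; if it is not,
#' a warning is raised and the far-end scan still returns the first
#' crossing from the far side. `NA` means no grid distance qualifies
#' (distinct from a crossing exactly at the grid minimum).
#'
#' @param curve Output of [contrast_curve()] (or any data.frame with
#'   `distance_mm` and `contrast`).
#' @param threshold Detection threshold on the curve's scale (JND or
#'   Michelson contrast).
#' @return Distance in mm, or `NA_real_` when never detectable.
#' @export
max_detection_distance <- function(curve, threshold) {
  stopifnot(is.data.frame(curve),
            all(c("distance_mm", "contrast") %in% names(curve)))
  curve <- curve[order(curve$distance_mm), ]
  if (any(diff(curve$contrast) > 1e-12 * max(abs(curve$contrast), 1e-300)))
    warning("contrast curve is not non-increasing in distance; ",
            "scanning from the far end", call. = FALSE)
  ok <- which(curve$contrast >= threshold)
  if (length(ok) == 0L) return(NA_real_)
  curve$distance_mm[max(ok)]
}

#' Sweep configuration
#'
#' The four swept factors and the evaluation grid: spark radius (mm, within
#' the measured 0.09--0.25 range), spark band-mean relative radiance
#' (within the measured 0.63--2.09 range), the coaxial:non-coaxial
#' reflectance categories (2.68, 4.09, 9.87), and the prey shading
#' categories. Distances run over 5--45 mm: beyond 45 mm the prey eye falls
#' below the viewer's resolution limit, and 5 mm is the distance of nearest
#' focus.
#'
#' @param spark_radii_mm Radii (mm); default 9 values spanning
#'   \[0.09, 0.25\].
#' @param spark_radiance_means Band-mean relative radiances; default 9
#'   values spanning \[0.63, 2.09\].
#' @param ratios Subset of `c(2.68, 4.09, 9.87)`.
#' @param shadings Subset of `c("none", "weak", "average", "strong")`.
#' @param distances_mm Integer distance grid within \[5, 45\] mm.
#' @param channels Subset of `c("achromatic_optimistic",
#'   "achromatic_conservative", "chromatic")`.
#' @param seed Integer seed forwarded to synthetic input generation.
#' @return Validated list of class `"sweep_config"`.
#' @export
sweep_config <- function(spark_radii_mm = seq(0.09, 0.25, length.out = 9),
                         spark_radiance_means = seq(0.63, 2.09,
                                                    length.out = 9),
                         ratios = c(2.68, 4.09, 9.87),
                         shadings = c("none", "weak", "average", "strong"),
                         distances_mm = 5:45,
                         channels = c("achromatic_optimistic",
                                      "achromatic_conservative",
                                      "chromatic"),
                         seed = 1L) {
  if (length(spark_radii_mm) == 0L || length(spark_radiance_means) == 0L ||
      length(ratios) == 0L || length(shadings) == 0L ||
      length(channels) == 0L)
    stop("every sweep axis needs at least one value", call. = FALSE)
  if (any(spark_radii_mm < 0.09 - 1e-9) || any(spark_radii_mm > 0.25 + 1e-9))
    stop("spark radii must lie within [0.09, 0.25] mm", call. = FALSE)
  if (any(spark_radiance_means < 0.63 - 1e-9) ||
      any(spark_radiance_means > 2.09 + 1e-9))
    stop("spark radiance means must lie within [0.63, 2.09]", call. = FALSE)
  if (!all(ratios %in% c(2.68, 4.09, 9.87)))
    stop("ratios must be a subset of {2.68, 4.09, 9.87}", call. = FALSE)
  shadings <- match.arg(shadings, c("none", "weak", "average", "strong"),
                        several.ok = TRUE)
  channels <- match.arg(channels, c("achromatic_optimistic",
                                    "achromatic_conservative", "chromatic"),
                        several.ok = TRUE)
  if (any(distances_mm < 5) || any(distances_mm > 45))
    stop("distance grid must lie within [5, 45] mm", call. = FALSE)
  structure(list(spark_radii_mm = spark_radii_mm,
                 spark_radiance_means = spark_radiance_means,
                 ratios = ratios, shadings = shadings,
                 distances_mm = distances_mm, channels = channels,
                 seed = as.integer(seed)),
            class = "sweep_config")
}

#' Run the four-factor detection-distance sweep
#'
#' Evaluates [contrast_curve()] and [max_detection_distance()] over the
#' full factorial grid of a [sweep_config()], producing the
#' detection-distance map: per cell and channel, the maximum distance (mm)
#' at which switching the spark on produces a detectable contrast, or `NA`
#' when no distance in the grid qualifies ("active photolocation does not
#' assist"). Inputs default to the seeded synthetic fixture set from
#' [build_inputs()]; pass measured spectra through the same structure to
#' run the sweep on real data.
#'
#' @param cfg A [sweep_config()].
#' @param inputs Input bundle from [build_inputs()]; defaults to the
#'   synthetic set generated with `cfg$seed`.
#' @param target `"eye"` or `"body"` (negative control).
#' @return `data.frame` of class `"detection_map"` with columns
#'   `spark_radius_mm`, `spark_radiance_mean`, `ratio`, `shading`,
#'   `channel`, `threshold`, `max_distance_mm`.
#' @export
run_sweep <- function(cfg, inputs = build_inputs(synth_config(seed = cfg$seed)),
                      target = c("eye", "body")) {
  stopifnot(inherits(cfg, "sweep_config"))
  target <- match.arg(target)
  thr <- inputs$visual$michelson_thresholds
  chan_spec <- list(
    achromatic_optimistic = list(channel = "achromatic",
                                 threshold = thr[["optimistic"]]),
    achromatic_conservative = list(channel = "achromatic",
                                   threshold = thr[["conservative"]]),
    chromatic = list(channel = "chromatic",
                     threshold = inputs$visual$jnd_threshold))
  grid <- expand.grid(spark_radius_mm = cfg$spark_radii_mm,
                      spark_radiance_mean = cfg$spark_radiance_means,
                      ratio = cfg$ratios, shading = cfg$shadings,
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid) * length(cfg$channels))
  k <- 0L
  for (i in seq_len(nrow(grid))) {
    cell <- grid[i, ]
    lf <- inputs$light_fields[[cell$shading]]
    g <- inputs$gammarids[[as.character(cell$ratio)]]
    sp <- spark_model(cell$spark_radius_mm,
                      scale_to_band_mean(inputs$spark_shape,
                                         cell$spark_radiance_mean))
    curves <- list()
    for (ch in cfg$channels) {
      base <- chan_spec[[ch]]
      if (is.null(curves[[base$channel]]))
        curves[[base$channel]] <- contrast_curve(
          lf, g, sp, inputs$viewer, inputs$visual, cfg$distances_mm,
          channel = base$channel, target = target,
          substrate = inputs$substrate)
      k <- k + 1L
      rows[[k]] <- data.frame(
        spark_radius_mm = cell$spark_radius_mm,
        spark_radiance_mean = cell$spark_radiance_mean,
        ratio = cell$ratio, shading = cell$shading, channel = ch,
        threshold = base$threshold,
        max_distance_mm = max_detection_distance(curves[[base$channel]],
                                                 base$threshold))
    }
  }
  out <- do.call(rbind, rows[seq_len(k)])
  class(out) <- c("detection_map", "data.frame")
  out
}

# Rescale a relative-radiance spectrum so its 400-700 nm band mean equals
# `target` (the swept spark-radiance axis scales the whole curve, keeping
# its shape).
scale_to_band_mean <- function(s, target) {
  m <- band_mean(s, 400, 700)
  if (m <= 0) stop("cannot rescale a zero spectrum", call. = FALSE)
  spectrum(s$wl, s$value * target / m, s$unit)
}

#' Write a detection map as long-format CSV
#'
#' @param map A `"detection_map"` from [run_sweep()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_detection_map <- function(map, path) {
  stopifnot(inherits(map, "detection_map"))
  utils::write.csv(map, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Heatmap of a detection map
#'
#' Facets by reflectance ratio (rows) and shading (columns), with spark
#' radius and radiance on the axes and maximum detection distance as fill;
#' cells where photolocation never clears the threshold are blank.
#' Requires ggplot2.
#'
#' @param map A `"detection_map"` from [run_sweep()].
#' @param channel Channel to plot.
#' @return A ggplot object.
#' @export
plot_detection_map <- function(map, channel = "achromatic_optimistic") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_detection_map() requires ggplot2", call. = FALSE)
  d <- map[map$channel == channel, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data[["spark_radius_mm"]],
                                  y = .data[["spark_radiance_mean"]],
                                  fill = .data[["max_distance_mm"]])) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(ratio ~ shading) +
    ggplot2::scale_fill_viridis_c(na.value = "white",
                                  name = "max distance (mm)") +
    ggplot2::labs(x = "spark radius (mm)",
                  y = "spark band-mean relative radiance",
                  title = paste("Maximum detection distance,", channel))
}

utils::globalVariables(".data")
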