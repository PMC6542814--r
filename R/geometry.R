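#' Solid angle of a disc seen from an on-axis point
#'
#' Exact closed form for a circular disc of radius `radius_mm` viewed from a
#' point on its axis at distance `distance_mm`:
#' `2*pi*(1 - d/sqrt(d^2 + r^2))`. This is the point-receiver limit against
#' which the extended-receiver and Monte-Carlo estimates are validated.
#'
#' @param radius_mm Disc radius (mm), >= 0.
#' @param distance_mm Centre-to-centre distance along the common axis (mm),
#'   > 0.
#' @return Solid angle in steradians.
#' @examples
#' solid_angle_point(0.0625, 10)  # a gammarid eye at 10 mm
#' @export
solid_angle_point <- function(radius_mm, distance_mm) {
  if (any(distance_mm <= 0)) stop("distance must be > 0", call. = FALSE)
  if (any(radius_mm < 0)) stop("radius must be >= 0", call. = FALSE)
  2 * pi * (1 - distance_mm / sqrt(distance_mm^2 + radius_mm^2))
}

# Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch eigenvalue
# method; cached per order.
.gl_cache <- new.env(parent = emptyenv())
gauss_legendre <- function(n) {
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  k <- seq_len(n - 1L)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1L)] <- b
  J[cbind(k + 1L, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  out <- list(x = e$values[ord], w = 2 * e$vectors[1L, ord]^2)
  .gl_cache[[key]] <- out
  out
}

# Solid angle of a disc (radius r, axial distance d) from a point offset
# rho from the axis, by Gauss-Legendre quadrature of
#   Omega = 2 * int_0^pi int_0^r  d * t / (d^2 + t^2 + rho^2
#                                          - 2 t rho cos(phi))^(3/2) dt dphi.
omega_offaxis <- function(r, d, rho, n_nodes = 64L) {
  if (rho == 0) return(solid_angle_point(r, d))
  gl <- gauss_legendre(n_nodes)
  t <- (gl$x + 1) * r / 2          # radial nodes on (0, r)
  wt <- gl$w * r / 2
  phi <- (gl$x + 1) * pi / 2       # azimuth on (0, pi); integrand symmetric
  wphi <- gl$w * pi / 2
  ct <- cos(phi)
  M <- d^2 + rho^2 + outer(t^2, rep(1, n_nodes)) -
    2 * rho * outer(t, ct)
  integrand <- d * outer(t, rep(1, n_nodes)) / M^1.5
  2 * as.numeric(wt %*% integrand %*% wphi)
}

#' Solid angle of a disc averaged over an extended receiver disc
#'
#' Deterministic reference for the extended-receiver solid angle: the
#' source-disc solid angle is evaluated at quadrature points spread over the
#' coaxial receiver disc (uniform in area) and averaged. With
#' `receiver_radius_mm = 0` this reduces exactly to [solid_angle_point()].
#' Both discs are coaxial, matching the modelled geometry in which predator
#' and prey eyes face each other at normal incidence.
#'
#' @param radius_mm Source disc radius (mm).
#' @param distance_mm Axial distance between disc centres (mm), > 0.
#' @param receiver_radius_mm Receiver disc radius (mm); 0 for a point
#'   receiver.
#' @param n_nodes Gauss-Legendre order for the off-axis disc integral.
#' @param n_receiver_nodes Gauss-Legendre order for the receiver average.
#' @return Solid angle in steradians.
#' @export
solid_angle_disc <- function(radius_mm, distance_mm, receiver_radius_mm = 0,
                             n_nodes = 64L, n_receiver_nodes = 16L) {
  if (distance_mm <= 0) stop("distance must be > 0", call. = FALSE)
  if (radius_mm < 0 || receiver_radius_mm < 0)
    stop("radii must be >= 0", call. = FALSE)
  if (radius_mm == 0) return(0)
  if (receiver_radius_mm == 0)
    return(solid_angle_point(radius_mm, distance_mm))
  gl <- gauss_legendre(n_receiver_nodes)
  u <- (gl$x + 1) / 2              # uniform-in-area variable (rho/R)^2
  wu <- gl$w / 2
  vals <- vapply(u, function(ui) {
    omega_offaxis(radius_mm, distance_mm,
                  sqrt(ui) * receiver_radius_mm, n_nodes)
  }, numeric(1))
  sum(wu * vals)
}

#' Monte-Carlo estimate of a disc solid angle
#'
#' Samples a point P uniformly on the receiver disc and a point Q uniformly
#' on the source disc; the estimator `A_source * d / |PQ|^3` is an unbiased
#' estimate of the receiver-averaged solid angle (`d/|PQ|` is the cosine of
#' the angle between PQ and the common axis). With a point receiver it
#' converges to [solid_angle_point()]. The global RNG state is saved and
#' restored; the same `(seed, n_samples)` always returns the identical
#' estimate.
#'
#' @inheritParams solid_angle_disc
#' @param n_samples Number of samples, >= 1000.
#' @param seed Integer seed (required; every stochastic operation in the
#'   package takes one).
#' @return List with `estimate` (sr), `se` (standard error of the mean,
#'   sr), and `n_samples`.
#' @export
solid_angle_mc <- function(radius_mm, distance_mm, receiver_radius_mm = 0,
                           n_samples = 1e6, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (distance_mm <= 0) stop("distance must be > 0", call. = FALSE)
  if (radius_mm < 0 || receiver_radius_mm < 0)
    stop("radii must be >= 0", call. = FALSE)
  if (n_samples < 1e3) stop("n_samples must be >= 1000", call. = FALSE)
  n <- as.integer(n_samples)
  w <- with_local_seed(seed, {
    # receiver point (area-uniform: radius scales with sqrt(u))
    rp <- receiver_radius_mm * sqrt(stats::runif(n))
    tp <- stats::runif(n, 0, 2 * pi)
    # source point
    rq <- radius_mm * sqrt(stats::runif(n))
    tq <- stats::runif(n, 0, 2 * pi)
    dx <- rq * cos(tq) - rp * cos(tp)
    dy <- rq * sin(tq) - rp * sin(tp)
    (pi * radius_mm^2) * distance_mm /
      (dx^2 + dy^2 + distance_mm^2)^1.5
  })
  list(estimate = mean(w),
       se = stats::sd(w) / sqrt(n),
       n_samples = n)
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Memoised deterministic solid angles, keyed on the full geometry; used by
# the detection sweep so repeated (radius, distance) pairs cost one
# quadrature each.
.omega_cache <- new.env(parent = emptyenv())
solid_angle_cached <- function(radius_mm, distance_mm, receiver_radius_mm) {
  key <- paste(radius_mm, distance_mm, receiver_radius_mm, sep = "|")
  v <- .omega_cache[[key]]
  if (is.null(v)) {
    v <- solid_angle_disc(radius_mm, distance_mm, receiver_radius_mm)
    .omega_cache[[key]] <- v
  }
  v
}
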