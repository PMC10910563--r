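#' Fan-beam acquisition geometry
#'
#' Equiangular fan-beam geometry: uniformly spaced source angles over the arc
#' and equiangular detector channels spanning the fan. By default the
#' source-to-isocentre distance is derived from the fan angle and field of
#' view so that the fan exactly subtends the FOV; pass `source_iso` to
#' override.
#'
#' @param n_views Number of projection views over the arc (default 1200).
#' @param n_channels Number of detector channels (default 800).
#' @param fan_angle Full fan angle in degrees (default 47).
#' @param fov Field of view diameter in cm (default 50).
#' @param source_iso Source-to-isocentre distance in cm (default derived).
#' @param arc Scan arc in degrees; only 360 is supported by the reconstructor.
#' @return A list of class `dex_geometry`.
#' @export
fanbeam_geometry <- function(n_views = 1200, n_channels = 800, fan_angle = 47,
                             fov = 50, source_iso = NULL, arc = 360) {
  fan_rad <- fan_angle * pi / 180
  if (is.null(source_iso)) source_iso <- (fov / 2) / sin(fan_rad / 2)
  dgamma <- fan_rad / n_channels
  structure(list(
    n_views = n_views, n_channels = n_channels,
    fan_angle = fan_angle, fov = fov, arc = arc,
    source_iso = source_iso, source_det = 2 * source_iso,
    dgamma = dgamma,
    gamma = (seq_len(n_channels) - (n_channels + 1) / 2) * dgamma,
    beta = (seq_len(n_views) - 1) / n_views * (arc * pi / 180)
  ), class = "dex_geometry")
}

#' @export
print.dex_geometry <- function(x, ...) {
  cat(sprintf("<dex_geometry> %d views x %d channels, fan %.3g deg, FOV %.3g cm, SID %.4g cm\n",
              x$n_views, x$n_channels, x$fan_angle, x$fov, x$source_iso))
  invisible(x)
}

# source position and unit direction for every (view, channel) ray,
# channel-major within view (matches matrix vec order used throughout)
geometry_rays <- function(geom, views = seq_len(geom$n_views),
                          channels = seq_len(geom$n_channels)) {
  beta <- geom$beta[views]
  gamma <- geom$gamma[channels]
  b <- rep(beta, each = length(gamma))
  gm <- rep(gamma, times = length(beta))
  sx <- geom$source_iso * cos(b)
  sy <- geom$source_iso * sin(b)
  # central direction is (-cos b, -sin b); rotate CCW by gamma
  dx <- -cos(b) * cos(gm) + sin(b) * sin(gm)
  dy <- -cos(b) * sin(gm) - sin(b) * cos(gm)
  list(sx = sx, sy = sy, dx = dx, dy = dy,
       view = rep(views, each = length(gamma)),
       channel = rep(channels, times = length(beta)))
}

#' Exact per-material radiological path lengths
#'
#' Siddon-style exact intersection lengths of one ray (or all rays) with the
#' phantom raster, accumulated by material label. The per-material lengths of
#' each ray sum to its total in-grid chord length.
#'
#' @param geom A [fanbeam_geometry()].
#' @param phantom A `dex_phantom`.
#' @param view,channel Optional single indices; when given, returns a tibble
#'   of lengths per material for that one ray. Otherwise all rays are traced
#'   and matrices are returned.
#' @return For a single ray, a tibble (`material`, `length_cm`) plus a
#'   `total_cm` attribute; otherwise a list with `lengths` (rays x materials,
#'   channel-major within view) and `total`.
#' @export
siddon_paths <- function(geom, phantom, view = NULL, channel = NULL) {
  nmat <- length(phantom$materials)
  px <- phantom$pixel_mm / 10
  if (!is.null(view)) {
    stopifnot(length(view) == 1, length(channel) == 1)
    rays <- geometry_rays(geom, views = view, channels = channel)
    res <- cpp_siddon_all(phantom$labels, px, max(nmat, 1L),
                          rays$sx, rays$sy, rays$dx, rays$dy)
    out <- tibble::tibble(material = names(phantom$materials),
                          length_cm = drop(res$lengths))
    attr(out, "total_cm") <- res$total[1]
    return(out)
  }
  rays <- geometry_rays(geom)
  cpp_siddon_all(phantom$labels, px, max(nmat, 1L),
                 rays$sx, rays$sy, rays$dx, rays$dy)
}

new_sinogram <- function(data, geom, content_kind, label = "", seed = NULL,
                         dose_uGy = NULL, extra = list()) {
  structure(c(list(data = data, geometry = geom, content_kind = content_kind,
                   label = label, seed = seed, dose_uGy = dose_uGy), extra),
            class = "dex_sinogram")
}

#' @export
print.dex_sinogram <- function(x, ...) {
  cat(sprintf("<dex_sinogram> %s [%s]: %d views x %d channels\n",
              x$label, x$content_kind, nrow(x$data), ncol(x$data)))
  invisible(x)
}

# per-label linear attenuation matrix (nbins x nmat) on the spectrum grid
phantom_mulin <- function(phantom, energies) {
  mats <- phantom$materials
  out <- matrix(0, length(energies), length(mats))
  for (i in seq_along(mats)) {
    out[, i] <- phantom$densities[[i]] * mu_over_rho(mats[[i]], energies)
  }
  out
}

#' Polychromatic forward projection
#'
#' Traces every ray through the phantom, applies Beer-Lambert transmission on
#' the spectrum's energy grid, and accumulates the detected signal
#' D(E) I(E) T(E) eta(E) per ray. With `noise = TRUE` each energy bin draws an
#' independent Poisson count with that mean (the compound-Poisson detector
#' model); the run is reproducible under `seed`. The spectrum must already be
#' dose-normalised (see [scale_to_dose()]); the per-view spectrum is the
#' normalised spectrum scaled by `1 / n_views` so the view doses sum to the
#' spectrum's dose attribute.
#'
#' @param phantom A `dex_phantom`.
#' @param spectrum A dose-normalised `dex_spectrum` (total scan dose).
#' @param det A [detector()].
#' @param geom A [fanbeam_geometry()].
#' @param noise Draw Poisson noise? Default `FALSE`.
#' @param seed Integer seed used when `noise = TRUE`.
#' @param paths Optional precomputed [siddon_paths()] result for this
#'   phantom/geometry (saves retracing when projecting several spectra).
#' @return A `dex_sinogram` with `content_kind = "raw_signal"`; carries the
#'   open-beam mean signal per ray as `open_beam`.
#' @export
project_polychromatic <- function(phantom, spectrum, det, geom,
                                  noise = FALSE, seed = NULL, paths = NULL) {
  if (is.null(attr(spectrum, "dose_uGy"))) {
    stop("spectrum is not dose-normalised; call scale_to_dose() first",
         call. = FALSE)
  }
  if (is.null(paths)) paths <- siddon_paths(geom, phantom)
  e <- spectrum$energy_kev
  mulin <- phantom_mulin(phantom, e)
  srcw <- spectrum$photons_per_bin / geom$n_views * efficiency(det, e)
  dw <- detector_weight(det, e)
  if (noise && !is.null(seed)) set.seed(seed)
  res <- cpp_poly_signal(paths$lengths, mulin, srcw, dw, noise)
  open_beam <- sum(dw * srcw)
  data <- matrix(res$lambda, nrow = geom$n_views, ncol = geom$n_channels,
                 byrow = TRUE)
  new_sinogram(data, geom, "raw_signal", label = spectrum_label(spectrum),
               seed = if (noise) seed else NULL,
               dose_uGy = attr(spectrum, "dose_uGy"),
               extra = list(open_beam = open_beam,
                            variance = matrix(res$variance, geom$n_views,
                                              geom$n_channels, byrow = TRUE)))
}

#' Log-normalise a raw sinogram to line integrals
#'
#' Computes -log(signal / open_beam) per ray. Non-positive or photon-starved
#' signals are clipped to `floor` before the log; the number of floored rays
#' is recorded in the `n_flagged` attribute of the result.
#'
#' @param sino A raw-signal `dex_sinogram`.
#' @param open_beam Open-beam signal (scalar or per-channel); defaults to the
#'   value recorded at projection time.
#' @param floor Signal floor (same units as the sinogram data).
#' @return A `dex_sinogram` with `content_kind = "line_integral"`.
#' @export
log_normalize <- function(sino, open_beam = NULL, floor = 0.1) {
  stopifnot(inherits(sino, "dex_sinogram"), sino$content_kind == "raw_signal")
  if (is.null(open_beam)) open_beam <- sino$open_beam
  if (is.null(open_beam) || any(open_beam <= 0)) {
    stop("open-beam signal must be positive", call. = FALSE)
  }
  starved <- sino$data < floor
  data <- -log(pmax(sino$data, floor) / open_beam)
  out <- new_sinogram(data, sino$geometry, "line_integral", sino$label,
                      sino$seed, sino$dose_uGy)
  attr(out, "n_flagged") <- sum(starved)
  out
}
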