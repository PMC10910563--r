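#' Phantom images
#'
#' A phantom is a 2-D integer raster of material labels on a square grid plus
#' per-label materials and densities, named regions of interest for CNR
#' measurement, and a body mask for error metrics. Label 0 is air.
#'
#' @name dex_phantom
NULL

new_phantom <- function(labels, pixel_mm, materials, densities, rois,
                        body_mask, name) {
  structure(list(labels = labels, pixel_mm = pixel_mm, materials = materials,
                 densities = densities, rois = rois, body_mask = body_mask,
                 name = name),
            class = "dex_phantom")
}

#' @export
print.dex_phantom <- function(x, ...) {
  cat(sprintf("<dex_phantom> %s: %dx%d, %.3g mm pixels, materials: %s\n",
              x$name, nrow(x$labels), ncol(x$labels), x$pixel_mm,
              paste(names(x$materials), collapse = ", ")))
  invisible(x)
}

# coordinate grids in cm, pixel centres, isocentre at (0, 0)
phantom_coords <- function(n, pixel_mm) {
  px <- pixel_mm / 10
  u <- ((seq_len(n) - 0.5) - n / 2) * px
  list(x = matrix(u, n, n, byrow = TRUE), y = matrix(u, n, n), px = px)
}

#' Water cylinder phantom
#'
#' A circular water disk centred on the isocentre, air elsewhere. Used for
#' dose normalisation checks and beam-hardening calibration tests.
#'
#' @param diameter Cylinder diameter in cm (default 40).
#' @param n Grid size in pixels (default 512).
#' @param pixel_mm Pixel size in mm (default 1).
#' @return A `dex_phantom`.
#' @export
water_cylinder <- function(diameter = 40, n = 512, pixel_mm = 1) {
  fov <- n * pixel_mm / 10
  if (diameter > fov) {
    stop(sprintf("diameter %.3g cm exceeds the %.3g cm field of view",
                 diameter, fov), call. = FALSE)
  }
  g <- phantom_coords(n, pixel_mm)
  inside <- (g$x^2 + g$y^2) <= (diameter / 2)^2
  labels <- matrix(0L, n, n)
  labels[inside] <- 1L
  new_phantom(labels, pixel_mm,
              materials = list(water = dexct_material("water")),
              densities = c(water = 1.00),
              rois = list(), body_mask = inside, name = "water_cylinder")
}

# fixed geometry of the parametric pelvis (cm, isocentre at body centre)
.pelvis_geom <- list(
  body = c(cx = 0, cy = 0, a = 17, b = 11),
  ring_outer = c(cx = 0, cy = 1.5, a = 12.5, b = 8.0),
  ring_inner = c(cx = 0, cy = 1.5, a = 10.5, b = 6.2),
  head = list(r = 2.2, cx = 11.5, cy = -2.5),   # femoral heads at +/- cx
  implant = list(head_r = 1.6, lining_r = 2.0, shell_r = 2.4),
  inset = c(cx = 0, cy = -0.5, a = 3.5, b = 2.5),
  roi_r = 1.5,
  roi1 = c(0, -0.5),    # signal: inside the soft-tissue inset
  roi2 = c(0, -8.5)     # background: plain tissue away from bone and implant
)

in_ellipse <- function(g, p) {
  ((g$x - p["cx"]) / p["a"])^2 + ((g$y - p["cy"]) / p["b"])^2 <= 1
}

#' Parametric pelvis phantom with optional hip prosthesis
#'
#' A synthetic pelvis built from fixed analytic shapes: an elliptical
#' soft-tissue body, a cortical-bone pelvic ring, two femoral heads, and a
#' low-contrast soft-tissue inset (bladder-like, density 1.06 g/cm^3 with the
#' tissue attenuation curve) that provides the CNR signal region. The implant
#' variants replace the left femoral head with a metal head, a PMMA lining,
#' and a hemispherical metal shell opening toward the acetabulum. All
#' variants share identical anatomy outside the implant region. Construction
#' is fully deterministic; `seed` is accepted for interface symmetry with the
#' stochastic simulators and recorded, but no randomness is used.
#'
#' Two disjoint circular ROIs are defined: `roi1` inside the inset (signal)
#' and `roi2` in homogeneous tissue (background).
#'
#' @param implant `"none"`, `"titanium"`, or `"steel"`.
#' @param n Grid size in pixels (default 512).
#' @param pixel_mm Pixel size in mm (default 1).
#' @param seed Optional integer, recorded in the phantom.
#' @return A `dex_phantom` with labels air(0), tissue(1), bone(2), inset(3)
#'   and, for implant variants, metal(4) and pmma(5).
#' @export
pelvis_phantom <- function(implant = c("none", "titanium", "steel"),
                           n = 512, pixel_mm = 1, seed = NULL) {
  implant <- match.arg(implant)
  p <- .pelvis_geom
  g <- phantom_coords(n, pixel_mm)
  labels <- matrix(0L, n, n)

  labels[in_ellipse(g, p$body)] <- 1L
  ring <- in_ellipse(g, p$ring_outer) & !in_ellipse(g, p$ring_inner)
  labels[ring] <- 2L
  for (s in c(-1, 1)) {
    head <- (g$x - s * p$head$cx)^2 + (g$y - p$head$cy)^2 <= p$head$r^2
    labels[head] <- 2L
  }
  labels[in_ellipse(g, p$inset)] <- 3L

  materials <- list(tissue = dexct_material("tissue"),
                    bone = dexct_material("bone"),
                    inset = dexct_material("tissue"))
  densities <- c(tissue = 1.00, bone = 1.85, inset = 1.06)

  if (implant != "none") {
    metal <- dexct_material(implant)
    cx <- -p$head$cx; cy <- p$head$cy
    r2 <- (g$x - cx)^2 + (g$y - cy)^2
    imp <- p$implant
    # clear the native femoral head, then build head / lining / shell
    labels[r2 <= p$head$r^2] <- 1L
    shell <- r2 <= imp$shell_r^2 & r2 > imp$lining_r^2
    # hemispherical shell: keep the half opening away from the isocentre
    outward <- (g$x - cx) * sign(cx) >= 0
    labels[shell & outward] <- 4L
    labels[r2 <= imp$lining_r^2 & r2 > imp$head_r^2] <- 5L
    labels[r2 <= imp$head_r^2] <- 4L
    materials$metal <- metal
    materials$pmma <- dexct_material("pmma")
    densities <- c(densities, metal = metal$density,
                   pmma = .dexct_densities[["pmma"]])
  }

  roi_mask <- function(centre) {
    which((g$x - centre[1])^2 + (g$y - centre[2])^2 <= p$roi_r^2)
  }
  rois <- list(roi1 = roi_mask(p$roi1), roi2 = roi_mask(p$roi2))

  ph <- new_phantom(labels, pixel_mm, materials, densities, rois,
                    body_mask = in_ellipse(g, p$body),
                    name = paste0("pelvis_", implant))
  ph$seed <- seed
  ph
}

#' Per-pixel density map of a phantom (g/cm^3)
#' @param phantom A `dex_phantom`.
#' @export
density_map <- function(phantom) {
  out <- matrix(0, nrow(phantom$labels), ncol(phantom$labels))
  lab <- phantom$labels
  for (i in seq_along(phantom$densities)) {
    out[lab == i] <- phantom$densities[[i]]
  }
  out
}

#' Monoenergetic ground-truth image of a phantom
#'
#' The noiseless linear-attenuation map at a single energy, with Hounsfield
#' conversion against water at that energy: HU = 1000 (mu - mu_w) / mu_w.
#' Air pixels sit at -1000 HU by construction.
#'
#' @param phantom A `dex_phantom`.
#' @param energy Energy in keV, inside all material tables.
#' @return A `dex_image` with `kind = "hu"` carrying `mu` as well.
#' @export
ground_truth_vmi <- function(phantom, energy) {
  lab <- phantom$labels
  mu <- matrix(0, nrow(lab), ncol(lab))
  for (i in seq_along(phantom$materials)) {
    sel <- lab == i
    if (any(sel)) {
      mu[sel] <- phantom$densities[[i]] *
        mu_over_rho(phantom$materials[[i]], energy)
    }
  }
  mu_w <- mu_over_rho(dexct_material("water"), energy)  # rho_w = 1
  hu <- 1000 * ((mu - mu_w) / mu_w)
  new_image(hu, fov = nrow(lab) * phantom$pixel_mm / 10, kind = "hu",
            energy = energy, provenance = list(source = "ground_truth",
                                               phantom = phantom$name),
            mu = mu)
}
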