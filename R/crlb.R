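#' Two-material line object
#'
#' The object seen by a single ray: mass thicknesses A_j = rho_j t_j (g/cm^2)
#' of the two basis materials, soft tissue and bone. Defaults follow the
#' single-line study conditions: 40 cm of tissue at 1.00 g/cm^3 and a bone
#' thickness in centimetres at 1.85 g/cm^3.
#'
#' @param t_tissue,t_bone Thicknesses in cm (converted using the packaged
#'   densities), or give mass thicknesses directly via `a_tissue`/`a_bone`.
#' @param a_tissue,a_bone Mass thicknesses in g/cm^2 (override thicknesses).
#' @return A list of class `dex_line_object`.
#' @export
line_object <- function(t_tissue = 40, t_bone = 1,
                        a_tissue = NULL, a_bone = NULL) {
  if (is.null(a_tissue)) a_tissue <- t_tissue * .dexct_densities[["tissue"]]
  if (is.null(a_bone)) a_bone <- t_bone * .dexct_densities[["bone"]]
  if (a_tissue < 0 || a_bone < 0) stop("mass thicknesses must be >= 0", call. = FALSE)
  structure(list(a_tissue = a_tissue, a_bone = a_bone),
            class = "dex_line_object")
}

#' Spectral transmission of a two-material line object
#'
#' Beer-Lambert transmission T(E) = exp(-(mu/rho)_t(E) A_t - (mu/rho)_b(E) A_b).
#'
#' @param object A [line_object()].
#' @param energies Energies in keV.
#' @param materials List with elements `tissue` and `bone` ([material()]s);
#'   defaults to the packaged tables.
#' @return Transmission values in (0, 1].
#' @export
transmission_line <- function(object, energies,
                              materials = dexct_material(c("tissue", "bone"))) {
  stopifnot(inherits(object, "dex_line_object"))
  exp(-mu_over_rho(materials$tissue, energies) * object$a_tissue -
        mu_over_rho(materials$bone, energies) * object$a_bone)
}

#' First two moments of the detected signals for an allocated pair
#'
#' For each allocated spectrum i: mean lambda_i = sum D I T eta and variance
#' sigma_i^2 = sum D^2 I T eta (compound Poisson; for a counting detector the
#' variance equals the mean).
#'
#' @param pair A [spectral_pair()].
#' @param object A [line_object()].
#' @param det A [detector()].
#' @inheritParams transmission_line
#' @return A tibble with one row per spectrum: `spectrum`, `lambda`, `variance`.
#' @export
signal_moments <- function(pair, object, det,
                           materials = dexct_material(c("tissue", "bone"))) {
  alloc <- allocate(pair)
  purrr::map2_dfr(alloc, names(alloc), function(sp, nm) {
    if (sum(sp$photons_per_bin) <= 0) {
      stop("degenerate (zero-fluence) spectrum: ", spectrum_label(sp), call. = FALSE)
    }
    e <- sp$energy_kev
    w <- detector_weight(det, e) * sp$photons_per_bin *
      transmission_line(object, e, materials) * efficiency(det, e)
    tibble::tibble(spectrum = nm, label = spectrum_label(sp),
                   lambda = sum(w),
                   variance = sum(w * detector_weight(det, e)))
  })
}

# per-spectrum ingredients for the Fisher matrix: lambda, sigma^2 and their
# analytic derivatives wrt the two mass thicknesses
moment_derivatives <- function(sp, object, det, materials) {
  e <- sp$energy_kev
  d <- detector_weight(det, e)
  mu_t <- mu_over_rho(materials$tissue, e)
  mu_b <- mu_over_rho(materials$bone, e)
  base <- sp$photons_per_bin * transmission_line(object, e, materials) *
    efficiency(det, e)
  w1 <- d * base          # integrand of lambda
  w2 <- d * w1            # integrand of sigma^2
  list(
    lambda = sum(w1), var = sum(w2),
    dlam = c(-sum(w1 * mu_t), -sum(w1 * mu_b)),
    dvar = c(-sum(w2 * mu_t), -sum(w2 * mu_b))
  )
}

#' Fisher information and Cramer-Rao bound for one line integral
#'
#' Builds the 2x2 Fisher information matrix of the Gaussian approximation to
#' the compound-Poisson dual-energy measurement (mean and variance matched to
#' the true first two moments):
#' F_jk = sum_i (1/sigma_i^2) dlambda_i/dA_j dlambda_i/dA_k
#'      + (1/2) sum_i (1/sigma_i^4) dsigma_i^2/dA_j dsigma_i^2/dA_k,
#' where derivatives are taken analytically. The variance bound per basis
#' material is the corresponding diagonal of the matrix inverse, and
#' SNR_j = A_j / sqrt(CRLB_j).
#'
#' A numerically singular system (condition number above `cond_max`) is
#' reported as unbounded variance with SNR 0 and `singular = TRUE` rather
#' than an error, so allocation sweeps never abort.
#'
#' @inheritParams signal_moments
#' @param cond_max Condition-number threshold for declaring singularity.
#' @return An object of class `dex_fisher`: list with `fisher`, `crlb`,
#'   `snr` (named vectors tissue/bone), `moments` tibble, `singular` flag.
#' @export
fisher_matrix <- function(pair, object, det,
                          materials = dexct_material(c("tissue", "bone")),
                          cond_max = 1e12) {
  alloc <- allocate(pair)
  parts <- lapply(alloc, moment_derivatives, object = object, det = det,
                  materials = materials)
  f <- matrix(0, 2, 2)
  for (p in parts) {
    f <- f + tcrossprod(p$dlam) / p$var +
      0.5 * tcrossprod(p$dvar) / p$var^2
  }
  dimnames(f) <- list(c("tissue", "bone"), c("tissue", "bone"))
  a <- c(tissue = object$a_tissue, bone = object$a_bone)
  # closed-form 2x2 inverse with explicit conditioning check
  det2 <- f[1, 1] * f[2, 2] - f[1, 2] * f[2, 1]
  singular <- !is.finite(det2) || det2 <= 0 || kappa(f, exact = TRUE) > cond_max
  if (singular) {
    crlb <- c(tissue = Inf, bone = Inf)
    snr <- c(tissue = 0, bone = 0)
  } else {
    crlb <- c(tissue = f[2, 2], bone = f[1, 1]) / det2
    snr <- a / sqrt(crlb)
  }
  moments <- tibble::tibble(
    spectrum = names(parts),
    label = vapply(alloc, spectrum_label, character(1)),
    lambda = vapply(parts, function(p) p$lambda, numeric(1)),
    variance = vapply(parts, function(p) p$var, numeric(1))
  )
  structure(list(fisher = f, crlb = crlb, snr = snr, a = a,
                 moments = moments, singular = singular),
            class = "dex_fisher")
}

#' @export
print.dex_fisher <- function(x, ...) {
  cat("<dex_fisher>", if (x$singular) "(singular system)" else "", "\n")
  cat(sprintf("  SNR tissue %.4g | bone %.4g\n", x$snr[["tissue"]], x$snr[["bone"]]))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Fisher/CRLB result
#'
#' One row per basis material with mass thickness, variance bound and SNR.
#' @param x A `dex_fisher`.
#' @param ... Unused.
#' @export
tidy.dex_fisher <- function(x, ...) {
  tibble::tibble(
    material = names(x$snr),
    mass_thickness = unname(x$a),
    crlb = unname(x$crlb),
    snr = unname(x$snr)
  )
}

#' @rdname tidy.dex_fisher
#' @export
glance.dex_fisher <- function(x, ...) {
  tibble::tibble(
    snr_tissue = x$snr[["tissue"]], snr_bone = x$snr[["bone"]],
    lambda_low = x$moments$lambda[1], lambda_high = x$moments$lambda[2],
    singular = x$singular
  )
}

#' Sweep basis-material SNR over the dose-allocation fraction
#'
#' Evaluates the CRLB-based SNR at each allocation fraction on a fixed grid
#' (1% to 99% by default, matching the study design) and records the peak per
#' material; ties break toward the smaller r, and no sub-grid refinement is
#' performed, so peaks land on the grid.
#'
#' @param low,high The two spectra (unnormalised is fine; they are scaled to
#'   the budget internally).
#' @param object A [line_object()].
#' @param det A [detector()].
#' @param total_dose Dose budget in uGy (default 1).
#' @param r_grid Allocation fractions (default `seq(0.01, 0.99, 0.01)`).
#' @param depth Dose normalisation depth in cm.
#' @inheritParams signal_moments
#' @return A tibble of class `dex_allocation` with columns `r`, `snr_tissue`,
#'   `snr_bone` and a `peaks` attribute (see [allocation_peaks()]).
#' @export
sweep_allocation <- function(low, high, object = line_object(), det = detector(),
                             total_dose = 1, r_grid = seq(0.01, 0.99, by = 0.01),
                             depth = 20,
                             materials = dexct_material(c("tissue", "bone"))) {
  low <- scale_to_dose(low, total_dose, depth)
  high <- scale_to_dose(high, total_dose, depth)
  pair0 <- structure(list(low = low, high = high, r = 0.5,
                          total_dose = total_dose, depth = depth),
                     class = "dex_pair")
  rows <- purrr::map_dfr(r_grid, function(r) {
    pair0$r <- r
    fi <- fisher_matrix(pair0, object, det, materials)
    tibble::tibble(r = r, snr_tissue = fi$snr[["tissue"]],
                   snr_bone = fi$snr[["bone"]], singular = fi$singular)
  })
  peaks <- tibble::tibble(
    material = c("tissue", "bone"),
    r_max = c(rows$r[which.max(rows$snr_tissue)],
              rows$r[which.max(rows$snr_bone)]),
    snr_max = c(max(rows$snr_tissue), max(rows$snr_bone))
  )
  out <- rows
  class(out) <- c("dex_allocation", class(tibble::tibble()))
  attr(out, "peaks") <- peaks
  attr(out, "pair_label") <- paste0(spectrum_label(high), "-", spectrum_label(low))
  attr(out, "object") <- object
  out
}

#' Peak coordinates of an allocation sweep
#' @param curve A `dex_allocation` from [sweep_allocation()].
#' @return Tibble with `material`, `r_max`, `snr_max`.
#' @export
allocation_peaks <- function(curve) attr(curve, "peaks")

#' Peak SNR as a function of bone thickness
#'
#' Runs [sweep_allocation()] at each bone thickness and collects the per-
#' material peak coordinates; used for the bone-thickness crossover analysis
#' between MV-kV and kV-kV pairs.
#'
#' @inheritParams sweep_allocation
#' @param t_bone_grid Bone thicknesses in cm (default 1:10).
#' @param t_tissue Tissue thickness in cm (default 40).
#' @return A tibble with columns `t_bone`, `material`, `r_max`, `snr_max`.
#' @export
thickness_sweep <- function(low, high, t_bone_grid = 1:10, det = detector(),
                            t_tissue = 40, total_dose = 1,
                            r_grid = seq(0.01, 0.99, by = 0.01), depth = 20,
                            materials = dexct_material(c("tissue", "bone"))) {
  purrr::map_dfr(t_bone_grid, function(tb) {
    cur <- sweep_allocation(low, high, line_object(t_tissue, tb), det,
                            total_dose = total_dose, r_grid = r_grid,
                            depth = depth, materials = materials)
    dplyr::mutate(allocation_peaks(cur), t_bone = tb, .before = 1)
  })
}
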