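#' X-ray spectrum as a tibble
#'
#' A spectrum is a tibble with columns `energy_kev` (strictly increasing bin
#' centres) and `photons_per_bin` (non-negative fluence per bin), carrying a
#' `label` attribute. All energy integrals in the package are bin sums on the
#' spectrum's own grid.
#'
#' @param energies Bin-centre energies in keV, strictly increasing.
#' @param fluence Photons per bin, non-negative, same length.
#' @param label Short name for the spectrum.
#' @return A tibble of class `dex_spectrum`.
#' @export
spectrum_table <- function(energies, fluence, label = "spectrum") {
  if (length(energies) < 2) stop("a spectrum needs at least 2 energy bins", call. = FALSE)
  if (any(diff(energies) <= 0)) stop("spectrum energies must be strictly increasing", call. = FALSE)
  if (any(!is.finite(fluence)) || any(fluence < 0)) {
    stop("fluence must be finite and non-negative", call. = FALSE)
  }
  out <- tibble::tibble(energy_kev = as.numeric(energies),
                        photons_per_bin = as.numeric(fluence))
  class(out) <- c("dex_spectrum", class(out))
  attr(out, "label") <- label
  out
}

#' @export
print.dex_spectrum <- function(x, ...) {
  cat(sprintf("<dex_spectrum> %s: %d bins, %.4g-%.5g keV, mean energy %.4g keV\n",
              spectrum_label(x), nrow(x), min(x$energy_kev), max(x$energy_kev),
              mean_energy(x)))
  if (!is.null(attr(x, "dose_uGy"))) {
    cat(sprintf("  normalised: %.6g uGy at %.3g cm water depth\n",
                attr(x, "dose_uGy"), attr(x, "dose_depth_cm")))
  }
  invisible(x)
}

#' @rdname spectrum_table
#' @param x A `dex_spectrum`.
#' @export
spectrum_label <- function(x) attr(x, "label") %||% "spectrum"

#' Fluence-weighted mean photon energy (keV)
#' @param x A `dex_spectrum`.
#' @export
mean_energy <- function(x) {
  tot <- sum(x$photons_per_bin)
  if (tot <= 0) return(NA_real_)
  sum(x$energy_kev * x$photons_per_bin) / tot
}

#' Synthetic bremsstrahlung kV spectrum
#'
#' Kramers-law tube spectrum shaped by aluminum filtration: unfiltered fluence
#' proportional to (kVp - E)/E on 1 keV bins from 1 keV to the tube voltage,
#' multiplied by Beer-Lambert transmission through the stated aluminum
#' thickness. Characteristic lines are omitted. The endpoint energy equals the
#' tube voltage, and mean energy rises with both kVp and filtration.
#'
#' @param kvp Tube voltage in kV, between 40 and 150.
#' @param filtration_mm_al Total aluminum filtration in mm (default 2.5).
#' @return A `dex_spectrum` (arbitrary flux scale; see [scale_to_dose()]).
#' @export
generate_kv_spectrum <- function(kvp, filtration_mm_al = 2.5) {
  if (!is.numeric(kvp) || length(kvp) != 1 || kvp < 40 || kvp > 150) {
    stop("`kvp` must be a single value in [40, 150] kV", call. = FALSE)
  }
  if (filtration_mm_al < 0) stop("filtration must be >= 0", call. = FALSE)
  e <- seq(1, kvp, by = 1)
  n <- pmax(0, (kvp - e)) / e
  al <- dexct_material("aluminum")
  trans <- exp(-linear_atten(al, e) * filtration_mm_al / 10)
  spectrum_table(e, n * trans,
                 label = sprintf("%gkV", kvp))
}

#' Synthetic megavoltage spectrum
#'
#' Thin-target bremsstrahlung form, fluence proportional to (1 - E/E_max)/E on
#' 10 keV bins from 10 keV to the endpoint, hardened by a water-equivalent
#' flattening filtration. `mode = "treatment"` models a 6 MV therapy beam
#' (heavy flattening); `mode = "detuned"` models an imaging beam with endpoint
#' below 3 MeV and lighter filtration, hence a lower mean energy.
#'
#' @param endpoint Endpoint energy in MeV, in [1, 10]; defaults to 6
#'   (treatment) or 2.5 (detuned).
#' @param mode `"treatment"` or `"detuned"`.
#' @param filtration_cm_water Water-equivalent filtration in cm; defaults to
#'   15 (treatment) or 5 (detuned).
#' @return A `dex_spectrum` (arbitrary flux scale).
#' @export
generate_mv_spectrum <- function(endpoint = NULL,
                                 mode = c("treatment", "detuned"),
                                 filtration_cm_water = NULL) {
  mode <- match.arg(mode)
  if (is.null(endpoint)) endpoint <- if (mode == "treatment") 6 else 2.5
  if (!is.numeric(endpoint) || length(endpoint) != 1 ||
      endpoint < 1 || endpoint > 10) {
    stop("`endpoint` must be a single value in [1, 10] MeV", call. = FALSE)
  }
  if (mode == "detuned" && endpoint >= 3) {
    stop("detuned mode requires an endpoint below 3 MeV", call. = FALSE)
  }
  if (is.null(filtration_cm_water)) {
    filtration_cm_water <- if (mode == "treatment") 15 else 5
  }
  e_max <- endpoint * 1000
  e <- seq(10, e_max, by = 10)
  n <- pmax(0, 1 - e / e_max) / e
  water <- dexct_material("water")
  trans <- exp(-linear_atten(water, e) * filtration_cm_water)
  label <- if (mode == "treatment") sprintf("%gMV", endpoint) else "detunedMV"
  spectrum_table(e, n * trans, label = label)
}

#' Read / write a spectrum file
#'
#' Delimited text with a header line and columns `energy_kev`,
#' `photons_per_bin`; `#` lines are comments. This is the escape hatch for
#' externally produced spectra (e.g. measured or Monte-Carlo beams).
#'
#' @param path File path.
#' @param label Label for the loaded spectrum; defaults to the file stem.
#' @return `read_spectrum()` returns a `dex_spectrum`; `write_spectrum()`
#'   returns `path` invisibly.
#' @export
read_spectrum <- function(path, label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, comment.char = "#")
  need <- c("energy_kev", "photons_per_bin")
  if (!all(need %in% names(tab))) {
    stop("spectrum file must have columns energy_kev, photons_per_bin", call. = FALSE)
  }
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  spectrum_table(tab$energy_kev, tab$photons_per_bin, label = label)
}

#' @rdname read_spectrum
#' @param x A `dex_spectrum`.
#' @export
write_spectrum <- function(x, path) {
  utils::write.table(as.data.frame(x[, c("energy_kev", "photons_per_bin")]),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# keV -> J is 1.602176634e-16; doses are reported in uGy for unit fluence
# per cm^2, giving Gy = J/kg via cm^2/g = 0.1 m^2/kg.
.kev_to_uGy <- 1.602176634e-16 * 1000 / 1e-6  # = 1.602e-7 uGy per (keV cm^2/g)

#' Dose at depth in water
#'
#' Absorbed dose delivered at a stated depth in water under charged-particle
#' equilibrium: the bin sum of fluence x water transmission x mass
#' energy-absorption coefficient x photon energy, converted to micro-gray.
#' Linear in the fluence.
#'
#' @param spectrum A `dex_spectrum`.
#' @param depth Depth in cm (default 20, the centre of a 40 cm cylinder).
#' @param water Water material (defaults to the packaged table).
#' @return Dose in uGy.
#' @export
dose_at_depth <- function(spectrum, depth = 20, water = dexct_material("water")) {
  stopifnot(depth >= 0)
  e <- spectrum$energy_kev
  trans <- exp(-linear_atten(water, e) * depth)
  muen <- muen_over_rho(water, e)
  sum(spectrum$photons_per_bin * trans * muen * e) * .kev_to_uGy
}

#' Scale a spectrum to deliver a target dose
#'
#' Multiplies the fluence by a single factor so [dose_at_depth()] returns the
#' target; the spectral shape is unchanged. The result carries `dose_uGy` and
#' `dose_depth_cm` attributes recording its normalisation.
#'
#' @param spectrum A `dex_spectrum`.
#' @param target Target dose in uGy (default 1).
#' @param depth Depth in cm (default 20).
#' @inheritParams dose_at_depth
#' @return The rescaled `dex_spectrum`.
#' @export
scale_to_dose <- function(spectrum, target = 1, depth = 20,
                          water = dexct_material("water")) {
  d0 <- dose_at_depth(spectrum, depth = depth, water = water)
  if (!is.finite(d0) || d0 <= 0) {
    stop("spectrum delivers zero dose; cannot normalise", call. = FALSE)
  }
  out <- spectrum
  out$photons_per_bin <- out$photons_per_bin * (target / d0)
  attr(out, "label") <- spectrum_label(spectrum)
  attr(out, "dose_uGy") <- target
  attr(out, "dose_depth_cm") <- depth
  class(out) <- class(spectrum)
  out
}

#' Dose-allocated spectral pair
#'
#' Couples a low- and a high-energy spectrum with a total dose budget and the
#' fraction `r` of that budget allocated to the high-energy spectrum. Both
#' spectra are normalised to the full budget at construction; [allocate()]
#' rescales the high spectrum by `r` and the low spectrum by `1 - r`, so the
#' two component doses sum exactly to the budget.
#'
#' @param low,high `dex_spectrum` objects.
#' @param r Fraction of the dose given to `high`, in (0, 1).
#' @param total_dose Total dose in uGy (default 1).
#' @param depth Normalisation depth in cm (default 20).
#' @return A list of class `dex_pair`.
#' @export
spectral_pair <- function(low, high, r = 0.5, total_dose = 1, depth = 20) {
  if (!is.numeric(r) || length(r) != 1 || r <= 0 || r >= 1) {
    stop("`r` must be a single value strictly inside (0, 1)", call. = FALSE)
  }
  structure(
    list(low = scale_to_dose(low, total_dose, depth),
         high = scale_to_dose(high, total_dose, depth),
         r = r, total_dose = total_dose, depth = depth),
    class = "dex_pair"
  )
}

#' @rdname spectral_pair
#' @param pair A `dex_pair`.
#' @export
allocate <- function(pair) {
  stopifnot(inherits(pair, "dex_pair"))
  lo <- pair$low; hi <- pair$high
  lo$photons_per_bin <- lo$photons_per_bin * (1 - pair$r)
  hi$photons_per_bin <- hi$photons_per_bin * pair$r
  attr(lo, "dose_uGy") <- pair$total_dose * (1 - pair$r)
  attr(hi, "dose_uGy") <- pair$total_dose * pair$r
  list(low = lo, high = hi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
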