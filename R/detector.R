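#' Detector model
#'
#' Models the CT detector as a detective-efficiency curve eta(E) in [0, 1]
#' combined with a response weight D(E): `"energy_integrating"` weights each
#' stopped photon by its energy (D(E) = E, the default), `"counting"` weights
#' each photon equally (D(E) = 1, used for analytic oracles).
#'
#' The default efficiency is a thick-absorber model for a high-DQE pressurised
#' xenon detector, eta(E) = 1 - exp(-(mu/rho)_Xe x m_eff), with the effective
#' mass thickness m_eff calibrated so eta(1 MeV) = 0.20; kV-range efficiency is
#' then close to 1. A tabulated efficiency (columns `energy_kev`, `eta`) may
#' be supplied instead.
#'
#' @param response `"energy_integrating"` or `"counting"`.
#' @param eta_table Optional data frame with columns `energy_kev`, `eta`.
#' @param eta_mv Calibration value of eta at 1 MeV for the absorber model
#'   (default 0.20).
#' @return An object of class `dex_detector`.
#' @export
detector <- function(response = c("energy_integrating", "counting"),
                     eta_table = NULL, eta_mv = 0.20) {
  response <- match.arg(response)
  if (is.null(eta_table)) {
    xe <- dexct_material("xenon")
    m_eff <- -log(1 - eta_mv) / mu_over_rho(xe, 1000)
    eff <- function(e) 1 - exp(-mu_over_rho(xe, e) * m_eff)
  } else {
    stopifnot(all(c("energy_kev", "eta") %in% names(eta_table)))
    if (any(eta_table$eta < 0 | eta_table$eta > 1)) {
      stop("eta values must lie in [0, 1]", call. = FALSE)
    }
    m_eff <- NA_real_
    tab <- eta_table
    eff <- function(e) {
      stats::approx(tab$energy_kev, tab$eta, xout = e, rule = 2)$y
    }
  }
  structure(list(response = response, eta_fun = eff, m_eff = m_eff),
            class = "dex_detector")
}

#' @export
print.dex_detector <- function(x, ...) {
  cat(sprintf("<dex_detector> %s response, eta(60 keV) = %.3f, eta(1 MeV) = %.3f\n",
              x$response, efficiency(x, 60), efficiency(x, 1000)))
  invisible(x)
}

#' Detective efficiency at given energies
#'
#' @param det A [detector()].
#' @param energies Energies in keV, within 1 keV to 10 MeV.
#' @return eta values in [0, 1].
#' @export
efficiency <- function(det, energies) {
  stopifnot(inherits(det, "dex_detector"))
  if (any(energies < 1 | energies > 1e4)) {
    stop("energies outside modeled range 1 keV - 10 MeV", call. = FALSE)
  }
  pmin(1, pmax(0, det$eta_fun(energies)))
}

detector_weight <- function(det, energies) {
  if (det$response == "energy_integrating") energies else rep(1, length(energies))
}

#' Mean detected signal for a spectrum through a transmission function
#'
#' The bin sum of D(E) x I(E) x T(E) x eta(E): the expected detector signal
#' for the compound-Poisson model.
#'
#' @param spectrum A `dex_spectrum`.
#' @param transmission Transmission values on the spectrum's energy grid,
#'   in [0, 1] (or any non-negative factor).
#' @param det A [detector()].
#' @return The scalar mean signal lambda.
#' @export
detected_mean <- function(spectrum, transmission, det) {
  if (length(transmission) != nrow(spectrum)) {
    stop("transmission must be given on the spectrum's energy grid", call. = FALSE)
  }
  if (any(transmission < 0)) stop("negative transmission", call. = FALSE)
  e <- spectrum$energy_kev
  sum(detector_weight(det, e) * spectrum$photons_per_bin * transmission *
        efficiency(det, e))
}
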