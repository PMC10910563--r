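test_that("noiseless single-ray measurements round-trip exactly", {
  det <- detector()
  sp <- study_spectra()
  al <- allocate(spectral_pair(sp$kV80, sp$detunedMV, r = 0.9,
                               total_dose = 1e4))
  mats <- dexct_material(c("tissue", "bone"))
  truth <- c(40, 1.85 * 4)
  obj <- line_object(a_tissue = truth[1], a_bone = truth[2])
  lam <- vapply(al, function(s) {
    detected_mean(s, transmission_line(obj, s$energy_kev, mats), det)
  }, numeric(1))
  res <- decompose_ray(lam, al, det)
  expect_true(res$converged)
  expect_equal(res$a_tissue, truth[1], tolerance = 1e-6)
  expect_equal(res$a_bone, truth[2], tolerance = 1e-6)

  # open beam -> the empty object
  lam0 <- vapply(al, function(s) {
    detected_mean(s, rep(1, nrow(s)), det)
  }, numeric(1))
  res0 <- decompose_ray(lam0, al, det)
  expect_lt(abs(res0$a_tissue), 1e-8)
  expect_lt(abs(res0$a_bone), 1e-8)
})

test_that("the monoenergetic pair reduces to the log-linear 2x2 solve", {
  ideal_eta <- data.frame(energy_kev = c(1, 1e4), eta = c(1, 1))
  cnt <- detector("counting", eta_table = ideal_eta)
  mats <- dexct_material(c("tissue", "bone"))
  lo <- mono_spectrum(60, n = 1e6)
  hi <- mono_spectrum(100, n = 1e6)
  attr(lo, "dose_uGy") <- attr(hi, "dose_uGy") <- 1
  truth <- c(12, 3)
  M <- rbind(c(mu_over_rho(mats$tissue, 60), mu_over_rho(mats$bone, 60)),
             c(mu_over_rho(mats$tissue, 100), mu_over_rho(mats$bone, 100)))
  lam <- 1e6 * exp(-as.vector(M %*% truth))
  # hand inversion of the linear log system
  a_hand <- solve(M, log(1e6 / lam))
  res <- decompose_ray(lam, list(low = lo, high = hi), cnt)
  expect_equal(c(res$a_tissue, res$a_bone), a_hand, tolerance = 1e-8)
  expect_equal(a_hand, truth, tolerance = 1e-12)
})

test_that("noiseless sinogram decomposition is self-consistent", {
  fx <- noiseless_de_pelvis()
  dec <- fx$dec
  # all rays converge on clean data
  expect_equal(sum(!dec$converged), 0)
  expect_equal(dec$n_flagged, 0)
  # basis sinograms reproject to the measured signals
  det <- fx$det
  for (nm in c("low", "high")) {
    s <- fx$alloc[[nm]]
    e <- s$energy_kev
    mats <- dexct_material(c("tissue", "bone"))
    lam <- dexct:::cpp_poly_signal(
      cbind(as.vector(t(dec$a_tissue$data)), as.vector(t(dec$a_bone$data))),
      cbind(mu_over_rho(mats$tissue, e), mu_over_rho(mats$bone, e)),
      s$photons_per_bin / fx$geom$n_views * efficiency(det, e),
      dexct:::detector_weight(det, e), FALSE)$lambda
    meas <- as.vector(t((if (nm == "low") fx$sino_low else fx$sino_high)$data))
    expect_lt(max(abs(lam - meas) / pmax(meas, 1)), 1e-5)
  }
})

test_that("decomposition recovers the true mass-thickness sinogram", {
  fx <- noiseless_de_pelvis()
  # ground-truth mass thickness per ray from the traced paths
  dens <- fx$phantom$densities
  truth_t <- fx$paths$lengths[, 1] * dens[["tissue"]] +
    fx$paths$lengths[, 3] * dens[["inset"]]
  truth_b <- fx$paths$lengths[, 2] * dens[["bone"]]
  got_t <- as.vector(t(fx$dec$a_tissue$data))
  got_b <- as.vector(t(fx$dec$a_bone$data))
  # the inset is tissue-equivalent, so tissue+inset mass collapses into the
  # tissue basis; bone maps to bone
  expect_lt(max(abs(got_b - truth_b)), 1e-4)
  expect_lt(max(abs(got_t - truth_t)), 1e-4)
})

test_that("geometry mismatch is refused", {
  fx <- noiseless_de_pelvis()
  bad <- fx$sino_high
  bad$data <- bad$data[, -1]
  expect_error(decompose_sinogram(fx$sino_low, bad, fx$alloc, fx$det),
               "geometry")
})
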