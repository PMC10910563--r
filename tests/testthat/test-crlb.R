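test_that("line transmission follows Beer-Lambert", {
  mats <- dexct_material(c("tissue", "bone"))
  e <- c(60, 100, 1000)
  empty <- line_object(a_tissue = 0, a_bone = 0)
  expect_equal(transmission_line(empty, e), rep(1, 3))
  obj <- line_object(a_tissue = 40, a_bone = 1.85)
  t1 <- transmission_line(obj, e)
  obj2 <- line_object(a_tissue = 80, a_bone = 3.70)
  expect_equal(transmission_line(obj2, e), t1^2, tolerance = 1e-12)
  # scalar hand computation at 100 keV from the fixture knots
  expect_equal(t1[2], exp(-0.1693 * 40 - 0.1855 * 1.85), tolerance = 1e-12)
  expect_error(line_object(a_tissue = -1), ">= 0")
})

test_that("signal moments match the compound-Poisson closed forms", {
  obj <- line_object(40, 1)
  ideal_eta <- data.frame(energy_kev = c(1, 1e4), eta = c(1, 1))
  s80 <- generate_kv_spectrum(80)
  mvd <- generate_mv_spectrum(mode = "detuned")
  pair <- spectral_pair(s80, mvd, r = 0.5, total_dose = 1)

  # counting response: variance equals the mean (Poisson)
  cnt <- detector("counting", eta_table = ideal_eta)
  m <- signal_moments(pair, obj, cnt)
  expect_equal(m$variance, m$lambda, tolerance = 1e-12)

  # single-bin EID: variance = E0 x mean
  eid <- detector(eta_table = ideal_eta)
  mono <- mono_spectrum(60, n = 1e8)
  pair_m <- spectral_pair(mono, mono_spectrum(61, n = 1e8), r = 0.5,
                          total_dose = 1)
  mm <- signal_moments(pair_m, obj, eid)
  expect_equal(mm$variance[1], 60 * mm$lambda[1], tolerance = 1e-12)

  # two-bin spectrum: hand-summed lambda and sigma^2 (knot energies, eta = 1)
  a_t <- 2; a_b <- 1
  t60 <- exp(-0.2048 * a_t - 0.3148 * a_b)
  t100 <- exp(-0.1693 * a_t - 0.1855 * a_b)
  toy <- spectrum_table(c(60, 100), c(1000, 2000))
  lam_hand <- 60 * 1000 * t60 + 100 * 2000 * t100
  var_hand <- 60^2 * 1000 * t60 + 100^2 * 2000 * t100
  obj2 <- line_object(a_tissue = a_t, a_bone = a_b)
  w <- transmission_line(obj2, c(60, 100))
  expect_equal(detected_mean(toy, w, eid), lam_hand, tolerance = 1e-12)
  pair2 <- structure(list(low = toy, high = toy, r = 0.5, total_dose = NA,
                          depth = 20), class = "dex_pair")
  m2 <- signal_moments(pair2, obj2, eid)
  expect_equal(m2$lambda[1], lam_hand / 2, tolerance = 1e-12)
  expect_equal(m2$variance[1], var_hand / 2, tolerance = 1e-12)
})

test_that("Fisher matrix is symmetric and matches the monoenergetic closed form", {
  ideal_eta <- data.frame(energy_kev = c(1, 1e4), eta = c(1, 1))
  cnt <- detector("counting", eta_table = ideal_eta)
  obj <- line_object(a_tissue = 10, a_bone = 2)
  lo <- mono_spectrum(60, n = 1e6)
  hi <- mono_spectrum(100, n = 1e6)
  pair <- structure(list(low = lo, high = hi, r = 0.5, total_dose = NA,
                         depth = 20), class = "dex_pair")
  fi <- fisher_matrix(pair, obj, cnt)
  expect_identical(fi$fisher[1, 2], fi$fisher[2, 1])

  # closed form: counting, one bin per spectrum -> lambda_i Poisson-like with
  # F = sum_i lambda_i mu_i mu_i^T + (1/2) sum_i mu_i mu_i^T
  # (second term from dvar/dA = -lambda mu, var = lambda)
  mats <- dexct_material(c("tissue", "bone"))
  mu60 <- c(mu_over_rho(mats$tissue, 60), mu_over_rho(mats$bone, 60))
  mu100 <- c(mu_over_rho(mats$tissue, 100), mu_over_rho(mats$bone, 100))
  lam <- c(0.5 * 1e6 * exp(-sum(mu60 * c(10, 2))),
           0.5 * 1e6 * exp(-sum(mu100 * c(10, 2))))
  f_hand <- lam[1] * tcrossprod(mu60) + lam[2] * tcrossprod(mu100) +
    0.5 * (tcrossprod(mu60) + tcrossprod(mu100))
  expect_equal(unname(fi$fisher), f_hand, tolerance = 1e-10)
  expect_equal(unname(fi$snr), c(10, 2) / sqrt(diag(solve(f_hand))),
               tolerance = 1e-10)
})

test_that("analytic moment derivatives agree with central finite differences", {
  det <- detector()
  s80 <- generate_kv_spectrum(80)
  mvd <- generate_mv_spectrum(mode = "detuned")
  pair <- spectral_pair(s80, mvd, r = 0.7, total_dose = 1)
  a0 <- c(40, 1.85)
  h <- 1e-4
  fd <- function(fun, j) {
    ap <- a0; am <- a0
    ap[j] <- ap[j] + h; am[j] <- am[j] - h
    (fun(ap) - fun(am)) / (2 * h)
  }
  lam_of <- function(a) {
    m <- signal_moments(pair, line_object(a_tissue = a[1], a_bone = a[2]), det)
    m$lambda
  }
  var_of <- function(a) {
    m <- signal_moments(pair, line_object(a_tissue = a[1], a_bone = a[2]), det)
    m$variance
  }
  parts <- lapply(allocate(pair), dexct:::moment_derivatives,
                  object = line_object(a_tissue = a0[1], a_bone = a0[2]),
                  det = det, materials = dexct_material(c("tissue", "bone")))
  for (j in 1:2) {
    dl_fd <- fd(lam_of, j)
    dv_fd <- fd(var_of, j)
    dl_an <- c(parts[[1]]$dlam[j], parts[[2]]$dlam[j])
    dv_an <- c(parts[[1]]$dvar[j], parts[[2]]$dvar[j])
    expect_equal(dl_an, dl_fd, tolerance = 1e-6)
    expect_equal(dv_an, dv_fd, tolerance = 1e-6)
  }
})

test_that("degenerate systems are flagged rather than thrown", {
  ideal_eta <- data.frame(energy_kev = c(1, 1e4), eta = c(1, 1))
  cnt <- detector("counting", eta_table = ideal_eta)
  # same energy in both spectra: rank-1 information, unbounded variance
  pair <- structure(list(low = mono_spectrum(60), high = mono_spectrum(60),
                         r = 0.5, total_dose = NA, depth = 20),
                    class = "dex_pair")
  fi <- fisher_matrix(pair, line_object(10, 1), cnt)
  expect_true(fi$singular)
  expect_equal(unname(fi$snr), c(0, 0))
  expect_equal(unname(fi$crlb), c(Inf, Inf))
})

test_that("identical spectra make allocation irrelevant", {
  det <- detector()
  s <- generate_kv_spectrum(120)
  cur <- sweep_allocation(s, s, line_object(40, 1), det,
                          r_grid = seq(0.1, 0.9, by = 0.1))
  expect_lt(diff(range(cur$snr_tissue)) / max(cur$snr_tissue), 1e-7)
  expect_lt(diff(range(cur$snr_bone)) / max(cur$snr_bone), 1e-7)
})

test_that("SNR grows with the dose budget at fixed allocation", {
  det <- detector()
  s80 <- generate_kv_spectrum(80)
  s140 <- generate_kv_spectrum(140)
  obj <- line_object(40, 1)
  snrs <- vapply(c(0.25, 0.5, 1, 2, 4), function(d) {
    fisher_matrix(spectral_pair(s80, s140, r = 0.5, total_dose = d),
                  obj, det)$snr[["tissue"]]
  }, numeric(1))
  expect_true(all(diff(snrs) > 0))
})

test_that("tidy and glance summarise a Fisher result", {
  det <- detector()
  fi <- fisher_matrix(spectral_pair(generate_kv_spectrum(80),
                                    generate_kv_spectrum(140)),
                      line_object(40, 1), det)
  td <- tidy(fi)
  expect_equal(td$material, c("tissue", "bone"))
  expect_equal(td$snr, unname(fi$snr))
  gl <- glance(fi)
  expect_false(gl$singular)
  expect_equal(gl$snr_tissue, fi$snr[["tissue"]])
})
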