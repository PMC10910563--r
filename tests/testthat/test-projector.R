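test_that("Siddon paths are exact for axis-aligned and diagonal rays", {
  # 10-pixel water row, 1 mm pixels: a horizontal ray must see exactly 10 mm
  labels <- matrix(0L, 16, 16)
  labels[8, 4:13] <- 1L
  res <- dexct:::cpp_siddon_all(labels, 0.1, 1L,
                                sx = -10, sy = (8 - 0.5 - 8) * 0.1,
                                dx = 1, dy = 0)
  expect_equal(res$lengths[1, 1], 1.0, tolerance = 1e-12)

  # a 45 degree ray through a single pixel sees sqrt(2) x pixel size
  one <- matrix(0L, 2, 2)
  one[1, 1] <- 1L
  d <- 1 / sqrt(2)
  res2 <- dexct:::cpp_siddon_all(one, 0.1, 1L, sx = -1 - 0.1, sy = -1 - 0.1,
                                 dx = d, dy = d)
  expect_equal(res2$lengths[1, 1], sqrt(2) * 0.1, tolerance = 1e-10)
})

test_that("per-material sums match a fine-step ray-marching oracle", {
  set.seed(11)
  n <- 32
  labels <- matrix(sample(0:3, n * n, replace = TRUE), n, n)
  px <- 0.2
  half <- n * px / 2
  march <- function(sx, sy, dx, dy, step = 2e-4) {
    t <- seq(0, 4 * half, by = step)
    x <- sx + t * dx; y <- sy + t * dy
    keep <- x > -half & x < half & y > -half & y < half
    ix <- floor((x[keep] + half) / px) + 1
    iy <- floor((y[keep] + half) / px) + 1
    lab <- labels[cbind(iy, ix)]
    vapply(1:3, function(m) sum(lab == m) * step, numeric(1))
  }
  for (ang in c(0.3, 1.2, 2.5, 4.0)) {
    sx <- 2.5 * half * cos(ang); sy <- 2.5 * half * sin(ang)
    dx <- -cos(ang - 0.1); dy <- -sin(ang - 0.1)
    exact <- dexct:::cpp_siddon_all(labels, px, 3L, sx, sy, dx, dy)
    oracle <- march(sx, sy, dx, dy)
    expect_equal(drop(exact$lengths), oracle, tolerance = 1e-3)
    # conservation: material + background lengths sum to the chord
    bg <- dexct:::cpp_siddon_all((labels == 0L) * 1L, px, 1L, sx, sy, dx, dy)
    expect_equal(sum(exact$lengths) + bg$lengths[1, 1], exact$total[1],
                 tolerance = 1e-10)
  }
})

test_that("noiseless projection of an empty phantom is the open beam", {
  det <- detector()
  geom <- fanbeam_geometry(n_views = 10, n_channels = 21)
  empty <- water_cylinder(40, n = 32, pixel_mm = 16)
  empty$labels[] <- 0L
  sp <- scale_to_dose(generate_kv_spectrum(80), 100)
  sino <- project_polychromatic(empty, sp, det, geom)
  expect_equal(max(abs(sino$data - sino$open_beam)) / sino$open_beam, 0,
               tolerance = 1e-12)
  # unnormalised spectra are refused
  expect_error(project_polychromatic(empty, generate_kv_spectrum(80), det,
                                     geom),
               "dose-normalised")
})

test_that("noisy projections are unbiased, seeded, and match the variance model", {
  det <- detector()
  geom <- fanbeam_geometry(n_views = 1, n_channels = 3)
  ph <- water_cylinder(30, n = 64, pixel_mm = 8)
  sp <- scale_to_dose(generate_kv_spectrum(80), 2)
  clean <- project_polychromatic(ph, sp, det, geom)
  reps <- vapply(1:400, function(i) {
    project_polychromatic(ph, sp, det, geom, noise = TRUE, seed = i)$data[1, 2]
  }, numeric(1))
  lam <- clean$data[1, 2]
  sig2 <- clean$variance[1, 2]
  expect_lt(abs(mean(reps) - lam), 3 * sqrt(sig2 / 400))
  # sample variance consistent with sum D^2 I T eta within sampling error
  expect_lt(abs(var(reps) / sig2 - 1), 0.35)
  # reproducibility under a fixed seed
  a <- project_polychromatic(ph, sp, det, geom, noise = TRUE, seed = 99)
  b <- project_polychromatic(ph, sp, det, geom, noise = TRUE, seed = 99)
  expect_identical(a$data, b$data)
})

test_that("log-normalisation inverts the open beam and flags starvation", {
  det <- detector()
  geom <- fanbeam_geometry(n_views = 4, n_channels = 31)
  ph <- water_cylinder(40, n = 64, pixel_mm = 8)
  sp <- scale_to_dose(generate_kv_spectrum(80), 100)
  sino <- project_polychromatic(ph, sp, det, geom)
  li <- log_normalize(sino)
  # air rays -> 0
  expect_equal(li$data[1, 1], 0, tolerance = 1e-12)
  # central ray: effective mu x 40 cm brackets between the extreme mu values
  w <- dexct_material("water")
  e_nz <- sp$energy_kev[sp$photons_per_bin > 1e-12 * max(sp$photons_per_bin)]
  centre <- li$data[1, 16]
  expect_gt(centre, mu_over_rho(w, max(e_nz)) * 40 * 0.9)
  expect_lt(centre, mu_over_rho(w, 40) * 40)
  # a dead ray is floored and counted
  sino$data[2, 16] <- 0
  li2 <- log_normalize(sino)
  expect_equal(attr(li2, "n_flagged"), 1)
  expect_true(is.finite(li2$data[2, 16]))
})
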