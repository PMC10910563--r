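test_that("VMI synthesis follows the basis linear combination", {
  mats <- dexct_material(c("tissue", "bone"))
  zeros <- dexct:::new_image(matrix(0, 8, 8), fov = 8, kind = "basis")
  vm <- synthesize_vmi(zeros, zeros, 80)
  expect_true(all(vm$values == -1000))
  expect_true(all(vm$mu == 0))

  set.seed(3)
  bt <- dexct:::new_image(matrix(runif(64), 8, 8), fov = 8, kind = "basis")
  bb <- dexct:::new_image(matrix(runif(64), 8, 8), fov = 8, kind = "basis")
  vm80 <- synthesize_vmi(bt, bb, 80)
  hand <- bt$values * mu_over_rho(mats$tissue, 80) +
    bb$values * mu_over_rho(mats$bone, 80)
  expect_equal(vm80$mu, hand, tolerance = 1e-12)
  # linearity in the basis images
  bt2 <- bt; bt2$values <- 2 * bt$values
  bb2 <- bb; bb2$values <- 2 * bb$values
  expect_equal(synthesize_vmi(bt2, bb2, 80)$mu, 2 * vm80$mu,
               tolerance = 1e-12)
  # attenuation curves are convex in energy: averaging VMIs across energies
  # differs from the VMI at the mean energy on bone-rich pixels
  vm60 <- synthesize_vmi(bt, bb, 60)
  vm100 <- synthesize_vmi(bt, bb, 100)
  expect_gt(max(abs((vm60$mu + vm100$mu) / 2 - vm80$mu)), 1e-4)
  expect_error(synthesize_vmi(bt, bb, 1e5), "outside")
})

test_that("CNR handles degenerate, shifted, and Gaussian inputs", {
  img <- dexct:::new_image(matrix(5, 10, 10), fov = 10, kind = "hu")
  r1 <- 1:20; r2 <- 51:70
  m <- cnr(img, r1, r2)
  expect_equal(m$contrast, 0)
  expect_true(is.infinite(m$cnr) || m$cnr == 0)  # zero contrast, zero noise

  set.seed(42)
  noise <- rnorm(100)
  vals <- matrix(noise, 10, 10)
  vals[r1] <- vals[r1] + 7
  img2 <- dexct:::new_image(vals, fov = 10, kind = "hu")
  # same noise field in both ROIs after the shift: contrast is the shift
  expect_equal(cnr(img2, r1, r2)$contrast,
               abs(mean(vals[r1]) - mean(vals[r2])))

  # Monte-Carlo Gaussian ROIs: CNR -> |mu1 - mu2| / sqrt(2 sigma^2)
  set.seed(7)
  n <- 1e4
  big <- dexct:::new_image(matrix(c(rnorm(n, 100, 10), rnorm(n, 50, 10)),
                                  ncol = 1), fov = 1, kind = "hu")
  m3 <- cnr(big, 1:n, (n + 1):(2 * n))
  expect_equal(m3$cnr, 50 / sqrt(200), tolerance = 0.05)
  expect_error(cnr(big, 1:10, 5:20), "overlap")
})

test_that("RMSE is a metric on images", {
  a <- dexct:::new_image(matrix(rnorm(64), 8, 8), fov = 8, kind = "hu")
  b <- dexct:::new_image(a$values + 10, fov = 8, kind = "hu")
  expect_equal(rmse(a, a), 0)
  expect_equal(rmse(a, b), 10)
  c3 <- dexct:::new_image(matrix(rnorm(64, sd = 30), 8, 8), fov = 8,
                          kind = "hu")
  expect_lte(rmse(a, c3), rmse(a, b) + rmse(b, c3))
  expect_gte(rmse(a, c3), 0)
  mask <- matrix(FALSE, 8, 8)
  expect_error(rmse(a, b, mask), "empty mask")
  mask[1:2, 1:2] <- TRUE
  expect_equal(rmse(a, b, mask), 10)
})

test_that("exact basis images give zero-variance ROIs, hence infinite CNR", {
  ph <- pelvis_phantom("none", n = 128, pixel_mm = 4)
  bt <- dexct:::new_image((ph$labels == 1L) * 1.0 + (ph$labels == 3L) * 1.06,
                          fov = 51.2, kind = "basis")
  bb <- dexct:::new_image((ph$labels == 2L) * 1.85, fov = 51.2,
                          kind = "basis")
  curve <- cnr_vs_energy(bt, bb, ph, energies = c(60, 100), with_rmse = FALSE)
  expect_true(all(is.infinite(curve$cnr)))
  expect_true(all(curve$contrast > 0))
})

test_that("the noiseless pipeline VMI is accurate in material interiors", {
  fx <- noiseless_de_pelvis()
  bt <- ffbp(fx$dec$a_tissue, n = 192)
  bb <- ffbp(fx$dec$a_bone, n = 192)
  vm <- synthesize_vmi(bt, bb, 80)
  gt <- ground_truth_vmi(fx$phantom, 80)
  interiors <- material_interior(fx$phantom, 1) |
    material_interior(fx$phantom, 2) | material_interior(fx$phantom, 3)
  expect_lt(rmse(vm, gt, interiors), 20)  # HU, away from edge ringing
  tissue_int <- material_interior(fx$phantom, 1)
  expect_lt(stats::median(abs(vm$mu[tissue_int] / gt$mu[tissue_int] - 1)),
            0.02)
})

test_that("VMIs are beam-hardening free where the raw SE image cups", {
  det <- detector()
  geom <- small_geometry(240, 200)
  ph <- water_cylinder(40, n = 128, pixel_mm = 4)
  sp <- study_spectra()
  al <- allocate(spectral_pair(sp$kV80, sp$kV140, r = 0.5, total_dose = 1e4))
  paths <- siddon_paths(geom, ph)
  s_lo <- project_polychromatic(ph, al$low, det, geom, paths = paths)
  s_hi <- project_polychromatic(ph, al$high, det, geom, paths = paths)
  dec <- decompose_sinogram(s_lo, s_hi, al, det)
  vm <- synthesize_vmi(ffbp(dec$a_tissue, n = 128), ffbp(dec$a_bone, n = 128),
                       60)
  img_se <- ffbp(log_normalize(s_lo), n = 128)
  n <- 128; px <- 50 / n
  u <- ((1:n) - 0.5 - n / 2) * px
  X <- matrix(u, n, n, byrow = TRUE); Y <- matrix(u, n, n); R2 <- X^2 + Y^2
  centre <- R2 < 9; periph <- R2 > 256 & R2 < 324
  cup <- function(v) (mean(v[periph]) - mean(v[centre])) / mean(v[periph])
  expect_gt(cup(img_se$values), 0.05)
  expect_lt(abs(cup(vm$mu)), 0.01)
})
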