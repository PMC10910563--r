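test_that("water cylinder has the right area and chord", {
  ph <- water_cylinder(40, n = 512, pixel_mm = 1)
  n_water <- sum(ph$labels == 1L)
  expect_lt(abs(n_water / (pi * 200^2) - 1), 0.005)
  # central row chord of 400 mm +/- 1 pixel
  chord <- sum(ph$labels[256, ] == 1L)
  expect_lte(abs(chord - 400), 1)
  expect_error(water_cylinder(60, n = 512, pixel_mm = 1), "field of view")
})

test_that("central ray sees the full cylinder diameter", {
  ph <- water_cylinder(40, n = 256, pixel_mm = 2)
  geom <- fanbeam_geometry(n_views = 8, n_channels = 101)
  ray <- siddon_paths(geom, ph, view = 1, channel = 51)
  expect_equal(ray$length_cm[ray$material == "water"], 40, tolerance = 1e-2)
})

test_that("pelvis variants contain the expected materials", {
  ph0 <- pelvis_phantom("none", n = 256, pixel_mm = 2)
  expect_named(ph0$materials, c("tissue", "bone", "inset"))
  expect_false(any(ph0$labels > 3L))

  for (impl in c("titanium", "steel")) {
    ph <- pelvis_phantom(impl, n = 256, pixel_mm = 2)
    expect_named(ph$materials, c("tissue", "bone", "inset", "metal", "pmma"))
    expect_equal(ph$materials$metal$name, impl)
    expect_gt(sum(ph$labels == 4L), 0)  # metal head + shell
    expect_gt(sum(ph$labels == 5L), 0)  # pmma lining
  }
  expect_error(pelvis_phantom("cobalt"), "arg")
})

test_that("ROIs are disjoint, populated, and inside the body", {
  ph <- pelvis_phantom("steel", n = 512, pixel_mm = 1)
  expect_gte(length(ph$rois$roi1), 100)
  expect_gte(length(ph$rois$roi2), 100)
  expect_length(intersect(ph$rois$roi1, ph$rois$roi2), 0)
  expect_true(all(ph$body_mask[ph$rois$roi1]))
  expect_true(all(ph$body_mask[ph$rois$roi2]))
  # signal ROI sits in the inset, background in plain tissue
  expect_true(all(ph$labels[ph$rois$roi1] == 3L))
  expect_true(all(ph$labels[ph$rois$roi2] == 1L))
})

test_that("construction is deterministic and variants share anatomy", {
  a <- pelvis_phantom("none", n = 256, pixel_mm = 2, seed = 5)
  b <- pelvis_phantom("none", n = 256, pixel_mm = 2, seed = 5)
  expect_identical(a$labels, b$labels)
  ti <- pelvis_phantom("titanium", n = 256, pixel_mm = 2)
  st <- pelvis_phantom("steel", n = 256, pixel_mm = 2)
  # outside the implant labels, titanium and steel variants are identical
  changed <- ti$labels != a$labels | st$labels != a$labels
  expect_identical(ti$labels[!changed], st$labels[!changed])
  expect_identical(ti$labels[!changed], a$labels[!changed])
  # and the implant occupies only the left-hip region
  idx <- which(changed, arr.ind = TRUE)
  expect_true(all(idx[, "col"] < 128))
})

test_that("ground-truth images honour the Hounsfield definitions", {
  ph <- water_cylinder(20, n = 128, pixel_mm = 4)
  gt <- ground_truth_vmi(ph, 80)
  expect_equal(gt$values[64, 64], 0, tolerance = 1e-9)   # water centre
  expect_equal(gt$values[1, 1], -1000)                   # air corner
  pel <- pelvis_phantom("none", n = 128, pixel_mm = 4)
  gt80 <- ground_truth_vmi(pel, 80)
  bone_px <- which(pel$labels == 2L)[1]
  # hand HU from the fixture knots: bone 1.85 x 0.2229, water 0.1837
  expect_equal(gt80$values[bone_px],
               1000 * (1.85 * 0.2229 - 0.1837) / 0.1837, tolerance = 1e-9)
})

test_that("density map reflects per-label densities", {
  ph <- pelvis_phantom("steel", n = 128, pixel_mm = 4)
  dm <- density_map(ph)
  expect_equal(sort(unique(as.vector(dm))),
               sort(unique(c(0, unname(ph$densities)))))
  expect_equal(dm[ph$labels == 4L][1], 8.0)
})
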