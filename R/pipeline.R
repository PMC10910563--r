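#' Experiment configuration
#'
#' Assembles the settings for the two study designs: the single-line
#' dose-allocation survey (`run_model1()`) and the fan-beam CT simulation
#' (`run_model2()`). `scale = "test"` halves views, channels and grid so the
#' full pipeline runs in minutes while preserving the qualitative orderings.
#'
#' @param scale `"full"` (1200 x 800 rays, 512 grid) or `"test"`
#'   (600 x 400, 256 grid).
#' @param total_dose_mGy Total CT dose per acquisition in mGy (default 10).
#' @param r_mvkv,r_kvkv Dose fraction to the high-energy spectrum for the
#'   MV-kV and kV-kV pairs (defaults 0.9 and 0.5, the single-line optima).
#' @param vmi_energies VMI evaluation grid in keV (default 40:350).
#' @param seed Base integer seed for the noisy acquisitions.
#' @param implants Phantom variants for Model 2.
#' @return A list of class `dex_config`.
#' @export
experiment_config <- function(scale = c("test", "full"), total_dose_mGy = 10,
                              r_mvkv = 0.9, r_kvkv = 0.5,
                              vmi_energies = 40:350, seed = 1,
                              implants = c("none", "titanium", "steel")) {
  scale <- match.arg(scale)
  half <- scale == "test"
  structure(list(
    scale = scale,
    geometry = fanbeam_geometry(n_views = if (half) 600 else 1200,
                                n_channels = if (half) 400 else 800),
    phantom_n = if (half) 256 else 512,
    phantom_pixel_mm = if (half) 2 else 1,
    total_dose_mGy = total_dose_mGy,
    r_mvkv = r_mvkv, r_kvkv = r_kvkv,
    vmi_energies = vmi_energies, seed = seed, implants = implants
  ), class = "dex_config")
}

#' Single-line dose-allocation survey
#'
#' Runs the allocation sweep for every dual-energy combination of the five
#' study spectra (three kV, two MV: nine pairs) over a grid of bone
#' thicknesses, and tabulates the per-material peak coordinates. Fully
#' deterministic.
#'
#' @param t_bone_grid Bone thicknesses in cm (default 1:10).
#' @param total_dose Single-line dose budget in uGy (default 1).
#' @param det A [detector()].
#' @param spectra Optional named list of the five spectra; defaults to the
#'   packaged generators (80/120/140 kV, 6 MV, detuned MV).
#' @return A list with `peaks` (one row per pair x thickness x material) and
#'   `curves` (the full r-grids for the 1 cm case).
#' @export
run_model1 <- function(t_bone_grid = 1:10, total_dose = 1, det = detector(),
                       spectra = NULL) {
  if (is.null(spectra)) spectra <- study_spectra()
  pairs <- list(
    c("MV6", "kV80"), c("MV6", "kV120"), c("MV6", "kV140"),
    c("detunedMV", "kV80"), c("detunedMV", "kV120"), c("detunedMV", "kV140"),
    c("kV140", "kV80"), c("kV140", "kV120"), c("kV120", "kV80")
  )
  peaks <- purrr::map_dfr(pairs, function(p) {
    sw <- thickness_sweep(spectra[[p[2]]], spectra[[p[1]]], t_bone_grid, det,
                          total_dose = total_dose)
    dplyr::mutate(sw, pair = paste0(p[1], "-", p[2]), .before = 1)
  })
  curves <- purrr::map_dfr(pairs, function(p) {
    cur <- sweep_allocation(spectra[[p[2]]], spectra[[p[1]]],
                            line_object(40, t_bone_grid[1]), det,
                            total_dose = total_dose)
    dplyr::mutate(tibble::as_tibble(cur),
                  pair = paste0(p[1], "-", p[2]), .before = 1)
  })
  list(peaks = peaks, curves = curves)
}

#' The five study spectra
#'
#' 80, 120 and 140 kV bremsstrahlung beams plus a 6 MV treatment beam and a
#' detuned (sub-3 MV) imaging beam, from the packaged generators.
#'
#' @return A named list of `dex_spectrum`s.
#' @export
study_spectra <- function() {
  list(kV80 = generate_kv_spectrum(80),
       kV120 = generate_kv_spectrum(120),
       kV140 = generate_kv_spectrum(140),
       MV6 = generate_mv_spectrum(mode = "treatment"),
       detunedMV = generate_mv_spectrum(mode = "detuned"))
}

# one DE acquisition: project both allocated spectra, decompose, reconstruct
# basis images
de_acquisition <- function(phantom, low, high, r, cfg, det, paths, seed) {
  total_uGy <- cfg$total_dose_mGy * 1000
  pair <- spectral_pair(low, high, r = r, total_dose = total_uGy)
  al <- allocate(pair)
  s_lo <- project_polychromatic(phantom, al$low, det, cfg$geometry,
                                noise = TRUE, seed = seed, paths = paths)
  s_hi <- project_polychromatic(phantom, al$high, det, cfg$geometry,
                                noise = TRUE, seed = seed + 1, paths = paths)
  dec <- decompose_sinogram(s_lo, s_hi, al, det)
  list(
    basis_tissue = ffbp(dec$a_tissue, n = cfg$phantom_n),
    basis_bone = ffbp(dec$a_bone, n = cfg$phantom_n),
    decomposition = dec
  )
}

# one SE acquisition: project, water BHC, reconstruct, bone BHC
se_acquisition <- function(phantom, spectrum, cfg, det, paths, seed) {
  total_uGy <- cfg$total_dose_mGy * 1000
  sp <- scale_to_dose(spectrum, total_uGy)
  sino <- project_polychromatic(phantom, sp, det, cfg$geometry,
                                noise = TRUE, seed = seed, paths = paths)
  ref_e <- reference_energy(sp, det)
  wc <- water_bhc(sino, sp, det, ref_energy = ref_e)
  img_mu <- ffbp(wc, n = cfg$phantom_n)
  img_hu <- mu_to_hu(img_mu, ref_e)
  img_bhc <- bone_bhc(img_hu, sp, det, cfg$geometry)
  list(image = img_hu, image_bhc = img_bhc, ref_energy = ref_e)
}

#' Fan-beam CT study
#'
#' For each phantom variant, simulates the two dual-energy acquisitions
#' (MV-kV: detuned MV + 80 kV at the MV-heavy allocation; kV-kV: 140 kV +
#' 80 kV at equal allocation) and three dose-matched single-energy kV
#' acquisitions with two-material beam-hardening correction, then evaluates
#' CNR and RMSE. All randomness derives from the config seed.
#'
#' @param cfg An [experiment_config()].
#' @param det A [detector()].
#' @param with_se Include the three single-energy acquisitions
#'   (default `TRUE`).
#' @return A list of class `dex_model2` with per-variant results
#'   (`$variants`), a combined `metrics` tibble, and the config.
#' @export
run_model2 <- function(cfg = experiment_config(), det = detector(),
                       with_se = TRUE) {
  sp <- study_spectra()
  variants <- list()
  metrics <- list()
  seed0 <- cfg$seed
  for (impl in cfg$implants) {
    ph <- pelvis_phantom(impl, n = cfg$phantom_n,
                         pixel_mm = cfg$phantom_pixel_mm)
    paths <- siddon_paths(cfg$geometry, ph)
    res <- list(phantom = ph)

    de <- list(
      mvkv = de_acquisition(ph, sp$kV80, sp$detunedMV, cfg$r_mvkv, cfg, det,
                            paths, seed0),
      kvkv = de_acquisition(ph, sp$kV80, sp$kV140, cfg$r_kvkv, cfg, det,
                            paths, seed0 + 10)
    )
    for (nm in names(de)) {
      curve <- cnr_vs_energy(de[[nm]]$basis_tissue, de[[nm]]$basis_bone, ph,
                             energies = cfg$vmi_energies)
      de[[nm]]$curve <- curve
      pk <- attr(curve, "cnr_peak"); mn <- attr(curve, "rmse_min")
      metrics[[length(metrics) + 1]] <- tibble::tibble(
        phantom = impl, acquisition = toupper(nm), type = "DE",
        cnr = pk[["cnr"]], cnr_energy = pk[["energy"]],
        rmse_min = mn[["rmse"]], rmse_energy = mn[["energy"]]
      )
    }
    res$de <- de

    if (with_se) {
      se <- list()
      for (kv in c("kV80", "kV120", "kV140")) {
        acq <- se_acquisition(ph, sp[[kv]], cfg, det, paths,
                              seed0 + 100 + match(kv, names(sp)))
        m_raw <- cnr(acq$image, ph$rois$roi1, ph$rois$roi2)
        m_bhc <- cnr(acq$image_bhc, ph$rois$roi1, ph$rois$roi2)
        se[[kv]] <- acq
        metrics[[length(metrics) + 1]] <- tibble::tibble(
          phantom = impl, acquisition = kv, type = "SE",
          cnr = m_raw$cnr, cnr_energy = acq$ref_energy,
          rmse_min = NA_real_, rmse_energy = NA_real_
        )
        metrics[[length(metrics) + 1]] <- tibble::tibble(
          phantom = impl, acquisition = paste0(kv, "+BHC"), type = "SE",
          cnr = m_bhc$cnr, cnr_energy = acq$ref_energy,
          rmse_min = NA_real_, rmse_energy = NA_real_
        )
      }
      res$se <- se
    }
    variants[[impl]] <- res
    seed0 <- seed0 + 1000
  }
  structure(list(variants = variants,
                 metrics = dplyr::bind_rows(metrics),
                 config = cfg),
            class = "dex_model2")
}

#' @export
print.dex_model2 <- function(x, ...) {
  cat("<dex_model2> fan-beam CT study,", x$config$scale, "scale\n")
  print(x$metrics)
  invisible(x)
}

#' @rdname run_model2
#' @param x A `dex_model2`.
#' @param ... Unused.
#' @export
tidy.dex_model2 <- function(x, ...) x$metrics
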