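# shared fixtures: built in code, cached per test run where expensive

# a two-bin toy spectrum at knot energies (no interpolation error in oracles)
toy_spectrum <- function(n1 = 1e5, n2 = 2e5, e = c(60, 100), label = "toy") {
  spectrum_table(e, c(n1, n2), label = label)
}

# "monoenergetic" spectrum: all fluence in the first bin
mono_spectrum <- function(energy, n = 1e6, label = sprintf("mono%g", energy)) {
  spectrum_table(c(energy, energy + 1), c(n, 0), label = label)
}

# small geometry for reconstruction tests
small_geometry <- function(n_views = 200, n_channels = 150) {
  fanbeam_geometry(n_views = n_views, n_channels = n_channels)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# noiseless dual-energy pelvis acquisition at reduced scale, shared by the
# decomposition-roundtrip and end-to-end VMI checks
noiseless_de_pelvis <- function() {
  cached("noiseless_de", {
    det <- detector()
    geom <- fanbeam_geometry(n_views = 360, n_channels = 256)
    ph <- pelvis_phantom("none", n = 192, pixel_mm = 50 / 192 * 10)
    sp <- study_spectra()
    pair <- spectral_pair(sp$kV80, sp$detunedMV, r = 0.9, total_dose = 1e4)
    al <- allocate(pair)
    paths <- siddon_paths(geom, ph)
    s_lo <- project_polychromatic(ph, al$low, det, geom, paths = paths)
    s_hi <- project_polychromatic(ph, al$high, det, geom, paths = paths)
    dec <- decompose_sinogram(s_lo, s_hi, al, det)
    list(det = det, geom = geom, phantom = ph, alloc = al, paths = paths,
         sino_low = s_lo, sino_high = s_hi, dec = dec)
  })
}
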