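#' Material with tabulated attenuation coefficients
#'
#' A material couples a name and mass density with energy-resolved mass
#' attenuation (`mu_over_rho`, cm^2/g) and, optionally, mass energy-absorption
#' (`muen_over_rho`, cm^2/g) coefficients. Coefficients are interpolated
#' log-log between tabulated energies, the standard practice for smooth
#' photon cross sections.
#'
#' @param name Material name (string).
#' @param density Mass density in g/cm^3, must be positive.
#' @param table Data frame with columns `energy_kev`, `mu_over_rho` and
#'   optionally `muen_over_rho`; energies strictly increasing, values positive.
#' @return An object of class `dex_material`.
#' @export
material <- function(name, density, table) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(density) || length(density) != 1L || density <= 0) {
    stop("`density` must be a single positive number (g/cm^3)", call. = FALSE)
  }
  table <- validate_atten_table(table)
  structure(
    list(name = name, density = density, table = tibble::as_tibble(table)),
    class = "dex_material"
  )
}

validate_atten_table <- function(table) {
  needed <- c("energy_kev", "mu_over_rho")
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols) > 0) {
    stop("attenuation table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  e <- table$energy_kev
  if (any(!is.finite(e))) stop("non-finite energies in attenuation table", call. = FALSE)
  bad <- which(diff(e) <= 0)
  if (length(bad) > 0) {
    stop("energies must be strictly increasing; offending row ", bad[1] + 1L,
         " (", e[bad[1] + 1L], " keV)", call. = FALSE)
  }
  for (col in intersect(c("mu_over_rho", "muen_over_rho"), names(table))) {
    v <- table[[col]]
    bad <- which(!is.finite(v) | v <= 0)
    if (length(bad) > 0) {
      stop("non-positive or missing ", col, " at row ", bad[1],
           " (", e[bad[1]], " keV)", call. = FALSE)
    }
  }
  table
}

#' @export
print.dex_material <- function(x, ...) {
  rng <- range(x$table$energy_kev)
  cat(sprintf("<dex_material> %s  (rho = %.4g g/cm^3, %d knots, %.3g-%.5g keV)\n",
              x$name, x$density, nrow(x$table), rng[1], rng[2]))
  invisible(x)
}

#' Read an attenuation table from a delimited text file
#'
#' The file must be whitespace- or tab-delimited with a header line naming at
#' least `energy_kev` and `mu_over_rho` (cm^2/g); a `muen_over_rho` column is
#' kept when present. Lines starting with `#` are comments.
#'
#' @param path Path to the table file.
#' @param density Mass density in g/cm^3.
#' @param name Material name; defaults to the file stem.
#' @return A [material()].
#' @export
load_attenuation_table <- function(path, density, name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  material(name, density, tab)
}

# densities (g/cm^3) of the packaged materials; tissue and bone per the
# two-material model, implants from standard references
.dexct_densities <- c(
  water = 1.00, tissue = 1.00, bone = 1.85, pmma = 1.19,
  titanium = 4.506, steel = 8.00, aluminum = 2.699, xenon = 5.9e-3
)

.dexct_files <- c(
  water = "water.txt", tissue = "tissue_icru.txt", bone = "bone_icru.txt",
  pmma = "pmma.txt", titanium = "titanium.txt", steel = "steel.txt",
  aluminum = "aluminum.txt", xenon = "xenon_synthetic.txt"
)

.dexct_cache <- new.env(parent = emptyenv())

#' Packaged materials
#'
#' Returns one of the materials shipped with the package: `"water"`,
#' `"tissue"` (ICRU soft tissue, 1.00 g/cm^3), `"bone"` (ICRU cortical bone,
#' 1.85 g/cm^3), `"pmma"`, `"titanium"`, `"steel"`, `"aluminum"`, `"xenon"`
#' (synthetic detector-model table).
#'
#' @param name Material name, or a character vector of names for a list.
#' @return A [material()], or a named list of them when `name` has length > 1.
#' @export
dexct_material <- function(name) {
  if (length(name) > 1) {
    out <- lapply(name, dexct_material)
    names(out) <- name
    return(out)
  }
  name <- match.arg(name, names(.dexct_files))
  key <- paste0("mat_", name)
  if (!is.null(.dexct_cache[[key]])) return(.dexct_cache[[key]])
  path <- system.file("extdata", .dexct_files[[name]], package = "dexct",
                      mustWork = TRUE)
  m <- load_attenuation_table(path, .dexct_densities[[name]], name = name)
  .dexct_cache[[key]] <- m
  m
}

loglog_interp <- function(x, y, xout) {
  # photon cross sections are near power laws; interpolate in log-log space
  exp(stats::approx(log(x), log(y), xout = log(xout), rule = 1)$y)
}

#' Interpolated mass attenuation coefficient
#'
#' @param mat A [material()].
#' @param energies Photon energies in keV, inside the tabulated range.
#' @return mu/rho in cm^2/g at `energies` (log-log interpolation).
#' @export
mu_over_rho <- function(mat, energies) {
  stopifnot(inherits(mat, "dex_material"))
  rng <- range(mat$table$energy_kev)
  if (any(energies < rng[1] | energies > rng[2])) {
    stop(sprintf("energy outside tabulated range [%g, %g] keV for %s",
                 rng[1], rng[2], mat$name), call. = FALSE)
  }
  loglog_interp(mat$table$energy_kev, mat$table$mu_over_rho, energies)
}

#' Interpolated mass energy-absorption coefficient
#'
#' @inheritParams mu_over_rho
#' @return muen/rho in cm^2/g at `energies`.
#' @export
muen_over_rho <- function(mat, energies) {
  stopifnot(inherits(mat, "dex_material"))
  if (is.null(mat$table$muen_over_rho)) {
    stop("material ", mat$name, " has no muen_over_rho column", call. = FALSE)
  }
  rng <- range(mat$table$energy_kev)
  if (any(energies < rng[1] | energies > rng[2])) {
    stop(sprintf("energy outside tabulated range [%g, %g] keV for %s",
                 rng[1], rng[2], mat$name), call. = FALSE)
  }
  loglog_interp(mat$table$energy_kev, mat$table$muen_over_rho, energies)
}

#' Linear attenuation coefficient at the material's nominal density
#'
#' @inheritParams mu_over_rho
#' @return mu in 1/cm at `energies`.
#' @export
linear_atten <- function(mat, energies) {
  mat$density * mu_over_rho(mat, energies)
}
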