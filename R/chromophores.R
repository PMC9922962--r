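#' Near-infrared wavelength grid
#'
#' A regular wavelength grid, the spectral axis of every multispectral stack.
#' Two presets are in routine use: the clinical hand-held grid (700--970 nm in
#' 10 nm steps, 28 wavelengths) and the small-animal grid (680--960 nm in
#' 10 nm steps, 29 wavelengths).
#'
#' @param start_nm First wavelength (nm).
#' @param stop_nm Last wavelength (nm); must exceed `start_nm`.
#' @param step_nm Wavelength increment (nm); must divide `stop_nm - start_nm`.
#' @return An object of class `wavelength_grid`.
#' @examples
#' grid_count(wavelength_grid(700, 970, 10)) # clinical preset: 28
#' grid_count(wavelength_grid(680, 960, 10)) # mouse preset: 29
#' @export
wavelength_grid <- function(start_nm, stop_nm, step_nm = 10) {
  stopifnot(is.numeric(start_nm), is.numeric(stop_nm), is.numeric(step_nm))
  if (!(start_nm < stop_nm)) stop("start_nm must be < stop_nm", call. = FALSE)
  if (!(step_nm > 0)) stop("step_nm must be > 0", call. = FALSE)
  k <- (stop_nm - start_nm) / step_nm
  if (abs(k - round(k)) > 1e-9) {
    stop("(stop_nm - start_nm) must be divisible by step_nm", call. = FALSE)
  }
  structure(
    list(start_nm = start_nm, stop_nm = stop_nm, step_nm = step_nm),
    class = "wavelength_grid"
  )
}

#' @describeIn wavelength_grid Number of wavelengths on the grid.
#' @param grid A `wavelength_grid`.
#' @export
grid_count <- function(grid) {
  stopifnot(inherits(grid, "wavelength_grid"))
  as.integer(round((grid$stop_nm - grid$start_nm) / grid$step_nm)) + 1L
}

#' @describeIn wavelength_grid The wavelengths (nm) as a numeric vector.
#' @export
grid_wavelengths <- function(grid) {
  stopifnot(inherits(grid, "wavelength_grid"))
  seq(grid$start_nm, grid$stop_nm, by = grid$step_nm)
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf(
    "<wavelength_grid> %g-%g nm, step %g nm (%d wavelengths)\n",
    x$start_nm, x$stop_nm, x$step_nm, grid_count(x)
  ))
  invisible(x)
}

#' @export
format.wavelength_grid <- function(x, ...) {
  sprintf("%g:%g:%g", x$start_nm, x$stop_nm, x$step_nm)
}

grids_identical <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-12))
}

#' Tabulated chromophore absorption spectra
#'
#' Load the packaged NIR absorption tables for the four tissue chromophores
#' (oxyhemoglobin, deoxyhemoglobin, lipid, water) and resample them onto a
#' wavelength grid by linear interpolation. The tables are synthetic smooth
#' approximations of the standard literature shapes (see the package's
#' `inst/extdata/spectra/*_synthetic.tsv` headers); the analyses here depend
#' only on the qualitative shapes, most importantly the lipid absorption peak
#' near 930 nm, the strongest lipid feature in the NIR.
#'
#' @param grid A [wavelength_grid()] lying within the tabulated 680--970 nm
#'   range.
#' @return A named list of `chromophore_spectrum` objects, each with fields
#'   `name`, `wavelengths_nm` and `mu_a` (absorption coefficient, 1/cm, at the
#'   table's reference concentration / unit volume fraction).
#' @examples
#' sp <- load_builtin_spectra(wavelength_grid(700, 970, 10))
#' names(sp)
#' # the lipid peak:
#' sp$lipid$wavelengths_nm[which.max(sp$lipid$mu_a)]
#' @export
load_builtin_spectra <- function(grid) {
  stopifnot(inherits(grid, "wavelength_grid"))
  if (grid$start_nm < 680 || grid$stop_nm > 970) {
    stop("grid outside the tabulated 680-970 nm range", call. = FALSE)
  }
  wl <- grid_wavelengths(grid)
  out <- lapply(chromophore_names(), function(nm) {
    tab <- read_spectrum_table(nm)
    resample_spectrum(
      structure(
        list(name = nm, wavelengths_nm = tab$wavelength_nm, mu_a = tab$mu_a),
        class = "chromophore_spectrum"
      ),
      grid
    )
  })
  names(out) <- chromophore_names()
  out
}

chromophore_names <- function() {
  c("oxyhemoglobin", "deoxyhemoglobin", "lipid", "water")
}

read_spectrum_table <- function(name) {
  path <- system.file(
    "extdata", "spectra", paste0(name, "_synthetic.tsv"),
    package = "lipidquant", mustWork = TRUE
  )
  tab <- utils::read.table(
    path, header = FALSE, sep = "\t", comment.char = "#",
    col.names = c("wavelength_nm", "mu_a")
  )
  stopifnot(all(diff(tab$wavelength_nm) > 0), all(tab$mu_a >= 0))
  tab
}

#' Resample a chromophore spectrum onto a wavelength grid
#'
#' Linear interpolation in wavelength; the target grid must lie inside the
#' spectrum's tabulated range (no extrapolation).
#'
#' @param spectrum A `chromophore_spectrum`.
#' @param grid A [wavelength_grid()].
#' @return A `chromophore_spectrum` on the new grid.
#' @export
resample_spectrum <- function(spectrum, grid) {
  stopifnot(inherits(spectrum, "chromophore_spectrum"))
  wl <- grid_wavelengths(grid)
  if (min(wl) < min(spectrum$wavelengths_nm) ||
      max(wl) > max(spectrum$wavelengths_nm)) {
    stop("grid outside the spectrum's tabulated range", call. = FALSE)
  }
  mu <- stats::approx(spectrum$wavelengths_nm, spectrum$mu_a, xout = wl)$y
  structure(
    list(name = spectrum$name, wavelengths_nm = wl, mu_a = mu),
    class = "chromophore_spectrum"
  )
}

#' @export
print.chromophore_spectrum <- function(x, ...) {
  cat(sprintf(
    "<chromophore_spectrum> %s: %d wavelengths (%g-%g nm), mu_a %.3g-%.3g /cm\n",
    x$name, length(x$wavelengths_nm), min(x$wavelengths_nm),
    max(x$wavelengths_nm), min(x$mu_a), max(x$mu_a)
  ))
  invisible(x)
}

#' Tissue composition
#'
#' Volume fractions of the four chromophores making up a tissue, plus the
#' tissue's Grueneisen parameter (dimensionless optoacoustic efficiency, the
#' conversion factor from absorbed optical energy to initial pressure).
#' Fractions need not sum to 1; the remainder is optically inert matrix.
#'
#' @param oxyhemoglobin,deoxyhemoglobin,lipid,water Volume fractions in
#'   `[0, 1]`, jointly summing to at most 1.
#' @param grueneisen Positive scalar efficiency. The default derives it from
#'   the lipid content (`0.12 + 0.68 * lipid`, interpolating between an
#'   aqueous-tissue value and a pure-fat value): lipid-rich tissue converts
#'   absorbed energy to pressure considerably more efficiently than aqueous
#'   tissue, which is why fatty infiltration brightens the optoacoustic image
#'   beyond its absorption change alone.
#' @return A `tissue_composition` object.
#' @export
tissue_composition <- function(oxyhemoglobin = 0, deoxyhemoglobin = 0,
                               lipid = 0, water = 0,
                               grueneisen = 0.12 + 0.68 * lipid) {
  fr <- c(
    oxyhemoglobin = oxyhemoglobin, deoxyhemoglobin = deoxyhemoglobin,
    lipid = lipid, water = water
  )
  if (any(fr < 0)) stop("volume fractions must be >= 0", call. = FALSE)
  if (sum(fr) > 1 + 1e-9) {
    stop("volume fractions must sum to <= 1", call. = FALSE)
  }
  if (!(grueneisen > 0) && sum(fr) > 0) {
    stop("grueneisen must be > 0", call. = FALSE)
  }
  structure(
    list(fractions = fr, grueneisen = grueneisen),
    class = "tissue_composition"
  )
}

#' @export
print.tissue_composition <- function(x, ...) {
  cat("<tissue_composition>",
      paste(sprintf("%s=%.3g", names(x$fractions), x$fractions),
            collapse = " "),
      sprintf("Gamma=%.3g\n", x$grueneisen))
  invisible(x)
}

#' Mix chromophore spectra into a tissue absorption spectrum
#'
#' Linear (Beer--Lambert) mixing: the tissue absorption coefficient at each
#' wavelength is the volume-fraction-weighted sum of the chromophore
#' reference spectra, `mu_a(lambda) = sum_c f_c * mu_a_c(lambda)`.
#'
#' @param comp A [tissue_composition()].
#' @param spectra Named list of `chromophore_spectrum` objects on one shared
#'   grid, as returned by [load_builtin_spectra()].
#' @return Numeric vector of absorption coefficients (1/cm), one per
#'   wavelength of the shared grid.
#' @export
mix_absorption <- function(comp, spectra) {
  stopifnot(inherits(comp, "tissue_composition"))
  missing <- setdiff(names(comp$fractions)[comp$fractions > 0], names(spectra))
  if (length(missing)) {
    stop("no spectrum supplied for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  wl0 <- spectra[[1]]$wavelengths_nm
  for (sp in spectra) {
    if (length(sp$wavelengths_nm) != length(wl0) ||
        any(abs(sp$wavelengths_nm - wl0) > 1e-9)) {
      stop("chromophore spectra are not on a shared wavelength grid",
           call. = FALSE)
    }
  }
  mu <- numeric(length(wl0))
  for (nm in names(comp$fractions)) {
    f <- comp$fractions[[nm]]
    if (f > 0) mu <- mu + f * spectra[[nm]]$mu_a
  }
  mu
}
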