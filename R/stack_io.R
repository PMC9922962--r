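#' Multispectral optoacoustic stack
#'
#' The pipeline's atomic input: a set of co-registered single-wavelength
#' images for one subject, stored as a `rows x cols x wavelengths` array.
#' Row 0 of the image is the probe side; depth increases with row index, and
#' the depth of a row is `(row - skin_row) * pixel_pitch_cm`. Rows above
#' `skin_row` image the acoustic coupling medium (water tank) and carry no
#' tissue signal; they supply the noise estimate for SNR profiling.
#'
#' @param pixels Non-negative numeric array, `rows x cols x wavelengths`
#'   (non-negativity mirrors the reconstruction's non-negativity constraint).
#' @param grid A [wavelength_grid()]; its count must equal `dim(pixels)[3]`.
#' @param pixel_pitch_cm Spatial sampling (cm per pixel).
#' @param skin_row 1-based row index of the first tissue row.
#' @param subject_id Subject identifier.
#' @param cohort Cohort label, `"healthy"` or `"steatosis"`.
#' @return An `msot_stack` object.
#' @export
msot_stack <- function(pixels, grid, pixel_pitch_cm, skin_row,
                       subject_id = "subject",
                       cohort = c("healthy", "steatosis")) {
  cohort <- match.arg(cohort)
  stopifnot(inherits(grid, "wavelength_grid"), is.array(pixels),
            length(dim(pixels)) == 3)
  if (any(pixels < 0)) {
    stop("pixels must be non-negative", call. = FALSE)
  }
  if (dim(pixels)[3] != grid_count(grid)) {
    stop(sprintf(
      "wavelength axis length (%d) does not match the grid count (%d)",
      dim(pixels)[3], grid_count(grid)
    ), call. = FALSE)
  }
  if (skin_row < 1 || skin_row > dim(pixels)[1]) {
    stop("skin_row outside the image", call. = FALSE)
  }
  structure(
    list(
      pixels = pixels, grid = grid, pixel_pitch_cm = pixel_pitch_cm,
      skin_row = as.integer(skin_row), subject_id = subject_id,
      cohort = cohort
    ),
    class = "msot_stack"
  )
}

#' @export
print.msot_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<msot_stack> %s (%s): %d x %d px, %d wavelengths (%s nm), pitch %g cm, skin row %d\n",
    x$subject_id, x$cohort, d[1], d[2], d[3], format(x$grid),
    x$pixel_pitch_cm, x$skin_row
  ))
  invisible(x)
}

plane <- function(stack, wavelength_nm) {
  wl <- grid_wavelengths(stack$grid)
  k <- match(wavelength_nm, wl)
  if (is.na(k)) {
    stop(sprintf("wavelength %g nm is not on the stack's grid (%s)",
                 wavelength_nm, format(stack$grid)), call. = FALSE)
  }
  stack$pixels[, , k]
}

#' ROI masks for a stack
#'
#' Boolean masks for the subcutaneous adipose tissue (SAT), the liver, and
#' the background region (BGR). The BGR is the entire imaged tissue region
#' and therefore contains both the SAT and liver masks; all masks lie at or
#' below the skin line; SAT and liver are disjoint.
#'
#' @param SAT,liver,BGR Logical matrices on the stack's pixel grid. If `BGR`
#'   is `NULL` it is completed as the union of SAT and liver, with a message.
#' @param skin_row 1-based row index of the first tissue row.
#' @return A `roi_set` object with fields `masks` (named list) and
#'   `skin_row`.
#' @export
roi_set <- function(SAT, liver, BGR = NULL, skin_row) {
  stopifnot(is.logical(SAT), is.logical(liver), is.matrix(SAT),
            is.matrix(liver), all(dim(SAT) == dim(liver)))
  if (is.null(BGR)) {
    message("BGR mask absent; completed as the union of SAT and liver")
    BGR <- SAT | liver
  }
  stopifnot(is.logical(BGR), all(dim(BGR) == dim(SAT)))
  if (any(SAT & liver)) {
    stop("SAT and liver masks overlap", call. = FALSE)
  }
  if (any((SAT | liver) & !BGR)) {
    stop("BGR must contain the SAT and liver masks", call. = FALSE)
  }
  above <- seq_len(max(skin_row - 1L, 0L))
  if (length(above) && any(SAT[above, ] | liver[above, ] | BGR[above, ])) {
    stop("masks must lie entirely at or below the skin line", call. = FALSE)
  }
  structure(
    list(masks = list(SAT = SAT, liver = liver, BGR = BGR),
         skin_row = as.integer(skin_row)),
    class = "roi_set"
  )
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf(
    "<roi_set> SAT %d px, liver %d px, BGR %d px, skin row %d\n",
    sum(x$masks$SAT), sum(x$masks$liver), sum(x$masks$BGR), x$skin_row
  ))
  invisible(x)
}

#' Analysis configuration
#'
#' @param target_wavelength_nm Wavelength at which groups are compared
#'   (default 930 nm, where lipid absorption is highest in the NIR).
#' @param slab_thickness_cm Depth-slab thickness for SNR profiling (default
#'   0.5 cm).
#' @param gate_alpha Shapiro-Wilk normality gate level.
#' @param density Density-estimation settings for the pixel analysis: a list
#'   with `method` (`"kde"` or `"hist"`), `n_grid`, and `bw`/`bins`.
#' @param var_equal Pooled-variance Student t-test (`TRUE`, default) or
#'   Welch.
#' @param seed Seed recorded with analyses that simulate.
#' @return An `analysis_config` object.
#' @export
analysis_config <- function(target_wavelength_nm = 930,
                            slab_thickness_cm = 0.5,
                            gate_alpha = 0.05,
                            density = list(method = "kde", n_grid = 512,
                                           bw = "nrd0", bins = 64),
                            var_equal = TRUE, seed = NULL) {
  if (!(slab_thickness_cm > 0)) {
    stop("slab_thickness_cm must be > 0", call. = FALSE)
  }
  structure(
    list(
      target_wavelength_nm = target_wavelength_nm,
      slab_thickness_cm = slab_thickness_cm, gate_alpha = gate_alpha,
      density = density, var_equal = var_equal, seed = seed
    ),
    class = "analysis_config"
  )
}

stack_meta <- function(stack) {
  list(
    format = "lipidquant-stack",
    version = 1L,
    dim = dim(stack$pixels),
    grid = list(start_nm = stack$grid$start_nm, stop_nm = stack$grid$stop_nm,
                step_nm = stack$grid$step_nm),
    wavelengths_nm = grid_wavelengths(stack$grid),
    pixel_pitch_cm = stack$pixel_pitch_cm,
    skin_row = stack$skin_row,
    subject_id = stack$subject_id,
    cohort = stack$cohort
  )
}

#' Read and write multispectral stacks
#'
#' Two on-disk dialects are supported, both consisting of a data file plus a
#' `<prefix>.json` metadata sidecar (wavelength grid, pixel pitch, skin row,
#' subject, cohort):
#'
#' * `"bin"` (canonical): `<prefix>.bin`, raw little-endian float64 pixels in
#'   column-major order. Round-trips are bit-exact.
#' * `"tiff"`: `<prefix>.tif`, a multi-page 32-bit float TIFF with one page
#'   per wavelength. Round-trips are exact to float32 precision; pixel
#'   values must lie in `[0, 1]`.
#'
#' Readers validate rather than coerce: a missing or inconsistent sidecar
#' (e.g. a declared grid whose count disagrees with the number of planes),
#' or negative pixel values, raise errors.
#'
#' @param stack An [msot_stack()].
#' @param prefix Path prefix (without extension).
#' @param format `"bin"` or `"tiff"`.
#' @return `read_stack()` returns an `msot_stack`; `write_stack()` returns
#'   `prefix` invisibly.
#' @export
write_stack <- function(stack, prefix, format = c("bin", "tiff")) {
  stopifnot(inherits(stack, "msot_stack"))
  format <- match.arg(format)
  meta <- stack_meta(stack)
  meta$data_format <- format
  jsonlite::write_json(meta, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  if (format == "bin") {
    con <- file(paste0(prefix, ".bin"), "wb")
    on.exit(close(con))
    writeBin(as.vector(stack$pixels), con, size = 8, endian = "little")
  } else {
    if (any(stack$pixels > 1)) {
      stop("TIFF dialect requires pixel values in [0, 1]", call. = FALSE)
    }
    planes <- lapply(seq_len(dim(stack$pixels)[3]),
                     function(k) stack$pixels[, , k])
    tiff::writeTIFF(planes, paste0(prefix, ".tif"), bits.per.sample = 32L,
                    compression = "none", reduce = FALSE)
  }
  invisible(prefix)
}

#' @rdname write_stack
#' @export
read_stack <- function(prefix) {
  meta_path <- paste0(prefix, ".json")
  if (!file.exists(meta_path)) {
    stop("missing metadata sidecar: ", meta_path, call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  req <- c("dim", "grid", "pixel_pitch_cm", "skin_row", "data_format")
  if (!all(req %in% names(meta))) {
    stop("metadata sidecar lacks required fields: ",
         paste(setdiff(req, names(meta)), collapse = ", "), call. = FALSE)
  }
  grid <- wavelength_grid(meta$grid$start_nm, meta$grid$stop_nm,
                          meta$grid$step_nm)
  d <- as.integer(meta$dim)
  if (length(d) != 3) stop("metadata dim must have length 3", call. = FALSE)
  if (d[3] != grid_count(grid)) {
    stop(sprintf(
      "declared grid count (%d) does not match declared plane count (%d)",
      grid_count(grid), d[3]
    ), call. = FALSE)
  }
  if (identical(meta$data_format, "bin")) {
    path <- paste0(prefix, ".bin")
    n <- prod(d)
    con <- file(path, "rb")
    on.exit(close(con))
    v <- readBin(con, "double", n = n + 1, size = 8, endian = "little")
    if (length(v) != n) {
      stop(sprintf("pixel payload has %d values, expected %d",
                   length(v), n), call. = FALSE)
    }
    pixels <- array(v, dim = d)
  } else {
    planes <- tiff::readTIFF(paste0(prefix, ".tif"), all = TRUE)
    if (length(planes) != d[3]) {
      stop(sprintf("TIFF has %d pages but metadata declares %d planes",
                   length(planes), d[3]), call. = FALSE)
    }
    pixels <- array(0, dim = d)
    for (k in seq_along(planes)) pixels[, , k] <- planes[[k]]
  }
  if (any(pixels < 0)) {
    stop("negative pixel values violate the non-negativity contract",
         call. = FALSE)
  }
  msot_stack(
    pixels = pixels, grid = grid, pixel_pitch_cm = meta$pixel_pitch_cm,
    skin_row = meta$skin_row,
    subject_id = if (is.null(meta$subject_id)) "subject" else meta$subject_id,
    cohort = if (is.null(meta$cohort)) "healthy" else meta$cohort
  )
}

#' Read and write ROI mask sets
#'
#' Masks are stored losslessly as single-channel PNG images
#' (`<prefix>_SAT.png`, `<prefix>_liver.png`, `<prefix>_BGR.png`) with a
#' `<prefix>_roiset.json` sidecar holding the skin row. A missing BGR file
#' is completed as the union of SAT and liver (with a message); dimensions
#' must match the stack, and all [roi_set()] invariants are enforced on
#' read.
#'
#' @param roiset A [roi_set()].
#' @param prefix Path prefix.
#' @param stack The [msot_stack()] the masks belong to (for dimension
#'   checks).
#' @return `read_roiset()` returns a `roi_set`; `write_roiset()` returns
#'   `prefix` invisibly.
#' @export
write_roiset <- function(roiset, prefix) {
  stopifnot(inherits(roiset, "roi_set"))
  for (nm in names(roiset$masks)) {
    png::writePNG(roiset$masks[[nm]] * 1.0,
                  paste0(prefix, "_", nm, ".png"))
  }
  jsonlite::write_json(list(skin_row = roiset$skin_row),
                       paste0(prefix, "_roiset.json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' @rdname write_roiset
#' @export
read_roiset <- function(prefix, stack) {
  stopifnot(inherits(stack, "msot_stack"))
  meta <- jsonlite::read_json(paste0(prefix, "_roiset.json"),
                              simplifyVector = TRUE)
  read_mask <- function(nm) {
    path <- paste0(prefix, "_", nm, ".png")
    if (!file.exists(path)) return(NULL)
    m <- png::readPNG(path) > 0.5
    if (!all(dim(m) == dim(stack$pixels)[1:2])) {
      stop(sprintf("%s mask dimensions do not match the stack", nm),
           call. = FALSE)
    }
    m
  }
  roi_set(
    SAT = read_mask("SAT"), liver = read_mask("liver"),
    BGR = read_mask("BGR"), skin_row = meta$skin_row
  )
}
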