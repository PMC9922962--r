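#' Mean pixel intensity within a mask
#'
#' Arithmetic mean of the single-wavelength image over the masked pixels.
#'
#' @param stack An [msot_stack()].
#' @param mask Logical matrix on the stack's pixel grid; must be non-empty.
#' @param wavelength_nm Wavelength, exact grid member.
#' @return Scalar mean intensity.
#' @export
roi_mean <- function(stack, mask, wavelength_nm) {
  stopifnot(inherits(stack, "msot_stack"), is.logical(mask))
  if (!any(mask)) stop("empty mask", call. = FALSE)
  img <- plane(stack, wavelength_nm)
  mean(img[mask])
}

#' Normalized ROI/BGR ratio spectrum
#'
#' The per-subject spectral biomarker: at each wavelength, the ratio of the
#' mean intensity in the ROI to the mean intensity in the background region
#' (BGR, the entire imaged tissue). Because laser pulse-energy fluctuations
#' scale ROI and BGR together, the ratio is insensitive to them; dividing by
#' the maximum ratio across wavelengths then maps each subject's curve into
#' `[0, 1]`, making curves comparable across subjects regardless of overall
#' signal level. Normalization is per ROI: each ROI's curve is divided by
#' its own maximum (ties broken toward the shortest wavelength).
#'
#' @param stack An [msot_stack()].
#' @param roiset A [roi_set()].
#' @param roi_name `"liver"` or `"SAT"`.
#' @return A `ratio_spectrum` with fields `subject_id`, `roi_name`,
#'   `wavelengths_nm`, `raw_ratio` and `normalized_ratio`.
#' @export
ratio_spectrum <- function(stack, roiset, roi_name = c("liver", "SAT")) {
  roi_name <- match.arg(roi_name)
  stopifnot(inherits(roiset, "roi_set"))
  wl <- grid_wavelengths(stack$grid)
  raw <- vapply(wl, function(w) {
    b <- roi_mean(stack, roiset$masks$BGR, w)
    if (b == 0) {
      stop(sprintf("BGR mean is 0 at %g nm: ratio undefined", w),
           call. = FALSE)
    }
    roi_mean(stack, roiset$masks[[roi_name]], w) / b
  }, numeric(1))
  m <- max(raw)
  normalized <- if (m > 0) raw / m else raw
  structure(
    list(
      subject_id = stack$subject_id, roi_name = roi_name,
      wavelengths_nm = wl, raw_ratio = raw, normalized_ratio = normalized
    ),
    class = "ratio_spectrum"
  )
}

#' @export
print.ratio_spectrum <- function(x, ...) {
  peak <- x$wavelengths_nm[which.max(x$normalized_ratio)]
  cat(sprintf(
    "<ratio_spectrum> %s/%s: %d wavelengths, peak at %g nm\n",
    x$subject_id, x$roi_name, length(x$wavelengths_nm), peak
  ))
  invisible(x)
}

#' @export
as.data.frame.ratio_spectrum <- function(x, ...) {
  data.frame(
    subject_id = x$subject_id, roi_name = x$roi_name,
    wavelength_nm = x$wavelengths_nm, raw_ratio = x$raw_ratio,
    normalized_ratio = x$normalized_ratio
  )
}

#' @export
plot.ratio_spectrum <- function(x, ...) {
  plot(x$wavelengths_nm, x$normalized_ratio, type = "b", pch = 16,
       xlab = "wavelength (nm)", ylab = "normalized ROI/BGR ratio",
       ylim = c(0, 1), main = sprintf("%s - %s", x$subject_id, x$roi_name),
       ...)
  abline(v = 930, lty = 3)
  invisible(x)
}

#' Look up a ratio spectrum at a wavelength
#'
#' Exact grid lookup; off-grid wavelengths are an error, never silently
#' snapped to the nearest neighbor.
#'
#' @param spectrum A [ratio_spectrum()].
#' @param wavelength_nm Wavelength, exact grid member.
#' @param which `"normalized"` (default) or `"raw"`.
#' @return Scalar ratio value.
#' @export
value_at <- function(spectrum, wavelength_nm,
                     which = c("normalized", "raw")) {
  stopifnot(inherits(spectrum, "ratio_spectrum"))
  which <- match.arg(which)
  k <- match(wavelength_nm, spectrum$wavelengths_nm)
  if (is.na(k)) {
    stop(sprintf("wavelength %g nm is not on the spectrum's grid",
                 wavelength_nm), call. = FALSE)
  }
  if (which == "normalized") spectrum$normalized_ratio[k]
  else spectrum$raw_ratio[k]
}

#' Group mean +/- SEM ratio spectrum
#'
#' Per-wavelength mean and standard error of the mean of the normalized
#' ratio over a group's subjects.
#'
#' @param spectra List of at least two [ratio_spectrum()]s sharing one grid
#'   and ROI.
#' @param cohort Group label stored on the result.
#' @return A `group_spectrum`: data.frame with `wavelength_nm`, `mean`,
#'   `sem`, plus attributes `roi_name`, `cohort` and `n`.
#' @export
group_spectrum <- function(spectra, cohort = "group") {
  if (length(spectra) < 2) stop("need >= 2 spectra", call. = FALSE)
  for (s in spectra) stopifnot(inherits(s, "ratio_spectrum"))
  wl <- spectra[[1]]$wavelengths_nm
  roi <- spectra[[1]]$roi_name
  for (s in spectra) {
    if (length(s$wavelengths_nm) != length(wl) ||
        any(abs(s$wavelengths_nm - wl) > 1e-9)) {
      stop("spectra are not on one shared wavelength grid", call. = FALSE)
    }
    if (!identical(s$roi_name, roi)) {
      stop("spectra mix ROI names", call. = FALSE)
    }
  }
  mat <- vapply(spectra, function(s) s$normalized_ratio,
                numeric(length(wl)))
  n <- length(spectra)
  out <- data.frame(
    wavelength_nm = wl,
    mean = rowMeans(mat),
    sem = apply(mat, 1, stats::sd) / sqrt(n)
  )
  structure(out, roi_name = roi, cohort = cohort, n = n,
            class = c("group_spectrum", "data.frame"))
}
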