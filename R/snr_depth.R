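#' Noise estimate from the coupling-medium region
#'
#' Standard deviation of the pixel values above the skin line at one
#' wavelength. Those rows image the water tank / coupling medium, which
#' carries no tissue signal, so their spread estimates the noise floor used
#' as the SNR denominator.
#'
#' @param stack An [msot_stack()].
#' @param wavelength_nm Wavelength, exact grid member.
#' @param skin_row First tissue row; defaults to the stack's own.
#' @return Scalar noise standard deviation.
#' @export
estimate_noise <- function(stack, wavelength_nm,
                           skin_row = stack$skin_row) {
  stopifnot(inherits(stack, "msot_stack"))
  if (skin_row < 2) stop("no rows above the skin line", call. = FALSE)
  img <- plane(stack, wavelength_nm)
  standoff <- img[seq_len(skin_row - 1L), , drop = FALSE]
  if (length(standoff) < 50) {
    stop("need >= 50 pixels above the skin line for a noise estimate",
         call. = FALSE)
  }
  stats::sd(as.vector(standoff))
}

#' Partition the liver mask into depth slabs
#'
#' Tiles the liver ROI from its shallowest pixel downward into contiguous
#' horizontal slabs of `slab_thickness_cm` (default 0.5 cm, i.e. 5 mm); the
#' final slab may be thinner and empty slabs are omitted. The slab masks
#' are an exact partition of the liver mask. Depth of a row is
#' `(row - skin_row) * pixel_pitch_cm`; each slab's centroid depth is the
#' mean depth of its pixels.
#'
#' @param roiset A [roi_set()].
#' @param pixel_pitch_cm Spatial sampling (cm per pixel).
#' @param slab_thickness_cm Slab thickness (cm), > 0.
#' @return List of `depth_slab` objects with fields `top_depth_cm`,
#'   `bottom_depth_cm`, `centroid_depth_cm`, `mask` and `n_pixels`.
#' @export
partition_liver <- function(roiset, pixel_pitch_cm,
                            slab_thickness_cm = 0.5) {
  stopifnot(inherits(roiset, "roi_set"))
  if (!(slab_thickness_cm > 0)) {
    stop("slab_thickness_cm must be > 0", call. = FALSE)
  }
  liver <- roiset$masks$liver
  if (!any(liver)) stop("empty liver mask", call. = FALSE)
  row_depth <- (seq_len(nrow(liver)) - roiset$skin_row) * pixel_pitch_cm
  liver_rows <- which(rowSums(liver) > 0)
  d0 <- row_depth[min(liver_rows)]
  idx <- floor((row_depth - d0) / slab_thickness_cm + 1e-9)
  slabs <- list()
  for (k in sort(unique(idx[liver_rows]))) {
    rows <- liver_rows[idx[liver_rows] == k]
    mask <- liver & FALSE
    mask[rows, ] <- liver[rows, ]
    if (!any(mask)) next
    px_depth <- row_depth[row(mask)[mask]]
    slabs[[length(slabs) + 1L]] <- structure(
      list(
        top_depth_cm = d0 + k * slab_thickness_cm,
        bottom_depth_cm = min(d0 + (k + 1) * slab_thickness_cm,
                              max(px_depth) + pixel_pitch_cm),
        centroid_depth_cm = mean(px_depth),
        mask = mask, n_pixels = sum(mask)
      ),
      class = "depth_slab"
    )
  }
  slabs
}

#' SNR versus depth profile
#'
#' For each liver depth slab (and, optionally, the whole SAT mask as one
#' depth-labeled segment) the SNR is the mean optoacoustic signal of the
#' segment divided by the noise standard deviation estimated from the
#' region above the skin line. Both linear SNR and the amplitude dB
#' convention `20 * log10(snr)` are reported, since reconstructed
#' optoacoustic images are amplitude-like.
#'
#' @param stack An [msot_stack()].
#' @param roiset A [roi_set()].
#' @param wavelength_nm Target wavelength (default 930 nm).
#' @param slab_thickness_cm Slab thickness (default 0.5 cm).
#' @param include_sat Prepend the SAT segment to the profile.
#' @return An `snr_profile`: data.frame with `segment`,
#'   `centroid_depth_cm`, `snr_linear`, `snr_db`, `n_pixels`; attribute
#'   `noise_sd`.
#' @export
snr_profile <- function(stack, roiset, wavelength_nm = 930,
                        slab_thickness_cm = 0.5, include_sat = TRUE) {
  noise <- estimate_noise(stack, wavelength_nm)
  if (noise <= 0) {
    stop("noise SD is 0: SNR undefined", call. = FALSE)
  }
  img <- plane(stack, wavelength_nm)
  row_depth <- (seq_len(nrow(img)) - roiset$skin_row) * stack$pixel_pitch_cm
  rows <- list()
  if (include_sat && any(roiset$masks$SAT)) {
    m <- roiset$masks$SAT
    rows[[1]] <- data.frame(
      segment = "SAT",
      centroid_depth_cm = mean(row_depth[row(m)[m]]),
      snr_linear = mean(img[m]) / noise, n_pixels = sum(m)
    )
  }
  slabs <- partition_liver(roiset, stack$pixel_pitch_cm, slab_thickness_cm)
  for (i in seq_along(slabs)) {
    s <- slabs[[i]]
    rows[[length(rows) + 1L]] <- data.frame(
      segment = sprintf("liver_%02d", i),
      centroid_depth_cm = s$centroid_depth_cm,
      snr_linear = mean(img[s$mask]) / noise, n_pixels = s$n_pixels
    )
  }
  out <- do.call(rbind, rows)
  out$snr_db <- ifelse(out$snr_linear > 0, 20 * log10(out$snr_linear), -Inf)
  out <- out[, c("segment", "centroid_depth_cm", "snr_linear", "snr_db",
                 "n_pixels")]
  structure(out, noise_sd = noise, wavelength_nm = wavelength_nm,
            class = c("snr_profile", "data.frame"))
}

#' Percent SNR decrease per slab step and per centimeter
#'
#' Summaries of signal decay with depth over the liver segments of an
#' [snr_profile()]: the step decrease between consecutive slabs is
#' `100 * (1 - snr[k+1] / snr[k])` on linear SNR, and the per-centimeter
#' figure rescales each step ratio geometrically (exponentially in depth),
#' `100 * (1 - (snr[k+1]/snr[k])^(1 / dz))` with `dz` the centroid depth
#' difference in cm, consistent with an exponential attenuation model.
#' Steps with zero SNR in the shallower slab are flagged and excluded from
#' the means.
#'
#' @param profile An [snr_profile()].
#' @return List with `step_decrease_pct` (per consecutive liver pair),
#'   `mean_step_decrease_pct`, `per_cm_decrease_pct`,
#'   `mean_per_cm_decrease_pct`, and `undefined_steps`.
#' @export
percent_decrease <- function(profile) {
  stopifnot(inherits(profile, "snr_profile"))
  liv <- profile[grepl("^liver", profile$segment), , drop = FALSE]
  if (nrow(liv) < 2) stop("need >= 2 liver slabs", call. = FALSE)
  liv <- liv[order(liv$centroid_depth_cm), ]
  s <- liv$snr_linear
  z <- liv$centroid_depth_cm
  k <- seq_len(nrow(liv) - 1L)
  undefined <- s[k] == 0
  ratio <- ifelse(undefined, NA_real_, s[k + 1L] / s[k])
  step <- 100 * (1 - ratio)
  per_cm <- 100 * (1 - ratio^(1 / (z[k + 1L] - z[k])))
  list(
    step_decrease_pct = step,
    mean_step_decrease_pct = mean(step, na.rm = TRUE),
    per_cm_decrease_pct = per_cm,
    mean_per_cm_decrease_pct = mean(per_cm, na.rm = TRUE),
    undefined_steps = which(undefined)
  )
}
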