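# Small in-code fixtures shared across the test files.

# A toy stack built from an explicit list of single-wavelength matrices.
toy_stack <- function(planes, start_nm = 700, step_nm = 10,
                      pixel_pitch_cm = 0.1, skin_row = 1L,
                      subject_id = "toy", cohort = "healthy") {
  # a wavelength grid needs >= 2 wavelengths; duplicate single planes
  if (length(planes) == 1) planes <- c(planes, planes)
  H <- nrow(planes[[1]])
  W <- ncol(planes[[1]])
  px <- array(0, dim = c(H, W, length(planes)))
  for (k in seq_along(planes)) px[, , k] <- planes[[k]]
  msot_stack(
    pixels = px,
    grid = wavelength_grid(start_nm, start_nm + (length(planes) - 1) * step_nm,
                           step_nm),
    pixel_pitch_cm = pixel_pitch_cm, skin_row = skin_row,
    subject_id = subject_id, cohort = cohort
  )
}

full_mask <- function(H, W, rows = seq_len(H)) {
  m <- matrix(FALSE, H, W)
  m[rows, ] <- TRUE
  m
}

# Reduced-size preset arguments used wherever many phantoms are rendered.
reduced_phantom_args <- function() {
  list(pixel_pitch_cm = 0.04, image_width_px = 16L)
}

reduced_cohort <- function(base_seed, species = "human", n_per_group = 5) {
  do.call(generate_cohort, c(
    list(n_per_group = n_per_group, base_seed = base_seed, species = species),
    reduced_phantom_args()
  ))
}

# Independent brute-force oracle for the ratio spectrum: explicit loops over
# pixels and wavelengths, no shared code with ratio_spectrum().
brute_force_ratio <- function(stack, roiset, roi_name) {
  wl <- grid_wavelengths(stack$grid)
  raw <- numeric(length(wl))
  for (k in seq_along(wl)) {
    num <- 0; nn <- 0; den <- 0; nd <- 0
    for (i in seq_len(dim(stack$pixels)[1])) {
      for (j in seq_len(dim(stack$pixels)[2])) {
        v <- stack$pixels[i, j, k]
        if (roiset$masks[[roi_name]][i, j]) { num <- num + v; nn <- nn + 1 }
        if (roiset$masks$BGR[i, j]) { den <- den + v; nd <- nd + 1 }
      }
    }
    raw[k] <- (num / nn) / (den / nd)
  }
  list(raw = raw, normalized = raw / max(raw))
}

# density_curve from an exact formula on a shared grid
analytic_curve <- function(x, mean, sd, label) {
  structure(list(x = x, y = stats::dnorm(x, mean, sd), label = label,
                 bandwidth = NA_real_),
            class = "density_curve")
}

# one-subject "group" wrapping a vector of pixel values in a toy stack
pixel_group <- function(values, ncol = 1) {
  H <- length(values) + 1
  img <- matrix(0, H, ncol)
  img[-1, 1] <- values
  st <- toy_stack(list(img), skin_row = 2L)
  liver <- matrix(FALSE, H, ncol)
  liver[-1, 1] <- TRUE
  roi <- roi_set(SAT = matrix(FALSE, H, ncol),
                 liver = liver,
                 BGR = full_mask(H, ncol, 2:H), skin_row = 2)
  list(list(stack = st, roi = roi))
}

# Construct a ratio_spectrum object directly (for tests of consumers that
# only need the numeric fields).
make_ratio_spectrum <- function(normalized, raw = normalized,
                                start_nm = 700, step_nm = 10,
                                roi_name = "liver", subject_id = "toy") {
  structure(
    list(subject_id = subject_id, roi_name = roi_name,
         wavelengths_nm = seq(start_nm, by = step_nm,
                              length.out = length(normalized)),
         raw_ratio = raw, normalized_ratio = normalized),
    class = "ratio_spectrum"
  )
}
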