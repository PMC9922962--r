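test_that("noise is estimated as the SD of the coupling-medium pixels", {
  H <- 20; W <- 10
  img <- matrix(0, H, W)
  set.seed(5)
  standoff_vals <- stats::rnorm(8 * W, mean = 2, sd = 0.3)
  img[1:8, ] <- abs(standoff_vals)
  st <- toy_stack(list(img), skin_row = 9L)
  expect_equal(estimate_noise(st, 700), stats::sd(abs(standoff_vals)))

  # constant standoff: zero noise, and SNR downstream refuses to divide
  st0 <- toy_stack(list(matrix(1, H, W)), skin_row = 9L)
  expect_equal(estimate_noise(st0, 700), 0)

  # too few standoff pixels
  st_small <- toy_stack(list(matrix(1, 4, 4)), skin_row = 3L)
  expect_error(estimate_noise(st_small, 700), ">= 50")
})

test_that("the phantom noise level is recovered from the standoff region", {
  hits <- 0L
  for (seed in 1:100) {
    ph <- generate_stack(phantom_preset(
      "human", "healthy", seed = seed, noise_sd = 0.05,
      pixel_pitch_cm = 0.04, image_width_px = 64L,
      truncate_negative = FALSE
    ))
    est <- estimate_noise(ph$stack, 930)
    if (abs(est - 0.05) / 0.05 < 0.10) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("liver slabs tile the mask in 5 mm bands anchored at its top", {
  # liver spanning depths 2.25-3.65 cm at 0.05 cm pitch
  pitch <- 0.05
  skin_row <- 5L
  H <- skin_row + round(3.7 / pitch); W <- 6
  liver_rows <- which(
    ((seq_len(H) - skin_row) * pitch) >= 2.25 &
      ((seq_len(H) - skin_row) * pitch) < 3.70 - 1e-9
  )
  roi <- roi_set(SAT = full_mask(H, W, skin_row + 1),
                 liver = full_mask(H, W, liver_rows),
                 BGR = full_mask(H, W, skin_row:H), skin_row = skin_row)
  slabs <- partition_liver(roi, pitch, 0.5)
  expect_length(slabs, 3)
  expect_equal(vapply(slabs, function(s) s$top_depth_cm, numeric(1)),
               c(2.25, 2.75, 3.25))
  # slab masks partition the liver mask
  u <- Reduce(`|`, lapply(slabs, function(s) s$mask))
  expect_identical(u, roi$masks$liver)
  for (i in seq_along(slabs)) {
    for (j in seq_along(slabs)) {
      if (i < j) expect_false(any(slabs[[i]]$mask & slabs[[j]]$mask))
    }
  }

  # liver spanning exactly one slab thickness -> a single slab
  one_rows <- which(abs((seq_len(H) - skin_row) * pitch - 2.5) < 0.25 - 1e-9)
  roi1 <- roi_set(SAT = full_mask(H, W, skin_row + 1),
                  liver = full_mask(H, W, one_rows),
                  BGR = full_mask(H, W, skin_row:H), skin_row = skin_row)
  expect_length(partition_liver(roi1, pitch, 0.5), 1)

  expect_error(
    partition_liver(roi_set(SAT = full_mask(H, W, skin_row + 1),
                            liver = matrix(FALSE, H, W),
                            BGR = full_mask(H, W, skin_row:H),
                            skin_row = skin_row), pitch),
    "empty liver"
  )
})

test_that("slab partition is exact on randomly shaped liver masks", {
  set.seed(91)
  for (rep in 1:10) {
    H <- 40; W <- 8; skin_row <- 4L
    liver <- matrix(FALSE, H, W)
    rows <- sort(sample(6:H, sample(8:25, 1)))
    for (r in rows) liver[r, sample(W, sample(1:W, 1))] <- TRUE
    roi <- roi_set(SAT = full_mask(H, W, 5), liver = liver,
                   BGR = full_mask(H, W, 4:H), skin_row = skin_row)
    slabs <- partition_liver(roi, 0.07, 0.5)
    u <- Reduce(`|`, lapply(slabs, function(s) s$mask))
    expect_identical(u, liver)
    expect_equal(sum(vapply(slabs, function(s) s$n_pixels, integer(1))),
                 sum(liver))
  }
})

test_that("SNR is segment mean over noise SD, reported in linear and dB", {
  H <- 30; W <- 10; skin_row <- 11L
  sigma <- 0.25
  img <- matrix(0, H, W)
  set.seed(6)
  img[1:10, ] <- abs(stats::rnorm(10 * W, 0, sigma))
  noise <- stats::sd(img[1:10, ])
  img[16:25, ] <- 4.97 * noise
  st <- toy_stack(list(img), skin_row = skin_row, pixel_pitch_cm = 0.05)
  roi <- roi_set(SAT = full_mask(H, W, 12:14),
                 liver = full_mask(H, W, 16:25),
                 BGR = full_mask(H, W, 11:H), skin_row = skin_row)
  prof <- snr_profile(st, roi, 700, slab_thickness_cm = 0.5)
  liv <- prof[grepl("liver", prof$segment), ]
  expect_equal(liv$snr_linear[1], 4.97, tolerance = 1e-12)
  expect_equal(liv$snr_db, 20 * log10(liv$snr_linear))
  # dB/linear round trip
  expect_equal(10^(liv$snr_db / 20), liv$snr_linear, tolerance = 1e-12)

  # an all-zero slab reports SNR 0
  img0 <- img; img0[16:25, ] <- 0
  prof0 <- snr_profile(toy_stack(list(img0), skin_row = skin_row,
                                 pixel_pitch_cm = 0.05), roi, 700)
  expect_equal(prof0$snr_linear[grepl("liver", prof0$segment)], rep(0, 1))

  # zero noise SD is a division error
  st_const <- toy_stack(list(matrix(c(rep(1, 10 * W), rep(2, 20 * W)),
                                    H, W, byrow = FALSE)), skin_row = skin_row)
  st_const$pixels[1:10, , 1] <- 1
  expect_error(snr_profile(st_const, roi, 700), "noise SD is 0")
})

test_that("SNR decreases monotonically with depth on noise-free phantoms", {
  spec <- phantom_preset("human", "healthy", noise_sd = 0,
                         pulse_jitter_cv = 0, pixel_pitch_cm = 0.02,
                         image_width_px = 8L)
  ph <- generate_stack(spec)
  # supply a reference noise level since the noise-free standoff has SD 0
  img <- ph$stack$pixels[, , 24]
  slabs <- partition_liver(ph$roi, spec$pixel_pitch_cm, 0.5)
  means <- vapply(slabs, function(s) mean(img[s$mask]), numeric(1))
  expect_true(all(diff(means) < 0))

  # log-linear fit of slab SNR vs depth recovers mu_eff within 1%
  full <- vapply(slabs, function(s) s$bottom_depth_cm - s$top_depth_cm,
                 numeric(1))
  keep <- abs(full - 0.5) < 1e-9
  z <- vapply(slabs, function(s) s$centroid_depth_cm, numeric(1))[keep]
  slope <- stats::coef(stats::lm(log(means[keep]) ~ z))[["z"]]
  expect_equal(slope, -spec$mu_eff_per_cm,
               tolerance = 0.01)
})

test_that("percent decrease summaries follow the geometric model", {
  prof <- structure(
    data.frame(
      segment = c("SAT", "liver_01", "liver_02"),
      centroid_depth_cm = c(0.4, 2.5, 3.0),
      snr_linear = c(50, 10, 5),
      snr_db = 20 * log10(c(50, 10, 5)),
      n_pixels = c(100L, 100L, 100L)
    ),
    noise_sd = 1, wavelength_nm = 930,
    class = c("snr_profile", "data.frame")
  )
  pd <- percent_decrease(prof)
  expect_equal(pd$step_decrease_pct, 50)
  expect_equal(pd$per_cm_decrease_pct, 100 * (1 - 0.5^(1 / 0.5)))

  # constant SNR: zero decrease
  prof$snr_linear <- c(50, 10, 10)
  expect_equal(percent_decrease(prof)$mean_step_decrease_pct, 0)

  # exponential SNR exp(-1.5 z): per-cm decrease 100 * (1 - exp(-1.5))
  z <- seq(2.25, 4.25, by = 0.5)
  prof_exp <- structure(
    data.frame(
      segment = sprintf("liver_%02d", seq_along(z)),
      centroid_depth_cm = z, snr_linear = exp(-1.5 * z),
      snr_db = 20 * log10(exp(-1.5 * z)), n_pixels = 10L
    ),
    noise_sd = 1, wavelength_nm = 930,
    class = c("snr_profile", "data.frame")
  )
  pd_exp <- percent_decrease(prof_exp)
  expect_equal(pd_exp$mean_per_cm_decrease_pct, 100 * (1 - exp(-1.5)),
               tolerance = 1e-9)

  # zero-SNR steps are flagged and excluded
  prof$snr_linear <- c(50, 0, 10)
  pd0 <- percent_decrease(prof)
  expect_equal(pd0$undefined_steps, 1L)
  expect_true(is.nan(pd0$mean_step_decrease_pct) ||
                is.finite(pd0$mean_step_decrease_pct))
})
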