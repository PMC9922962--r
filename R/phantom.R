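#' Tissue layer of a phantom
#'
#' @param name Layer name: `"standoff"` (acoustic coupling medium above the
#'   skin line), `"skin"`, `"SAT"`, `"other"` (unanalyzed intervening tissue,
#'   e.g. muscle/fascia between SAT and liver) or `"liver"`.
#' @param thickness_cm Depth extent of the layer (cm), > 0.
#' @param composition A [tissue_composition()]. The standoff layer must have
#'   all fractions zero: coupling medium contributes no tissue signal, only
#'   noise, which is what makes it usable as the noise-reference region.
#' @return A `layer_spec` object.
#' @export
layer_spec <- function(name, thickness_cm, composition) {
  name <- match.arg(name, c("standoff", "skin", "SAT", "other", "liver"))
  stopifnot(inherits(composition, "tissue_composition"))
  if (!(thickness_cm > 0)) stop("thickness_cm must be > 0", call. = FALSE)
  if (name == "standoff" && any(composition$fractions > 0)) {
    stop("standoff composition must have all fractions 0", call. = FALSE)
  }
  structure(
    list(name = name, thickness_cm = thickness_cm, composition = composition),
    class = "layer_spec"
  )
}

#' Phantom specification
#'
#' Describes a layered rectangular phantom: a stack of horizontal tissue
#' layers under a coupling-medium standoff, imaged on a regular pixel grid at
#' each wavelength of `grid`. The forward model for a tissue pixel at depth
#' `z` below the skin line and wavelength `lambda` is
#' \deqn{p(z, \lambda) = \Gamma \, \mu_a(\lambda) \, e^{-\mu_{eff} z}
#'   \, j(\lambda) + \epsilon,}
#' with `j(lambda)` a per-wavelength multiplicative pulse-energy factor
#' (mean 1, coefficient of variation `pulse_jitter_cv`) and
#' `epsilon ~ Normal(0, noise_sd)`. Negative values are clipped at 0 by
#' default, mirroring the non-negativity constraint of tomographic
#' reconstruction. Standoff rows carry noise only.
#'
#' @param grid A [wavelength_grid()].
#' @param layers List of [layer_spec()]s, top to bottom, starting with a
#'   standoff layer. Total thickness must not exceed the image height.
#' @param pixel_pitch_cm Spatial sampling (cm per pixel).
#' @param image_height_px,image_width_px Image extents in pixels.
#' @param mu_eff_per_cm Effective optical attenuation rate (1/cm), >= 0;
#'   single-exponential and wavelength-independent.
#' @param noise_sd Additive noise standard deviation (signal units), >= 0.
#' @param pulse_jitter_cv Coefficient of variation of the per-wavelength
#'   pulse-energy factor, >= 0.
#' @param seed Optional integer seed; same seed, same phantom, bit for bit.
#' @param truncate_negative Clip negative pixel values at 0 (default `TRUE`).
#'   Disable only to inspect the untruncated noise distribution.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid, layers, pixel_pitch_cm,
                         image_height_px, image_width_px,
                         mu_eff_per_cm = 1.0, noise_sd = 0,
                         pulse_jitter_cv = 0, seed = NULL,
                         truncate_negative = TRUE) {
  stopifnot(inherits(grid, "wavelength_grid"), length(layers) >= 2)
  for (l in layers) stopifnot(inherits(l, "layer_spec"))
  if (layers[[1]]$name != "standoff") {
    stop("layers must begin with a standoff layer", call. = FALSE)
  }
  if (!(mu_eff_per_cm >= 0)) stop("mu_eff_per_cm must be >= 0", call. = FALSE)
  if (!(noise_sd >= 0)) stop("noise_sd must be >= 0", call. = FALSE)
  if (!(pulse_jitter_cv >= 0)) {
    stop("pulse_jitter_cv must be >= 0", call. = FALSE)
  }
  total <- sum(vapply(layers, function(l) l$thickness_cm, numeric(1)))
  if (total > image_height_px * pixel_pitch_cm + 1e-9) {
    stop("total layer thickness exceeds the image height", call. = FALSE)
  }
  structure(
    list(
      grid = grid, layers = layers, pixel_pitch_cm = pixel_pitch_cm,
      image_height_px = as.integer(image_height_px),
      image_width_px = as.integer(image_width_px),
      mu_eff_per_cm = mu_eff_per_cm, noise_sd = noise_sd,
      pulse_jitter_cv = pulse_jitter_cv, seed = seed,
      truncate_negative = truncate_negative
    ),
    class = "phantom_spec"
  )
}

# Default tissue compositions (volume fractions against the packaged
# reference spectra), calibrated so the noise-free normalized liver ratio
# at 930 nm lands near the study anchors (healthy ~0.22-0.5, steatosis
# ~0.74-0.83 depending on species) with the SAT curve peaking at 930 nm.
# Healthy liver is blood-rich and venous-dominated (18% blood, SO2 0.55);
# severe steatosis displaces blood and water with lipid (55%) and gains
# optoacoustic efficiency through the Grueneisen-lipid rule.
preset_compositions <- function() {
  list(
    standoff = tissue_composition(),
    skin = tissue_composition(
      oxyhemoglobin = 0.0195, deoxyhemoglobin = 0.0105,
      lipid = 0.10, water = 0.50
    ),
    SAT = tissue_composition(
      oxyhemoglobin = 0.026, deoxyhemoglobin = 0.014,
      lipid = 0.55, water = 0.30
    ),
    other = tissue_composition(
      oxyhemoglobin = 0.013, deoxyhemoglobin = 0.007,
      lipid = 0.02, water = 0.65
    ),
    liver_healthy = tissue_composition(
      oxyhemoglobin = 0.099, deoxyhemoglobin = 0.081,
      lipid = 0.05, water = 0.50
    ),
    liver_steatosis = tissue_composition(
      oxyhemoglobin = 0.0275, deoxyhemoglobin = 0.0225,
      lipid = 0.55, water = 0.30
    )
  )
}

#' Phantom presets for the two study designs
#'
#' Builds a concrete [phantom_spec()] for the clinical hand-held geometry
#' (`"human"`: 700--970 nm grid, 0.3 cm standoff, 0.1 cm skin, 0.8 cm SAT
#' thickened to 1.6 cm in the steatosis cohort, a 1.35 cm unanalyzed
#' muscle/fascia spacer, liver to the image bottom) or the small-animal
#' geometry (`"mouse"`: 680--960 nm grid, shallower layers, no spacer).
#' The cohorts differ in SAT thickness and liver composition only.
#'
#' @param species `"human"` or `"mouse"`.
#' @param cohort `"healthy"` or `"steatosis"`.
#' @param sat_scale,liver_lipid_scale,blood_scale Multiplicative
#'   perturbations of SAT thickness, liver lipid fraction, and all blood
#'   fractions; used by [generate_cohort()] to inject between-subject
#'   variability.
#' @param pixel_pitch_cm,image_width_px Spatial sampling overrides; the
#'   image height follows from the layer thicknesses.
#' @param mu_eff_per_cm,noise_sd,pulse_jitter_cv,seed,truncate_negative
#'   Forwarded to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
phantom_preset <- function(species = c("human", "mouse"),
                           cohort = c("healthy", "steatosis"),
                           sat_scale = 1, liver_lipid_scale = 1,
                           blood_scale = 1,
                           pixel_pitch_cm = 0.01, image_width_px = 64L,
                           mu_eff_per_cm = 1.3, noise_sd = 5e-4,
                           pulse_jitter_cv = 0.05, seed = NULL,
                           truncate_negative = TRUE) {
  species <- match.arg(species)
  cohort <- match.arg(cohort)
  comps <- preset_compositions()

  liver0 <- if (cohort == "healthy") comps$liver_healthy else
    comps$liver_steatosis
  fr <- liver0$fractions
  fr[["lipid"]] <- min(fr[["lipid"]] * liver_lipid_scale, 1)
  liver <- tissue_composition(
    oxyhemoglobin = fr[["oxyhemoglobin"]] * blood_scale,
    deoxyhemoglobin = fr[["deoxyhemoglobin"]] * blood_scale,
    lipid = fr[["lipid"]], water = fr[["water"]]
  )
  scale_blood <- function(comp) {
    f <- comp$fractions
    tissue_composition(
      oxyhemoglobin = f[["oxyhemoglobin"]] * blood_scale,
      deoxyhemoglobin = f[["deoxyhemoglobin"]] * blood_scale,
      lipid = f[["lipid"]], water = f[["water"]]
    )
  }

  if (species == "human") {
    grid <- wavelength_grid(700, 970, 10)
    sat_thick <- (if (cohort == "healthy") 0.8 else 1.6) * sat_scale
    depth_cm <- 4.8
    layers <- list(
      layer_spec("standoff", 0.3, comps$standoff),
      layer_spec("skin", 0.1, scale_blood(comps$skin)),
      layer_spec("SAT", sat_thick, scale_blood(comps$SAT)),
      layer_spec("other", 1.35, scale_blood(comps$other)),
      layer_spec("liver", depth_cm - 0.3 - 0.1 - sat_thick - 1.35, liver)
    )
  } else {
    grid <- wavelength_grid(680, 960, 10)
    sat_thick <- (if (cohort == "healthy") 0.3 else 0.6) * sat_scale
    depth_cm <- 2.0
    layers <- list(
      layer_spec("standoff", 0.2, comps$standoff),
      layer_spec("skin", 0.05, scale_blood(comps$skin)),
      layer_spec("SAT", sat_thick, scale_blood(comps$SAT)),
      layer_spec("liver", depth_cm - 0.2 - 0.05 - sat_thick, liver)
    )
  }
  phantom_spec(
    grid = grid, layers = layers, pixel_pitch_cm = pixel_pitch_cm,
    image_height_px = as.integer(round(depth_cm / pixel_pitch_cm)),
    image_width_px = image_width_px,
    mu_eff_per_cm = mu_eff_per_cm, noise_sd = noise_sd,
    pulse_jitter_cv = pulse_jitter_cv, seed = seed,
    truncate_negative = truncate_negative
  )
}

with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

layer_row_ranges <- function(spec) {
  thick <- vapply(spec$layers, function(l) l$thickness_cm, numeric(1))
  bounds <- round(cumsum(c(0, thick)) / spec$pixel_pitch_cm)
  bounds[length(bounds)] <- min(bounds[length(bounds)], spec$image_height_px)
  lapply(seq_along(spec$layers), function(i) {
    lo <- bounds[i] + 1L
    hi <- bounds[i + 1L]
    if (lo > hi) integer(0) else seq.int(lo, hi)
  })
}

#' Generate a synthetic multispectral stack with ground-truth ROIs
#'
#' Renders a [phantom_spec()] to an `msot_stack` (a non-negative
#' `rows x cols x wavelengths` pixel array with spatial and spectral
#' metadata) and the matching [roi_set()]: SAT and liver masks exactly equal
#' to the generating layers, and a background region (BGR) covering the
#' entire imaged tissue, SAT and liver included.
#'
#' @param spec A [phantom_spec()].
#' @param subject_id Subject identifier stored on the stack.
#' @param cohort Cohort label in `{"healthy", "steatosis"}` stored on the
#'   stack (metadata only; the spec's layers define the actual tissue).
#' @return A list with elements `stack` (`msot_stack`) and `roi` (`roi_set`).
#' @examples
#' ph <- generate_stack(phantom_preset("human", "healthy", seed = 1))
#' dim(ph$stack$pixels)
#' @export
generate_stack <- function(spec, subject_id = "phantom",
                           cohort = c("healthy", "steatosis")) {
  stopifnot(inherits(spec, "phantom_spec"))
  cohort <- match.arg(cohort)
  H <- spec$image_height_px
  W <- spec$image_width_px
  wl <- grid_wavelengths(spec$grid)
  L <- length(wl)
  spectra <- load_builtin_spectra(spec$grid)

  ranges <- layer_row_ranges(spec)
  skin_row <- length(ranges[[1]]) + 1L # first tissue row (1-based)
  depth <- (seq_len(H) - skin_row) * spec$pixel_pitch_cm

  with_local_seed(spec$seed, {
    j <- if (spec$pulse_jitter_cv > 0) {
      stats::rnorm(L, mean = 1, sd = spec$pulse_jitter_cv)
    } else {
      rep(1, L)
    }
    # depth x wavelength signal template, constant across columns
    base <- matrix(0, H, L)
    for (i in seq_along(spec$layers)) {
      l <- spec$layers[[i]]
      rows <- ranges[[i]]
      if (l$name == "standoff" || !length(rows)) next
      mu <- mix_absorption(l$composition, spectra)
      base[rows, ] <- exp(-spec$mu_eff_per_cm * depth[rows]) %o%
        (l$composition$grueneisen * mu * j)
    }
    pixels <- array(0, dim = c(H, W, L))
    for (k in seq_len(L)) {
      pixels[, , k] <- matrix(base[, k], H, W)
    }
    if (spec$noise_sd > 0) {
      pixels <- pixels + stats::rnorm(length(pixels), sd = spec$noise_sd)
    }
    if (spec$truncate_negative) pixels[pixels < 0] <- 0

    full <- matrix(FALSE, H, W)
    mask_of <- function(rows) {
      m <- full
      if (length(rows)) m[rows, ] <- TRUE
      m
    }
    name_of <- vapply(spec$layers, function(l) l$name, character(1))
    tissue_rows <- sort(unlist(ranges[name_of != "standoff"]))
    roi <- roi_set(
      SAT = mask_of(unlist(ranges[name_of == "SAT"])),
      liver = mask_of(unlist(ranges[name_of == "liver"])),
      BGR = mask_of(tissue_rows),
      skin_row = skin_row
    )
    stack <- if (spec$truncate_negative) {
      msot_stack(
        pixels = pixels, grid = spec$grid,
        pixel_pitch_cm = spec$pixel_pitch_cm, skin_row = skin_row,
        subject_id = subject_id, cohort = cohort
      )
    } else {
      # diagnostic mode: keep the untruncated noise, bypassing the
      # non-negativity contract the constructor enforces
      structure(
        list(pixels = pixels, grid = spec$grid,
             pixel_pitch_cm = spec$pixel_pitch_cm,
             skin_row = skin_row, subject_id = subject_id, cohort = cohort),
        class = "msot_stack"
      )
    }
    list(stack = stack, roi = roi)
  })
}

#' Generate matched healthy and steatosis phantom cohorts
#'
#' Renders `n_per_group` subjects per cohort with deterministic per-subject
#' seeds derived from `base_seed` and bounded between-subject variability:
#' SAT thickness and liver lipid fraction each scaled by Uniform(0.85, 1.15)
#' and blood fractions by Uniform(0.9, 1.1), drawn per subject.
#'
#' @param n_per_group Subjects per cohort, >= 2 (the study design used 5).
#' @param base_seed Integer seed from which all per-subject seeds derive.
#' @param species `"human"` or `"mouse"` preset.
#' @param perturb Logical; disable to render every subject from the
#'   unperturbed cohort template (variation then comes from noise only).
#' @param ... Further arguments to [phantom_preset()] (e.g.
#'   `pixel_pitch_cm`, `image_width_px` to scale the simulation down).
#' @return A list with elements `healthy` and `steatosis`, each a list of
#'   `n_per_group` subjects as returned by [generate_stack()].
#' @export
generate_cohort <- function(n_per_group = 5, base_seed = 1,
                            species = c("human", "mouse"),
                            perturb = TRUE, ...) {
  species <- match.arg(species)
  if (n_per_group < 2) stop("n_per_group must be >= 2", call. = FALSE)
  n <- as.integer(n_per_group)
  draws <- with_local_seed(base_seed, {
    list(
      seeds = sample.int(.Machine$integer.max - 1L, 2L * n),
      sat = stats::runif(2L * n, 0.85, 1.15),
      lip = stats::runif(2L * n, 0.85, 1.15),
      blood = stats::runif(2L * n, 0.90, 1.10)
    )
  })
  make <- function(cohort, i, k) {
    spec <- phantom_preset(
      species, cohort,
      sat_scale = if (perturb) draws$sat[k] else 1,
      liver_lipid_scale = if (perturb) draws$lip[k] else 1,
      blood_scale = if (perturb) draws$blood[k] else 1,
      seed = draws$seeds[k], ...
    )
    generate_stack(spec, subject_id = sprintf("%s_%s_%02d", species, cohort, i),
                   cohort = cohort)
  }
  list(
    healthy = lapply(seq_len(n), function(i) make("healthy", i, i)),
    steatosis = lapply(seq_len(n), function(i) make("steatosis", i, n + i))
  )
}
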