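#' Pool liver pixels across a group's subjects
#'
#' @param subjects List of subjects, each a list with elements `stack`
#'   ([msot_stack()]) and `roi` ([roi_set()]), as produced by
#'   [generate_cohort()].
#' @param wavelength_nm Wavelength, exact grid member.
#' @param roi_name Mask to pool from (default `"liver"`).
#' @return List with `pooled` (numeric vector over all subjects) and
#'   `per_subject` (named list of per-subject vectors).
#' @export
pool_pixels <- function(subjects, wavelength_nm, roi_name = "liver") {
  per <- lapply(subjects, function(s) {
    img <- plane(s$stack, wavelength_nm)
    img[s$roi$masks[[roi_name]]]
  })
  names(per) <- vapply(subjects, function(s) s$stack$subject_id,
                       character(1))
  list(pooled = unlist(per, use.names = FALSE), per_subject = per)
}

density_curve <- function(x, y, label, bandwidth) {
  structure(list(x = x, y = y, label = label, bandwidth = bandwidth),
            class = "density_curve")
}

#' @export
print.density_curve <- function(x, ...) {
  cat(sprintf(
    "<density_curve> %s: %d grid points on [%.3g, %.3g], mode at %.4g\n",
    x$label, length(x$x), min(x$x), max(x$x), x$x[which.max(x$y)]
  ))
  invisible(x)
}

#' Pooled pixel-intensity density curves for two groups
#'
#' Pools all liver pixels of each group's subjects at the target wavelength
#' and estimates each group's intensity density on one shared evaluation
#' grid, either by Gaussian kernel density estimation with Silverman's
#' bandwidth (default) or by a shared-bin histogram.
#'
#' @param group_a,group_b Subject lists (see [pool_pixels()]).
#' @param wavelength_nm Target wavelength (default 930 nm).
#' @param method `"kde"` or `"hist"`.
#' @param n_grid Evaluation grid size (kde) .
#' @param bw Bandwidth rule or numeric bandwidth passed to
#'   [stats::density()].
#' @param bins Bin count (hist).
#' @param labels Group labels.
#' @return List of two `density_curve`s (`a`, `b`) sharing an evaluation
#'   grid; each integrates to 1 (trapezoid) within discretization error.
#' @export
pooled_density <- function(group_a, group_b, wavelength_nm = 930,
                           method = c("kde", "hist"), n_grid = 512,
                           bw = "nrd0", bins = 64,
                           labels = c("healthy", "steatosis")) {
  method <- match.arg(method)
  va <- pool_pixels(group_a, wavelength_nm)$pooled
  vb <- pool_pixels(group_b, wavelength_nm)$pooled
  if (!length(va) || !length(vb)) stop("empty pixel pool", call. = FALSE)
  if (method == "kde") {
    bwa <- if (is.numeric(bw)) bw else stats::bw.nrd0(va)
    bwb <- if (is.numeric(bw)) bw else stats::bw.nrd0(vb)
    lo <- min(va, vb) - 3 * max(bwa, bwb)
    hi <- max(va, vb) + 3 * max(bwa, bwb)
    da <- stats::density(va, bw = bwa, from = lo, to = hi, n = n_grid)
    db <- stats::density(vb, bw = bwb, from = lo, to = hi, n = n_grid)
    list(
      a = density_curve(da$x, da$y, labels[1], da$bw),
      b = density_curve(db$x, db$y, labels[2], db$bw)
    )
  } else {
    breaks <- seq(min(va, vb), max(va, vb), length.out = bins + 1L)
    mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
    w <- diff(breaks)[1]
    ha <- graphics::hist(va, breaks = breaks, plot = FALSE)
    hb <- graphics::hist(vb, breaks = breaks, plot = FALSE)
    list(
      a = density_curve(mids, ha$density, labels[1], w),
      b = density_curve(mids, hb$density, labels[2], w)
    )
  }
}

#' Density-intersection threshold
#'
#' The classification threshold is the intensity at which the two groups'
#' density curves cross, located between their global modes. The crossing
#' is found as a sign change of the density difference on the shared grid
#' and refined by linear interpolation between the bracketing grid points.
#' If several crossings lie between the modes, the one closest to the
#' midpoint of the modes is returned and all candidates are reported.
#'
#' @param curve_a,curve_b `density_curve`s on one shared grid, each with a
#'   unique global mode; the modes must differ.
#' @return List with `threshold`, `candidates` (all crossings between the
#'   modes) and `modes` (the two mode locations).
#' @export
find_threshold <- function(curve_a, curve_b) {
  stopifnot(inherits(curve_a, "density_curve"),
            inherits(curve_b, "density_curve"))
  x <- curve_a$x
  if (length(x) != length(curve_b$x) || any(abs(x - curve_b$x) > 1e-12)) {
    stop("curves do not share an evaluation grid", call. = FALSE)
  }
  mode_of <- function(cv) {
    i <- which(cv$y == max(cv$y))
    if (length(i) > 1) {
      stop(sprintf("density '%s' has a tied global mode", cv$label),
           call. = FALSE)
    }
    i
  }
  ia <- mode_of(curve_a)
  ib <- mode_of(curve_b)
  if (x[ia] == x[ib]) stop("the two modes coincide", call. = FALSE)
  lo <- min(ia, ib)
  hi <- max(ia, ib)
  d <- curve_a$y - curve_b$y
  candidates <- numeric(0)
  for (i in seq.int(lo, hi - 1L)) {
    if (d[i] == 0) {
      candidates <- c(candidates, x[i])
    } else if (d[i] * d[i + 1L] < 0) {
      frac <- d[i] / (d[i] - d[i + 1L])
      candidates <- c(candidates, x[i] + frac * (x[i + 1L] - x[i]))
    }
  }
  if (d[hi] == 0) candidates <- c(candidates, x[hi])
  if (!length(candidates)) {
    stop(sprintf(
      "no density intersection between the modes (%.4g and %.4g)",
      x[ia], x[ib]
    ), call. = FALSE)
  }
  mid <- (x[ia] + x[ib]) / 2
  list(
    threshold = candidates[which.min(abs(candidates - mid))],
    candidates = candidates,
    modes = c(x[ia], x[ib])
  )
}

two_proportion_z <- function(x1, n1, x2, n2) {
  phat <- (x1 + x2) / (n1 + n2)
  if (phat == 0 || phat == 1) {
    warning("degenerate pooled proportion (all pixels on one side); p = 1",
            call. = FALSE)
    return(list(z = 0, p = 1))
  }
  z <- (x1 / n1 - x2 / n2) /
    sqrt(phat * (1 - phat) * (1 / n1 + 1 / n2))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Proportion of liver pixels above a threshold, with a two-group test
#'
#' Computes the per-subject proportion of liver pixels exceeding the
#' threshold, then tests the group difference. The default (`"pooled"`)
#' test is a two-sided two-sample proportion z-test on the pooled pixel
#' counts; because pooled pixels within a subject are not independent, a
#' cluster-aware alternative (`"subject"`: Welch t-test on the
#' subject-level proportions) is also provided and is the statistically
#' safer choice.
#'
#' @param group_a,group_b Subject lists (see [pool_pixels()]).
#' @param wavelength_nm Target wavelength (default 930 nm).
#' @param threshold Finite intensity threshold.
#' @param method `"pooled"` or `"subject"`.
#' @param labels Group labels.
#' @return A `threshold_result`: list with `threshold`, per-group
#'   `proportions` (per subject), pooled `counts`, `statistic`, `p_value`
#'   and `method`.
#' @export
proportions_above <- function(group_a, group_b, wavelength_nm = 930,
                              threshold, method = c("pooled", "subject"),
                              labels = c("healthy", "steatosis")) {
  method <- match.arg(method)
  if (!is.finite(threshold)) stop("threshold must be finite", call. = FALSE)
  per_group <- function(subjects) {
    px <- pool_pixels(subjects, wavelength_nm)$per_subject
    keep <- vapply(px, length, integer(1)) > 0
    if (any(!keep)) {
      warning("skipping subject(s) with empty liver mask: ",
              paste(names(px)[!keep], collapse = ", "), call. = FALSE)
      px <- px[keep]
    }
    list(
      prop = vapply(px, function(v) mean(v > threshold), numeric(1)),
      above = sum(vapply(px, function(v) sum(v > threshold), numeric(1))),
      total = sum(vapply(px, length, integer(1)))
    )
  }
  ga <- per_group(group_a)
  gb <- per_group(group_b)
  if (method == "pooled") {
    ts <- two_proportion_z(ga$above, ga$total, gb$above, gb$total)
    statistic <- ts$z
    p <- ts$p
  } else {
    tt <- stats::t.test(ga$prop, gb$prop)
    statistic <- unname(tt$statistic)
    p <- tt$p.value
  }
  structure(
    list(
      threshold = threshold,
      proportions = stats::setNames(list(ga$prop, gb$prop), labels),
      counts = data.frame(
        group = labels, above = c(ga$above, gb$above),
        total = c(ga$total, gb$total)
      ),
      statistic = statistic, p_value = p, method = method
    ),
    class = "threshold_result"
  )
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(
    "<threshold_result> threshold=%.4g (%s test): z/t=%.3f, p=%.3g\n",
    x$threshold, x$method, x$statistic, x$p_value
  ))
  with(x$counts, cat(sprintf("  %s: %d/%d above\n", group, above, total)))
  invisible(x)
}
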