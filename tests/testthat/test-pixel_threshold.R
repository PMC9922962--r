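test_that("pooled densities are normalized, non-negative, and locate group modes", {
  set.seed(14)
  ga <- pixel_group(abs(stats::rnorm(400, 1, 0.3)))
  gb <- pixel_group(abs(stats::rnorm(400, 3, 0.3)))
  d <- pooled_density(ga, gb, wavelength_nm = 700)
  for (cv in d) {
    expect_true(all(cv$y >= 0))
    area <- sum(diff(cv$x) * (head(cv$y, -1) + tail(cv$y, -1)) / 2)
    expect_equal(area, 1, tolerance = 1e-3)
  }
  expect_equal(d$a$x, d$b$x) # shared evaluation grid
  expect_lt(abs(d$a$x[which.max(d$a$y)] - 1), 3 * d$a$bandwidth)
  expect_lt(abs(d$b$x[which.max(d$b$y)] - 3), 3 * d$b$bandwidth)

  dh <- pooled_density(ga, gb, wavelength_nm = 700, method = "hist")
  for (cv in dh) {
    expect_true(all(cv$y >= 0))
    expect_equal(sum(cv$y * cv$bandwidth), 1, tolerance = 1e-9)
  }
})

test_that("density intersection reproduces analytic Gaussian crossings", {
  x <- seq(-5, 8, length.out = 4001)
  step <- diff(x)[1]

  # equal-variance, equal-weight: symmetry forces the midpoint
  thr1 <- find_threshold(analytic_curve(x, 0, 1, "a"),
                         analytic_curve(x, 2, 1, "b"))
  expect_equal(thr1$threshold, 1.0, tolerance = step)
  thr2 <- find_threshold(analytic_curve(x, 0, 1, "a"),
                         analytic_curve(x, 3, 1, "b"))
  expect_equal(thr2$threshold, 1.5, tolerance = step)

  # unequal spreads: closed-form root of the equal-density quadratic
  m1 <- 0; s1 <- 1; m2 <- 2; s2 <- 2
  A <- 1 / s1^2 - 1 / s2^2
  B <- -2 * (m1 / s1^2 - m2 / s2^2)
  C <- m1^2 / s1^2 - m2^2 / s2^2 - 2 * log(s2 / s1)
  roots <- (-B + c(-1, 1) * sqrt(B^2 - 4 * A * C)) / (2 * A)
  root_between <- roots[roots > m1 & roots < m2]
  thr3 <- find_threshold(analytic_curve(x, m1, s1, "a"),
                         analytic_curve(x, m2, s2, "b"))
  expect_equal(thr3$threshold, root_between, tolerance = step)

  # exchanging the group labels leaves the threshold unchanged
  thr3_swapped <- find_threshold(analytic_curve(x, m2, s2, "b"),
                                 analytic_curve(x, m1, s1, "a"))
  expect_equal(thr3_swapped$threshold, thr3$threshold)
})

test_that("degenerate density geometries are rejected with diagnostics", {
  x <- seq(0, 3, length.out = 4)
  mk <- function(y, label) {
    structure(list(x = x, y = y, label = label, bandwidth = NA_real_),
              class = "density_curve")
  }
  # one curve everywhere above the other between the modes
  expect_error(find_threshold(mk(c(5, 4, 3, 2), "a"),
                              mk(c(1, 1.1, 1.2, 1.3), "b")),
               "no density intersection")
  # coincident modes
  expect_error(find_threshold(mk(c(1, 3, 2, 1), "a"),
                              mk(c(0.5, 2, 1, 0.5), "b")), "coincide")
  # mismatched grids
  other <- structure(list(x = x + 0.5, y = c(1, 2, 1, 0.5), label = "c",
                          bandwidth = NA_real_), class = "density_curve")
  expect_error(find_threshold(mk(c(1, 3, 2, 1), "a"), other), "share")
})

test_that("the two-proportion z-test matches the closed form and prop.test", {
  ga <- pixel_group(c(rep(1, 30), rep(0.1, 70)))
  gb <- pixel_group(c(rep(1, 70), rep(0.1, 30)))
  res <- proportions_above(ga, gb, 700, threshold = 0.5)
  phat <- 0.5
  z_expected <- (0.3 - 0.7) / sqrt(phat * (1 - phat) * (2 / 100))
  expect_equal(res$statistic, z_expected, tolerance = 1e-12)
  expect_equal(abs(z_expected), 4 / sqrt(0.5), tolerance = 1e-12)
  expect_lt(res$p_value, 0.001)

  ref <- stats::prop.test(c(30, 70), c(100, 100), correct = FALSE)
  expect_equal(res$statistic^2, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("threshold classification handles degenerate and null cases", {
  g <- pixel_group(seq(1, 2, length.out = 50))
  # threshold below every pixel: all proportions 1, degenerate test
  expect_warning(res <- proportions_above(g, g, 700, threshold = 0.5),
                 "degenerate")
  expect_true(all(unlist(res$proportions) == 1))
  expect_equal(res$p_value, 1)

  # identical groups: z = 0, p = 1
  res0 <- proportions_above(g, g, 700, threshold = 1.5)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)

  # subject-level variant runs a t-test on per-subject proportions
  set.seed(3)
  many_a <- c(pixel_group(stats::runif(60)), pixel_group(stats::runif(60)),
              pixel_group(stats::runif(60)))
  many_b <- c(pixel_group(stats::runif(60, 0.3, 1.3)),
              pixel_group(stats::runif(60, 0.3, 1.3)),
              pixel_group(stats::runif(60, 0.3, 1.3)))
  res_subj <- proportions_above(many_a, many_b, 700, threshold = 0.7,
                                method = "subject")
  expect_equal(res_subj$method, "subject")
  expect_length(res_subj$proportions[[1]], 3)
  expect_error(proportions_above(g, g, 700, threshold = Inf), "finite")
})

test_that("steatosis pools more above-threshold pixels than healthy cohorts", {
  wins <- 0L
  for (seed in 1:10) {
    co <- reduced_cohort(base_seed = 400 + seed)
    d <- pooled_density(co$healthy, co$steatosis)
    thr <- find_threshold(d$a, d$b)
    res <- proportions_above(co$healthy, co$steatosis,
                             threshold = thr$threshold)
    pa <- res$counts$above / res$counts$total
    if (pa[2] > pa[1]) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("the subject-level test holds its size under the null", {
  rejections <- 0L
  for (seed in 1:30) {
    a <- reduced_cohort(base_seed = 900 + seed)$healthy
    b <- reduced_cohort(base_seed = 950 + seed)$healthy
    res <- proportions_above(a, b, threshold = 0.002, method = "subject")
    if (res$p_value < 0.05) rejections <- rejections + 1L
  }
  expect_lte(rejections, 5L)
})
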