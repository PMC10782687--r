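test_that("spectrum container validates and orders its grid", {
  s <- ftir_spectrum(c(1000, 996, 992), c(3, 2, 1))
  expect_equal(s$wavenumbers, c(992, 996, 1000))   # stored ascending
  expect_equal(s$absorbance, c(1, 2, 3))
  expect_error(ftir_spectrum(c(1, 2), 1), "equal length")
  expect_error(ftir_spectrum(c(1, 2, 2), c(1, 2, 3)), "monotone")
  expect_error(ftir_spectrum(c(1, 2, 3), c(1, NA, 3)), "finite")
})

test_that("replicate averaging reduces noise like 1/sqrt(n)", {
  w <- seq(600, 4000, by = 4)
  base <- synthetic_spectrum(peaks = data.frame(center = 1200, height = 1,
                                                width = 40))
  expect_equal(average_replicates(list(base, base))$absorbance,
               base$absorbance)
  expect_equal(average_replicates(list(base))$absorbance, base$absorbance)

  set.seed(61)
  sd0 <- 0.05
  reps <- lapply(1:64, function(i)
    ftir_spectrum(w, base$absorbance + rnorm(length(w), sd = sd0)))
  avg <- average_replicates(reps)
  resid_sd <- sd(avg$absorbance - base$absorbance)
  expect_equal(resid_sd, sd0 / 8, tolerance = 0.15)

  bad <- ftir_spectrum(w + 2, base$absorbance)
  expect_error(average_replicates(list(base, bad)), "common wavenumber grid")
})

test_that("baseline correction removes lines and recovers peaks", {
  w <- seq(600, 4000, by = 4)
  line <- ftir_spectrum(w, 0.2 + 1e-4 * w)
  expect_lt(max(abs(baseline_correct(line)$absorbance)), 1e-12)

  flat <- ftir_spectrum(w, rep(0, length(w)))
  expect_equal(baseline_correct(flat)$absorbance, rep(0, length(w)))

  # Gaussian peak on a linear ramp: height recovered within 1%
  peak <- 0.8 * exp(-0.5 * ((w - 2300) / 60)^2)
  ramp <- 0.1 + 5e-5 * w
  s <- ftir_spectrum(w, peak + ramp)
  corr <- baseline_correct(s)
  expect_equal(max(corr$absorbance), 0.8, tolerance = 0.01)
  corr_rb <- baseline_correct(s, method = "rubberband")
  expect_equal(max(corr_rb$absorbance), 0.8, tolerance = 0.01)
  expect_error(baseline_correct(s, method = "spline"))
})

test_that("unit-area normalisation has its defining and invariance properties", {
  w <- seq(600, 4000, by = 4)
  s <- synthetic_spectrum(peaks = data.frame(center = c(1100, 1500),
                                             height = c(1, 2),
                                             width = c(50, 80)),
                          baseline = 0.1)
  ns <- normalize_unit_area(s)
  grid <- w[w >= 900 & w <= 1800]
  vals <- approx(ns$wavenumbers, ns$absorbance, xout = grid)$y
  area <- sum(diff(grid) * (head(vals, -1) + tail(vals, -1)) / 2)
  expect_equal(area, 1, tolerance = 1e-9)

  # scaling the input changes nothing; normalising twice changes nothing
  s5 <- ftir_spectrum(w, 5 * s$absorbance)
  expect_equal(normalize_unit_area(s5)$absorbance, ns$absorbance,
               tolerance = 1e-12)
  expect_equal(normalize_unit_area(ns)$absorbance, ns$absorbance,
               tolerance = 1e-12)

  # constant c over the window normalises to 1/900
  cs <- normalize_unit_area(ftir_spectrum(w, rep(3, length(w))))
  expect_equal(unique(round(cs$absorbance, 12)), 1 / 900)

  expect_error(normalize_unit_area(ftir_spectrum(w, rep(0, length(w)))),
               "area")
  expect_error(normalize_unit_area(ftir_spectrum(seq(1000, 2000, 4),
                                                 rep(1, 251))),
               "beyond the spectrum grid")
})

test_that("band values sample, interpolate and respect linearity", {
  w <- seq(600, 4000, by = 4)
  bands <- default_bands()
  const <- ftir_spectrum(w, rep(0.37, length(w)))
  for (b in bands) expect_equal(band_value(const, b), 0.37)

  # triangular peak centred at 970: the five 10 cm-1 samples interpolate
  # linearly, so the band mean has a closed form
  tri <- pmax(0, 1 - abs(w - 970) / 25)
  s <- ftir_spectrum(w, tri)
  pts <- c(950, 960, 970, 980, 990)
  expected <- mean(approx(w, tri, xout = pts)$y)
  expect_equal(band_value(s, bands$LMP), expected, tolerance = 1e-12)
  hand <- mean(pmax(0, 1 - abs(pts - 970) / 25))
  # the 4 cm-1 grid clips the apex slightly, so allow interpolation error
  expect_lt(abs(band_value(s, bands$LMP) - hand), 0.02)

  # linear in absorbance, invariant under grid reversal
  s2 <- ftir_spectrum(w, 2 * tri + 0.1)
  expect_equal(band_value(s2, bands$LMP),
               2 * band_value(s, bands$LMP) + 0.1, tolerance = 1e-12)
  srev <- ftir_spectrum(rev(w), rev(tri))
  expect_equal(band_value(srev, bands$LMP), band_value(s, bands$LMP))

  expect_error(band_value(s, band_definition("X", c(100, 200))),
               "outside the spectrum grid")
  expect_error(band_definition("X", list(c(1, 2), c(1.5, 3))), "overlap")

  # discontinuous SAM sub-segments are supported
  sam2 <- band_definition("SAM", list(c(1470, 1520), c(1560, 1630)))
  expect_equal(band_value(const, sam2), 0.37)
})

test_that("the demo spectrum is calibrated to the published band means", {
  s <- demo_spectrum()
  bands <- default_bands()
  expect_equal(band_value(s, bands$LMP), 0.5512, tolerance = 1e-6)
  expect_equal(band_value(s, bands$SAM), 3.9617, tolerance = 1e-6)
  expect_equal(band_value(s, bands$GSH), 0.0051, tolerance = 1e-6)
})

test_that("the full pipeline recovers generating band contrasts under noise", {
  w <- seq(600, 4000, by = 4)
  set.seed(91)
  make_sample <- function(lmp_height) {
    reps <- lapply(1:16, function(i)
      synthetic_spectrum(
        peaks = data.frame(center = c(970, 1550), height = c(lmp_height, 1.5),
                           width = c(30, 70)),
        baseline = c(0.05, 0.02), noise_sd = 0.02))
    s <- average_replicates(reps)
    baseline_correct(s)
  }
  hi <- band_value(make_sample(0.9), default_bands()$LMP)
  lo <- band_value(make_sample(0.3), default_bands()$LMP)
  # generating contrast is 0.6 at the peak; band mean scales it by the
  # average Gaussian profile over the sampled points
  prof <- mean(exp(-0.5 * ((c(950, 960, 970, 980, 990) - 970) / 30)^2))
  expect_equal(hi - lo, 0.6 * prof, tolerance = 0.05)
})

test_that("spectrum CSV round-trips", {
  s <- demo_spectrum()
  f <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(s, f)
  s2 <- read_spectrum(f)
  expect_equal(s2$wavenumbers, s$wavenumbers)
  expect_equal(s2$absorbance, s$absorbance, tolerance = 1e-12)
})
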