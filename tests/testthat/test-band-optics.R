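test_that("meanReflectance is a trapezoid-integral mean", {
  grid <- 400:1300
  expect_equal(meanReflectance(SnowSpectrum(grid, rep(0.5, 901)), 400, 700),
               0.5)
  ## analytic mean of the ramp R = l/1300 over 400-700 is 550/1300
  ramp <- SnowSpectrum(grid, grid / 1300)
  expect_equal(meanReflectance(ramp, 400, 700), 550 / 1300,
               tolerance = 1e-12)
  expect_error(meanReflectance(ramp, 700, 700), "window start")
  expect_error(meanReflectance(ramp, 300, 700), "support")
})

test_that("band-equivalent reflectance is an SRF-weighted mean", {
  grid <- 400:1300
  flat <- SnowSpectrum(grid, rep(0.3, 901))
  ramp <- SnowSpectrum(grid, grid / 1300)
  for (shape in c("boxcar", "gaussian")) {
    b <- BandDefinition("B3", 560, 36, shape = shape)
    expect_equal(bandEquivalentReflectance(flat, b), 0.3, tolerance = 1e-9)
    ## symmetric SRF on a linear ramp returns the ramp at the centre
    expect_equal(bandEquivalentReflectance(ramp, b), 560 / 1300,
                 tolerance = 1e-9)
  }
  ## degenerate one-grid-step boxcar is a point sample at the centre
  bd <- BandDefinition("P", 665, 1)
  s <- random_smooth_spectrum(7)
  expect_equal(bandEquivalentReflectance(s, bd),
               reflectance(s)[wavelengths(s) == 665],
               tolerance = 2e-6)
  ## out-of-support band errors
  expect_error(bandEquivalentReflectance(flat, BandDefinition("X", 390, 30)),
               "support")
})

test_that("band-equivalent reflectance is bounded by the spectrum over the band", {
  for (seed in 1:20) {
    s <- random_smooth_spectrum(seed)
    for (b in sentinel2Bands()) {
      lo <- b@center - b@fwhm / 2
      hi <- b@center + b@fwhm / 2
      idx <- wavelengths(s) >= floor(lo) & wavelengths(s) <= ceiling(hi)
      v <- bandEquivalentReflectance(s, b)
      expect_gte(v, min(reflectance(s)[idx]) - 1e-12)
      expect_lte(v, max(reflectance(s)[idx]) + 1e-12)
    }
  }
})

test_that("tabulated SRF reproduces the boxcar it tabulates", {
  s <- random_smooth_spectrum(3)
  box <- BandDefinition("B4", 665, 31)
  tab <- BandDefinition("B4t", 665, 31, shape = "tabulated",
                        srf = data.frame(wavelength_nm = seq(649.5, 680.5, 0.5),
                                         weight = 1))
  expect_equal(bandEquivalentReflectance(s, tab),
               bandEquivalentReflectance(s, box), tolerance = 1e-6)
})

test_that("continuum reflectance uses the printed 104/144 interpolation", {
  expect_equal(continuumReflectanceB4(0.20, 0.20), 0.20)
  expect_equal(continuumReflectanceB4(0.20, 0.344),
               0.20 + (104 / 144) * 0.144)
  expect_equal(continuumReflectanceB4(0.20, 0.344), 0.304)
  expect_equal(continuumReflectanceB4(0.30, 0.20), 0.30 - (104 / 144) * 0.1)
  expect_equal(continuumReflectanceB4(0.30, 0.20), 0.2277778,
               tolerance = 1e-6)
})

test_that("band depth is the scaled continuum-removed depth", {
  expect_equal(bandDepthIB4(0.2, continuumReflectanceB4(0.2, 0.344), 0.344),
               0)
  expect_equal(bandDepthIB4(0.2, 0, 0.344), 1)
  expect_equal(bandDepthIB4(0.20, 0.25, 0.344), (0.304 - 0.25) / 0.304)
  expect_equal(bandDepthIB4(0.20, 0.25, 0.344), 0.1776316, tolerance = 1e-6)
  expect_equal(bandDepthIB4(0.20, 0.25, 0.344, percent = TRUE), 17.76316,
               tolerance = 1e-4)
  expect_error(bandDepthIB4(0.1, 0.1, -0.2), "not positive")
  ## band depth never exceeds 1 for non-negative reflectances
  for (seed in 1:50) {
    set.seed(seed)
    v <- runif(3, 0, 1)
    rc <- continuumReflectanceB4(v[1], v[3])
    if (rc > 0) expect_lte(bandDepthIB4(v[1], v[2], v[3]), 1)
  }
})

test_that("IB4 from a spectrum: flat is zero, deeper 680-nm dips raise it", {
  grid <- 400:1300
  flat <- SnowSpectrum(grid, rep(0.3, 901))
  expect_equal(ib4FromSpectrum(flat), 0, tolerance = 1e-12)

  dip_spec <- function(depth)
    SnowSpectrum(grid, 0.3 * exp(-depth * exp(-(grid - 680)^2 / (2 * 12^2))))
  depths <- seq(0.1, 1.2, by = 0.1)
  vals <- vapply(depths, function(d) ib4FromSpectrum(dip_spec(d)),
                 numeric(1))
  expect_true(all(vals > 0))
  expect_true(all(diff(vals) > 0))
})

test_that("broad carotenoid absorption lowers RB3 and can lower IB4 (masking)", {
  grid <- 400:1300
  base <- SnowSpectrum(grid,
    0.3 * exp(-0.5 * exp(-(grid - 680)^2 / (2 * 12^2))))
  masked <- SnowSpectrum(grid,
    reflectance(base) * exp(-0.8 * exp(-(grid - 510)^2 / (2 * 45^2))))
  b <- sentinel2Bands()
  expect_lt(bandEquivalentReflectance(masked, b$B3),
            bandEquivalentReflectance(base, b$B3))
  expect_lt(ib4FromSpectrum(masked), ib4FromSpectrum(base))
})

test_that("percent reduction matches the printed-arithmetic contrasts", {
  expect_equal(percentReduction(0.25, 0.25), 0)
  expect_equal(percentReduction(0.25, 0.11), 56.0)
  expect_equal(percentReduction(0.25, 0.15), 40.0)
  expect_error(percentReduction(0, 0.1), "positive")
})

test_that("band config round-trips through YAML and JSON", {
  cfg <- list(list(name = "B3", center_nm = 560, fwhm_nm = 36),
              list(name = "B4", center_nm = 665, fwhm_nm = 31,
                   shape = "gaussian"))
  fy <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, fy)
  by <- readBandConfig(fy)
  expect_named(by, c("B3", "B4"))
  expect_equal(by$B4@shape, "gaussian")
  fj <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, fj, auto_unbox = TRUE)
  bj <- readBandConfig(fj)
  expect_equal(bj$B3@fwhm, 36)
  ## the bundled default config matches sentinel2Bands()
  bundled <- readBandConfig(system.file("extdata", "sentinel2_bands.yaml",
                                        package = "snowbloom"))
  ref <- sentinel2Bands()
  for (nm in names(ref)) {
    expect_equal(bundled[[nm]]@center, ref[[nm]]@center)
    expect_equal(bundled[[nm]]@fwhm, ref[[nm]]@fwhm)
  }
})
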