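test_that("clean-spectrum generation is seeded and exact at zero noise", {
  expect_identical(reflectance(synthCleanSpectrum(5)),
                   reflectance(synthCleanSpectrum(5)))
  expect_false(identical(reflectance(synthCleanSpectrum(5)),
                         reflectance(synthCleanSpectrum(6))))
  expect_identical(reflectance(synthCleanSpectrum(1, siteSd = 0,
                                                  noiseSd = 0)),
                   cleanBaseline())
})

test_that("default clean spectra centre on the reported clean-snow means", {
  par_means <- vapply(1:100, function(k)
    meanReflectance(synthCleanSpectrum(k), 400, 700), numeric(1))
  expect_lt(max(abs(par_means - 0.25)), 0.08)
  expect_lt(abs(mean(par_means) - 0.25), 0.01)
  nir_means <- vapply(1:100, function(k)
    meanReflectance(synthCleanSpectrum(k), 700, 1300), numeric(1))
  expect_lt(abs(mean(nir_means) - 0.16), 0.01)
})

test_that("bloom forward model is the identity at zero loading", {
  arch <- defaultArchetypes()$green
  arch@residualVisOd <- 0
  arch@residualNirOd <- 0
  arch@noiseSd <- 0
  clean <- synthCleanSpectrum(3, siteSd = 0, noiseSd = 0)
  out <- synthBloomSpectrum(clean, PigmentProfile(0, 0, 0, 0), arch,
                            seed = 1)
  expect_equal(reflectance(out), reflectance(clean))
  expect_error(synthBloomSpectrum(clean, PigmentProfile(-1, 0, 0, 0),
                                  arch, seed = 1), ">= 0|non-negative")
})

test_that("more chlorophyll a deepens the 680-nm dip and raises IB4", {
  arch <- defaultArchetypes()$green
  arch@noiseSd <- 0
  clean <- synthCleanSpectrum(3, siteSd = 0, noiseSd = 0)
  ib4_at <- function(chla) ib4FromSpectrum(
    synthBloomSpectrum(clean, PigmentProfile(0.9, chla, 0.8, 0.05), arch,
                       seed = 1))
  vals <- vapply(c(0.3, 0.6, 1.2, 2.4), ib4_at, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("astaxanthin-only loading darkens PAR more than NIR", {
  arch <- defaultArchetypes()$red
  arch@residualVisOd <- 0; arch@residualNirOd <- 0; arch@noiseSd <- 0
  clean <- synthCleanSpectrum(3, siteSd = 0, noiseSd = 0)
  out <- synthBloomSpectrum(clean, PigmentProfile(2.4, 0, 0, 0), arch,
                            seed = 1)
  par_drop <- meanReflectance(clean, 400, 700) -
    meanReflectance(out, 400, 700)
  nir_drop <- meanReflectance(clean, 700, 1300) -
    meanReflectance(out, 700, 1300)
  expect_gt(par_drop, 10 * max(nir_drop, 0))
})

test_that("synthSampleSet emulates the study design deterministically", {
  dir1 <- tempfile(); dir2 <- tempfile()
  set1 <- synthSampleSet(nPerGroup = 7, nClean = 6, seed = 42,
                         outdir = dir1)
  set2 <- synthSampleSet(nPerGroup = 7, nClean = 6, seed = 42,
                         outdir = dir2)
  ## 3 x 7 bloom samples + 6 clean sites = 27 spectra plus a manifest
  expect_equal(nrow(set1$manifest), 27)
  expect_equal(length(set1$spectra), 27)
  expect_length(list.files(dir1, pattern = "^spectrum_.*csv$"), 27)
  expect_true(file.exists(file.path(dir1, "manifest.csv")))
  expect_true(file.exists(file.path(dir1, "biology.csv")))
  ## byte-identical regeneration under the same seed
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
  ## different seed changes the data
  set3 <- synthSampleSet(nPerGroup = 2, nClean = 2, seed = 43)
  expect_false(identical(
    reflectance(set3$spectra[["red-01"]]),
    reflectance(set1$spectra[["red-01"]])))
  ## sample ids join spectra to biology one-to-one
  expect_setequal(names(set1$spectra), names(set1$biology))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  a <- runif(1)
  set.seed(123)
  invisible(synthSampleSet(nPerGroup = 1, nClean = 1, seed = 9))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("generated pigment means converge to the archetype means", {
  arch <- defaultArchetypes()
  chla_means <- t(vapply(1:50, function(k) {
    set <- synthSampleSet(nPerGroup = 7, nClean = 0, seed = 1000 + k)
    tab <- set$biologyTable
    tab <- tab[!duplicated(tab$sample_id), ]
    c(red = mean(tab$chla_ug_ml[tab$color_group == "red"]),
      green = mean(tab$astax_ug_ml[tab$color_group == "green"]),
      orange = mean(tab$astax_ug_ml[tab$color_group == "orange"]))
  }, numeric(3)))
  check <- function(vals, target) {
    se <- sd(vals) / sqrt(length(vals))
    expect_lt(abs(mean(vals) - target), 3 * se + 0.02 * target)
  }
  check(chla_means[, "red"], arch$red@pigmentMeans@chla)
  check(chla_means[, "green"], arch$green@pigmentMeans@astax)
  check(chla_means[, "orange"], arch$orange@pigmentMeans@astax)
})

test_that("archetype YAML overrides merge onto the defaults", {
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(red = list(pigment_means = list(astax = 3.0),
                                   noise_sd = 0)), f)
  arch <- readArchetypeConfig(f)
  expect_equal(arch$red@pigmentMeans@astax, 3.0)
  expect_equal(arch$red@pigmentMeans@chla, 0.434)  # default retained
  expect_equal(arch$red@noiseSd, 0)
  expect_equal(arch$green@noiseSd, 0.003)          # untouched archetype
  yaml::write_yaml(list(violet = list(noise_sd = 0)), f)
  expect_error(readArchetypeConfig(f), "unknown archetype")
})
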