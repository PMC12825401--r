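test_that("cell volumes follow sphere and prolate-spheroid geometry", {
  expect_equal(cellVolume(CellPopulation("sphere", 10, density = 1)),
               pi / 6 * 1000)
  expect_equal(cellVolume(CellPopulation("sphere", 10, density = 1)),
               523.60, tolerance = 1e-4)
  orange <- CellPopulation("prolate_spheroid", 25.9, 14.6, 1)
  expect_equal(cellVolume(orange), pi / 6 * 25.9 * 14.6^2)
  expect_equal(cellVolume(orange), 2890.7, tolerance = 1e-4)
  expect_equal(cellVolume(CellPopulation("sphere", 0, density = 0)), 0)
  expect_error(cellVolume(CellPopulation("prolate_spheroid", 20,
                                         density = 1)), "minor axis")
  ## sphere(d) equals prolate(a = d, b = d)
  expect_equal(cellVolume(CellPopulation("sphere", 12, density = 1)),
               cellVolume(CellPopulation("prolate_spheroid", 12, 12, 1)))
  ## strictly increasing in each dimension
  v0 <- cellVolume(CellPopulation("prolate_spheroid", 20, 10, 1))
  expect_gt(cellVolume(CellPopulation("prolate_spheroid", 21, 10, 1)), v0)
  expect_gt(cellVolume(CellPopulation("prolate_spheroid", 20, 11, 1)), v0)
})

test_that("mean-volume mode averages per-cell volumes", {
  dims <- c(8, 10, 12)
  mv <- cellVolume(list(shape = "sphere", dimMajor = dims, dimMinor = NA),
                   mode = "mean_volume")
  expect_equal(mv, mean(pi / 6 * dims^3))
  ## per-cell averaging exceeds the mean-dimension volume (Jensen)
  expect_gt(mv, pi / 6 * mean(dims)^3)
})

test_that("total biovolume is density-weighted and additive", {
  p1 <- CellPopulation("sphere", 10, density = 1000)
  expect_equal(totalBiovolume(list(p1)), 5.236e5, tolerance = 1e-4)
  ## printed red bloom: d = 35.96 um spheres at 3175 cells ml-1
  red <- CellPopulation("sphere", 35.96, density = 3175)
  expect_equal(totalBiovolume(list(red)), 7.729e7, tolerance = 1e-3)
  p2 <- CellPopulation("prolate_spheroid", 21.1, 14.7, 97815)
  expect_equal(totalBiovolume(list(p1, p2)),
               totalBiovolume(list(p1)) + totalBiovolume(list(p2)))
  expect_error(totalBiovolume(list()), "at least one")
})

test_that("pigment signature percentages sum to 100 and match arithmetic", {
  eq <- PigmentProfile(1, 1, 1, 1)
  expect_equal(unname(pigmentSignature(eq)), rep(25, 4))
  ## printed red means: astax + bcar carry ~80% of the pool
  sig <- pigmentSignature(red_profile())
  expect_equal(unname(sig[["astax"]] + sig[["bcar"]]),
               100 * 2.52 / 3.14, tolerance = 1e-6)
  expect_equal(sum(sig), 100, tolerance = 1e-12)
  for (seed in 1:20) {
    set.seed(seed)
    p <- do.call(PigmentProfile, as.list(runif(4, 0.01, 5)))
    expect_equal(sum(pigmentSignature(p)), 100, tolerance = 1e-12)
  }
  expect_error(pigmentSignature(PigmentProfile(0, 0, 0, 0)), "positive")
  expect_error(pigmentSignature(PigmentProfile(1, NA, 1, 1)), "missing")
  ## missing chlb tolerated only when explicitly flagged
  p_nb <- PigmentProfile(1, 1, NA, 1)
  expect_error(pigmentSignature(p_nb), "missing")
  expect_equal(unname(pigmentSignature(p_nb, chlbMissingAsZero = TRUE)),
               c(100 / 3, 100 / 3, 0, 100 / 3))
})

test_that("astaxanthin:chlorophyll-a ratio and its contract", {
  expect_equal(astaxChlaRatio(PigmentProfile(1.2, 1.2, 0, 0)), 1)
  expect_equal(astaxChlaRatio(red_profile()), 2.39 / 0.434)
  expect_equal(astaxChlaRatio(red_profile()), 5.507, tolerance = 1e-3)
  expect_error(astaxChlaRatio(PigmentProfile(1, 0, 0, 0)), "positive")
  expect_error(astaxChlaRatio(PigmentProfile(1, NA, 0, 0)), "measured")
})

test_that("per-cell and per-biovolume pigment normalization", {
  p <- red_profile()
  per_cell <- pigmentPerCell(p, 3175)
  expect_equal(per_cell[["chla"]], 13.67e-5, tolerance = 1e-3)
  ## round-trip: per-cell times density recovers the concentration
  expect_equal(per_cell[["astax"]] * 3175, 2.39)
  ## printed cross-group ratios recomputed from per-cell values
  expect_equal(13.68 / 0.60, 22.8)
  expect_equal(1.86 / 0.59, 3.153, tolerance = 1e-3)
  per_bv <- pigmentPerBiovolume(p, 7.326e7)
  expect_equal(per_bv[["chla"]], 0.434 / 7.326e7)
  expect_error(pigmentPerCell(p, 0), "positive")
  expect_error(pigmentPerBiovolume(p, -1), "positive")
})

test_that("population fractions reproduce the printed green split", {
  pops <- list(CellPopulation("prolate_spheroid", 21.1, 14.7, 97815,
                              label = "ellipsoids"),
               CellPopulation("sphere", 8.3, density = 2185,
                              label = "small_spheres"))
  fr <- populationFractions(pops)
  expect_equal(unname(fr), c(97.815, 2.185))
  expect_equal(sum(fr), 100)
  expect_equal(unname(populationFractions(list(pops[[1]]))), 100)
  eq <- list(CellPopulation("sphere", 10, density = 500),
             CellPopulation("sphere", 12, density = 500))
  expect_equal(unname(populationFractions(eq)), c(50, 50))
  zero <- list(CellPopulation("sphere", 0, density = 0))
  expect_error(populationFractions(zero), "positive")
})
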