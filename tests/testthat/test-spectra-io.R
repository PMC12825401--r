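test_that("readSpectrum reads the documented two-column dialect", {
  f <- write_spectrum_csv(c("400,0.25", "401,0.25"))
  s <- readSpectrum(f, sampleId = "a")
  expect_s4_class(s, "SnowSpectrum")
  expect_equal(wavelengths(s), c(400, 401))
  expect_equal(reflectance(s), c(0.25, 0.25))

  ## optional header line is tolerated
  fh <- write_spectrum_csv(c("wavelength_nm,value", "400,0.25", "401,0.25"))
  expect_equal(reflectance(readSpectrum(fh)), c(0.25, 0.25))
})

test_that("duplicate wavelengths collapse by mean", {
  f <- write_spectrum_csv(c("499,0.1", "500,0.2", "500,0.4", "501,0.1"))
  s <- readSpectrum(f)
  expect_equal(wavelengths(s), c(499, 500, 501))
  expect_equal(reflectance(s)[2], 0.30)
})

test_that("parse errors name the offending row and bad files fail", {
  f <- write_spectrum_csv(c("400,0.25", "401,NA", "402,0.25"))
  expect_error(readSpectrum(f), "row 2")
  expect_error(readSpectrum(write_spectrum_csv(character())), "empty")
  ## rows outside the instrument range are rejected
  f2 <- write_spectrum_csv(c("300,0.5", "2600,0.5"))
  expect_error(readSpectrum(f2), "instrument range")
  f3 <- write_spectrum_csv(c("340,0.5", "400,0.25", "401,0.26"))
  expect_equal(length(wavelengths(readSpectrum(f3))), 2)
})

test_that("negative reflectance is clipped with a warning, or errors in strict mode", {
  f <- write_spectrum_csv(c("400,-0.01", "401,0.25"))
  expect_warning(s <- readSpectrum(f), "clipped")
  expect_equal(reflectance(s)[1], 0)
  expect_error(readSpectrum(f, negative = "error"), "negative")
})

test_that("write/read round-trip is the identity on the documented dialect", {
  s <- SnowSpectrum(seq(400, 410, 0.5), runif(21, 0.1, 0.3),
                    sampleId = "rt", colorGroup = "red", replicate = 3L)
  f <- tempfile(fileext = ".csv")
  writeSpectrum(s, f)
  s2 <- readSpectrum(f, sampleId = "rt", colorGroup = "red", replicate = 3L)
  expect_equal(wavelengths(s2), wavelengths(s))
  expect_equal(reflectance(s2), reflectance(s))
})

test_that("resampleToGrid interpolates linearly and never extrapolates", {
  s <- SnowSpectrum(c(350, 800, 2500), c(0.5, 0.5, 0.5))
  r <- resampleToGrid(s, 400, 1300, 1)
  expect_equal(reflectance(r), rep(0.5, 901))

  s2 <- SnowSpectrum(c(400, 500), c(0.0, 1.0))
  expect_equal(reflectance(resampleToGrid(s2, 450, 460, 10))[1], 0.5)

  ## exact on a linear ramp
  s3 <- SnowSpectrum(seq(350, 1350, 5), seq(350, 1350, 5) / 1300)
  r3 <- resampleToGrid(s3, 400, 1300, 1)
  expect_lt(max(abs(reflectance(r3) - (400:1300) / 1300)), 1e-12)

  ## idempotent when the input is already on the grid
  r4 <- resampleToGrid(r3, 400, 1300, 1)
  expect_identical(reflectance(r4), reflectance(r3))

  expect_error(resampleToGrid(SnowSpectrum(450:1200, rep(1, 751))),
               "outside spectrum support")
})

test_that("SnowSpectrum validity enforces its invariants", {
  expect_error(SnowSpectrum(c(400, 400), c(1, 1)), "strictly increasing")
  expect_error(SnowSpectrum(400:401, c(1, NA)), "finite")
  expect_error(SnowSpectrum(400:401, c(-0.1, 0.2)), "non-negative")
  expect_error(SnowSpectrum(400:401, c(0.1, 0.2), colorGroup = "blue"),
               "colorGroup")
})

test_that("readBiologyTable builds SampleBiology records and validates", {
  f <- tempfile(fileext = ".csv")
  writeLines(c(
    paste("sample_id,color_group,cell_shape,dim_major_um,dim_minor_um,",
          "density_cells_ml,astax_ug_ml,chla_ug_ml,chlb_ug_ml,bcar_ug_ml,",
          "laip_mg_m2", sep = ""),
    "red-1,red,sphere,35.96,,3175,2.39,0.434,0.186,0.13,1336",
    "green-1,green,prolate_spheroid,21.1,14.7,97815,0.92,0.6,0.8,0.05,3033",
    "green-1,green,sphere,8.3,,2185,0.92,0.6,0.8,0.05,3033"), f)
  bio <- readBiologyTable(f)
  expect_named(bio, c("green-1", "red-1"))
  red <- bio[["red-1"]]
  pop <- cellPopulations(red)[[1]]
  expect_equal(pop@density, 3175)
  expect_equal(pop@dimMajor, 35.96)
  expect_equal(length(cellPopulations(bio[["green-1"]])), 2)
  expect_equal(pigments(red)@astax, 2.39)

  ## missing pigments: profile has NAs and pigment ops refuse
  f2 <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,color_group,cell_shape,dim_major_um,density_cells_ml",
               "red-2,red,sphere,30,1000"), f2)
  bio2 <- readBiologyTable(f2)
  expect_true(is.na(pigments(bio2[["red-2"]])@chla))
  expect_error(pigmentSignature(pigments(bio2[["red-2"]])), "missing")

  ## negative density is a validation error
  f3 <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,color_group,cell_shape,dim_major_um,density_cells_ml",
               "red-3,red,sphere,30,-1"), f3)
  expect_error(readBiologyTable(f3), "negative cell density")
})

test_that("readSpectraSet joins manifest rows to spectra on the common grid", {
  dir <- tempfile(); dir.create(dir)
  for (id in c("s1", "s2")) {
    s <- SnowSpectrum(seq(350, 1350, 1), rep(0.2, 1001), sampleId = id)
    writeSpectrum(s, file.path(dir, sprintf("spectrum_%s.csv", id)))
  }
  man <- data.frame(file = c("spectrum_s1.csv", "spectrum_s2.csv"),
                    sample_id = c("s1", "s2"),
                    color_group = c("clean", "red"), replicate = 1:2)
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  specs <- readSpectraSet(file.path(dir, "manifest.csv"))
  expect_named(specs, c("s1", "s2"))
  expect_equal(wavelengths(specs$s1), 400:1300)
  expect_equal(colorGroup(specs$s2), "red")
})
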