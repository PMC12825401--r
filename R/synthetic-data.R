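## Seeded synthetic-data generator: clean-snow spectra, bloom spectra via a
## Beer-Lambert-like forward model, and matched cell-population and pigment
## tables for red, orange and green community archetypes.
##
## All randomness flows from one explicit seed: every sample receives a
## deterministic sub-seed derived from the base seed and its index, and the
## caller's RNG state is saved and restored around every draw.

## deterministic sub-seed derivation (a Lehmer-style hash, kept < 2^31)
.subSeed <- function(seed, key) {
  s <- (as.numeric(seed) %% 2147483647) + 1
  for (k in key) s <- (s * 48271 + as.numeric(k) * 8191 + 1) %% 2147483647
  as.integer(s)
}

## evaluate expr under a local seed without disturbing the caller's RNG
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## lognormal with a given mean and coefficient of variation
.rlnorm_mean <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Analytic clean-snow reflectance baseline
#'
#' The noise-free baseline the generator attenuates: a gentle quadratic
#' decline `R(l) = p - d ((l - 400) / 900)^2` whose constants are chosen so
#' the PAR-window mean is 0.25 and the NIR-window mean 0.16, the group
#' means reported for visibly clean alpine snow.
#'
#' @param grid wavelength grid in nm.
#' @return Numeric vector of baseline reflectance.
#' @export
cleanBaseline <- function(grid = analysisGrid()) {
  x <- (grid - 400) / 900
  0.25750 - 0.20250 * x^2
}

## non-pigment absorber shapes: a visible ramp (mineral dust etc.) that
## vanishes at 900 nm, and a smooth NIR onset between 700 and 900 nm.
.visRamp <- function(grid) pmax(0, (900 - grid) / 500)
.nirShape <- function(grid) pmin(1, pmax(0, (grid - 700) / 200))

#' Generate a synthetic clean-snow spectrum
#'
#' The analytic [cleanBaseline()] plus a per-site level shift
#' (`N(0, siteSd)`) and white measurement noise (`N(0, noiseSd)` per
#' wavelength), clipped at zero. Deterministic for a given seed; with
#' `siteSd = 0` and `noiseSd = 0` the result is exactly the baseline.
#'
#' @param seed integer seed for this spectrum.
#' @param grid wavelength grid (default the 1-nm analysis grid).
#' @param siteSd sd of the site-level reflectance shift (default 0.03,
#'   emulating clean-snow variability across snowfield sections).
#' @param noiseSd sd of white noise per wavelength (default 0.003).
#' @param sampleId,replicate metadata for the returned spectrum.
#' @return A [SnowSpectrum-class] with `colorGroup = "clean"`.
#' @export
synthCleanSpectrum <- function(seed, grid = analysisGrid(), siteSd = 0.03,
                               noiseSd = 0.003, sampleId = "clean",
                               replicate = 1L) {
  base <- cleanBaseline(grid)
  r <- .withSeed(seed, {
    shift <- if (siteSd > 0) stats::rnorm(1, 0, siteSd) else 0
    noise <- if (noiseSd > 0) stats::rnorm(length(grid), 0, noiseSd) else 0
    base + shift + noise
  })
  SnowSpectrum(grid, pmax(r, 0), sampleId = sampleId, colorGroup = "clean",
               replicate = replicate)
}

#' Attenuate a clean spectrum by pigment and impurity absorption
#'
#' The bloom forward model:
#' `R_algae(l) = R_clean(l) * exp(-tau(l))` with
#' `tau(l) = sum_p c_p a_p(l) + dust(l) + nir(l)`, where each pigment
#' kernel `a_p` is a Gaussian in wavelength (peak optical depth per
#' ug ml-1 from the archetype's absorption table), `dust` is the
#' archetype's residual visible optical depth scaled by the sample's LAIP
#' load, and `nir` is the archetype's residual NIR term (negative values
#' brighten, emulating snow-physical differences). White measurement noise
#' (`N(0, noiseSd)`) is added under the given seed. The exponential form
#' guarantees `0 < R_algae <= R_clean` before noise, so zero pigments and
#' zero residuals return the clean spectrum unchanged.
#'
#' @param clean a [SnowSpectrum-class] (the site's clean baseline).
#' @param pigments a [PigmentProfile-class]; concentrations must be >= 0.
#' @param archetype a [BloomArchetype-class] providing kernels, residual
#'   optical depths and the noise model.
#' @param seed integer seed for the measurement noise.
#' @param laip sample LAIP load (mg m-2) scaling the visible residual;
#'   defaults to the archetype mean.
#' @param sampleId,replicate metadata for the returned spectrum.
#' @return A [SnowSpectrum-class] with the archetype's colour group.
#' @export
synthBloomSpectrum <- function(clean, pigments, archetype, seed,
                               laip = archetype@laipMean,
                               sampleId = archetype@name, replicate = 1L) {
  stopifnot(is(clean, "SnowSpectrum"), is(pigments, "PigmentProfile"),
            is(archetype, "BloomArchetype"))
  conc <- .profile_values(pigments, chlbMissingAsZero = TRUE)
  conc[is.na(conc)] <- 0
  if (any(conc < 0))
    stop("pigment concentrations must be non-negative", call. = FALSE)
  grid <- clean@wavelength
  tau <- numeric(length(grid))
  ab <- archetype@absorption
  for (i in seq_len(nrow(ab))) {
    cp <- conc[[ab$pigment[i]]]
    if (is.null(cp) || cp == 0) next
    tau <- tau + cp * ab$strength[i] *
      exp(-(grid - ab$center_nm[i])^2 / (2 * ab$width_nm[i]^2))
  }
  laip_scale <- if (archetype@laipMean > 0) laip / archetype@laipMean else 0
  tau <- tau + archetype@residualVisOd * laip_scale * .visRamp(grid) +
    archetype@residualNirOd * .nirShape(grid)
  r <- clean@reflectance * exp(-tau)
  if (archetype@noiseSd > 0)
    r <- r + .withSeed(seed, stats::rnorm(length(grid), 0,
                                          archetype@noiseSd))
  SnowSpectrum(grid, pmax(r, 0), sampleId = sampleId,
               colorGroup = archetype@name, replicate = replicate)
}

## ---------------------------------------------------------------------------
## Default archetypes

## Gaussian absorption kernels: centre (nm), width (Gaussian sd, nm) and
## base peak optical depth per ug ml-1. Centres follow the pigments'
## in-vivo absorption regions (chlorophyll a 680 nm, chlorophyll b 650 nm,
## astaxanthin broad around 480-540 nm, beta-carotene 454 nm); widths and
## strengths are conventions calibrated once (see
## inst/scripts/calibrate-archetypes.R) so that archetype-mean spectra
## land on the reported group means.
.KERNELS <- data.frame(
  pigment   = c("astax", "chla", "chlb", "bcar"),
  center_nm = c(510, 680, 650, 454),
  width_nm  = c(45, 12, 11, 25),
  strength  = c(0.70, 1.195648, 0.129639, 0.50),
  stringsAsFactors = FALSE
)

## Per-archetype in-vivo efficiency multipliers for the kernel strengths.
## Pigment packaging differs between communities: large red cysts package
## both chlorophyll and astaxanthin tightly, while the orange community's
## spectra behave as if chlorophyll absorbs more efficiently per unit mass
## and astaxanthin considerably less -- the calibration's scalar knob for
## the packaging effect.
.EFFICIENCY <- list(
  red    = c(astax = 1.0, chla = 1.0, chlb = 1.0, bcar = 1.0),
  orange = c(astax = 0.25, chla = 2.064988, chlb = 2.064988, bcar = 1.0),
  green  = c(astax = 1.0, chla = 1.0, chlb = 1.0, bcar = 1.0)
)

## Residual (non-pigment) optical depths per archetype, calibrated so the
## archetype-mean spectrum hits the reported PAR and NIR group means
## (red 0.11/0.12, orange 0.15/0.19, green 0.19/0.16 against clean
## 0.25/0.16). Values frozen from inst/scripts/calibrate-archetypes.R.
.RESIDUALS <- list(
  red    = c(vis = 0.4156677,  nir = 0.2979124),
  orange = c(vis = 0.4937112,  nir = -0.2396555),
  green  = c(vis = -0.0233997, nir = 0.0295803)
)

.archetype_absorption <- function(name) {
  ab <- .KERNELS
  eff <- .EFFICIENCY[[name]]
  ab$strength <- ab$strength * unname(eff[ab$pigment])
  ab
}

#' Default bloom archetypes
#'
#' Returns the four community archetypes (red, orange, green, clean) with
#' pigment means, cell-population geometry and densities taken from the
#' reported group means of an alpine multi-colour bloom campaign, and
#' absorption-kernel strengths plus residual optical depths calibrated
#' once so archetype-mean spectra reproduce the reported group-mean PAR
#' and NIR reflectances. Dispersion parameters are set at
#' replicate-measurement level (see the methods vignette).
#'
#' @return Named list of [BloomArchetype-class] objects.
#' @export
defaultArchetypes <- function() {
  pops <- list(
    red = data.frame(
      label = "red_spheres", shape = "sphere",
      dim_major_um = 35.96, dim_minor_um = NA_real_, dim_cv = 0.08,
      density_cells_ml = 3175, density_cv = 0.72,
      stringsAsFactors = FALSE),
    orange = data.frame(
      label = "orange_spheroids", shape = "prolate_spheroid",
      dim_major_um = 25.9, dim_minor_um = 14.6, dim_cv = 0.08,
      density_cells_ml = 19154, density_cv = 0.70,
      stringsAsFactors = FALSE),
    green = data.frame(
      label = c("green_ellipsoids", "green_small_spheres"),
      shape = c("prolate_spheroid", "sphere"),
      dim_major_um = c(21.1, 8.3), dim_minor_um = c(14.7, NA_real_),
      dim_cv = c(0.08, 0.08),
      density_cells_ml = c(97815, 2185), density_cv = c(0.024, 0.8),
      stringsAsFactors = FALSE)
  )
  pig <- list(
    red    = PigmentProfile(astax = 2.39, chla = 0.434, chlb = 0.186,
                            bcar = 0.13),
    orange = PigmentProfile(astax = 1.85, chla = 0.31, chlb = 0.29,
                            bcar = 0.03),
    green  = PigmentProfile(astax = 0.92, chla = 0.60, chlb = 0.80,
                            bcar = 0.05)
  )
  laip <- c(red = 1336, orange = 8250, green = 3033)
  ## red chlorophylls are decoupled from bloom intensity (secondary
  ## carotenogenesis: astaxanthin accumulates while the chl pool is stable)
  coupling <- list(
    red    = c(astax = 1, chla = 0, chlb = 0, bcar = 1),
    orange = c(astax = 1, chla = 1, chlb = 1, bcar = 1),
    green  = c(astax = 1, chla = 1, chlb = 1, bcar = 1))
  arch <- lapply(c("red", "orange", "green"), function(nm) {
    new("BloomArchetype", name = nm, pigmentMeans = pig[[nm]],
        sharedPigmentSd = 0.12, pigmentNoiseSd = 0.10,
        densityCoupling = 0.3, pigmentCoupling = coupling[[nm]],
        populations = pops[[nm]],
        absorption = .archetype_absorption(nm),
        residualVisOd = unname(.RESIDUALS[[nm]]["vis"]),
        residualNirOd = unname(.RESIDUALS[[nm]]["nir"]),
        laipMean = unname(laip[nm]), laipCv = 0.15,
        siteSd = 0.004, noiseSd = 0.003)
  })
  names(arch) <- c("red", "orange", "green")
  arch$clean <- new("BloomArchetype", name = "clean",
      pigmentMeans = PigmentProfile(0, 0, 0, 0),
      sharedPigmentSd = 0, pigmentNoiseSd = 0, densityCoupling = 0,
      pigmentCoupling = c(astax = 1, chla = 1, chlb = 1, bcar = 1),
      populations = data.frame(), absorption = .KERNELS[0, ],
      residualVisOd = 0, residualNirOd = 0, laipMean = 1500, laipCv = 0.5,
      siteSd = 0.03, noiseSd = 0.003)
  arch
}

## draw one bloom sample's biology from an archetype
.draw_biology <- function(archetype, seed) {
  .withSeed(seed, {
    pops <- archetype@populations
    dens <- dima <- dimb <- numeric(nrow(pops))
    for (i in seq_len(nrow(pops))) {
      dens[i] <- .rlnorm_mean(1, pops$density_cells_ml[i],
                              pops$density_cv[i])
      dima[i] <- .rlnorm_mean(1, pops$dim_major_um[i], pops$dim_cv[i])
      dimb[i] <- if (is.na(pops$dim_minor_um[i])) NA_real_
                 else .rlnorm_mean(1, pops$dim_minor_um[i], pops$dim_cv[i])
    }
    rel_density <- sum(dens) / sum(pops$density_cells_ml)
    shared <- rel_density^archetype@densityCoupling *
      exp(stats::rnorm(1, 0, archetype@sharedPigmentSd) -
          archetype@sharedPigmentSd^2 / 2)
    pm <- .profile_values(archetype@pigmentMeans)
    eps <- exp(stats::rnorm(4, 0, archetype@pigmentNoiseSd) -
               archetype@pigmentNoiseSd^2 / 2)
    coupl <- archetype@pigmentCoupling[names(pm)]
    conc <- pm * shared^coupl * eps
    laip <- .rlnorm_mean(1, archetype@laipMean, archetype@laipCv)
    list(densities = dens, dim_major = dima, dim_minor = dimb,
         pigments = PigmentProfile(conc[["astax"]], conc[["chla"]],
                                   conc[["chlb"]], conc[["bcar"]]),
         laip = laip)
  })
}

#' Generate a complete synthetic sample set
#'
#' Emulates the study design of a multi-colour bloom campaign: `nPerGroup`
#' samples for each bloom archetype plus `nClean` clean-snow sites, each
#' with a reflectance spectrum on the 1-nm analysis grid and, for bloom
#' samples, matching cell-population and pigment records. Deterministic
#' for a given seed. With `outdir` set, the set is written to disk in the
#' documented CSV formats (`manifest.csv`, `biology.csv`, one
#' `spectrum_<sample_id>.csv` per sample), byte-identical across reruns
#' with the same seed.
#'
#' @param archetypes named list of [BloomArchetype-class] objects
#'   (default [defaultArchetypes()]); the `clean` archetype drives the
#'   clean sites.
#' @param nPerGroup bloom samples per colour group (default 7).
#' @param nClean clean-snow sites (default 6).
#' @param seed integer base seed.
#' @param outdir optional output directory.
#' @return A list with `manifest` (data.frame), `spectra` (named list of
#'   [SnowSpectrum-class]), `biology` (named list of
#'   [SampleBiology-class]) and `biologyTable` (data.frame, one row per
#'   population, in the documented CSV layout).
#' @export
synthSampleSet <- function(archetypes = defaultArchetypes(), nPerGroup = 7,
                           nClean = 6, seed = 1, outdir = NULL) {
  stopifnot(nPerGroup >= 1, nClean >= 0)
  bloom_names <- setdiff(names(archetypes), "clean")
  spectra <- list()
  biology <- list()
  manifest <- data.frame(file = character(), sample_id = character(),
                         color_group = character(), replicate = integer(),
                         stringsAsFactors = FALSE)
  biorows <- list()

  add_manifest <- function(id, group, rep_) {
    manifest[nrow(manifest) + 1L, ] <<-
      list(sprintf("spectrum_%s.csv", id), id, group, rep_)
  }

  clean_arch <- archetypes$clean
  for (j in seq_len(nClean)) {
    id <- sprintf("clean-%02d", j)
    s <- synthCleanSpectrum(.subSeed(seed, c(0, j)),
                            siteSd = clean_arch@siteSd,
                            noiseSd = clean_arch@noiseSd,
                            sampleId = id, replicate = j)
    spectra[[id]] <- s
    biology[[id]] <- SampleBiology(id, "clean")
    add_manifest(id, "clean", j)
  }

  for (gi in seq_along(bloom_names)) {
    arch <- archetypes[[bloom_names[gi]]]
    for (j in seq_len(nPerGroup)) {
      id <- sprintf("%s-%02d", arch@name, j)
      bio_seed  <- .subSeed(seed, c(gi, j, 1))
      site_seed <- .subSeed(seed, c(gi, j, 2))
      spec_seed <- .subSeed(seed, c(gi, j, 3))
      bio <- .draw_biology(arch, bio_seed)
      site_clean <- synthCleanSpectrum(site_seed, siteSd = arch@siteSd,
                                       noiseSd = 0, sampleId = id)
      s <- synthBloomSpectrum(site_clean, bio$pigments, arch, spec_seed,
                              laip = bio$laip, sampleId = id,
                              replicate = j)
      pops <- lapply(seq_along(bio$densities), function(i) {
        CellPopulation(arch@populations$shape[i], bio$dim_major[i],
                       bio$dim_minor[i], bio$densities[i],
                       label = arch@populations$label[i])
      })
      spectra[[id]] <- s
      biology[[id]] <- SampleBiology(id, arch@name, pops, bio$pigments,
                                     laip = bio$laip)
      add_manifest(id, arch@name, j)
      pg <- bio$pigments
      for (i in seq_along(pops)) {
        biorows[[length(biorows) + 1L]] <- data.frame(
          sample_id = id, color_group = arch@name,
          population_label = arch@populations$label[i],
          cell_shape = arch@populations$shape[i],
          dim_major_um = bio$dim_major[i], dim_minor_um = bio$dim_minor[i],
          density_cells_ml = bio$densities[i],
          astax_ug_ml = pg@astax, chla_ug_ml = pg@chla,
          chlb_ug_ml = pg@chlb, bcar_ug_ml = pg@bcar,
          laip_mg_m2 = bio$laip, stringsAsFactors = FALSE)
      }
    }
  }
  biologyTable <- if (length(biorows)) do.call(rbind, biorows) else
    data.frame()

  out <- list(manifest = manifest, spectra = spectra, biology = biology,
              biologyTable = biologyTable)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(spectra))
      writeSpectrum(spectra[[id]],
                    file.path(outdir, sprintf("spectrum_%s.csv", id)))
    utils::write.csv(manifest, file.path(outdir, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(biologyTable, file.path(outdir, "biology.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  out
}

#' Read bloom archetypes from a YAML config
#'
#' Each top-level entry names an archetype and may override any of the
#' default parameters: `pigment_means` (named list), `shared_pigment_sd`,
#' `pigment_noise_sd`, `density_coupling`, `populations` (list of rows),
#' `absorption` (list of rows with `pigment`, `center_nm`, `width_nm`,
#' `strength`), `residual_vis_od`, `residual_nir_od`, `laip_mean`,
#' `laip_cv`, `site_sd`, `noise_sd`. Unmentioned archetypes and fields
#' keep their defaults.
#'
#' @param path path to a YAML file.
#' @return Named list of [BloomArchetype-class] objects.
#' @export
readArchetypeConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  arch <- defaultArchetypes()
  for (nm in names(cfg)) {
    if (!nm %in% names(arch))
      stop("unknown archetype in config: ", nm, call. = FALSE)
    a <- arch[[nm]]
    o <- cfg[[nm]]
    if (!is.null(o$pigment_means))
      a@pigmentMeans <- PigmentProfile(
        astax = o$pigment_means$astax %||% a@pigmentMeans@astax,
        chla  = o$pigment_means$chla  %||% a@pigmentMeans@chla,
        chlb  = o$pigment_means$chlb  %||% a@pigmentMeans@chlb,
        bcar  = o$pigment_means$bcar  %||% a@pigmentMeans@bcar)
    num_fields <- c(shared_pigment_sd = "sharedPigmentSd",
                    pigment_noise_sd = "pigmentNoiseSd",
                    density_coupling = "densityCoupling",
                    residual_vis_od = "residualVisOd",
                    residual_nir_od = "residualNirOd",
                    laip_mean = "laipMean", laip_cv = "laipCv",
                    site_sd = "siteSd", noise_sd = "noiseSd")
    for (f in names(num_fields))
      if (!is.null(o[[f]])) slot(a, num_fields[[f]]) <- as.numeric(o[[f]])
    if (!is.null(o$populations))
      a@populations <- do.call(rbind, lapply(o$populations, as.data.frame))
    if (!is.null(o$absorption))
      a@absorption <- do.call(rbind, lapply(o$absorption, as.data.frame))
    validObject(a)
    arch[[nm]] <- a
  }
  arch
}
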