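#' @import methods
NULL

.COLOR_GROUPS <- c("red", "orange", "green", "clean")

## The common analysis window and grid. Field spectroradiometers deliver
## 1-nm-resampled output, and all band/irradiance integrals below assume a
## shared regular grid, so 1-nm steps over 400-1300 nm are the package-wide
## convention.
#' Analysis window constants
#'
#' The shared analysis window is 400--1300 nm: the visible/PAR window is
#' 400--700 nm and the near-infrared window (as delimited for snow-algae
#' work) is 700--1300 nm. `analysisGrid()` returns the canonical 1-nm grid.
#'
#' @return `analysisGrid()` returns an integer vector of wavelengths (nm).
#' @export
analysisGrid <- function() seq(400, 1300, by = 1)

#' @rdname analysisGrid
#' @export
parWindow <- function() c(400, 700)

#' @rdname analysisGrid
#' @export
nirWindow <- function() c(700, 1300)

#' @rdname analysisGrid
#' @export
fullWindow <- function() c(400, 1300)

## ---------------------------------------------------------------------------
## SnowSpectrum

#' SnowSpectrum: a single reflectance spectrum with sample metadata
#'
#' Holds one hemispherical-directional reflectance factor (HDRF) spectrum on
#' a strictly increasing wavelength grid, tagged with a sample identifier,
#' a bloom colour group (`red`, `orange`, `green` or `clean`) and a
#' replicate number. Reflectance values are dimensionless and must be
#' finite and non-negative after validation.
#'
#' @slot wavelength numeric, strictly increasing wavelengths in nm.
#' @slot reflectance numeric, HDRF per wavelength.
#' @slot sampleId character scalar.
#' @slot colorGroup character scalar, one of `red`, `orange`, `green`,
#'   `clean`.
#' @slot replicate integer scalar.
#'
#' @seealso [readSpectrum()], [resampleToGrid()], [meanReflectance()]
#' @export
setClass("SnowSpectrum",
  representation(
    wavelength  = "numeric",
    reflectance = "numeric",
    sampleId    = "character",
    colorGroup  = "character",
    replicate   = "integer"
  ),
  prototype(
    wavelength  = numeric(),
    reflectance = numeric(),
    sampleId    = NA_character_,
    colorGroup  = "clean",
    replicate   = 1L
  )
)

setValidity("SnowSpectrum", function(object) {
  msg <- character()
  w <- object@wavelength
  r <- object@reflectance
  if (length(w) != length(r))
    msg <- c(msg, "wavelength and reflectance must have equal length")
  if (length(w) && any(!is.finite(w)))
    msg <- c(msg, "wavelengths must be finite")
  if (length(w) > 1 && any(diff(w) <= 0))
    msg <- c(msg, "wavelengths must be strictly increasing")
  if (length(r) && any(!is.finite(r)))
    msg <- c(msg, "reflectance values must be finite")
  if (length(r) && any(r < 0, na.rm = TRUE))
    msg <- c(msg, "reflectance values must be non-negative")
  if (length(object@sampleId) != 1)
    msg <- c(msg, "sampleId must be a single string")
  if (length(object@colorGroup) != 1 ||
      !object@colorGroup %in% .COLOR_GROUPS)
    msg <- c(msg, sprintf("colorGroup must be one of %s",
                          paste(.COLOR_GROUPS, collapse = ", ")))
  if (length(object@replicate) != 1 || is.na(object@replicate))
    msg <- c(msg, "replicate must be a single integer")
  if (length(msg)) msg else TRUE
})

#' Construct a SnowSpectrum
#'
#' @param wavelength numeric vector of wavelengths (nm), strictly increasing.
#' @param reflectance numeric vector of HDRF values, same length.
#' @param sampleId sample identifier.
#' @param colorGroup one of `"red"`, `"orange"`, `"green"`, `"clean"`.
#' @param replicate replicate number.
#' @return A [SnowSpectrum-class] object.
#' @examples
#' s <- SnowSpectrum(400:700, rep(0.25, 301), sampleId = "clean-1")
#' meanReflectance(s, 400, 700)
#' @export
SnowSpectrum <- function(wavelength, reflectance, sampleId = NA_character_,
                         colorGroup = "clean", replicate = 1L) {
  new("SnowSpectrum",
      wavelength  = as.numeric(wavelength),
      reflectance = as.numeric(reflectance),
      sampleId    = as.character(sampleId),
      colorGroup  = as.character(colorGroup),
      replicate   = as.integer(replicate))
}

## ---------------------------------------------------------------------------
## Irradiance

#' Irradiance: a downwelling spectral irradiance table
#'
#' Spectral irradiance Ed(lambda) in W m-2 nm-1 on a strictly increasing
#' wavelength grid. For radiative-forcing integrals the table must cover
#' the full 400--1300 nm analysis window.
#'
#' @slot wavelength numeric, strictly increasing wavelengths in nm.
#' @slot irradiance numeric, Ed in W m-2 nm-1, non-negative.
#' @seealso [defaultIrradiance()], [computeIRF()]
#' @export
setClass("Irradiance",
  representation(wavelength = "numeric", irradiance = "numeric"))

setValidity("Irradiance", function(object) {
  msg <- character()
  w <- object@wavelength
  e <- object@irradiance
  if (length(w) != length(e))
    msg <- c(msg, "wavelength and irradiance must have equal length")
  if (length(w) > 1 && any(diff(w) <= 0))
    msg <- c(msg, "wavelengths must be strictly increasing")
  if (length(e) && (any(!is.finite(e)) || any(e < 0)))
    msg <- c(msg, "irradiance must be finite and non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct an Irradiance table
#'
#' @param wavelength numeric wavelengths (nm).
#' @param irradiance numeric spectral irradiance (W m-2 nm-1).
#' @return An [Irradiance-class] object.
#' @export
Irradiance <- function(wavelength, irradiance) {
  new("Irradiance", wavelength = as.numeric(wavelength),
      irradiance = as.numeric(irradiance))
}

## ---------------------------------------------------------------------------
## BandDefinition

#' BandDefinition: a satellite band spectral response function
#'
#' Describes one satellite band by its centre, full width at half maximum
#' and spectral response function (SRF) shape. The default Sentinel-2A
#' visible/red-edge bands used for the chlorophyll band-depth index are
#' Band 3 (560 nm), Band 4 (665 nm) and Band 5 (705 nm) with nominal
#' bandwidths 36, 31 and 15 nm and boxcar SRFs; tabulated SRFs can be
#' supplied instead.
#'
#' @slot name band name, e.g. `"B4"`.
#' @slot center centre wavelength (nm).
#' @slot fwhm full width at half maximum (nm), positive.
#' @slot shape one of `"boxcar"`, `"gaussian"`, `"tabulated"`.
#' @slot srf data.frame with columns `wavelength_nm`, `weight` (only used
#'   when `shape == "tabulated"`); weights non-negative with positive sum.
#' @seealso [sentinel2Bands()], [bandEquivalentReflectance()]
#' @export
setClass("BandDefinition",
  representation(name = "character", center = "numeric", fwhm = "numeric",
                 shape = "character", srf = "data.frame"),
  prototype(srf = data.frame(wavelength_nm = numeric(), weight = numeric())))

setValidity("BandDefinition", function(object) {
  msg <- character()
  if (length(object@fwhm) != 1 || !is.finite(object@fwhm) || object@fwhm <= 0)
    msg <- c(msg, "fwhm must be a positive number")
  if (!object@shape %in% c("boxcar", "gaussian", "tabulated"))
    msg <- c(msg, "shape must be boxcar, gaussian or tabulated")
  if (object@shape == "tabulated") {
    srf <- object@srf
    if (!all(c("wavelength_nm", "weight") %in% names(srf)) || !nrow(srf))
      msg <- c(msg, "tabulated SRF needs wavelength_nm and weight columns")
    else if (any(srf$weight < 0) || sum(srf$weight) <= 0)
      msg <- c(msg, "tabulated SRF weights must be >= 0 with positive sum")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a BandDefinition
#'
#' @param name band name.
#' @param center centre wavelength (nm).
#' @param fwhm full width at half maximum (nm).
#' @param shape `"boxcar"` (default), `"gaussian"` or `"tabulated"`.
#' @param srf optional data.frame (`wavelength_nm`, `weight`) for tabulated
#'   SRFs.
#' @return A [BandDefinition-class] object.
#' @export
BandDefinition <- function(name, center, fwhm, shape = "boxcar",
                           srf = data.frame(wavelength_nm = numeric(),
                                            weight = numeric())) {
  new("BandDefinition", name = as.character(name), center = as.numeric(center),
      fwhm = as.numeric(fwhm), shape = as.character(shape),
      srf = as.data.frame(srf))
}

## ---------------------------------------------------------------------------
## PigmentProfile

#' PigmentProfile: the four quantified pigments of one sample
#'
#' Concentrations of all-trans-astaxanthin, chlorophyll a, chlorophyll b and
#' beta-carotene in micrograms per millilitre of melted snow. Missing values
#' (`NA`) are permitted at construction; operations that need a pigment
#' refuse to run on missing values rather than guessing.
#'
#' @slot astax,chla,chlb,bcar numeric scalars, >= 0 or NA.
#' @seealso [pigmentSignature()], [astaxChlaRatio()]
#' @export
setClass("PigmentProfile",
  representation(astax = "numeric", chla = "numeric", chlb = "numeric",
                 bcar = "numeric"))

setValidity("PigmentProfile", function(object) {
  vals <- c(object@astax, object@chla, object@chlb, object@bcar)
  if (length(vals) != 4)
    return("each pigment must be a single number (or NA)")
  bad <- !is.na(vals) & (!is.finite(vals) | vals < 0)
  if (any(bad)) "pigment concentrations must be >= 0 (or NA)" else TRUE
})

#' Construct a PigmentProfile
#'
#' @param astax,chla,chlb,bcar concentrations in ug ml-1 of melted snow;
#'   `NA` marks an unmeasured pigment.
#' @return A [PigmentProfile-class] object.
#' @examples
#' p <- PigmentProfile(astax = 2.39, chla = 0.434, chlb = 0.186, bcar = 0.13)
#' pigmentSignature(p)
#' @export
PigmentProfile <- function(astax = NA_real_, chla = NA_real_,
                           chlb = NA_real_, bcar = NA_real_) {
  new("PigmentProfile", astax = as.numeric(astax), chla = as.numeric(chla),
      chlb = as.numeric(chlb), bcar = as.numeric(bcar))
}

## ---------------------------------------------------------------------------
## CellPopulation

#' CellPopulation: one morphological cell population of a sample
#'
#' A population is described by its geometric shape class (sphere or prolate
#' spheroid, following standard phytoplankton biovolume geometry), its mean
#' dimensions in micrometres and its cell density in cells per millilitre of
#' melted snow. Spheres need only the diameter (`dimMajor`); prolate
#' spheroids need major and minor axes.
#'
#' @slot shape `"sphere"` or `"prolate_spheroid"`.
#' @slot dimMajor diameter (sphere) or major axis (spheroid), um.
#' @slot dimMinor minor axis (spheroid), um; NA for spheres.
#' @slot density cells per ml of melted snow, >= 0.
#' @slot label free-text population label.
#' @seealso [cellVolume()], [totalBiovolume()], [populationFractions()]
#' @export
setClass("CellPopulation",
  representation(shape = "character", dimMajor = "numeric",
                 dimMinor = "numeric", density = "numeric",
                 label = "character"),
  prototype(dimMinor = NA_real_, label = NA_character_))

setValidity("CellPopulation", function(object) {
  msg <- character()
  if (!object@shape %in% c("sphere", "prolate_spheroid"))
    msg <- c(msg, "shape must be sphere or prolate_spheroid")
  if (!is.finite(object@density) || object@density < 0)
    msg <- c(msg, "density must be a non-negative number")
  if (!is.finite(object@dimMajor) || object@dimMajor < 0)
    msg <- c(msg, "dimMajor must be a non-negative number")
  if (object@shape == "prolate_spheroid" &&
      (!is.na(object@dimMinor) && object@dimMinor < 0))
    msg <- c(msg, "dimMinor must be non-negative")
  if (object@density > 0 && object@dimMajor <= 0)
    msg <- c(msg, "dimensions must be positive when density > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a CellPopulation
#'
#' @param shape `"sphere"` or `"prolate_spheroid"`.
#' @param dimMajor diameter (sphere) or major axis (um).
#' @param dimMinor minor axis (um); required for prolate spheroids.
#' @param density cells per ml.
#' @param label optional population label.
#' @return A [CellPopulation-class] object.
#' @examples
#' cellVolume(CellPopulation("sphere", dimMajor = 10, density = 1000))
#' @export
CellPopulation <- function(shape, dimMajor, dimMinor = NA_real_,
                           density = 0, label = NA_character_) {
  new("CellPopulation", shape = as.character(shape),
      dimMajor = as.numeric(dimMajor), dimMinor = as.numeric(dimMinor),
      density = as.numeric(density), label = as.character(label))
}

## ---------------------------------------------------------------------------
## SampleBiology

#' SampleBiology: biology and snow-physics measurements for one sample
#'
#' Joins the cell populations, pigment profile and optional snow physical
#' covariates of one sample. The `sampleId` is the join key to the sample's
#' reflectance spectrum.
#'
#' @slot sampleId character scalar.
#' @slot colorGroup bloom colour group.
#' @slot populations list of [CellPopulation-class] objects.
#' @slot pigments a [PigmentProfile-class].
#' @slot laip light-absorbing inorganic particles, mg m-2, or NA.
#' @slot snowDepth snowpack depth, cm, or NA.
#' @slot surfaceTemp snow surface temperature, degrees C, or NA.
#' @slot waterContent snow water content, percent, or NA.
#' @export
setClass("SampleBiology",
  representation(sampleId = "character", colorGroup = "character",
                 populations = "list", pigments = "PigmentProfile",
                 laip = "numeric", snowDepth = "numeric",
                 surfaceTemp = "numeric", waterContent = "numeric"),
  prototype(laip = NA_real_, snowDepth = NA_real_, surfaceTemp = NA_real_,
            waterContent = NA_real_))

setValidity("SampleBiology", function(object) {
  msg <- character()
  if (!object@colorGroup %in% .COLOR_GROUPS)
    msg <- c(msg, "colorGroup must be red, orange, green or clean")
  if (!all(vapply(object@populations, inherits, logical(1), "CellPopulation")))
    msg <- c(msg, "populations must be a list of CellPopulation objects")
  if (object@colorGroup != "clean" && length(object@populations) < 1)
    msg <- c(msg, "non-clean samples need at least one cell population")
  if (!is.na(object@laip) && object@laip < 0)
    msg <- c(msg, "laip must be >= 0 or NA")
  if (length(msg)) msg else TRUE
})

#' Construct a SampleBiology record
#'
#' @param sampleId sample identifier (joins to the sample's spectrum).
#' @param colorGroup bloom colour group.
#' @param populations list of [CellPopulation-class] objects.
#' @param pigments a [PigmentProfile-class].
#' @param laip light-absorbing inorganic particles (mg m-2) or NA.
#' @param snowDepth snow depth (cm) or NA.
#' @param surfaceTemp surface temperature (C) or NA.
#' @param waterContent water content (percent) or NA.
#' @return A [SampleBiology-class] object.
#' @export
SampleBiology <- function(sampleId, colorGroup, populations = list(),
                          pigments = PigmentProfile(), laip = NA_real_,
                          snowDepth = NA_real_, surfaceTemp = NA_real_,
                          waterContent = NA_real_) {
  new("SampleBiology", sampleId = as.character(sampleId),
      colorGroup = as.character(colorGroup), populations = populations,
      pigments = pigments, laip = as.numeric(laip),
      snowDepth = as.numeric(snowDepth),
      surfaceTemp = as.numeric(surfaceTemp),
      waterContent = as.numeric(waterContent))
}

## ---------------------------------------------------------------------------
## BloomArchetype

#' BloomArchetype: generator parameters for one bloom colour
#'
#' Bundles everything the synthetic-data generator needs to emulate one
#' community type: mean pigment concentrations and their dispersion
#' structure, cell-population geometry and density specifications,
#' pigment-specific Gaussian absorption kernels (optical depth per ug ml-1),
#' residual broadband/NIR optical depths capturing non-pigment differences
#' between bloom patches and clean snow, and the noise model.
#'
#' @slot name archetype name (`red`, `orange`, `green`, `clean`).
#' @slot pigmentMeans a [PigmentProfile-class] of group-mean concentrations.
#' @slot sharedPigmentSd sd (log scale) of the per-sample shared pigment
#'   factor: all four pigments of a sample scale together by this lognormal
#'   factor, emulating bloom patchiness.
#' @slot pigmentNoiseSd sd (log scale) of independent per-pigment noise.
#' @slot densityCoupling exponent coupling the shared pigment factor to the
#'   sample's relative cell density (pigment ~ density^coupling), which
#'   reproduces the observed positive pigment-abundance correlations.
#' @slot pigmentCoupling named numeric (astax, chla, chlb, bcar): exponent
#'   applied to the shared factor per pigment. 1 means the pigment scales
#'   fully with bloom intensity; 0 decouples it. Red communities use 0 for
#'   the chlorophylls: secondary carotenogenesis accumulates astaxanthin
#'   with bloom development while the chlorophyll pool stays comparatively
#'   stable, which is what makes the band-depth index a poor chlorophyll
#'   proxy in red snow.
#' @slot populations data.frame with one row per cell population: `label`,
#'   `shape`, `dim_major_um`, `dim_minor_um`, `dim_cv`, `density_cells_ml`,
#'   `density_cv`.
#' @slot absorption data.frame with one row per pigment: `pigment`,
#'   `center_nm`, `width_nm` (Gaussian sd), `strength` (peak optical depth
#'   per ug ml-1, already including the archetype's in-vivo packaging
#'   efficiency).
#' @slot residualVisOd optical depth of the non-pigment visible absorber
#'   (mineral dust and other impurities), applied as a linear ramp that
#'   vanishes at 900 nm.
#' @slot residualNirOd optical depth (possibly negative, i.e. brightening
#'   from snow-physical differences) applied over the NIR with a smooth
#'   onset at 700 nm.
#' @slot laipMean,laipCv mean and coefficient of variation of the sample
#'   LAIP load (mg m-2), which scales the visible residual per sample.
#' @slot siteSd sd of the per-site reflectance level shift.
#' @slot noiseSd sd of white measurement noise added per wavelength.
#' @seealso [defaultArchetypes()], [synthBloomSpectrum()], [synthSampleSet()]
#' @export
setClass("BloomArchetype",
  representation(name = "character", pigmentMeans = "PigmentProfile",
                 sharedPigmentSd = "numeric", pigmentNoiseSd = "numeric",
                 densityCoupling = "numeric", pigmentCoupling = "numeric",
                 populations = "data.frame",
                 absorption = "data.frame", residualVisOd = "numeric",
                 residualNirOd = "numeric", laipMean = "numeric",
                 laipCv = "numeric", siteSd = "numeric", noiseSd = "numeric"))

setValidity("BloomArchetype", function(object) {
  msg <- character()
  if (!object@name %in% .COLOR_GROUPS)
    msg <- c(msg, "name must be red, orange, green or clean")
  if (length(object@pigmentCoupling) &&
      (length(object@pigmentCoupling) != 4 ||
       !all(c("astax", "chla", "chlb", "bcar") %in%
            names(object@pigmentCoupling))))
    msg <- c(msg, "pigmentCoupling must be named astax, chla, chlb, bcar")
  if (nrow(object@absorption) &&
      any(object@absorption$strength < 0))
    msg <- c(msg, "absorption strengths must be >= 0")
  if (object@name == "clean") {
    pm <- object@pigmentMeans
    tot <- sum(c(pm@astax, pm@chla, pm@chlb, pm@bcar), na.rm = TRUE)
    if (tot > 0 || nrow(object@populations) > 0)
      msg <- c(msg, "clean archetype must have zero pigments and populations")
  }
  if (length(msg)) msg else TRUE
})
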