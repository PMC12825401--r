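#' Accessors for snowbloom classes
#'
#' `wavelengths()` returns the wavelength grid (nm); `reflectance()` the
#' HDRF values; `irradiance()` the spectral irradiance; `sampleId()`,
#' `colorGroup()` and `replicate()` the sample metadata.
#'
#' @param object a snowbloom S4 object.
#' @return The slot contents.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(object) standardGeneric("wavelengths"))

#' @rdname accessors
#' @export
setGeneric("reflectance", function(object) standardGeneric("reflectance"))

#' @rdname accessors
#' @export
setGeneric("irradiance", function(object) standardGeneric("irradiance"))

#' @rdname accessors
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setGeneric("colorGroup", function(object) standardGeneric("colorGroup"))

#' @rdname accessors
#' @export
setGeneric("replicateNum", function(object) standardGeneric("replicateNum"))

#' @rdname accessors
#' @export
setMethod("wavelengths", "SnowSpectrum", function(object) object@wavelength)

#' @rdname accessors
#' @export
setMethod("reflectance", "SnowSpectrum", function(object) object@reflectance)

#' @rdname accessors
#' @export
setMethod("sampleId", "SnowSpectrum", function(object) object@sampleId)

#' @rdname accessors
#' @export
setMethod("colorGroup", "SnowSpectrum", function(object) object@colorGroup)

#' @rdname accessors
#' @export
setMethod("replicateNum", "SnowSpectrum", function(object) object@replicate)

#' @rdname accessors
#' @export
setMethod("wavelengths", "Irradiance", function(object) object@wavelength)

#' @rdname accessors
#' @export
setMethod("irradiance", "Irradiance", function(object) object@irradiance)

#' @rdname accessors
#' @export
setMethod("sampleId", "SampleBiology", function(object) object@sampleId)

#' @rdname accessors
#' @export
setMethod("colorGroup", "SampleBiology", function(object) object@colorGroup)

#' @rdname accessors
#' @export
setGeneric("pigments", function(object) standardGeneric("pigments"))

#' @rdname accessors
#' @export
setMethod("pigments", "SampleBiology", function(object) object@pigments)

#' @rdname accessors
#' @export
setGeneric("cellPopulations",
           function(object) standardGeneric("cellPopulations"))

#' @rdname accessors
#' @export
setMethod("cellPopulations", "SampleBiology",
          function(object) object@populations)

setMethod("show", "SnowSpectrum", function(object) {
  w <- object@wavelength
  cat(sprintf("SnowSpectrum '%s' (%s, rep %d): %d points, %.0f-%.0f nm\n",
              object@sampleId, object@colorGroup, object@replicate,
              length(w), if (length(w)) min(w) else NA,
              if (length(w)) max(w) else NA))
  if (length(w))
    cat(sprintf("  HDRF range %.4f-%.4f\n",
                min(object@reflectance), max(object@reflectance)))
})

setMethod("show", "Irradiance", function(object) {
  w <- object@wavelength
  cat(sprintf("Irradiance: %d points, %.0f-%.0f nm, peak %.3f W m-2 nm-1\n",
              length(w), min(w), max(w), max(object@irradiance)))
})

setMethod("show", "BandDefinition", function(object) {
  cat(sprintf("BandDefinition %s: center %.1f nm, fwhm %.1f nm, %s SRF\n",
              object@name, object@center, object@fwhm, object@shape))
})

setMethod("show", "PigmentProfile", function(object) {
  cat(sprintf(
    "PigmentProfile (ug ml-1): astax %.3g, chla %.3g, chlb %.3g, bcar %.3g\n",
    object@astax, object@chla, object@chlb, object@bcar))
})

setMethod("show", "CellPopulation", function(object) {
  cat(sprintf("CellPopulation [%s] %s: %.1f x %.1f um, %.0f cells ml-1\n",
              ifelse(is.na(object@label), "", object@label), object@shape,
              object@dimMajor,
              ifelse(is.na(object@dimMinor), object@dimMajor, object@dimMinor),
              object@density))
})

setMethod("show", "SampleBiology", function(object) {
  cat(sprintf("SampleBiology '%s' (%s): %d population(s)\n",
              object@sampleId, object@colorGroup, length(object@populations)))
})

setMethod("show", "BloomArchetype", function(object) {
  cat(sprintf("BloomArchetype '%s': %d population(s), %d absorption kernel(s)\n",
              object@name, nrow(object@populations), nrow(object@absorption)))
})
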