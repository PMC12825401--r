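## Band-range reflectance means, Sentinel-2A band-equivalent reflectances
## and the continuum-removal chlorophyll band depth at Band 4 (IB4).
##
## All integrals use the trapezoid rule on the spectrum's grid, with the
## window endpoints inserted by linear interpolation when they fall between
## grid points, so results are exact for the piecewise-linear interpolant
## the sampled spectrum represents.

## Trapezoid integral of y(w) over [lo, hi], inserting interpolated
## endpoint values. Requires coverage.
.windowIntegral <- function(w, y, lo, hi) {
  if (lo >= hi) stop("window start must be below window end", call. = FALSE)
  if (lo < min(w) || hi > max(w))
    stop(sprintf("window %.1f-%.1f nm outside spectrum support %.1f-%.1f nm",
                 lo, hi, min(w), max(w)), call. = FALSE)
  inside <- w > lo & w < hi
  wv <- c(lo, w[inside], hi)
  yv <- c(stats::approx(w, y, xout = lo)$y, y[inside],
          stats::approx(w, y, xout = hi)$y)
  pracma::trapz(wv, yv)
}

#' Mean reflectance over a wavelength interval
#'
#' Trapezoid-integral mean of the HDRF over `[lo, hi]`, the operation used
#' to summarise spectra over the visible/PAR window (400--700 nm) and the
#' NIR window (700--1300 nm).
#'
#' @param s a [SnowSpectrum-class] covering `[lo, hi]`.
#' @param lo,hi window limits in nm, `lo < hi`.
#' @return The mean reflectance (dimensionless).
#' @examples
#' s <- SnowSpectrum(400:1300, (400:1300) / 1300)
#' meanReflectance(s, 400, 700)  # 550/1300
#' @export
meanReflectance <- function(s, lo, hi) {
  stopifnot(is(s, "SnowSpectrum"))
  .windowIntegral(s@wavelength, s@reflectance, lo, hi) / (hi - lo)
}

#' Sentinel-2A band definitions for the chlorophyll band-depth index
#'
#' Bands 3 (560 nm), 4 (665 nm) and 5 (705 nm) with nominal bandwidths
#' 36, 31 and 15 nm and boxcar spectral response functions. Tabulated SRFs
#' can be substituted via [readBandConfig()].
#'
#' @return A named list of three [BandDefinition-class] objects.
#' @export
sentinel2Bands <- function() {
  list(B3 = BandDefinition("B3", 560, 36),
       B4 = BandDefinition("B4", 665, 31),
       B5 = BandDefinition("B5", 705, 15))
}

#' Band-equivalent reflectance under a spectral response function
#'
#' Convolves a hyperspectral reflectance spectrum with a band's SRF:
#' the SRF-weighted mean `integral(R * S) / integral(S)`. The result is
#' always bounded by the spectrum's minimum and maximum over the band
#' support.
#'
#' @param s a [SnowSpectrum-class] covering the band support.
#' @param band a [BandDefinition-class].
#' @return The band-equivalent reflectance.
#' @export
bandEquivalentReflectance <- function(s, band) {
  stopifnot(is(s, "SnowSpectrum"), is(band, "BandDefinition"))
  w <- s@wavelength
  r <- s@reflectance
  if (band@shape == "boxcar") {
    lo <- band@center - band@fwhm / 2
    hi <- band@center + band@fwhm / 2
    return(.windowIntegral(w, r, lo, hi) / (hi - lo))
  }
  if (band@shape == "gaussian") {
    sd <- band@fwhm / (2 * sqrt(2 * log(2)))
    lo <- band@center - 4 * sd
    hi <- band@center + 4 * sd
    if (lo < min(w) || hi > max(w))
      stop(sprintf("band %s support outside spectrum", band@name),
           call. = FALSE)
    idx <- w >= lo & w <= hi
    wv <- w[idx]
    sw <- stats::dnorm(wv, band@center, sd)
    return(pracma::trapz(wv, r[idx] * sw) / pracma::trapz(wv, sw))
  }
  ## tabulated SRF: evaluate on the union of spectrum and SRF nodes
  srf <- band@srf[order(band@srf$wavelength_nm), ]
  lo <- min(srf$wavelength_nm); hi <- max(srf$wavelength_nm)
  if (lo < min(w) || hi > max(w))
    stop(sprintf("band %s support outside spectrum", band@name),
         call. = FALSE)
  wv <- sort(unique(c(srf$wavelength_nm, w[w >= lo & w <= hi])))
  sw <- stats::approx(srf$wavelength_nm, srf$weight, xout = wv)$y
  rv <- stats::approx(w, r, xout = wv)$y
  pracma::trapz(wv, rv * sw) / pracma::trapz(wv, sw)
}

#' Continuum reflectance between Bands 3 and 5 at Band 4
#'
#' Linear interpolation of the Band 3 and Band 5 reflectances to the Band 4
#' position: `RB3 + ((664 - 560) / (704 - 560)) * (RB5 - RB3)`, i.e. an
#' interpolation factor of 104/144. The constants 664 and 704 nm are used
#' exactly as published for this index even though the band centres are
#' nominally 665 and 705 nm.
#'
#' @param rb3,rb5 band-equivalent reflectances in Bands 3 and 5.
#' @return The continuum reflectance at Band 4.
#' @export
continuumReflectanceB4 <- function(rb3, rb5) {
  stopifnot(is.finite(rb3), is.finite(rb5))
  rb3 + ((664 - 560) / (704 - 560)) * (rb5 - rb3)
}

#' Scaled band depth at Band 4 (IB4)
#'
#' The continuum-removed chlorophyll absorption depth
#' `(RcontB4 - RB4) / RcontB4`: positive when Band 4 sits below the
#' straight continuum spanned by Bands 3 and 5 (chlorophyll absorption),
#' negative when above, and never larger than 1. `percent = TRUE` returns
#' the index on the x100 scale commonly reported for field blooms.
#'
#' @param rb3,rb4,rb5 band-equivalent reflectances.
#' @param percent return 100 x the band depth (default FALSE).
#' @return The band depth (dimensionless, or percent).
#' @export
bandDepthIB4 <- function(rb3, rb4, rb5, percent = FALSE) {
  rcont <- continuumReflectanceB4(rb3, rb5)
  if (!is.finite(rcont) || rcont <= 0)
    stop("continuum reflectance is not positive; IB4 undefined",
         call. = FALSE)
  out <- (rcont - rb4) / rcont
  if (percent) 100 * out else out
}

#' IB4 band-depth index from a full spectrum
#'
#' Composes [bandEquivalentReflectance()] over the three bands with
#' [bandDepthIB4()].
#'
#' @param s a [SnowSpectrum-class] covering all three band supports.
#' @param bands named list of three [BandDefinition-class] objects
#'   (`B3`, `B4`, `B5`); default [sentinel2Bands()].
#' @param percent return the x100-scaled index (default FALSE).
#' @return The IB4 band depth.
#' @export
ib4FromSpectrum <- function(s, bands = sentinel2Bands(), percent = FALSE) {
  stopifnot(all(c("B3", "B4", "B5") %in% names(bands)))
  rb3 <- bandEquivalentReflectance(s, bands$B3)
  rb4 <- bandEquivalentReflectance(s, bands$B4)
  rb5 <- bandEquivalentReflectance(s, bands$B5)
  bandDepthIB4(rb3, rb4, rb5, percent = percent)
}

#' Percent reflectance reduction relative to clean snow
#'
#' `100 * (rClean - rAlgae) / rClean`.
#'
#' @param rClean clean-snow reflectance (> 0).
#' @param rAlgae bloom reflectance.
#' @return Reduction in percent (negative when the bloom is brighter).
#' @examples
#' percentReduction(0.25, 0.11)  # 56
#' @export
percentReduction <- function(rClean, rAlgae) {
  if (!is.finite(rClean) || rClean <= 0)
    stop("clean reflectance must be positive", call. = FALSE)
  100 * (rClean - rAlgae) / rClean
}

#' Read band definitions from a YAML or JSON config
#'
#' The config is a list of entries with fields `name`, `center_nm`,
#' `fwhm_nm`, optional `shape` (`boxcar`, `gaussian`, `tabulated`) and
#' optional `srf_table` (path to a CSV `wavelength_nm, weight`, resolved
#' relative to the config file).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list of [BandDefinition-class] objects.
#' @export
readBandConfig <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
    stop("band config must be .yaml, .yml or .json", call. = FALSE))
  bands <- lapply(cfg, function(b) {
    shape <- if (is.null(b$shape)) "boxcar" else b$shape
    srf <- data.frame(wavelength_nm = numeric(), weight = numeric())
    if (!is.null(b$srf_table)) {
      f <- b$srf_table
      if (!file.exists(f)) f <- file.path(dirname(path), b$srf_table)
      tab <- .read_two_col(f)
      srf <- data.frame(wavelength_nm = tab$wavelength, weight = tab$value)
      shape <- "tabulated"
    }
    BandDefinition(b$name, b$center_nm, b$fwhm_nm, shape = shape, srf = srf)
  })
  names(bands) <- vapply(bands, function(b) b@name, character(1))
  bands
}
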