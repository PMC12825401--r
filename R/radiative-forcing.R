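## Clean-snow reference construction and instantaneous radiative forcing
## (IRF): the extra solar power absorbed by the snowpack because algae
## darken the surface, integrated as Ed(l) * (Rclean(l) - Ralgae(l)) over a
## wavelength window, in W m-2.

#' Arithmetic-mean clean-snow reference spectrum
#'
#' Pointwise arithmetic mean of a set of clean-snow spectra measured across
#' the snowfield; used as the reference reflectance in IRF computations.
#' All spectra must share a common wavelength grid.
#'
#' @param cleans non-empty list of [SnowSpectrum-class] objects on one grid.
#' @return A [SnowSpectrum-class] with `sampleId = "clean-mean"`.
#' @export
meanCleanSpectrum <- function(cleans) {
  if (!length(cleans)) stop("need at least one clean spectrum", call. = FALSE)
  stopifnot(all(vapply(cleans, is, logical(1), "SnowSpectrum")))
  w <- cleans[[1]]@wavelength
  for (s in cleans)
    if (!isTRUE(all.equal(s@wavelength, w)))
      stop("clean spectra are not on a common wavelength grid", call. = FALSE)
  m <- rowMeans(vapply(cleans, function(s) s@reflectance,
                       numeric(length(w))))
  SnowSpectrum(w, m, sampleId = "clean-mean", colorGroup = "clean")
}

#' Instantaneous radiative forcing over a wavelength window
#'
#' Trapezoid integral of `Ed(l) * (Rclean(l) - Ralgae(l))` over
#' `[lo, hi]`, in W m-2. Positive IRF means the bloom absorbs more solar
#' power than clean snow; negative values occur when the bloom patch is
#' more reflective than the clean reference (as observed for orange blooms
#' in the NIR). The two spectra must share a grid; the irradiance table is
#' interpolated onto it. Because the shared 700-nm endpoint receives half
#' weight in each window, PAR (400--700 nm) and NIR (700--1300 nm) forcings
#' add exactly to the full-window forcing.
#'
#' @param clean,algae [SnowSpectrum-class] objects on a common grid
#'   covering `[lo, hi]`.
#' @param ed an [Irradiance-class] covering `[lo, hi]`.
#' @param lo,hi window limits in nm.
#' @return IRF in W m-2.
#' @examples
#' w <- 400:1300
#' clean <- SnowSpectrum(w, rep(0.25, length(w)))
#' algae <- SnowSpectrum(w, rep(0.15, length(w)))
#' ed <- Irradiance(w, rep(1, length(w)))
#' computeIRF(clean, algae, ed, 400, 700)  # 0.1 * 300 = 30 W m-2
#' @export
computeIRF <- function(clean, algae, ed, lo = 400, hi = 1300) {
  stopifnot(is(clean, "SnowSpectrum"), is(algae, "SnowSpectrum"),
            is(ed, "Irradiance"))
  w <- clean@wavelength
  if (!isTRUE(all.equal(algae@wavelength, w)))
    stop("clean and algae spectra are not on a common grid", call. = FALSE)
  if (lo < min(ed@wavelength) || hi > max(ed@wavelength))
    stop("irradiance table does not cover the requested window",
         call. = FALSE)
  edv <- stats::approx(ed@wavelength, ed@irradiance, xout = w)$y
  integrand <- edv * (clean@reflectance - algae@reflectance)
  .windowIntegral(w, integrand, lo, hi)
}

#' Normalize IRF by algal biomass
#'
#' Expresses an IRF relative to the sample's algal abundance:
#' per 10^3 cells ml-1 (`mode = "cells"`) or per 10^6 um^3 ml-1 of total
#' biovolume (`mode = "biovolume"`).
#'
#' @param irf IRF in W m-2.
#' @param denominator cell density (cells ml-1) or total biovolume
#'   (um^3 ml-1), matching `mode`; must be positive.
#' @param mode `"cells"` or `"biovolume"`.
#' @return Normalized IRF (W m-2 per scale unit).
#' @examples
#' normalizeIRF(30, 1000, "cells")  # 30 per 10^3 cells ml-1
#' @export
normalizeIRF <- function(irf, denominator, mode = c("cells", "biovolume")) {
  mode <- match.arg(mode)
  if (!is.finite(denominator) || denominator <= 0)
    stop("normalization denominator must be positive", call. = FALSE)
  scale <- if (mode == "cells") 1e3 else 1e6
  irf / (denominator / scale)
}

#' Bundled synthetic clear-sky irradiance spectrum
#'
#' A smooth analytic approximation to a clear-sky downwelling solar
#' spectrum: a 5800-K Planck shape scaled so that the irradiance
#' integrated over the PAR window (400--700 nm) equals `parTotal` W m-2.
#' The default total (318 W m-2) emulates mid-day late-season alpine
#' illumination consistent with the bloom campaign conditions the package's
#' synthetic study design mirrors. This table is a synthetic stand-in, not
#' an authoritative solar spectrum: absolute IRF values depend on it, while
#' window ratios and group orderings are insensitive to the exact shape.
#' Any user-supplied CSV read with [readIrradiance()] can be used instead.
#'
#' @param grid wavelength grid in nm (default the 1-nm analysis grid).
#' @param parTotal integrated irradiance over 400--700 nm, W m-2.
#' @return An [Irradiance-class].
#' @export
defaultIrradiance <- function(grid = analysisGrid(), parTotal = 318) {
  c2 <- 1.4388e7  # second radiation constant, nm K
  temp <- 5800
  shape <- grid^-5 / (exp(c2 / (grid * temp)) - 1)
  ed <- Irradiance(grid, shape)
  par_int <- .windowIntegral(grid, shape, 400, 700)
  Irradiance(grid, shape * parTotal / par_int)
}
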