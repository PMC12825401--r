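## Geometric cell volumes, total biovolume, pigment signatures and
## biomass-normalised pigment content.

#' Geometric cell volume of a population
#'
#' Standard phytoplankton biovolume geometry: spheres have volume
#' `(pi/6) d^3`; prolate spheroids `(pi/6) a b^2` with `a` the major and
#' `b` the minor axis. By default the volume is computed from the
#' population's mean dimensions (`mode = "mean_dims"`); with
#' `mode = "mean_volume"` and vectors of per-cell dimensions, the mean of
#' per-cell volumes is returned instead (the two differ for dispersed
#' sizes because volume is cubic in the dimensions).
#'
#' @param pop a [CellPopulation-class], or (for `mode = "mean_volume"`)
#'   a list with fields `shape`, `dimMajor`, `dimMinor` where the
#'   dimensions may be vectors of per-cell measurements.
#' @param mode `"mean_dims"` (default) or `"mean_volume"`.
#' @return Cell volume in um^3.
#' @examples
#' cellVolume(CellPopulation("sphere", 10, density = 1))      # 523.6
#' cellVolume(CellPopulation("prolate_spheroid", 25.9, 14.6, 1))
#' @export
cellVolume <- function(pop, mode = c("mean_dims", "mean_volume")) {
  mode <- match.arg(mode)
  if (is(pop, "CellPopulation")) {
    shape <- pop@shape; a <- pop@dimMajor; b <- pop@dimMinor
  } else {
    shape <- pop$shape; a <- pop$dimMajor; b <- pop$dimMinor
  }
  vol <- switch(shape,
    sphere = (pi / 6) * a^3,
    prolate_spheroid = {
      if (all(is.na(b)))
        stop("prolate spheroid requires a minor axis", call. = FALSE)
      (pi / 6) * a * b^2
    },
    stop("unknown shape: ", shape, call. = FALSE))
  if (mode == "mean_dims") {
    if (length(vol) != 1)
      stop("mean_dims mode expects scalar dimensions", call. = FALSE)
    vol
  } else {
    mean(vol)
  }
}

#' Total algal biovolume of a sample
#'
#' Sum over populations of cell volume times cell density, in um^3 per ml
#' of melted snow. For multi-population samples (e.g. green blooms with
#' ellipsoidal plus small spherical cells) the contributions add.
#'
#' @param pops list of [CellPopulation-class] objects (or a single one).
#' @param mode passed to [cellVolume()].
#' @return Total biovolume in um^3 ml-1.
#' @export
totalBiovolume <- function(pops, mode = "mean_dims") {
  if (is(pops, "CellPopulation")) pops <- list(pops)
  if (!length(pops)) stop("need at least one population", call. = FALSE)
  sum(vapply(pops, function(p) cellVolume(p, mode = mode) * p@density,
             numeric(1)))
}

.profile_values <- function(p, chlbMissingAsZero = FALSE) {
  v <- c(astax = p@astax, chla = p@chla, chlb = p@chlb, bcar = p@bcar)
  if (chlbMissingAsZero && is.na(v["chlb"])) v["chlb"] <- 0
  v
}

#' Pigment signature: percentage contribution of each pigment
#'
#' Each pigment's share of the total pigment pool, in percent; the four
#' shares sum to exactly 100. All four concentrations must be present
#' unless `chlbMissingAsZero = TRUE`, which treats a missing chlorophyll b
#' as zero for the total (useful when Chl b was below detection).
#'
#' @param p a [PigmentProfile-class] with total > 0.
#' @param chlbMissingAsZero treat `NA` Chl b as 0 (default FALSE).
#' @return Named numeric vector (`astax`, `chla`, `chlb`, `bcar`), percent.
#' @export
pigmentSignature <- function(p, chlbMissingAsZero = FALSE) {
  stopifnot(is(p, "PigmentProfile"))
  v <- .profile_values(p, chlbMissingAsZero)
  if (any(is.na(v)))
    stop("pigment profile has missing values; signature undefined",
         call. = FALSE)
  tot <- sum(v)
  if (tot <= 0)
    stop("total pigment concentration must be positive", call. = FALSE)
  100 * v / tot
}

#' Astaxanthin : chlorophyll a ratio
#'
#' Mass ratio of astaxanthin to chlorophyll a, an indicator of the balance
#' between photoprotection and photosynthetic capacity.
#'
#' @param p a [PigmentProfile-class] with `chla > 0`.
#' @return The ratio (dimensionless).
#' @export
astaxChlaRatio <- function(p) {
  stopifnot(is(p, "PigmentProfile"))
  if (is.na(p@astax) || is.na(p@chla))
    stop("astaxanthin and chlorophyll a must both be measured",
         call. = FALSE)
  if (p@chla <= 0)
    stop("chlorophyll a must be positive for the ratio", call. = FALSE)
  p@astax / p@chla
}

#' Pigment content per cell and per biovolume
#'
#' Divides the pigment concentrations (ug per ml of melted snow) by the
#' sample's total cell density (cells ml-1) or total biovolume
#' (um^3 ml-1), yielding ug per cell or ug per um^3.
#'
#' @param p a [PigmentProfile-class].
#' @param density total cell density in cells ml-1 (> 0).
#' @return Named numeric vector of per-cell (or per-um^3) contents; `NA`
#'   entries propagate for unmeasured pigments.
#' @export
pigmentPerCell <- function(p, density) {
  stopifnot(is(p, "PigmentProfile"))
  if (!is.finite(density) || density <= 0)
    stop("cell density must be positive", call. = FALSE)
  .profile_values(p) / density
}

#' @rdname pigmentPerCell
#' @param biovolume total biovolume in um^3 ml-1 (> 0).
#' @export
pigmentPerBiovolume <- function(p, biovolume) {
  stopifnot(is(p, "PigmentProfile"))
  if (!is.finite(biovolume) || biovolume <= 0)
    stop("biovolume must be positive", call. = FALSE)
  .profile_values(p) / biovolume
}

#' Population share of total cell density
#'
#' Each population's percentage of the sample's total cell density.
#'
#' @param pops list of [CellPopulation-class] objects.
#' @return Numeric vector of percentages (named by population label where
#'   available), summing to 100.
#' @examples
#' pops <- list(CellPopulation("prolate_spheroid", 21.1, 14.7, 97815),
#'              CellPopulation("sphere", 8.3, density = 2185))
#' populationFractions(pops)  # 97.815 and 2.185
#' @export
populationFractions <- function(pops) {
  if (is(pops, "CellPopulation")) pops <- list(pops)
  dens <- vapply(pops, function(p) p@density, numeric(1))
  tot <- sum(dens)
  if (tot <= 0) stop("total cell density must be positive", call. = FALSE)
  out <- 100 * dens / tot
  names(out) <- vapply(pops, function(p) p@label, character(1))
  out
}
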