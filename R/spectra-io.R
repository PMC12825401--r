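## Reading, validating, resampling and writing spectra and biology tables.
##
## CSV dialect (documented in the README): comma-separated, '.' decimal,
## optional single header line. A spectrum file has two columns,
## wavelength_nm and value. Rows outside the instrument range 350-2500 nm
## are rejected; duplicate wavelengths are collapsed by their mean.

.INSTRUMENT_RANGE <- c(350, 2500)

.read_two_col <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!length(trimws(lines)[nzchar(trimws(lines))]))
    stop("empty spectrum file: ", path, call. = FALSE)
  raw <- tryCatch(
    utils::read.csv(text = lines, header = FALSE, colClasses = "character",
                    strip.white = TRUE, blank.lines.skip = TRUE),
    error = function(e) stop("cannot parse '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (!nrow(raw)) stop("empty spectrum file: ", path, call. = FALSE)
  if (ncol(raw) < 2)
    stop("spectrum file must have two columns: ", path, call. = FALSE)
  ## optional single header line: drop it when the first row is non-numeric
  first <- suppressWarnings(as.numeric(raw[1, 1:2]))
  if (any(is.na(first))) raw <- raw[-1, , drop = FALSE]
  if (!nrow(raw)) stop("empty spectrum file: ", path, call. = FALSE)
  w <- suppressWarnings(as.numeric(raw[[1]]))
  v <- suppressWarnings(as.numeric(raw[[2]]))
  bad <- which(is.na(w) | is.na(v))
  if (length(bad))
    stop(sprintf("non-numeric value in '%s' at data row %d ('%s, %s')",
                 path, bad[1], raw[bad[1], 1], raw[bad[1], 2]),
         call. = FALSE)
  data.frame(wavelength = w, value = v)
}

#' Read a reflectance spectrum from a two-column CSV
#'
#' Reads a `wavelength_nm, value` table (optional single header line),
#' drops rows outside the instrument range 350--2500 nm, collapses
#' duplicate wavelengths by their mean, and validates the result.
#' Negative reflectance values -- occasional instrument noise around very
#' dark targets -- are clipped to zero with a warning by default;
#' `negative = "error"` enforces strict validation instead.
#'
#' @param path path to the CSV file.
#' @param sampleId,colorGroup,replicate sample metadata attached to the
#'   returned spectrum.
#' @param negative `"clip"` (default) or `"error"`.
#' @return A [SnowSpectrum-class].
#' @seealso [writeSpectrum()], [resampleToGrid()]
#' @export
readSpectrum <- function(path, sampleId = basename(path),
                         colorGroup = "clean", replicate = 1L,
                         negative = c("clip", "error")) {
  negative <- match.arg(negative)
  d <- .read_two_col(path)
  keep <- d$wavelength >= .INSTRUMENT_RANGE[1] &
          d$wavelength <= .INSTRUMENT_RANGE[2]
  d <- d[keep, , drop = FALSE]
  if (!nrow(d))
    stop("no rows within the instrument range 350-2500 nm in ", path,
         call. = FALSE)
  ## collapse duplicate wavelengths by mean, then sort
  if (anyDuplicated(d$wavelength)) {
    agg <- stats::aggregate(value ~ wavelength, data = d, FUN = mean)
    d <- agg[order(agg$wavelength), ]
  } else {
    d <- d[order(d$wavelength), ]
  }
  if (any(diff(d$wavelength) <= 0))
    stop("wavelengths are not strictly increasing after collapsing ",
         "duplicates in ", path, call. = FALSE)
  v <- d$value
  if (any(v < 0)) {
    if (negative == "error")
      stop("negative reflectance values in ", path, call. = FALSE)
    warning(sprintf("%d negative reflectance value(s) clipped to 0 in %s",
                    sum(v < 0), path), call. = FALSE)
    v[v < 0] <- 0
  }
  SnowSpectrum(d$wavelength, v, sampleId = sampleId,
               colorGroup = colorGroup, replicate = replicate)
}

#' Write a spectrum in the documented CSV dialect
#'
#' Writes `wavelength_nm, value` with a header line, such that
#' [readSpectrum()] reads it back identically.
#'
#' @param s a [SnowSpectrum-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSpectrum <- function(s, path) {
  stopifnot(is(s, "SnowSpectrum"))
  d <- data.frame(wavelength_nm = s@wavelength, value = s@reflectance)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a solar irradiance spectrum from CSV
#'
#' Expects columns `wavelength_nm, ed_w_m2_nm` (optional header).
#'
#' @param path path to the CSV file.
#' @return An [Irradiance-class].
#' @export
readIrradiance <- function(path) {
  d <- .read_two_col(path)
  d <- d[order(d$wavelength), ]
  Irradiance(d$wavelength, d$value)
}

#' Write an irradiance table to CSV
#'
#' @param ed an [Irradiance-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeIrradiance <- function(ed, path) {
  stopifnot(is(ed, "Irradiance"))
  d <- data.frame(wavelength_nm = ed@wavelength, ed_w_m2_nm = ed@irradiance)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resample a spectrum onto a regular grid by linear interpolation
#'
#' The requested grid must lie inside the support of the input spectrum:
#' no extrapolation is ever performed. Resampling is the identity when the
#' input already lies on the requested grid.
#'
#' @param s a [SnowSpectrum-class].
#' @param gridStart,gridStop grid limits in nm (defaults: the 400--1300 nm
#'   analysis window).
#' @param step grid step in nm (default 1).
#' @return A [SnowSpectrum-class] on the regular grid, metadata preserved.
#' @export
resampleToGrid <- function(s, gridStart = 400, gridStop = 1300, step = 1) {
  stopifnot(is(s, "SnowSpectrum"))
  w <- s@wavelength
  if (gridStart >= gridStop) stop("gridStart must be < gridStop")
  if (gridStart < min(w) || gridStop > max(w))
    stop(sprintf(
      "requested grid %.1f-%.1f nm outside spectrum support %.1f-%.1f nm",
      gridStart, gridStop, min(w), max(w)), call. = FALSE)
  grid <- seq(gridStart, gridStop, by = step)
  r <- stats::approx(w, s@reflectance, xout = grid, method = "linear")$y
  SnowSpectrum(grid, r, sampleId = s@sampleId, colorGroup = s@colorGroup,
               replicate = s@replicate)
}

## ---------------------------------------------------------------------------
## Biology tables

.BIOLOGY_COLS <- c("sample_id", "color_group", "cell_shape", "dim_major_um",
                   "dim_minor_um", "density_cells_ml", "astax_ug_ml",
                   "chla_ug_ml", "chlb_ug_ml", "bcar_ug_ml", "laip_mg_m2")

.num_or_na <- function(x) {
  if (is.null(x)) return(NA_real_)
  out <- suppressWarnings(as.numeric(x))
  out
}

#' Read a per-sample biology table
#'
#' Reads a delimited table with one row per cell population (rows sharing a
#' `sample_id` describe multiple populations of the same sample, as for
#' green blooms with ellipsoidal plus small spherical cells) and returns
#' one [SampleBiology-class] per sample. Pigment and snow-physics columns
#' are taken from the first row of each sample group. Missing optional
#' columns are tolerated; pigment values left empty yield a
#' [PigmentProfile-class] with `NA` entries, which downstream pigment
#' operations refuse.
#'
#' Required columns: `sample_id`, `color_group`, `cell_shape`,
#' `dim_major_um`, `density_cells_ml`. Optional: `dim_minor_um`,
#' `astax_ug_ml`, `chla_ug_ml`, `chlb_ug_ml`, `bcar_ug_ml`, `laip_mg_m2`,
#' `snow_depth_cm`, `surface_temp_c`, `water_content_pct`,
#' `population_label`.
#'
#' @param path path to the CSV file.
#' @return A named list of [SampleBiology-class] objects.
#' @export
readBiologyTable <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("sample_id", "color_group", "cell_shape", "dim_major_um",
            "density_cells_ml")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("biology table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  num_cols <- intersect(names(d),
                        c("dim_major_um", "dim_minor_um", "density_cells_ml",
                          "astax_ug_ml", "chla_ug_ml", "chlb_ug_ml",
                          "bcar_ug_ml", "laip_mg_m2", "snow_depth_cm",
                          "surface_temp_c", "water_content_pct"))
  for (cc in num_cols) d[[cc]] <- .num_or_na(d[[cc]])
  bad <- which(!is.na(d$density_cells_ml) & d$density_cells_ml < 0)
  if (length(bad))
    stop("negative cell density at row ", bad[1], call. = FALSE)
  bad <- which((!is.na(d$dim_major_um) & d$dim_major_um < 0) |
               (!is.na(d$dim_minor_um) & d$dim_minor_um < 0))
  if (length(bad))
    stop("negative cell dimension at row ", bad[1], call. = FALSE)

  out <- lapply(split(d, d$sample_id), function(g) {
    is_clean <- g$color_group[1] == "clean"
    pops <- if (is_clean) list() else lapply(seq_len(nrow(g)), function(i) {
      CellPopulation(
        shape    = g$cell_shape[i],
        dimMajor = g$dim_major_um[i],
        dimMinor = if ("dim_minor_um" %in% names(g)) g$dim_minor_um[i]
                   else NA_real_,
        density  = g$density_cells_ml[i],
        label    = if ("population_label" %in% names(g))
                     as.character(g$population_label[i]) else NA_character_)
    })
    grab <- function(col) if (col %in% names(g)) g[[col]][1] else NA_real_
    SampleBiology(
      sampleId    = g$sample_id[1],
      colorGroup  = g$color_group[1],
      populations = pops,
      pigments    = PigmentProfile(astax = grab("astax_ug_ml"),
                                   chla  = grab("chla_ug_ml"),
                                   chlb  = grab("chlb_ug_ml"),
                                   bcar  = grab("bcar_ug_ml")),
      laip         = grab("laip_mg_m2"),
      snowDepth    = grab("snow_depth_cm"),
      surfaceTemp  = grab("surface_temp_c"),
      waterContent = grab("water_content_pct"))
  })
  out[order(names(out))]
}

#' Read a spectra manifest and its spectra
#'
#' The manifest CSV maps spectrum files to sample metadata with columns
#' `file`, `sample_id`, `color_group`, `replicate`. Relative file paths are
#' resolved against the manifest's directory. All spectra are resampled to
#' the common 1-nm analysis grid unless `resample = FALSE`.
#'
#' @param path path to the manifest CSV.
#' @param resample resample all spectra onto the 400--1300 nm 1-nm grid
#'   (default TRUE).
#' @return A named list of [SnowSpectrum-class] objects keyed by sample_id.
#' @export
readSpectraSet <- function(path, resample = TRUE) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("file", "sample_id", "color_group", "replicate")
  miss <- setdiff(need, names(man))
  if (length(miss))
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  dir <- dirname(path)
  specs <- lapply(seq_len(nrow(man)), function(i) {
    f <- man$file[i]
    if (!file.exists(f)) f <- file.path(dir, man$file[i])
    s <- readSpectrum(f, sampleId = man$sample_id[i],
                      colorGroup = man$color_group[i],
                      replicate = as.integer(man$replicate[i]))
    if (resample) s <- resampleToGrid(s) else s
  })
  names(specs) <- man$sample_id
  specs
}
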