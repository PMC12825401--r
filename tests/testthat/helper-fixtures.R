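## Shared fixture builders for the test suite. Everything is generated in
## code; nothing is read from stored data files.

## write a spectrum CSV (documented dialect) and return its path
write_spectrum_csv <- function(lines, file = tempfile(fileext = ".csv")) {
  writeLines(lines, file)
  file
}

## a smooth random spectrum on the 1-nm analysis grid: clean-like baseline
## plus a few random Gaussian bumps/dips (positive reflectance guaranteed)
random_smooth_spectrum <- function(seed, nbumps = 4) {
  set.seed(seed)
  grid <- analysisGrid()
  r <- cleanBaseline(grid) + rnorm(1, 0, 0.02)
  for (i in seq_len(nbumps)) {
    center <- runif(1, 430, 1250)
    width  <- runif(1, 15, 80)
    amp    <- runif(1, -0.05, 0.05)
    r <- r + amp * exp(-(grid - center)^2 / (2 * width^2))
  }
  SnowSpectrum(grid, pmax(r, 0.01), sampleId = sprintf("rand-%d", seed))
}

## midpoint-rule oracle at 0.1 nm for the mean of the piecewise-linear
## interpolant of a sampled spectrum over [lo, hi]
oracle_window_mean <- function(s, lo, hi, step = 0.1) {
  f <- stats::approxfun(wavelengths(s), reflectance(s))
  mids <- seq(lo + step / 2, hi - step / 2, by = step)
  sum(f(mids)) * step / (hi - lo)
}

## brute-force IB4 oracle: band-equivalent reflectances via 0.1-nm
## midpoint integration of boxcar-weighted reflectance, then Eqn-style
## continuum removal computed directly
oracle_ib4 <- function(s, bands = sentinel2Bands()) {
  bmean <- function(b) {
    lo <- b@center - b@fwhm / 2
    hi <- b@center + b@fwhm / 2
    oracle_window_mean(s, lo, hi)
  }
  rb3 <- bmean(bands$B3); rb4 <- bmean(bands$B4); rb5 <- bmean(bands$B5)
  rcont <- rb3 + ((664 - 560) / (704 - 560)) * (rb5 - rb3)
  (rcont - rb4) / rcont
}

## the printed group-mean biology used for arithmetic checks
red_profile <- function() PigmentProfile(astax = 2.39, chla = 0.434,
                                         chlb = 0.186, bcar = 0.13)
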