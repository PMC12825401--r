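## End-to-end orchestration: spectra + biology -> band metrics, IB4, IRF,
## biomass normalisation, pigment signatures and group statistics, as one
## deterministic, pure function of its inputs.

.total_density <- function(bio) {
  if (!length(bio@populations)) return(NA_real_)
  sum(vapply(bio@populations, function(p) p@density, numeric(1)))
}

#' Run the full bloom bio-optics pipeline
#'
#' Joins reflectance spectra with per-sample biology, builds the
#' arithmetic-mean clean-snow reference, and computes for every sample the
#' PAR/NIR/full-window mean reflectances and percent reductions, the
#' Sentinel-2 band-equivalent reflectances and IB4 band depth, the
#' instantaneous radiative forcing over the full, PAR and NIR windows with
#' biomass-normalised variants, total biovolume, pigment signatures and
#' astaxanthin:Chl a ratios. Group summaries, Kruskal-Wallis/Dunn
#' comparisons and abundance correlations are attached. The result is a
#' pure function of the inputs: reruns produce identical output (no
#' timestamps), and with `outdir` set the tables are written as CSV plus a
#' JSON run manifest.
#'
#' @param spectra named list of [SnowSpectrum-class] objects, or the path
#'   to a manifest CSV (see [readSpectraSet()]). Must include clean-snow
#'   spectra (`colorGroup == "clean"`).
#' @param biology named list of [SampleBiology-class] objects, or the path
#'   to a biology CSV (see [readBiologyTable()]).
#' @param ed an [Irradiance-class], a CSV path, or NULL for
#'   [defaultIrradiance()].
#' @param bands band definitions for IB4 (default [sentinel2Bands()]).
#' @param outdir optional output directory for the CSV bundle.
#' @return A list with `samples` (per-sample data.frame), `groups`
#'   (per-group mean/sd summary), `kruskal`, `dunn`, `correlations`
#'   (data.frames) and `cleanReference` (the mean clean spectrum).
#' @export
runPipeline <- function(spectra, biology, ed = NULL,
                        bands = sentinel2Bands(), outdir = NULL) {
  if (is.character(spectra)) spectra <- readSpectraSet(spectra)
  if (is.character(biology)) biology <- readBiologyTable(biology)
  if (is.null(ed)) ed <- defaultIrradiance()
  else if (is.character(ed)) ed <- readIrradiance(ed)
  stopifnot(is(ed, "Irradiance"))

  groups <- vapply(spectra, colorGroup, character(1))
  cleans <- spectra[groups == "clean"]
  if (!length(cleans))
    stop("no clean-snow spectra in the input; IRF reference undefined",
         call. = FALSE)
  blooms <- spectra[groups != "clean"]
  orphans <- setdiff(names(blooms), names(biology))
  if (length(orphans))
    stop("spectra without biology records: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  ref <- meanCleanSpectrum(cleans)
  ref_par <- meanReflectance(ref, 400, 700)
  ref_nir <- meanReflectance(ref, 700, 1300)

  rows <- lapply(names(spectra), function(id) {
    s <- spectra[[id]]
    grp <- colorGroup(s)
    r_par  <- meanReflectance(s, 400, 700)
    r_nir  <- meanReflectance(s, 700, 1300)
    r_full <- meanReflectance(s, 400, 1300)
    rb3 <- bandEquivalentReflectance(s, bands$B3)
    rb4 <- bandEquivalentReflectance(s, bands$B4)
    rb5 <- bandEquivalentReflectance(s, bands$B5)
    ib4 <- bandDepthIB4(rb3, rb4, rb5)
    irf_full <- computeIRF(ref, s, ed, 400, 1300)
    irf_par  <- computeIRF(ref, s, ed, 400, 700)
    irf_nir  <- computeIRF(ref, s, ed, 700, 1300)
    row <- data.frame(
      sample_id = id, color_group = grp,
      replicate = replicateNum(s),
      r_par = r_par, r_nir = r_nir, r_full = r_full,
      pct_reduction_par = percentReduction(ref_par, r_par),
      pct_reduction_nir = percentReduction(ref_nir, r_nir),
      rb3 = rb3, rb4 = rb4, rb5 = rb5,
      ib4 = ib4, ib4_pct = 100 * ib4,
      irf_full = irf_full, irf_par = irf_par, irf_nir = irf_nir,
      density_cells_ml = NA_real_, biovolume_um3_ml = NA_real_,
      irf_per_kilocell = NA_real_, irf_per_biovolume = NA_real_,
      astax_ug_ml = NA_real_, chla_ug_ml = NA_real_,
      chlb_ug_ml = NA_real_, bcar_ug_ml = NA_real_,
      sig_astax_pct = NA_real_, sig_chla_pct = NA_real_,
      sig_chlb_pct = NA_real_, sig_bcar_pct = NA_real_,
      astax_chla_ratio = NA_real_,
      chla_per_cell_ug = NA_real_, chla_per_biovolume_ug_um3 = NA_real_,
      laip_mg_m2 = NA_real_, stringsAsFactors = FALSE)
    if (grp != "clean") {
      bio <- biology[[id]]
      dens <- .total_density(bio)
      bv <- totalBiovolume(bio@populations)
      row$density_cells_ml <- dens
      row$biovolume_um3_ml <- bv
      if (is.finite(dens) && dens > 0) {
        row$irf_per_kilocell <- normalizeIRF(irf_full, dens, "cells")
      }
      if (is.finite(bv) && bv > 0)
        row$irf_per_biovolume <- normalizeIRF(irf_full, bv, "biovolume")
      pg <- bio@pigments
      row$astax_ug_ml <- pg@astax; row$chla_ug_ml <- pg@chla
      row$chlb_ug_ml <- pg@chlb;   row$bcar_ug_ml <- pg@bcar
      pv <- .profile_values(pg)
      if (!any(is.na(pv)) && sum(pv) > 0) {
        sig <- pigmentSignature(pg)
        row$sig_astax_pct <- sig[["astax"]]
        row$sig_chla_pct  <- sig[["chla"]]
        row$sig_chlb_pct  <- sig[["chlb"]]
        row$sig_bcar_pct  <- sig[["bcar"]]
      }
      if (!is.na(pg@chla) && pg@chla > 0 && !is.na(pg@astax))
        row$astax_chla_ratio <- astaxChlaRatio(pg)
      if (!is.na(pg@chla) && is.finite(dens) && dens > 0)
        row$chla_per_cell_ug <- pigmentPerCell(pg, dens)[["chla"]]
      if (!is.na(pg@chla) && is.finite(bv) && bv > 0)
        row$chla_per_biovolume_ug_um3 <-
          pigmentPerBiovolume(pg, bv)[["chla"]]
      row$laip_mg_m2 <- bio@laip
    }
    row
  })
  samples <- do.call(rbind, rows)
  rownames(samples) <- NULL

  ## per-group mean/sd summary
  num_cols <- names(samples)[vapply(samples, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, "replicate")
  grp_split <- split(samples, samples$color_group)
  groups_df <- do.call(rbind, lapply(names(grp_split), function(g) {
    d <- grp_split[[g]]
    out <- data.frame(color_group = g, n = nrow(d),
                      stringsAsFactors = FALSE)
    for (cc in num_cols) {
      v <- d[[cc]]
      out[[paste0(cc, "_mean")]] <- mean(v, na.rm = TRUE)
      out[[paste0(cc, "_sd")]] <- stats::sd(v, na.rm = TRUE)
    }
    out
  }))
  rownames(groups_df) <- NULL

  ## group statistics: reflectance across all groups (incl. clean),
  ## forcing/index/biomass across bloom groups only
  stat_vars <- list(
    all   = c("r_par", "r_nir", "r_full"),
    bloom = c("irf_full", "irf_par", "irf_nir", "ib4_pct",
              "biovolume_um3_ml", "irf_per_kilocell"))
  kr_rows <- list(); dunn_rows <- list()
  for (scope in names(stat_vars)) {
    d <- if (scope == "all") samples else
      samples[samples$color_group != "clean", ]
    if (length(unique(d$color_group)) < 2) next
    for (v in stat_vars[[scope]]) {
      ok <- is.finite(d[[v]])
      if (sum(ok) < 3 || length(unique(d$color_group[ok])) < 2) next
      kw <- kruskalWallis(d[[v]][ok], d$color_group[ok])
      kr_rows[[length(kr_rows) + 1L]] <- data.frame(
        variable = v, h = kw$h, p = kw$p,
        stars = significanceStars(kw$p), stringsAsFactors = FALSE)
      dn <- dunnPosthoc(d[[v]][ok], d$color_group[ok])
      dn <- cbind(variable = v, dn)
      dunn_rows[[length(dunn_rows) + 1L]] <- dn
    }
  }
  kruskal <- if (length(kr_rows)) do.call(rbind, kr_rows) else data.frame()
  dunn <- if (length(dunn_rows)) do.call(rbind, dunn_rows) else data.frame()
  rownames(dunn) <- NULL

  ## per-group abundance correlations
  bloom_samples <- samples[samples$color_group != "clean", ]
  corr_rows <- list()
  for (g in unique(bloom_samples$color_group)) {
    d <- bloom_samples[bloom_samples$color_group == g, ]
    specs <- list(
      c(resp = "r_full", ab = "density_cells_ml"),
      c(resp = "r_full", ab = "biovolume_um3_ml"),
      c(resp = "irf_full", ab = "biovolume_um3_ml"),
      c(resp = "ib4_pct", ab = "chla_ug_ml"))
    for (sp in specs) {
      ok <- is.finite(d[[sp[["resp"]]]]) & is.finite(d[[sp[["ab"]]]]) &
        d[[sp[["ab"]]]] > 0
      if (sum(ok) < 3) next
      if (sp[["ab"]] == "chla_ug_ml") {
        pc <- pearsonCor(d[[sp[["ab"]]]][ok], d[[sp[["resp"]]]][ok])
        fit <- list(slope = NA_real_, r_squared = pc$r^2, p = pc$p)
        r <- pc$r
      } else {
        fit <- fitLogAbundance(d[[sp[["resp"]]]][ok], d[[sp[["ab"]]]][ok])
        r <- sign(fit$slope) * sqrt(fit$r_squared)
      }
      corr_rows[[length(corr_rows) + 1L]] <- data.frame(
        color_group = g, response = sp[["resp"]],
        abundance = sp[["ab"]], r = r, r_squared = fit$r_squared,
        slope = fit$slope, p = fit$p, stars = significanceStars(fit$p),
        stringsAsFactors = FALSE)
    }
  }
  correlations <- if (length(corr_rows)) do.call(rbind, corr_rows) else
    data.frame()

  out <- list(samples = samples, groups = groups_df, kruskal = kruskal,
              dunn = dunn, correlations = correlations,
              cleanReference = ref)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(samples, file.path(outdir, "samples.csv"),
                     row.names = FALSE)
    utils::write.csv(groups_df, file.path(outdir, "group_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(kruskal, file.path(outdir, "stats_kruskal.csv"),
                     row.names = FALSE)
    utils::write.csv(dunn, file.path(outdir, "stats_dunn.csv"),
                     row.names = FALSE)
    utils::write.csv(correlations, file.path(outdir, "correlations.csv"),
                     row.names = FALSE)
    manifest <- list(
      package = "snowbloom",
      version = as.character(utils::packageVersion("snowbloom")),
      n_samples = nrow(samples),
      groups = as.list(table(samples$color_group)),
      bands = lapply(bands, function(b)
        list(name = b@name, center_nm = b@center, fwhm_nm = b@fwhm,
             shape = b@shape)))
    jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

#' Dominant taxon per sample from a relative-abundance table
#'
#' Picks the most abundant taxon per sample (argmax of relative
#' abundance). When the runner-up is within `tieDelta` of the leader the
#' row is flagged as a near-tie and the runner-up is reported alongside.
#'
#' @param taxa data.frame with columns `sample_id`, `taxon`,
#'   `rel_abundance` (fractions in `[0, 1]`, summing to at most 1 per
#'   sample).
#' @param tieDelta near-tie threshold on the abundance gap (default 0.05).
#' @return A data.frame with one row per sample: `sample_id`, `taxon`,
#'   `rel_abundance`, `near_tie`, `runner_up`, `runner_up_abundance`.
#' @export
summarizeDominantTaxon <- function(taxa, tieDelta = 0.05) {
  need <- c("sample_id", "taxon", "rel_abundance")
  if (!all(need %in% names(taxa)))
    stop("taxon table needs columns sample_id, taxon, rel_abundance",
         call. = FALSE)
  if (!nrow(taxa)) stop("empty taxon table", call. = FALSE)
  if (any(taxa$rel_abundance < 0 | taxa$rel_abundance > 1))
    stop("relative abundances must lie in [0, 1]", call. = FALSE)
  tot <- tapply(taxa$rel_abundance, taxa$sample_id, sum)
  if (any(tot > 1 + 1e-8))
    stop("relative abundances exceed 1 for sample(s): ",
         paste(names(tot)[tot > 1 + 1e-8], collapse = ", "), call. = FALSE)
  out <- do.call(rbind, lapply(split(taxa, taxa$sample_id), function(d) {
    d <- d[order(-d$rel_abundance, d$taxon), ]
    top <- d[1, ]
    runner <- if (nrow(d) > 1) d[2, ] else NULL
    near <- !is.null(runner) &&
      (top$rel_abundance - runner$rel_abundance) < tieDelta
    data.frame(sample_id = top$sample_id, taxon = top$taxon,
               rel_abundance = top$rel_abundance, near_tie = near,
               runner_up = if (near) runner$taxon else NA_character_,
               runner_up_abundance = if (near) runner$rel_abundance
                                     else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
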