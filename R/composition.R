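#' Per-analyte sugar recovery factors from SRS tubes
#'
#' Sugar recovery standards (SRS) are known monosaccharide mixtures carried
#' through the second (4 % sulfuric acid, 121 degrees C) hydrolysis step
#' alongside the cell-wall samples; comparing hydrolyzed against control
#' tubes gives the fraction of each sugar that survives hydrolysis. The
#' recovery factor is the ratio of mean hydrolyzed to mean control
#' concentration. Recoveries above 1 (hydrolyzed reading exceeding the
#' control, i.e. apparent negative degradation) are clipped to 1 with a
#' warning, since the correction must never amplify a measurement. When a
#' non-missing `batch` column is present, factors are computed per batch,
#' matching the practice of hydrolyzing SRS tubes within each sample batch.
#'
#' @param srs Tibble with columns `analyte`, `control_conc`,
#'   `hydrolyzed_conc` and optionally `replicate`, `batch`.
#' @return Tibble with columns `batch` (NA when global), `analyte`,
#'   `recovery` in (0, 1].
#' @export
#' @examples
#' srs <- tibble::tibble(analyte = "xylose", replicate = 1:2,
#'                       control_conc = c(10, 12), hydrolyzed_conc = c(9, 9))
#' recovery_factors(srs)  # 9 / 11
recovery_factors <- function(srs) {
  srs <- tibble::as_tibble(srs)
  if (!all(c("analyte", "control_conc", "hydrolyzed_conc") %in% names(srs))) {
    abort("`srs` needs columns analyte, control_conc, hydrolyzed_conc.")
  }
  by_batch <- "batch" %in% names(srs) && any(!is.na(srs$batch))
  if (!by_batch) srs$batch <- NA_character_
  viol <- srs$hydrolyzed_conc > srs$control_conc
  if (any(viol, na.rm = TRUE)) {
    warn(sprintf("%d SRS record(s) have hydrolyzed_conc > control_conc (apparent negative degradation).",
                 sum(viol, na.rm = TRUE)))
  }
  out <- srs |>
    dplyr::group_by(.data$batch, .data$analyte) |>
    dplyr::summarise(
      n_control = sum(!is.na(.data$control_conc)),
      n_hydrolyzed = sum(!is.na(.data$hydrolyzed_conc)),
      recovery = mean(.data$hydrolyzed_conc, na.rm = TRUE) /
        mean(.data$control_conc, na.rm = TRUE),
      .groups = "drop"
    )
  incomplete <- out$analyte[out$n_control < 1 | out$n_hydrolyzed < 1]
  if (length(incomplete)) {
    abort(paste0("Analyte(s) missing a control or hydrolyzed SRS record: ",
                 paste(unique(incomplete), collapse = ", ")))
  }
  clipped <- out$recovery > 1
  if (any(clipped)) {
    warn(sprintf("Recovery > 1 clipped to 1 for: %s",
                 paste(unique(out$analyte[clipped]), collapse = ", ")))
    out$recovery[clipped] <- 1
  }
  if (any(out$recovery <= 0)) {
    abort(paste0("Non-positive recovery for: ",
                 paste(unique(out$analyte[out$recovery <= 0]), collapse = ", ")))
  }
  dplyr::select(out, "batch", "analyte", "recovery")
}

#' Monosaccharide content as percent of cell wall (AIR basis)
#'
#' Back-calculates the sugar mass in the whole hydrolysate from the
#' concentration measured in the injected dilution, corrects for
#' hydrolysis losses via the SRS recovery factor, and expresses the
#' result relative to the AIR mass hydrolyzed:
#' `conc * dilution * volume / recovery / air_mass * 100`.
#' Concentrations are mg/ml, volumes ml, masses mg.
#'
#' @param concentration Concentration in the injected (diluted) solution.
#' @param dilution_factor Dilution applied before injection (>= 1).
#' @param hydrolysate_volume_ml Total hydrolysate volume (nominally
#'   0.4 + 11.42 = 11.82 ml).
#' @param air_mass_mg AIR mass hydrolyzed (nominally 20 +/- 1 mg).
#' @param recovery SRS recovery fraction in (0, 1].
#' @return Percent of cell wall, vectorised.
#' @export
#' @examples
#' analyte_percent(0.1, 10, 11.82, 20)        # 59.1
#' analyte_percent(0.1, 10, 11.82, 20, 0.9)   # 65.67
analyte_percent <- function(concentration, dilution_factor,
                            hydrolysate_volume_ml, air_mass_mg,
                            recovery = 1) {
  if (any(recovery <= 0 | recovery > 1)) {
    abort("`recovery` must lie in (0, 1].")
  }
  if (any(concentration < 0, na.rm = TRUE)) abort("`concentration` must be >= 0.")
  if (any(air_mass_mg <= 0)) abort("`air_mass_mg` must be > 0.")
  if (any(hydrolysate_volume_ml <= 0)) abort("`hydrolysate_volume_ml` must be > 0.")
  mass_mg <- concentration * dilution_factor * hydrolysate_volume_ml
  mass_mg / recovery / air_mass_mg * 100
}

#' Klason lignin as percent of the AIR fraction
#'
#' Klason lignin is the acid-insoluble residue left on the glass-fibre
#' filter after the two-step sulfuric acid hydrolysis, dried and weighed:
#' `(gross - tare) / air_mass * 100`. The filters are pre-washed and
#' pre-dried precisely so that `gross >= tare`; a gross mass below tare
#' indicates filter loss and is an error.
#'
#' @param tare_mg Pre-washed, dried filter mass (mg).
#' @param gross_mg Filter plus residue, dried (mg).
#' @param air_mass_mg AIR mass hydrolyzed (mg).
#' @return Percent Klason lignin in the AIR fraction, vectorised.
#' @export
#' @examples
#' klason_percent(100, 102.8, 20)  # 14
klason_percent <- function(tare_mg, gross_mg, air_mass_mg) {
  if (any(tare_mg < 0 | gross_mg < 0)) abort("Masses must be >= 0.")
  if (any(gross_mg < tare_mg)) {
    abort("gross_mg < tare_mg: filter lost mass during filtration/drying.")
  }
  if (any(air_mass_mg <= 0)) abort("`air_mass_mg` must be > 0.")
  (gross_mg - tare_mg) / air_mass_mg * 100
}

#' Cell-wall content of the biomass (AIR % of dry matter)
#'
#' The cell-wall fraction of the milled material is the alcohol-insoluble
#' residue remaining after extraction, expressed on a dry-matter basis:
#' `residue / (initial * dm_fraction) * 100`.
#'
#' @param initial_mg Milled plant material weighed in (mg).
#' @param residue_mg AIR mass remaining after extraction (mg).
#' @param dm_fraction Dry-matter fraction of the milled material, (0, 1].
#' @return AIR as percent of dry matter, vectorised.
#' @export
#' @examples
#' cell_wall_percent(50, 46, 0.95)  # 96.84
cell_wall_percent <- function(initial_mg, residue_mg, dm_fraction) {
  if (any(dm_fraction <= 0 | dm_fraction > 1)) abort("`dm_fraction` must lie in (0, 1].")
  if (any(initial_mg <= 0)) abort("`initial_mg` must be > 0.")
  if (any(residue_mg < 0)) abort("`residue_mg` must be >= 0.")
  if (any(residue_mg > initial_mg)) abort("`residue_mg` exceeds `initial_mg`.")
  residue_mg / (initial_mg * dm_fraction) * 100
}

#' Mass-balance check on a composition table
#'
#' Sums the eight monosaccharide percentages and Klason lignin per sample
#' and flags totals outside the configured band. In a well-behaved run
#' the accounted total approaches the low nineties (the reference panel
#' reached 93.8 % for bast and 92.5 % for stem).
#'
#' @param composition Tibble with the eight analyte columns and
#'   `klason_lignin_pct` (as produced by [compose_study()]).
#' @param band Length-2 numeric acceptance band in percent.
#' @return `composition` with columns `total_accounted_pct` and
#'   `mass_balance_ok`; warns when any sample falls outside the band.
#' @export
mass_balance <- function(composition, band = c(80, 105)) {
  sugar_cols <- intersect(HEMP_ANALYTES, names(composition))
  if (!length(sugar_cols) || !"klason_lignin_pct" %in% names(composition)) {
    abort("`composition` needs the analyte columns and `klason_lignin_pct`.")
  }
  total <- rowSums(composition[, sugar_cols, drop = FALSE]) +
    composition$klason_lignin_pct
  ok <- total >= band[1] & total <= band[2]
  if (any(!ok, na.rm = TRUE)) {
    warn(sprintf("%d sample(s) outside the %g-%g%% mass-balance band.",
                 sum(!ok, na.rm = TRUE), band[1], band[2]))
  }
  composition$total_accounted_pct <- total
  composition$mass_balance_ok <- ok
  composition
}

# pick the injection record used for quantification: glucose is read off the
# 10x dilution (its concentration saturates the detector at 1x), all other
# sugars off the 1x; if only one dilution exists it is used as-is.
select_dilution <- function(quant) {
  quant |>
    dplyr::group_by(.data$sample_id, .data$analyte) |>
    dplyr::group_modify(function(g, key) {
      target <- if (key$analyte == "glucose") max(g$dilution_factor) else min(g$dilution_factor)
      g[which(g$dilution_factor == target)[1], , drop = FALSE]
    }) |>
    dplyr::ungroup()
}

#' Full composition stage: samples to percent-of-cell-wall table
#'
#' Chains [recovery_factors()], [analyte_percent()], [klason_percent()],
#' [cell_wall_percent()] and [mass_balance()] over whole tables. One row
#' per sample with the eight sugar percentages (AIR basis), Klason
#' lignin, AIR % of dry matter (when residue records with role
#' `air_residue` carry `initial_biomass_mg`) and the accounted total.
#'
#' @param quant Validated `quant` table (see [read_table()]).
#' @param samples Validated `samples` table.
#' @param srs Validated `srs` table.
#' @param residues Validated `residues` table, or `NULL` to skip the
#'   gravimetric columns.
#' @param config A [hemp_config()].
#' @return Tibble, one row per sample.
#' @export
compose_study <- function(quant, samples, srs, residues = NULL,
                          config = hemp_config()) {
  rec <- recovery_factors(srs)
  rec_by_batch <- any(!is.na(rec$batch))
  picked <- select_dilution(quant)
  dat <- dplyr::inner_join(picked, samples, by = "sample_id")
  orphan <- setdiff(picked$sample_id, samples$sample_id)
  if (length(orphan)) {
    abort(paste0("Quantification rows with no sample metadata: ",
                 paste(unique(orphan), collapse = ", ")))
  }
  if (rec_by_batch) {
    dat <- dplyr::left_join(dat, rec, by = c("batch", "analyte"))
  } else {
    dat <- dplyr::left_join(dat, rec[, c("analyte", "recovery")], by = "analyte")
  }
  if (any(is.na(dat$recovery))) {
    abort(paste0("No recovery factor for analyte(s): ",
                 paste(unique(dat$analyte[is.na(dat$recovery)]), collapse = ", ")))
  }
  dat$pct <- analyte_percent(dat$concentration, dat$dilution_factor,
                             dat$hydrolysate_volume_ml, dat$air_mass_mg,
                             dat$recovery)
  wide <- dat |>
    dplyr::select("sample_id", "accession", "tissue", "replicate",
                  "analyte", "pct") |>
    tidyr::pivot_wider(names_from = "analyte", values_from = "pct")
  for (a in setdiff(HEMP_ANALYTES, names(wide))) wide[[a]] <- NA_real_
  wide <- wide[, c("sample_id", "accession", "tissue", "replicate", HEMP_ANALYTES)]

  wide$klason_lignin_pct <- NA_real_
  wide$cell_wall_pct_dm <- NA_real_
  if (!is.null(residues)) {
    meta <- samples[, c("sample_id", "air_mass_mg", "dm_fraction")]
    kl <- dplyr::inner_join(
      residues[residues$residue_role == "klason", , drop = FALSE],
      meta, by = "sample_id")
    if (nrow(kl)) {
      kl$klason_lignin_pct <- klason_percent(kl$tare_mg, kl$gross_mg, kl$air_mass_mg)
      wide$klason_lignin_pct <- kl$klason_lignin_pct[match(wide$sample_id, kl$sample_id)]
    }
    air <- dplyr::inner_join(
      residues[residues$residue_role == "air_residue", , drop = FALSE],
      meta, by = "sample_id")
    air <- air[!is.na(air$initial_biomass_mg), , drop = FALSE]
    if (nrow(air)) {
      air$cw <- cell_wall_percent(air$initial_biomass_mg,
                                  air$gross_mg - air$tare_mg,
                                  air$dm_fraction)
      wide$cell_wall_pct_dm <- air$cw[match(wide$sample_id, air$sample_id)]
    }
  }
  mass_balance(wide, band = config$mass_balance_band)
}
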