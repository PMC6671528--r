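#' Ground truth for a synthetic phenotyping study
#'
#' Defines the true parameter values a synthetic study is drawn around.
#' Defaults emulate the reference six-accession panel: glucose-dominated
#' composition summing with Klason lignin to 92.5 % of the cell wall in
#' the stem and 93.8 % in the bast, cell-wall content 92 % (stem) and
#' 98 % (bast) of dry matter, crystallinity 94 % for cellulose and 65 %
#' for mannan, technical CVs of 3 % for biochemistry and 20 % for radius
#' measurements, and three technical replicates (3 cross-sections x 3
#' replicates for radii). One accession has a closed (zero-radius) lumen
#' in two of its three cross-sections, as observed in the real panel.
#'
#' @param accessions Accession labels.
#' @param composition Named list with one named numeric vector per
#'   tissue (`stem`, `bast`): the eight sugars plus `klason_lignin`,
#'   percent of cell wall.
#' @param air_pct Named numeric, AIR percent of dry matter per tissue.
#' @param crystallinity Named numeric: true percent-crystalline for
#'   `glucose` (cellulose) and `mannose` (mannan), and true
#'   percent-of-total for the entrapped co-monomers.
#' @param polymer_totals Named numeric: true total percent of cell wall
#'   for each analyte carried through the crystallinity assay.
#' @param recovery Named numeric, SRS recovery fraction per analyte.
#' @param srs_conc Named numeric, SRS control concentration (mg/ml) per
#'   analyte, resembling hemp hydrolysate concentrations.
#' @param radius_means Named numeric, true mean radius (um) per structure.
#' @param diameter_cm Baseline true stem diameter (cm).
#' @param cv_technical Technical (replicate) CV percent for biochemical
#'   assays.
#' @param cv_radius Technical CV percent for radius measurements.
#' @param accession_cv Between-accession CV percent (multiplicative
#'   accession effects drawn once per study and recorded as truth).
#' @param n_replicates Technical replicates per biochemical assay.
#' @param n_cross_sections,n_radius_replicates Radius design.
#' @param zero_lumen_accession Index (or label) of the accession whose
#'   lumen is closed in all but the last cross-section; `NULL` for none.
#' @param air_mass_mg,hydrolysate_volume_ml,dm_fraction Assay constants.
#' @param noise Noise model: multiplicative Gaussian (default, matches
#'   CV-based repeatability reporting) or additive Gaussian with sd
#'   equal to CV percent of the truth's magnitude at generation time.
#' @return A list of class `synth_truth`.
#' @export
synth_truth <- function(accessions = c("ACC1", "ACC2", "ACC3", "ACC4", "ACC5", "ACC6"),
                        composition = list(
                          stem = c(arabinose = 0.90, galactose = 0.84,
                                   galacturonic_acid = 4.77, glucose = 54.40,
                                   glucuronic_acid = 0.43, mannose = 2.28,
                                   rhamnose = 0.82, xylose = 14.00,
                                   klason_lignin = 14.06),
                          bast = c(arabinose = 1.20, galactose = 1.32,
                                   galacturonic_acid = 3.54, glucose = 76.24,
                                   glucuronic_acid = 0.10, mannose = 6.88,
                                   rhamnose = 0.78, xylose = 1.72,
                                   klason_lignin = 2.02)),
                        air_pct = c(stem = 92, bast = 98),
                        crystallinity = c(glucose = 94, mannose = 65,
                                          xylose = 30, galacturonic_acid = 38,
                                          rhamnose = 0.76),
                        polymer_totals = c(glucose = 76.24, mannose = 6.88,
                                           xylose = 1.67, galacturonic_acid = 2.24,
                                           rhamnose = 0.78),
                        recovery = c(arabinose = 0.95, galactose = 0.95,
                                     galacturonic_acid = 0.90, glucose = 0.98,
                                     glucuronic_acid = 0.90, mannose = 0.96,
                                     rhamnose = 0.93, xylose = 0.94),
                        srs_conc = c(arabinose = 0.05, galactose = 0.06,
                                     galacturonic_acid = 0.15, glucose = 1.20,
                                     glucuronic_acid = 0.02, mannose = 0.12,
                                     rhamnose = 0.03, xylose = 0.25),
                        radius_means = c(lumen = 320, whc = 1500,
                                         primary_bast = 200, secondary_bast = 150),
                        diameter_cm = 1.2,
                        cv_technical = 3,
                        cv_radius = 20,
                        accession_cv = 5,
                        n_replicates = 3,
                        n_cross_sections = 3,
                        n_radius_replicates = 3,
                        zero_lumen_accession = 2,
                        air_mass_mg = 20,
                        hydrolysate_volume_ml = 11.82,
                        dm_fraction = 0.94,
                        noise = c("multiplicative", "additive")) {
  noise <- match.arg(noise)
  stopifnot(all(unlist(composition) > 0), all(air_pct > 0), all(air_pct <= 100),
            all(crystallinity >= 0), all(crystallinity <= 100),
            all(recovery > 0), all(recovery <= 1),
            cv_technical >= 0, cv_radius >= 0, accession_cv >= 0,
            n_replicates >= 1, n_cross_sections >= 1, n_radius_replicates >= 1)
  totals <- vapply(composition, sum, numeric(1))
  if (any(totals > 100)) abort("Composition truth sums above 100% of cell wall.")
  if (is.character(zero_lumen_accession)) {
    zero_lumen_accession <- match(zero_lumen_accession, accessions)
  }
  structure(
    list(accessions = accessions, composition = composition,
         air_pct = air_pct, crystallinity = crystallinity,
         polymer_totals = polymer_totals, recovery = recovery,
         srs_conc = srs_conc, radius_means = radius_means,
         diameter_cm = diameter_cm, cv_technical = cv_technical,
         cv_radius = cv_radius, accession_cv = accession_cv,
         n_replicates = n_replicates, n_cross_sections = n_cross_sections,
         n_radius_replicates = n_radius_replicates,
         zero_lumen_accession = zero_lumen_accession,
         air_mass_mg = air_mass_mg,
         hydrolysate_volume_ml = hydrolysate_volume_ml,
         dm_fraction = dm_fraction, noise = noise),
    class = "synth_truth")
}

# multiplicative (or additive) technical noise, truncated at zero;
# returns the values plus the truncation count for QC
add_noise <- function(true_value, cv_pct, model = "multiplicative") {
  if (cv_pct == 0) return(list(values = true_value, truncated = 0L))
  z <- rnorm(length(true_value))
  out <- if (model == "multiplicative") {
    true_value * (1 + cv_pct / 100 * z)
  } else {
    true_value + cv_pct / 100 * abs(true_value) * z
  }
  trunc <- out < 0
  out[trunc] <- 0
  list(values = out, truncated = sum(trunc))
}

#' Generate a complete synthetic study with known truth
#'
#' Draws a full input-file bundle (sample metadata, chromatography
#' quantification at both dilutions, SRS records, residue masses,
#' sequential-hydrolysis fractions, radius and diameter tables) from a
#' [synth_truth()]. Per-accession effects are drawn once (multiplicative,
#' `accession_cv`) and recorded in the returned realised truth; replicate
#' values are truth times `1 + CV/100` standard-normal noise, truncated
#' at zero. Concentrations are back-computed through the inverse of the
#' composition equations (divide by dilution and hydrolysate volume,
#' multiply by recovery), so the pipeline's forward pass recovers the
#' recorded truth exactly at zero noise. The same seed always yields an
#' identical bundle.
#'
#' @param truth A [synth_truth()].
#' @param seed Integer random seed; required.
#' @return A list of class `hemp_bundle`: the seven input tibbles plus
#'   `truth` (with realised per-accession values) and `seed`.
#' @export
#' @examples
#' b <- generate_study(synth_truth(cv_technical = 0, cv_radius = 0), seed = 1)
#' names(b)
generate_study <- function(truth = synth_truth(), seed) {
  if (missing(seed) || is.null(seed)) {
    abort("A random seed is required to generate a synthetic study (set `seed`).")
  }
  stopifnot(inherits(truth, "synth_truth"))
  seed <- as.integer(seed)
  set.seed(seed)
  acc <- truth$accessions
  n_acc <- length(acc)
  truncated <- 0L
  n_draws <- 0L

  acc_effect <- function(n) {
    if (truth$accession_cv == 0) rep(1, n) else
      pmax(1 + truth$accession_cv / 100 * rnorm(n), 0.1)
  }

  # realised per-accession x tissue composition truth
  comp_truth <- dplyr::bind_rows(lapply(names(truth$composition), function(tis) {
    base <- truth$composition[[tis]]
    dplyr::bind_rows(lapply(acc, function(a) {
      tibble::tibble(accession = a, tissue = tis,
                     component = names(base),
                     true_pct = unname(base * acc_effect(length(base))))
    }))
  }))

  samples <- tidyr::expand_grid(accession = acc,
                                tissue = names(truth$composition),
                                replicate = seq_len(truth$n_replicates)) |>
    dplyr::mutate(sample_id = sprintf("%s_%s_r%d", .data$accession,
                                      .data$tissue, .data$replicate),
                  batch = sprintf("b%d", .data$replicate),
                  air_mass_mg = truth$air_mass_mg,
                  hydrolysate_volume_ml = truth$hydrolysate_volume_ml,
                  dm_fraction = truth$dm_fraction) |>
    dplyr::select("sample_id", "accession", "tissue", "replicate", "batch",
                  "air_mass_mg", "hydrolysate_volume_ml", "dm_fraction")

  # replicate-level measured percentages, then back-computed concentrations
  sugars <- setdiff(unique(comp_truth$component), "klason_lignin")
  quant_long <- samples |>
    dplyr::inner_join(comp_truth[comp_truth$component %in% sugars, ],
                      by = c("accession", "tissue"),
                      relationship = "many-to-many") |>
    dplyr::rename(analyte = "component")
  noisy <- add_noise(quant_long$true_pct, truth$cv_technical, truth$noise)
  truncated <- truncated + noisy$truncated
  n_draws <- n_draws + length(noisy$values)
  quant_long$meas_pct <- noisy$values
  quant_long$mass_mg <- quant_long$meas_pct / 100 * quant_long$air_mass_mg *
    unname(truth$recovery[quant_long$analyte])
  quant <- dplyr::bind_rows(lapply(c(1, 10), function(d) {
    tibble::tibble(sample_id = quant_long$sample_id,
                   analyte = quant_long$analyte,
                   concentration = quant_long$mass_mg /
                     (d * quant_long$hydrolysate_volume_ml),
                   dilution_factor = d)
  })) |> dplyr::arrange(.data$sample_id, .data$analyte, .data$dilution_factor)

  srs <- tidyr::expand_grid(analyte = names(truth$srs_conc), replicate = 1:2) |>
    dplyr::mutate(batch = NA_character_,
                  control_conc = unname(truth$srs_conc[.data$analyte]),
                  hydrolyzed_conc = .data$control_conc * unname(truth$recovery[.data$analyte]))

  kl_truth <- comp_truth[comp_truth$component == "klason_lignin", ]
  kl <- samples |>
    dplyr::inner_join(kl_truth, by = c("accession", "tissue"))
  noisy <- add_noise(kl$true_pct, truth$cv_technical, truth$noise)
  truncated <- truncated + noisy$truncated
  n_draws <- n_draws + length(noisy$values)
  residues_kl <- tibble::tibble(
    sample_id = kl$sample_id, residue_role = "klason",
    tare_mg = 100, gross_mg = 100 + noisy$values / 100 * kl$air_mass_mg,
    initial_biomass_mg = NA_real_)

  air <- samples
  air$true_air <- unname(truth$air_pct[air$tissue])
  noisy <- add_noise(air$true_air, truth$cv_technical, truth$noise)
  truncated <- truncated + noisy$truncated
  n_draws <- n_draws + length(noisy$values)
  # residue mass cannot exceed the material weighed in
  residues_air <- tibble::tibble(
    sample_id = air$sample_id, residue_role = "air_residue",
    tare_mg = 100,
    gross_mg = 100 + pmin(noisy$values / 100 * 50 * air$dm_fraction, 50),
    initial_biomass_mg = 50)
  residues <- dplyr::bind_rows(residues_kl, residues_air)

  # crystallinity assay runs on bast fibre only
  cryst_analytes <- names(truth$crystallinity)
  cryst_truth <- dplyr::bind_rows(lapply(acc, function(a) {
    tibble::tibble(accession = a, analyte = cryst_analytes,
                   true_total = unname(truth$polymer_totals[cryst_analytes] *
                     acc_effect(length(cryst_analytes))),
                   true_frac = unname(pmin(truth$crystallinity[cryst_analytes] *
                                      acc_effect(length(cryst_analytes)), 100)))
  }))
  hyd <- samples[samples$tissue == "bast", ] |>
    dplyr::inner_join(cryst_truth, by = "accession",
                      relationship = "many-to-many")
  n_h <- add_noise(hyd$true_frac / 100 * hyd$true_total,
                   truth$cv_technical, truth$noise)
  n_t <- add_noise((1 - hyd$true_frac / 100) * hyd$true_total,
                   truth$cv_technical, truth$noise)
  truncated <- truncated + n_h$truncated + n_t$truncated
  n_draws <- n_draws + 2L * nrow(hyd)
  hydrolysis <- tibble::tibble(sample_id = hyd$sample_id,
                               analyte = hyd$analyte,
                               tfa_pct = n_t$values,
                               h2so4_pct = n_h$values)

  # radius tables: accession effects, closed-lumen accession, replicate noise
  rad_truth <- dplyr::bind_rows(lapply(seq_along(acc), function(i) {
    tibble::tibble(accession = acc[i], structure = names(truth$radius_means),
                   true_radius = unname(truth$radius_means * acc_effect(length(truth$radius_means))))
  }))
  radii <- tidyr::expand_grid(accession = acc,
                              cross_section = seq_len(truth$n_cross_sections),
                              replicate = seq_len(truth$n_radius_replicates),
                              structure = names(truth$radius_means)) |>
    dplyr::inner_join(rad_truth, by = c("accession", "structure"))
  zl <- truth$zero_lumen_accession
  if (!is.null(zl) && !is.na(zl)) {
    closed <- radii$accession == acc[zl] & radii$structure == "lumen" &
      radii$cross_section < truth$n_cross_sections
    radii$true_radius[closed] <- 0
  }
  noisy <- add_noise(radii$true_radius, truth$cv_radius, truth$noise)
  truncated <- truncated + noisy$truncated
  n_draws <- n_draws + length(noisy$values)
  radii$radius_um <- noisy$values
  radii <- dplyr::select(radii, "accession", "cross_section", "replicate",
                         "structure", "radius_um")

  diam_truth <- tibble::tibble(accession = acc,
                               true_diameter_cm = truth$diameter_cm * acc_effect(n_acc))
  diameters <- tibble::tibble(accession = acc,
                              diameter_cm = diam_truth$true_diameter_cm)

  if (truncated > 0.01 * n_draws) {
    warn(sprintf("%.1f%% of noisy draws truncated at zero: CVs may be too large for the truth magnitudes.",
                 100 * truncated / n_draws))
  }

  realised <- truth
  realised$realised_composition <- comp_truth
  realised$realised_crystallinity <- cryst_truth
  realised$realised_radii <- rad_truth
  realised$realised_diameters <- diam_truth

  structure(
    list(samples = validate_table(samples, "samples", "synthetic samples"),
         quant = validate_table(quant, "quant", "synthetic quant"),
         srs = validate_table(srs, "srs", "synthetic srs"),
         residues = validate_table(residues, "residues", "synthetic residues"),
         hydrolysis = validate_table(hydrolysis, "hydrolysis", "synthetic hydrolysis"),
         radii = validate_table(radii, "radii", "synthetic radii"),
         diameters = validate_table(diameters, "diameters", "synthetic diameters"),
         truth = realised, seed = seed),
    class = "hemp_bundle")
}

#' Write a study bundle as delimited text files
#'
#' @param bundle A `hemp_bundle` from [generate_study()], or any named
#'   list of tables.
#' @param dir Output directory (created if needed).
#' @param delim Field delimiter.
#' @return Named character vector of the files written, invisibly.
#' @export
write_study <- function(bundle, dir, delim = ",") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tables <- bundle[vapply(bundle, is.data.frame, logical(1))]
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    write_table(tables[[nm]], p, delim = delim)
    p
  }, character(1))
  invisible(paths)
}
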