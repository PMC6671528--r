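# Reference six-accession fibre hemp panel, transcribed from the published
# tables: per-structure radius measurements (3 cross-sections x 3 technical
# replicates, micrometres; the published table header says mm but the
# magnitudes are micrometres), stem diameters (cm), crystallinity and
# crystalline-fraction percentages, and the published summary rows used as
# cross-checks. Values are data, not tunables.

hemp_accessions <- c("CRA410", "CRA412", "CRA416", "CRA420", "FNPC243", "WU101")

# rows: cross-section 1..3 x replicate 1..3 (cs-major); columns: accessions
fixture_radii_matrices <- function() {
  list(
    primary_bast = matrix(c(
      109.24, 229.17, 263.78, 231.00, 256.58, 211.54,
      159.66, 204.17, 181.10, 194.53, 276.32, 142.31,
      142.86, 270.83, 177.17, 234.04, 230.26, 196.15,
      158.91, 195.83, 213.38, 185.61, 222.51, 273.03,
      135.66, 241.67, 156.05, 174.24, 240.84, 322.37,
      139.53, 250.00, 219.75, 159.09, 251.31, 161.18,
       90.00, 229.17, 267.86, 213.59, 106.51, 116.07,
      180.00, 337.50, 187.50, 189.32, 186.39, 285.71,
      167.50, 245.83, 160.71, 165.05, 186.39, 205.36),
      nrow = 9, byrow = TRUE, dimnames = list(NULL, hemp_accessions)),
    secondary_bast = matrix(c(
       33.61, 241.67,  70.87,  94.22, 177.63, 261.54,
       46.22, 133.33,  74.80,  97.26, 220.39, 276.92,
       84.03, 200.00,  90.55,  94.22, 167.76, 261.54,
       31.01, 191.67, 121.02,  71.97, 178.01, 220.39,
       31.01, 241.67,  79.62,  64.39, 164.92, 243.42,
       58.14, 225.00,  54.14,  75.76, 180.63, 240.13,
       35.00, 250.00,  56.55,  97.09, 177.51, 285.71,
       57.50, 212.50,  44.64,  48.54, 224.85, 245.54,
       40.00, 241.67,  35.71,  43.69, 192.31, 303.57),
      nrow = 9, byrow = TRUE, dimnames = list(NULL, hemp_accessions)),
    whc = matrix(c(
      1025.21, 2791.67,  881.89, 1079.03, 2220.39, 3934.62,
       873.95, 2641.67,  862.20, 1091.19, 2167.76, 4330.77,
      1067.23, 2541.67,  870.08, 1209.73, 2648.03, 3880.77,
       883.72, 2929.17, 1248.41, 1007.58, 2099.48, 3776.32,
       984.50, 2820.83, 1063.69,  814.39, 2198.95, 3657.89,
      1003.88, 2587.50,  894.90,  799.24, 2651.83, 3187.50,
       897.50, 2570.83,  952.38, 1053.40, 2026.63, 3834.82,
       992.50, 2466.67, 1154.76,  883.50, 1866.86, 3700.89,
      1010.00, 2333.33, 1148.81,  975.73, 2292.90, 3589.29),
      nrow = 9, byrow = TRUE, dimnames = list(NULL, hemp_accessions)),
    lumen = matrix(c(
      357.14,   0.0, 358.27, 395.14, 305.92, 361.54,
      386.55,   0.0, 322.83, 395.14, 171.05, 415.38,
      382.35,   0.0, 385.83, 370.82, 434.21, 330.77,
      182.17,   0.0, 286.62, 174.24, 316.75, 384.87,
      267.44,   0.0, 455.41, 628.79, 253.93, 421.05,
      403.10,   0.0, 340.76, 250.00, 204.19, 299.34,
      357.50, 191.7, 187.50, 383.50, 443.79, 433.04,
      257.50, 187.5, 241.07, 388.35, 390.53, 459.82,
      295.00, 225.0, 252.98, 451.46, 109.47, 522.32),
      nrow = 9, byrow = TRUE, dimnames = list(NULL, hemp_accessions))
  )
}

#' Reference six-accession phenotyping panel
#'
#' Returns the published measurements of the six contrasting fibre hemp
#' accessions (CRA410, CRA412, CRA416, CRA420, FNPC243, WU101) in the
#' file schemas the pipeline consumes, so every stage can be exercised
#' end-to-end without external data:
#' \describe{
#'   \item{radii}{216 rows: 4 structures x 6 accessions x 3
#'     cross-sections x 3 technical replicates, micrometres. The
#'     CRA412 lumen is closed in cross-sections 1 and 2 (six genuine
#'     zeros, not missing data).}
#'   \item{diameters}{per-accession stem diameter, cm.}
#'   \item{crystallinity}{per-accession percent crystalline cellulose
#'     and mannan (mean of three technical replicates, with published
#'     sd and CV).}
#'   \item{crystalline_fraction}{xylose, galacturonic acid and rhamnose
#'     detected in the crystalline fraction: percent of cell wall and
#'     published percent-of-total.}
#'   \item{morphology}{published per-accession morphology summaries
#'     (stem diameter, bast/WHC ratio, bast area %, primary/secondary
#'     bast ratio) used as cross-checks.}
#'   \item{radius_cv}{published per accession x structure CV% of the
#'     nine radius replicates.}
#' }
#'
#' @return Named list of tibbles.
#' @export
#' @examples
#' fx <- hemp_fixture()
#' nrow(fx$radii)  # 216
hemp_fixture <- function() {
  mats <- fixture_radii_matrices()
  radii <- dplyr::bind_rows(lapply(names(mats), function(s) {
    m <- mats[[s]]
    tibble::tibble(
      accession = rep(hemp_accessions, each = 9),
      cross_section = rep(rep(1:3, each = 3), times = 6),
      replicate = rep(1:3, times = 18),
      structure = s,
      radius_um = as.vector(m))
  }))
  radii <- validate_table(radii, "radii", source = "fixture radii")

  diameters <- tibble::tibble(
    accession = hemp_accessions,
    diameter_cm = c(0.68, 1.82, 0.9, 0.9, 1.73, 2.1))
  diameters <- validate_table(diameters, "diameters", source = "fixture diameters")

  crystallinity <- tibble::tibble(
    accession = rep(hemp_accessions, times = 2),
    trait = rep(c("pct_cryst_cellulose", "pct_cryst_mannan"), each = 6),
    value = c(95.05, 94.50, 93.66, 93.23, 94.56, 94.30,
              73.13, 65.09, 61.90, 56.04, 69.54, 62.78),
    sd = c(0.588, 0.167, 0.586, 0.296, 0.233, 0.181,
           2.557, 0.242, 3.425, 3.117, 1.784, 1.788),
    cv_pct = c(0.62, 0.18, 0.63, 0.32, 0.25, 0.19,
               3.50, 0.37, 5.56, 5.56, 2.57, 2.85))

  crystalline_fraction <- tibble::tibble(
    accession = rep(hemp_accessions, times = 3),
    analyte = rep(c("xylose", "galacturonic_acid", "rhamnose"), each = 6),
    crystalline_pct = c(0.780, 0.34, 0.297, 0.272, 0.84, 0.45,
                        0.366, 1.18, 1.485, 0.838, 0.371, 0.868,
                        0.0053, 0.0067, 0.0073, 0.0056, 0.0045, 0.0061),
    pct_of_total = c(31.15, 12.77, 25.6, 27.4, 35.38, 39.46,
                     25.9, 40.63, 47.6, 38.66, 26.55, 39.86,
                     0.76, 0.71, 0.9, 0.7, 0.71, 0.77))

  morphology <- tibble::tibble(
    accession = hemp_accessions,
    stem_diameter_cm = c(0.68, 1.82, 0.9, 0.9, 1.73, 2.1),
    ratio_bast_whc = c(0.197, 0.218, 0.274, 0.239, 0.21, 0.161),
    bast_area_pct = c(16.45, 17.86, 21.51, 19.28, 17.32, 13.86),
    ratio_pf_sf = c(3.15, 1.17, 2.58, 2.62, 1.19, 0.84))

  radius_cv <- tibble::tibble(
    accession = rep(hemp_accessions, times = 4),
    structure = rep(c("primary_bast", "secondary_bast", "whc", "lumen"), each = 6),
    cv_pct = c(20.01, 16.99, 20.36, 13.99, 23.63, 32.53,
               38.09, 17.15, 37.21, 27.43, 11.54, 9.9,
                7.09,  7.11, 14.64, 13.8,  11.71, 8.12,
               23.18, 150.78, 26.04, 32.97, 40.29, 16.84))

  list(radii = radii, diameters = diameters,
       crystallinity = crystallinity,
       crystalline_fraction = crystalline_fraction,
       morphology = morphology, radius_cv = radius_cv)
}
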