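#' Concentric annulus areas of a stem cross-section
#'
#' The stem cross-section is modelled as concentric rings around the
#' central lumen: lumen, woody hemp core (WHC), and bast fibre (primary
#' plus secondary). Areas follow from the ring radii:
#' \deqn{A_{lumen} = \pi r_{lumen}^2}
#' \deqn{A_{WHC} = \pi (r_{lumen}+r_{WHC})^2 - A_{lumen}}
#' \deqn{A_{bast} = \pi (r_{lumen}+r_{WHC}+r_{bast})^2 - A_{lumen} - A_{WHC}}
#' The three areas sum exactly to the full disc of the summed radii.
#' A lumen radius of 0 (fully closed pith) is valid input.
#'
#' @param r_lumen,r_whc,r_bast Ring radii in micrometres, >= 0;
#'   `r_bast` is the combined primary + secondary bast radius.
#' @return Tibble with `a_lumen`, `a_whc`, `a_bast` in square
#'   micrometres, vectorised over the inputs.
#' @export
#' @examples
#' annulus_areas(357.14, 1025.21, 109.24 + 33.61)
annulus_areas <- function(r_lumen, r_whc, r_bast) {
  if (any(c(r_lumen, r_whc, r_bast) < 0, na.rm = TRUE)) {
    abort("Radii must be >= 0.")
  }
  a_lumen <- pi * r_lumen^2
  a_whc <- pi * (r_lumen + r_whc)^2 - a_lumen
  a_bast <- pi * (r_lumen + r_whc + r_bast)^2 - a_lumen - a_whc
  tibble::tibble(a_lumen = a_lumen, a_whc = a_whc, a_bast = a_bast)
}

#' Bast share of the fibre-bearing cross-section
#'
#' `bast_area_pct = a_bast / (a_whc + a_bast) * 100` and
#' `ratio_bast_whc = a_bast / a_whc`. The ratio is reported
#' unmultiplied: the published equation carries a stray factor of 100,
#' but the published per-accession values (0.161--0.274) are plainly the
#' plain ratio, so the factor is treated as a typographical error.
#' Zero denominators yield `NA` with a warning.
#'
#' @param a_whc,a_bast Areas in consistent units.
#' @return Tibble with `bast_area_pct` and `ratio_bast_whc`, vectorised.
#' @export
#' @examples
#' bast_metrics(a_whc = 3, a_bast = 1)
bast_metrics <- function(a_whc, a_bast) {
  if (any(c(a_whc, a_bast) < 0, na.rm = TRUE)) abort("Areas must be >= 0.")
  n <- max(length(a_whc), length(a_bast))
  a_whc <- rep_len(a_whc, n)
  a_bast <- rep_len(a_bast, n)
  denom_pct <- a_whc + a_bast
  bast_area_pct <- ifelse(denom_pct > 0, a_bast / denom_pct * 100, NA_real_)
  ratio <- ifelse(a_whc > 0, a_bast / a_whc, ifelse(a_bast == 0, NA_real_, NA_real_))
  if (any(denom_pct == 0, na.rm = TRUE) || any(a_whc == 0 & a_bast > 0, na.rm = TRUE)) {
    warn("Zero denominator in bast metrics: value set to NA.")
  }
  tibble::tibble(bast_area_pct = bast_area_pct, ratio_bast_whc = ratio)
}

#' Primary and secondary bast-fibre areas and their ratio
#'
#' Primary bast fibre forms the outermost ring of the stem and secondary
#' bast the ring just inside it; both are referenced to the overall stem
#' radius measured separately from the stem diameter:
#' \deqn{A_{PF} = \pi (r_{stem}^2 - (r_{stem}-r_{PF})^2)}
#' \deqn{A_{SF} = \pi ((r_{stem}-r_{PF})^2 - (r_{stem}-r_{PF}-r_{SF})^2)}
#' \deqn{ratio = A_{PF} / A_{SF}}
#'
#' @param r_stem Stem radius in micrometres (half the stem diameter).
#' @param r_pf,r_sf Primary and secondary bast-fibre ring radii (um).
#' @param accession Optional label used in the geometry error message.
#' @return Tibble with `a_pf`, `a_sf`, `ratio_pf_sf`, vectorised.
#' @export
#' @examples
#' primary_secondary(r_stem = 9100, r_pf = 244.91, r_sf = 215.28)
primary_secondary <- function(r_stem, r_pf, r_sf, accession = NULL) {
  if (any(c(r_stem, r_pf, r_sf) < 0, na.rm = TRUE)) abort("Radii must be >= 0.")
  n <- max(length(r_stem), length(r_pf), length(r_sf))
  r_stem <- rep_len(r_stem, n)
  r_pf <- rep_len(r_pf, n)
  r_sf <- rep_len(r_sf, n)
  bad <- which(r_pf + r_sf > r_stem)
  if (length(bad)) {
    who <- if (!is.null(accession)) rep_len(accession, n)[bad[1]] else sprintf("element %d", bad[1])
    abort(sprintf("Bast rings thicker than the stem radius (%s): r_pf + r_sf = %.2f > r_stem = %.2f um.",
                  who, (r_pf + r_sf)[bad[1]], r_stem[bad[1]]))
  }
  a_pf <- pi * (r_stem^2 - (r_stem - r_pf)^2)
  a_sf <- pi * ((r_stem - r_pf)^2 - (r_stem - r_pf - r_sf)^2)
  ratio <- ifelse(a_sf > 0, a_pf / a_sf, ifelse(a_pf == 0, 0, NA_real_))
  tibble::tibble(a_pf = a_pf, a_sf = a_sf, ratio_pf_sf = ratio)
}

#' Per-accession stem morphometry from radius tables
#'
#' Combines the annulus model with the measured stem diameters. Two
#' modes are provided:
#' \describe{
#'   \item{`mean_radius` (default)}{average the replicate radii per
#'     accession x structure first, then apply the geometry once; this
#'     mirrors how the reference ratios were tabulated.}
#'   \item{`per_replicate`}{apply the geometry to each cross-section x
#'     replicate, then average; the replicate spread gives an
#'     uncertainty estimate (sd columns).}
#' }
#' The stem radius comes from the separately measured diameter
#' (`diameter_cm * 10000 / 2` micrometres), not from the sum of the
#' structure radii: in real sections the two disagree because structure
#' radii are measured locally on a wedge of the section.
#'
#' @param radii Validated `radii` table (accession, cross_section,
#'   replicate, structure, radius_um).
#' @param diameters Validated `diameters` table (accession, diameter_cm).
#' @param mode `"mean_radius"` or `"per_replicate"`.
#' @return Tibble, one row per accession: mean structure radii, areas,
#'   `bast_area_pct`, `ratio_bast_whc`, `ratio_pf_sf`, replicate counts,
#'   the mode used, and (in per-replicate mode) sd columns.
#' @export
derive_traits <- function(radii, diameters,
                          mode = c("mean_radius", "per_replicate")) {
  mode <- match.arg(mode)
  radii <- tibble::as_tibble(radii)
  diameters <- tibble::as_tibble(diameters)

  wide_all <- radii |>
    tidyr::pivot_wider(names_from = "structure", values_from = "radius_um")
  missing_struct <- setdiff(HEMP_STRUCTURES, names(wide_all))
  for (s in missing_struct) wide_all[[s]] <- NA_real_

  per_acc <- wide_all |>
    dplyr::group_by(.data$accession) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(HEMP_STRUCTURES),
                    list(mean = ~ mean(.x, na.rm = TRUE),
                         n = ~ sum(!is.na(.x))),
                    .names = "{.col}_{.fn}"),
      .groups = "drop")

  incomplete <- per_acc$accession[rowSums(
    per_acc[, paste0(HEMP_STRUCTURES, "_n")] == 0) > 0]
  if (length(incomplete)) {
    warn(paste0("Structure(s) entirely missing for accession(s): ",
                paste(incomplete, collapse = ", "),
                "; derived traits set to NA."))
  }

  out <- dplyr::left_join(per_acc, diameters, by = "accession")
  out$r_stem_um <- out$diameter_cm * 10000 / 2

  if (mode == "mean_radius") {
    ann <- annulus_areas(out$lumen_mean, out$whc_mean,
                         out$primary_bast_mean + out$secondary_bast_mean)
    bm <- bast_metrics(ann$a_whc, ann$a_bast)
    ps <- primary_secondary(out$r_stem_um, out$primary_bast_mean,
                            out$secondary_bast_mean, accession = out$accession)
    res <- dplyr::bind_cols(out, ann, bm, ps)
  } else {
    per_rep <- dplyr::left_join(wide_all, diameters, by = "accession")
    per_rep$r_stem_um <- per_rep$diameter_cm * 10000 / 2
    ann <- annulus_areas(per_rep$lumen, per_rep$whc,
                         per_rep$primary_bast + per_rep$secondary_bast)
    bm <- bast_metrics(ann$a_whc, ann$a_bast)
    ps <- primary_secondary(per_rep$r_stem_um, per_rep$primary_bast,
                            per_rep$secondary_bast,
                            accession = per_rep$accession)
    rep_tab <- dplyr::bind_cols(per_rep, ann, bm, ps)
    res <- rep_tab |>
      dplyr::group_by(.data$accession) |>
      dplyr::summarise(
        dplyr::across(c("a_lumen", "a_whc", "a_bast", "a_pf", "a_sf",
                        "bast_area_pct", "ratio_bast_whc", "ratio_pf_sf"),
                      list(mean = ~ mean(.x, na.rm = TRUE),
                           sd = ~ sd(.x, na.rm = TRUE)),
                      .names = "{.col}_{.fn}"),
        .groups = "drop")
    res <- dplyr::left_join(out, res, by = "accession")
    # expose the per-replicate means under the plain trait names too
    for (v in c("a_lumen", "a_whc", "a_bast", "a_pf", "a_sf",
                "bast_area_pct", "ratio_bast_whc", "ratio_pf_sf")) {
      res[[v]] <- res[[paste0(v, "_mean")]]
    }
  }
  res$mode <- mode
  res
}
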