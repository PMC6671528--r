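#' Total polymer content from sequential hydrolysis fractions
#'
#' The crystallinity assay hydrolyses bast-fibre AIR in three consecutive
#' steps: weak acid (TFA) releases non-crystalline polysaccharides and
#' amorphous cellulose/mannan; the Updegraff reagent strips remaining
#' non-crystalline material (its supernatant is discarded, so it carries
#' no quantified sugars); and the two-step sulfuric acid hydrolysis breaks
#' down the crystalline polymers. The total content of a polymer is the
#' sum of its monosaccharide released in the TFA and sulfuric acid steps.
#'
#' @param tfa_pct Percent of cell wall released in the TFA step.
#' @param h2so4_pct Percent of cell wall released in the sulfuric acid step.
#' @return Total percent of cell wall, vectorised.
#' @export
#' @examples
#' total_content(2.4, 4.48)  # mannose, bast-like: 6.88
total_content <- function(tfa_pct, h2so4_pct) {
  if (any(tfa_pct < 0, na.rm = TRUE) || any(h2so4_pct < 0, na.rm = TRUE)) {
    abort("Hydrolysis fractions must be >= 0.")
  }
  tfa_pct + h2so4_pct
}

#' Percent of a polymer present in crystalline form
#'
#' `crystalline / total * 100`, where the crystalline amount is the
#' monosaccharide released only by the final sulfuric acid hydrolysis.
#' A crystalline amount exceeding the total within the relative
#' tolerance `tol` is clamped to the total (measurement noise); beyond
#' it the inputs are inconsistent and an error is raised. A zero total
#' leaves the percentage undefined (`NA` with a warning).
#'
#' @param crystalline_pct Amount in crystalline form (percent of cell wall).
#' @param total_pct Total amount (percent of cell wall).
#' @param tol Relative clamping tolerance (default 0.5 %).
#' @return Percent crystalline in \[0, 100\], vectorised.
#' @export
#' @examples
#' percent_crystalline(94, 100)  # 94
percent_crystalline <- function(crystalline_pct, total_pct, tol = 0.005) {
  if (any(crystalline_pct < 0, na.rm = TRUE) || any(total_pct < 0, na.rm = TRUE)) {
    abort("Inputs must be >= 0.")
  }
  n <- max(length(crystalline_pct), length(total_pct))
  crystalline_pct <- rep_len(crystalline_pct, n)
  total_pct <- rep_len(total_pct, n)
  over <- crystalline_pct > total_pct * (1 + tol)
  if (any(over, na.rm = TRUE)) {
    abort(sprintf("Crystalline amount exceeds total beyond %.1f%% relative tolerance (first at element %d).",
                  tol * 100, which(over)[1]))
  }
  clamp <- !is.na(crystalline_pct) & !is.na(total_pct) &
    crystalline_pct > total_pct & total_pct > 0
  if (any(clamp)) {
    warn(sprintf("%d value(s) with crystalline slightly above total clamped to 100%%.", sum(clamp)))
    crystalline_pct[clamp] <- total_pct[clamp]
  }
  out <- crystalline_pct / total_pct * 100
  undef <- !is.na(total_pct) & total_pct == 0
  if (any(undef)) {
    warn(sprintf("%d value(s) with zero total content: crystallinity undefined, set to NA.", sum(undef)))
    out[undef] <- NA_real_
  }
  out
}

#' Percent of a co-monomer entrapped in the crystalline fraction
#'
#' Xylose, galacturonic acid and rhamnose surviving into the final
#' sulfuric acid hydrolysis are interpreted as xylan/pectin entrapped by
#' (not part of) the crystalline polymers. The arithmetic is identical
#' to [percent_crystalline()]; only the interpretation differs, so the
#' two are kept as distinct named operations.
#'
#' @inheritParams percent_crystalline
#' @return Percent of the total co-monomer found in the crystalline
#'   fraction, vectorised.
#' @export
#' @examples
#' entrapped_fraction(0.34, 2.663)  # 12.77
entrapped_fraction <- function(crystalline_pct, total_pct, tol = 0.005) {
  percent_crystalline(crystalline_pct, total_pct, tol = tol)
}

#' Crystallinity stage over a hydrolysis-fractions table
#'
#' Per sample: crystallinity of cellulose (glucose) and mannan
#' (mannose), and for the co-monomers xylose, galacturonic acid and
#' rhamnose both the amount detected in the crystalline fraction
#' (percent of cell wall) and its share of the total.
#'
#' @param hydrolysis Validated `hydrolysis` table
#'   (`sample_id`, `analyte`, `tfa_pct`, `h2so4_pct`).
#' @param samples Optional validated `samples` table; when given,
#'   `accession`/`tissue`/`replicate` are carried through.
#' @param config A [hemp_config()] (supplies the clamping tolerance).
#' @return Tibble, one row per sample x analyte, with columns
#'   `total_pct`, `crystalline_pct`, `pct_of_total` and `measure`
#'   (`"crystallinity"` for glucose/mannose, `"entrapment"` otherwise).
#' @export
crystallinity_study <- function(hydrolysis, samples = NULL,
                                config = hemp_config()) {
  out <- tibble::as_tibble(hydrolysis)
  out$total_pct <- total_content(out$tfa_pct, out$h2so4_pct)
  out$crystalline_pct <- out$h2so4_pct
  out$measure <- ifelse(out$analyte %in% c("glucose", "mannose"),
                        "crystallinity", "entrapment")
  out$pct_of_total <- percent_crystalline(out$crystalline_pct, out$total_pct,
                                          tol = config$crystalline_tolerance)
  if (!is.null(samples)) {
    out <- dplyr::left_join(
      out, samples[, c("sample_id", "accession", "tissue", "replicate")],
      by = "sample_id")
  }
  dplyr::select(out, dplyr::any_of(c("sample_id", "accession", "tissue", "replicate")),
                "analyte", "measure", "tfa_pct", "h2so4_pct",
                "total_pct", "crystalline_pct", "pct_of_total")
}

#' Summary statistics for per-accession crystallinity values
#'
#' Arithmetic mean, sample standard deviation (n - 1), coefficient of
#' variation and range (max - min) across accessions or replicates.
#' Ranges are computed on the unrounded inputs, so they can differ in
#' the last digit from a range taken over values rounded for display.
#'
#' @param values Numeric vector, length >= 2.
#' @return One-row tibble with `n`, `mean`, `sd`, `cv_pct`, `range`.
#' @export
#' @examples
#' summarize_crystallinity(c(95.05, 94.50, 93.66, 93.23, 94.56, 94.30))
summarize_crystallinity <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) abort("Need at least two values to summarise.")
  m <- mean(values)
  s <- sd(values)
  tibble::tibble(
    n = length(values),
    mean = m,
    sd = s,
    cv_pct = if (m != 0) s / m * 100 else NA_real_,
    range = max(values) - min(values)
  )
}
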