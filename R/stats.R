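#' Coefficient of variation between technical replicates
#'
#' The repeatability metric of the pipeline: sample standard deviation
#' (divisor n - 1) over the mean, times 100. The n - 1 divisor is the
#' convention under which the reference radius tables' printed CVs
#' (20.01, 38.09, 7.11, 150.78, ...) are reproduced exactly.
#'
#' @param values Numeric vector of replicate measurements, length >= 2.
#' @return CV as a percentage; `NA` with a warning when the mean is zero.
#' @export
#' @examples
#' cv(c(5, 5, 5))     # 0
#' cv(c(1, 2, 3))     # 50
cv <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) abort("CV needs at least two replicate values.")
  m <- mean(values)
  if (m == 0) {
    warn("Mean is zero: CV undefined, returning NA.")
    return(NA_real_)
  }
  sd(values) / m * 100
}

#' Replicate summaries per accession x tissue x trait
#'
#' @param traits Long trait table (accession, tissue, replicate,
#'   trait_name, value); missing replicate cells are dropped per group.
#' @return Tibble with `n`, `mean`, `sd`, `cv_pct` per group; `cv_pct`
#'   is `NA` for groups with n < 2 or zero mean.
#' @export
trait_summary <- function(traits) {
  tibble::as_tibble(traits) |>
    dplyr::group_by(.data$accession, .data$tissue, .data$trait_name) |>
    dplyr::summarise(
      n = sum(!is.na(.data$value)),
      mean = mean(.data$value, na.rm = TRUE),
      sd = sd(.data$value, na.rm = TRUE),
      .groups = "drop") |>
    dplyr::mutate(
      cv_pct = dplyr::if_else(.data$n >= 2 & .data$mean != 0,
                              .data$sd / .data$mean * 100, NA_real_))
}

#' One-way ANOVA of a trait across accessions
#'
#' Classical fixed-effects one-way decomposition with accessions as
#' groups and technical replicates as the error stratum. Groups with
#' fewer than two observations are excluded with a warning. When both
#' the between- and within-group sums of squares are zero (all values
#' identical) the F statistic is 0/0 and the result is reported missing
#' rather than invented.
#'
#' @param values Numeric response vector.
#' @param groups Grouping vector (accession labels), same length.
#' @param star_thresholds Star mapping, as in [hemp_config()].
#' @return One-row tibble: `f`, `df_between`, `df_within`, `p_value`,
#'   `stars`, `n_groups`, `n_obs`.
#' @export
#' @examples
#' one_way_anova(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
one_way_anova <- function(values, groups,
                          star_thresholds = c("*" = 0.1, "**" = 0.01, "***" = 0.001)) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- as.character(groups[keep])
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warn(paste0("Group(s) with fewer than 2 observations excluded: ",
                paste(small, collapse = ", ")))
    keep <- !groups %in% small
    values <- values[keep]
    groups <- groups[keep]
  }
  k <- length(unique(groups))
  if (k < 2) abort("ANOVA needs at least two groups with >= 2 observations each.")
  df_b <- k - 1L
  df_w <- length(values) - k
  if (diff(range(values)) == 0) {
    # identical within and between: F is 0/0, reported missing
    f <- NA_real_
    p <- NA_real_
  } else {
    fit <- anova(lm(values ~ factor(groups)))
    f <- fit$`F value`[1]
    p <- fit$`Pr(>F)`[1]
  }
  tibble::tibble(
    f = f, df_between = df_b, df_within = df_w, p_value = p,
    stars = star_code(p, star_thresholds),
    n_groups = k, n_obs = length(values))
}

#' ANOVA report over a long trait table
#'
#' Runs [one_way_anova()] for each trait x tissue combination with
#' accession as the grouping factor.
#'
#' @param traits Long trait table.
#' @param config A [hemp_config()] (supplies the star mapping).
#' @return Tibble, one row per trait x tissue.
#' @export
anova_study <- function(traits, config = hemp_config()) {
  tibble::as_tibble(traits) |>
    dplyr::group_by(.data$trait_name, .data$tissue) |>
    dplyr::group_modify(function(g, key) {
      tryCatch(
        one_way_anova(g$value, g$accession, config$star_thresholds),
        error = function(e) {
          warn(sprintf("ANOVA skipped for %s/%s: %s",
                       key$trait_name, key$tissue, conditionMessage(e)))
          tibble::tibble(f = NA_real_, df_between = NA_integer_,
                         df_within = NA_integer_, p_value = NA_real_,
                         stars = NA_character_, n_groups = NA_integer_,
                         n_obs = nrow(g))
        })
    }) |>
    dplyr::ungroup()
}

#' Significance-masked Pearson correlation matrix of traits
#'
#' Pearson correlation with a two-sided t-test for every trait pair,
#' using pairwise-complete observations. Pairs whose p-value exceeds
#' `1 - confidence` are flagged `masked` (rendered blank in a
#' correlation plot). Correlations can be taken at replicate level or
#' between accession means; the two can differ noticeably when the
#' number of accessions is small.
#'
#' @param traits Long trait table.
#' @param confidence Confidence level for the mask (default 0.95).
#' @param level `"replicate"` or `"accession_mean"`.
#' @return Tibble with `trait_a`, `trait_b`, `n`, `r`, `p_value`,
#'   `masked` for every unordered pair (including the diagonal).
#' @export
correlation_matrix <- function(traits, confidence = 0.95,
                               level = c("replicate", "accession_mean")) {
  level <- match.arg(level)
  traits <- tibble::as_tibble(traits)
  if (level == "accession_mean") {
    traits <- traits |>
      dplyr::group_by(.data$accession, .data$tissue, .data$trait_name) |>
      dplyr::summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop") |>
      dplyr::mutate(replicate = 1L)
  }
  wide <- traits |>
    dplyr::mutate(trait = ifelse(.data$tissue %in% HEMP_TISSUES,
                                 paste(.data$trait_name, .data$tissue, sep = "_"),
                                 .data$trait_name)) |>
    dplyr::select("accession", "replicate", "trait", "value") |>
    tidyr::pivot_wider(names_from = "trait", values_from = "value")
  mat <- as.matrix(wide[, setdiff(names(wide), c("accession", "replicate")),
                        drop = FALSE])
  traits_n <- colnames(mat)
  pairs <- expand.grid(a = seq_along(traits_n), b = seq_along(traits_n))
  pairs <- pairs[pairs$a <= pairs$b, , drop = FALSE]
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    x <- mat[, pairs$a[i]]
    y <- mat[, pairs$b[i]]
    ok <- complete.cases(x, y)
    n <- sum(ok)
    if (n < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      return(tibble::tibble(trait_a = traits_n[pairs$a[i]],
                            trait_b = traits_n[pairs$b[i]],
                            n = n, r = NA_real_, p_value = NA_real_,
                            masked = NA))
    }
    if (pairs$a[i] == pairs$b[i]) {
      return(tibble::tibble(trait_a = traits_n[pairs$a[i]],
                            trait_b = traits_n[pairs$b[i]],
                            n = n, r = 1, p_value = 0, masked = FALSE))
    }
    ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "pearson"))
    tibble::tibble(trait_a = traits_n[pairs$a[i]],
                   trait_b = traits_n[pairs$b[i]],
                   n = n, r = unname(ct$estimate), p_value = ct$p.value,
                   masked = ct$p.value > 1 - confidence)
  })
  dplyr::bind_rows(res)
}
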