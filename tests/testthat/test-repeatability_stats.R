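test_that("CV uses the sample (n-1) standard deviation over the mean", {
  expect_equal(cv(c(5, 5, 5)), 0)
  expect_equal(cv(c(1, 2, 3)), 50)  # sd 1, mean 2
  expect_error(cv(7), "at least two")
  expect_warning(out <- cv(c(-1, 1)), "Mean is zero")
  expect_true(is.na(out))
})

test_that("CV reproduces the published radius-table repeatability values", {
  fx <- hemp_fixture()
  expect_equal(round(cv(fixture_structure(fx, "CRA410", "primary_bast")), 2), 20.01)
  expect_equal(round(cv(fixture_structure(fx, "CRA412", "lumen")), 2), 150.78)
})

test_that("CV is scale-invariant and agrees with a two-pass oracle to 10 significant digits", {
  set.seed(41)
  for (i in 1:30) {
    x <- runif(sample(3:12, 1), 1, 100)
    expect_equal(cv(x), cv_oracle(x), tolerance = 1e-10)
    k <- runif(1, 0.01, 50)
    expect_equal(cv(k * x), cv(x), tolerance = 1e-10)
  }
})

test_that("one-way ANOVA matches hand sums of squares on the two-group example", {
  res <- one_way_anova(c(1, 2, 3, 4, 5, 6), rep(c("g1", "g2"), each = 3))
  expect_equal(res$f, 13.5)  # SSB 13.5, SSW 4, df (1, 4)
  expect_equal(res$df_between, 1L)
  expect_equal(res$df_within, 4L)
  # equals the square of the pooled two-sample t statistic
  tt <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(res$f, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-12)
})

test_that("one-way ANOVA matches a brute-force oracle on all small random instances", {
  set.seed(42)
  for (i in 1:40) {
    k <- sample(2:4, 1)
    sizes <- sample(2:4, k, replace = TRUE)
    while (sum(sizes) > 12) sizes <- sample(2:4, k, replace = TRUE)
    groups <- rep(paste0("g", seq_len(k)), sizes)
    values <- rnorm(length(groups), mean = as.integer(factor(groups)))
    got <- one_way_anova(values, groups)
    want <- anova_oracle(values, groups)
    expect_equal(got$f, want$f, tolerance = 1e-10)
    expect_equal(got$p_value, want$p, tolerance = 1e-10)
    expect_equal(got$df_between, want$df_b)
    expect_equal(got$df_within, want$df_w)
  }
})

test_that("degenerate and underpowered ANOVA inputs are handled explicitly", {
  res <- one_way_anova(rep(7, 6), rep(c("a", "b"), each = 3))
  expect_true(is.na(res$f))
  expect_true(is.na(res$p_value))
  expect_warning(
    res2 <- one_way_anova(c(1, 2, 3, 4, 9), c("a", "a", "b", "b", "c")),
    "excluded")
  expect_equal(res2$n_groups, 2L)
  expect_error(suppressWarnings(one_way_anova(c(1, 2, 3), c("a", "a", "b"))),
               "at least two groups")
})

test_that("star codes follow the configured mapping and are monotone in p", {
  th <- c("*" = 0.1, "**" = 0.01, "***" = 0.001)
  p <- c(0.5, 0.09, 0.009, 0.0009, NA)
  got <- hempcw:::star_code(p, th)
  expect_equal(got, c("n.s.", "*", "**", "***", NA))
  grid <- sort(runif(50))
  stars <- nchar(gsub("[^*]", "", hempcw:::star_code(grid, th)))
  expect_true(all(diff(stars) <= 0))
})

test_that("correlations carry two-sided p-values and the confidence mask", {
  traits <- tidyr::expand_grid(accession = paste0("a", 1:6), replicate = 1:1) |>
    dplyr::mutate(tissue = "stem")
  set.seed(43)
  x <- rnorm(6)
  long <- dplyr::bind_rows(
    dplyr::mutate(traits, trait_name = "t1", value = x),
    dplyr::mutate(traits, trait_name = "t2", value = -x),
    dplyr::mutate(traits, trait_name = "t3", value = rnorm(6)))
  cm <- correlation_matrix(long, confidence = 0.95)
  self <- cm[cm$trait_a == "t1_stem" & cm$trait_b == "t1_stem", ]
  expect_equal(self$r, 1)
  expect_false(self$masked)
  anti <- cm[cm$trait_a == "t1_stem" & cm$trait_b == "t2_stem", ]
  expect_equal(anti$r, -1)
  # mask agrees with the p-value rule for every pair
  off <- cm[!is.na(cm$r), ]
  expect_equal(off$masked, off$p_value > 0.05)
})

test_that("accession-mean correlation of diameter vs primary/secondary ratio is strongly negative in the reference panel", {
  fx <- hemp_fixture()
  long <- dplyr::bind_rows(
    tibble::tibble(accession = fx$morphology$accession, tissue = "stem",
                   replicate = 1L, trait_name = "diameter",
                   value = fx$morphology$stem_diameter_cm),
    tibble::tibble(accession = fx$morphology$accession, tissue = "stem",
                   replicate = 1L, trait_name = "ratio_pf_sf",
                   value = fx$morphology$ratio_pf_sf))
  cm <- correlation_matrix(long, level = "accession_mean")
  r <- cm$r[cm$trait_a != cm$trait_b]
  expect_equal(round(r, 2), -0.99)
  expect_equal(r, cor(fx$morphology$stem_diameter_cm, fx$morphology$ratio_pf_sf),
               tolerance = 1e-12)
})

test_that("zero-variance traits yield missing correlations rather than NaN surprises", {
  long <- dplyr::bind_rows(
    tibble::tibble(accession = paste0("a", 1:5), tissue = "stem", replicate = 1L,
                   trait_name = "flat", value = 3),
    tibble::tibble(accession = paste0("a", 1:5), tissue = "stem", replicate = 1L,
                   trait_name = "varying", value = 1:5))
  cm <- correlation_matrix(long)
  pair <- cm[cm$trait_a != cm$trait_b, ]
  expect_true(is.na(pair$r))
})

test_that("trait summaries report n, mean, sd and CV per accession group", {
  traits <- tibble::tibble(accession = rep(c("a1", "a2"), each = 3),
                           tissue = "stem", replicate = rep(1:3, 2),
                           trait_name = "glc",
                           value = c(10, 11, 12, 20, 22, 24))
  s <- trait_summary(traits)
  expect_equal(s$n, c(3L, 3L))
  expect_equal(s$mean, c(11, 22))
  expect_equal(s$cv_pct[1], cv(c(10, 11, 12)))
})
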