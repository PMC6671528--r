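test_that("recovery factors are hydrolyzed/control means, clipped at 1", {
  srs1 <- tibble::tibble(analyte = "glucose", replicate = 1L,
                         control_conc = 10, hydrolyzed_conc = 10)
  expect_equal(recovery_factors(srs1)$recovery, 1)

  srs2 <- tibble::tibble(analyte = "glucose", replicate = 1L,
                         control_conc = 10, hydrolyzed_conc = 8)
  expect_equal(recovery_factors(srs2)$recovery, 0.8)

  # replicated tubes: ratio of means, not mean of ratios
  srs3 <- tibble::tibble(analyte = "xylose", replicate = 1:2,
                         control_conc = c(10, 12), hydrolyzed_conc = c(9, 9))
  expect_equal(recovery_factors(srs3)$recovery, 9 / 11)

  srs4 <- tibble::tibble(analyte = "mannose", replicate = 1L,
                         control_conc = 10, hydrolyzed_conc = 11)
  # flags the apparent negative degradation, then clips
  expect_warning(expect_warning(out <- recovery_factors(srs4), "clipped"),
                 "negative degradation")
  expect_equal(out$recovery, 1)
})

test_that("recovery factors are computed per batch when batches are present", {
  srs <- tibble::tibble(analyte = "glucose", replicate = c(1L, 1L),
                        batch = c("b1", "b2"),
                        control_conc = c(10, 10), hydrolyzed_conc = c(9, 8))
  out <- recovery_factors(srs)
  expect_equal(nrow(out), 2L)
  expect_equal(sort(out$recovery), c(0.8, 0.9))
})

test_that("analyte percent follows the dilution/volume/recovery arithmetic", {
  expect_equal(analyte_percent(0, 10, 11.82, 20), 0)
  expect_equal(analyte_percent(0.1, 10, 11.82, 20), 59.1)
  expect_equal(analyte_percent(0.1, 10, 11.82, 20, recovery = 0.9), 59.1 / 0.9)
  expect_equal(round(analyte_percent(0.1, 10, 11.82, 20, recovery = 0.9), 2), 65.67)
  expect_error(analyte_percent(0.1, 10, 11.82, 20, recovery = 0), "recovery")
})

test_that("analyte percent is linear in concentration and inverse in AIR mass", {
  set.seed(11)
  for (i in 1:20) {
    conc <- runif(1, 0.01, 2)
    k <- runif(1, 0.5, 3)
    base <- analyte_percent(conc, 10, 11.82, 20, 0.95)
    expect_equal(analyte_percent(k * conc, 10, 11.82, 20, 0.95), k * base)
    expect_equal(analyte_percent(conc, 10, 11.82, k * 20, 0.95), base / k)
  }
})

test_that("Klason lignin and cell-wall percentages follow the gravimetric formulas", {
  expect_equal(klason_percent(100, 100, 20), 0)
  expect_equal(klason_percent(100, 102.8, 20), 14)
  expect_error(klason_percent(100, 99, 20), "filter lost mass")

  expect_equal(cell_wall_percent(50, 50, 1), 100)
  expect_equal(cell_wall_percent(50, 46, 1), 92)
  expect_equal(cell_wall_percent(50, 46, 0.95), 46 / 47.5 * 100)
  expect_equal(round(cell_wall_percent(50, 46, 0.95), 2), 96.84)
  expect_error(cell_wall_percent(50, 51, 1), "exceeds")
})

test_that("mass balance totals sugars plus lignin and warns outside the band", {
  comp <- tibble::tibble(arabinose = 0, galactose = 0, galacturonic_acid = 0,
                         glucose = 0, glucuronic_acid = 0, mannose = 0,
                         rhamnose = 0, xylose = 0, klason_lignin_pct = 0)
  expect_warning(out <- mass_balance(comp), "mass-balance band")
  expect_equal(out$total_accounted_pct, 0)
  expect_false(out$mass_balance_ok)

  # bast-like truth summing to the reported 93.8% passes silently
  bast <- tibble::tibble(arabinose = 1.20, galactose = 1.32,
                         galacturonic_acid = 3.54, glucose = 76.24,
                         glucuronic_acid = 0.10, mannose = 6.88,
                         rhamnose = 0.78, xylose = 1.72,
                         klason_lignin_pct = 2.02)
  expect_silent(out <- mass_balance(bast))
  expect_equal(out$total_accounted_pct, 93.8)
  expect_true(out$mass_balance_ok)

  over <- bast
  over$glucose <- over$glucose + 30
  expect_warning(mass_balance(over), "mass-balance band")
})

test_that("glucose uses the 10x dilution record and other sugars the 1x", {
  b <- generate_study(noise_free_truth(), seed = 3)
  picked <- hempcw:::select_dilution(b$quant)
  expect_true(all(picked$dilution_factor[picked$analyte == "glucose"] == 10))
  expect_true(all(picked$dilution_factor[picked$analyte != "glucose"] == 1))
  # with a single record it is used as-is
  one <- tibble::tibble(sample_id = "s1", analyte = c("glucose", "xylose"),
                        concentration = c(1, 2), dilution_factor = c(1, 10))
  picked1 <- hempcw:::select_dilution(one)
  expect_equal(nrow(picked1), 2L)
})

test_that("noise-free synthetic composition recovers the generator truth exactly", {
  b <- generate_study(noise_free_truth(), seed = 5)
  comp <- compose_study(b$quant, b$samples, b$srs, b$residues)
  truth <- b$truth$realised_composition
  for (tis in c("stem", "bast")) {
    row <- comp[comp$tissue == tis, ][1, ]
    tr <- truth[truth$tissue == tis & truth$accession == row$accession, ]
    for (a in setdiff(unique(tr$component), "klason_lignin")) {
      expect_equal(row[[a]], tr$true_pct[tr$component == a], tolerance = 1e-12)
    }
    expect_equal(row$klason_lignin_pct,
                 tr$true_pct[tr$component == "klason_lignin"], tolerance = 1e-12)
    expect_equal(row$cell_wall_pct_dm, unname(b$truth$air_pct[tis]),
                 tolerance = 1e-12)
  }
  # and the totals match the configured tissue sums
  expect_equal(unique(round(comp$total_accounted_pct[comp$tissue == "bast"], 10)),
               93.8)
  expect_equal(unique(round(comp$total_accounted_pct[comp$tissue == "stem"], 10)),
               92.5)
})

test_that("missing SRS coverage for a quantified analyte is an error naming it", {
  b <- generate_study(noise_free_truth(), seed = 5)
  srs_short <- b$srs[b$srs$analyte != "xylose", ]
  expect_error(compose_study(b$quant, b$samples, srs_short, b$residues),
               "xylose")
})
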