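test_that("annulus areas follow the concentric-ring algebra", {
  expect_equal(annulus_areas(0, 0, 0),
               tibble::tibble(a_lumen = 0, a_whc = 0, a_bast = 0))
  deg <- annulus_areas(1, 0, 0)
  expect_equal(deg$a_lumen, pi)
  expect_equal(deg$a_whc, 0)
  expect_equal(deg$a_bast, 0)

  # CRA410 cross-section 1 replicate 1, expanded by hand
  a <- annulus_areas(357.14, 1025.21, 109.24 + 33.61)
  expect_equal(a$a_lumen, pi * 357.14^2)
  expect_equal(a$a_whc, pi * (357.14 + 1025.21)^2 - pi * 357.14^2)
  expect_equal(a$a_whc / pi, 1783342.54, tolerance = 1e-8)
  expect_equal(a$a_bast / pi, 415343.52, tolerance = 1e-8)
  expect_error(annulus_areas(-1, 0, 0), ">= 0")
})

test_that("the three ring areas sum exactly to the full disc", {
  set.seed(31)
  for (i in 1:50) {
    r <- runif(3, 0, 4000)
    a <- annulus_areas(r[1], r[2], r[3])
    expect_equal(a$a_lumen + a$a_whc + a$a_bast, pi * sum(r)^2,
                 tolerance = 1e-12)
  }
})

test_that("scaling all radii by k scales areas by k^2 and leaves ratios unchanged", {
  set.seed(32)
  for (i in 1:25) {
    r <- runif(3, 10, 2000)
    k <- runif(1, 0.2, 8)
    a1 <- annulus_areas(r[1], r[2], r[3])
    a2 <- annulus_areas(k * r[1], k * r[2], k * r[3])
    expect_equal(a2$a_bast, k^2 * a1$a_bast, tolerance = 1e-10)
    m1 <- bast_metrics(a1$a_whc, a1$a_bast)
    m2 <- bast_metrics(a2$a_whc, a2$a_bast)
    expect_equal(m1$bast_area_pct, m2$bast_area_pct, tolerance = 1e-10)
    expect_equal(m1$ratio_bast_whc, m2$ratio_bast_whc, tolerance = 1e-10)

    r_stem <- sum(r) + runif(1, 0, 3000)
    p1 <- primary_secondary(r_stem, r[1], r[2])
    p2 <- primary_secondary(k * r_stem, k * r[1], k * r[2])
    expect_equal(p1$ratio_pf_sf, p2$ratio_pf_sf, tolerance = 1e-10)
  }
})

test_that("bast metrics handle symmetry, zeros and report the plain ratio", {
  sym <- bast_metrics(a_whc = 2, a_bast = 2)
  expect_equal(sym$bast_area_pct, 50)
  expect_equal(sym$ratio_bast_whc, 1)  # unmultiplied, despite the printed *100
  zero <- bast_metrics(a_whc = 2, a_bast = 0)
  expect_equal(zero$bast_area_pct, 0)
  expect_equal(zero$ratio_bast_whc, 0)
  m <- bast_metrics(pi * 1783342.54, pi * 415343.52)
  expect_equal(round(m$bast_area_pct, 2), 18.89)
})

test_that("primary/secondary ring areas respect the stem-radius geometry", {
  none <- primary_secondary(1000, 0, 100)
  expect_equal(none$a_pf, 0)
  expect_equal(none$ratio_pf_sf, 0)
  expect_error(primary_secondary(300, 200, 150, accession = "ACCX"), "ACCX")

  # mean reference radii reproduce the published ratios
  expect_equal(round(primary_secondary(9100, 244.90778, 215.27889)$ratio_pf_sf, 2), 1.17)
  expect_equal(round(primary_secondary(4500, 194.05222, 76.34889)$ratio_pf_sf, 2), 2.62)
})

test_that("mean-radius mode reproduces the published primary/secondary ratios for the consistent accessions", {
  fx <- hemp_fixture()
  dt <- derive_traits(fx$radii, fx$diameters, mode = "mean_radius")
  got <- setNames(round(dt$ratio_pf_sf, 2), dt$accession)
  expect_equal(got[["CRA412"]], 1.17)
  expect_equal(got[["CRA420"]], 2.62)
  expect_equal(got[["FNPC243"]], 1.19)
  expect_equal(got[["WU101"]], 0.84)
  expect_equal(dt$r_stem_um, fx$diameters$diameter_cm * 1e4 / 2)
})

test_that("mean-radius and per-replicate modes coincide for a single replicate", {
  radii <- tibble::tibble(accession = "A", cross_section = 1L, replicate = 1L,
                          structure = c("lumen", "whc", "primary_bast", "secondary_bast"),
                          radius_um = c(300, 1200, 180, 120))
  diam <- tibble::tibble(accession = "A", diameter_cm = 1.0)
  m1 <- derive_traits(radii, diam, mode = "mean_radius")
  m2 <- derive_traits(radii, diam, mode = "per_replicate")
  for (v in c("a_lumen", "a_whc", "a_bast", "bast_area_pct",
              "ratio_bast_whc", "ratio_pf_sf")) {
    expect_equal(m2[[v]], m1[[v]], tolerance = 1e-12)
  }
})

test_that("an accession missing a structure yields NA traits with a warning", {
  fx <- hemp_fixture()
  radii <- fx$radii[!(fx$radii$accession == "CRA410" & fx$radii$structure == "whc"), ]
  expect_warning(dt <- derive_traits(radii, fx$diameters), "CRA410")
  expect_true(is.na(dt$ratio_bast_whc[dt$accession == "CRA410"]))
  expect_false(anyNA(dt$ratio_pf_sf[dt$accession != "CRA410"]))
})

test_that("a closed lumen is valid input, not missing data", {
  a <- annulus_areas(0, 1000, 300)
  expect_equal(a$a_lumen, 0)
  expect_gt(a$a_whc, 0)
})
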