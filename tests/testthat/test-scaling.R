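d_all <- adc_clearance_data()
d3 <- dplyr::filter(d_all, n_animal_species >= 3)

series_of <- function(drug, analyte = "total") {
  d_all[d_all$drug == drug & d_all$analyte == analyte, ]
}

test_that("three-species simple allometry reproduces published predictions", {
  sa <- scale_three_species(d3, strategy = "sa")
  a5 <- sa[sa$drug == "Anti-5T4" & sa$analyte == "total", ]
  expect_equal(a5$predicted_cl, 323, tolerance = 0.01)
  expect_equal(round(a5$ratio, 2), 0.90)
  tdm1c <- sa[sa$drug == "T-DM1" & sa$analyte == "conjugate", ]
  expect_equal(tdm1c$predicted_cl, 683, tolerance = 0.01)
})

test_that("ROE strategy refits with brain weight only above b = 1", {
  roe <- scale_three_species(d3, strategy = "roe")
  expect_equal(sum(roe$method == "brain_weight_product"), 4)
  expect_setequal(
    roe$drug[roe$method == "brain_weight_product"],
    c("DSTP3086S", "DNIB0600A", "Thiomab", "Polatuzumab vedotin")
  )
  expect_true(all(roe$analyte[roe$method == "brain_weight_product"] == "total"))
  dnib <- roe[roe$drug == "DNIB0600A", ]
  expect_equal(dnib$method, "brain_weight_product")
  expect_equal(dnib$predicted_cl, 886, tolerance = 0.01)
  # the corrected exponent sits ~1 above the simple exponent
  expect_equal(dnib$exponent_b - dnib$exponent_sa, 1, tolerance = 0.01)
})

test_that("forced MLP scaling under-predicts relative to simple allometry", {
  sa <- scale_three_species(d3, strategy = "sa")
  mlp <- scale_three_species(d3, strategy = "mlp")
  expect_equal(mlp$drug, sa$drug)
  expect_true(all(mlp$predicted_cl < sa$predicted_cl))
  tdm1 <- mlp[mlp$drug == "T-DM1" & mlp$analyte == "total", ]
  expect_equal(tdm1$predicted_cl, 111, tolerance = 0.01)
  brent <- mlp[mlp$drug == "Brentuximab vedotin", ]
  expect_equal(brent$predicted_cl, 274, tolerance = 0.01)
})

test_that("series with fewer than three species are rejected with guidance", {
  expect_error(scale_three_species(series_of("DMOT4039A")),
               "scale_two_species|scale_one_species")
})

test_that("two-species fits are exact interpolants with no correction", {
  two <- scale_two_species(d3)
  dnib <- two[two$drug == "DNIB0600A" & two$detail == "mouse,monkey", ]
  expect_equal(round(dnib$exponent_b, 2), 1.08)
  brent <- two[two$drug == "Brentuximab vedotin" & two$detail == "mouse,rat", ]
  expect_equal(round(brent$exponent_b, 2), 0.60)
  expect_equal(brent$exponent_b, log(2.25 / 0.50) / log(0.25 / 0.02),
               tolerance = 1e-12)
  expect_true(all(two$method == "simple"))

  # exact interpolation property: both points are reproduced
  for (i in seq_len(nrow(two))) {
    series <- series_of(two$drug[i], two$analyte[i])
    sp <- strsplit(two$detail[i], ",")[[1]]
    animals <- series$animals[[1]]
    sub <- animals[match(sp, animals$species), ]
    expect_equal(two$coefficient_a[i] * sub$body_weight_kg^two$exponent_b[i],
                 sub$clearance_ml_per_day, tolerance = 1e-9)
  }
})

test_that("two-species scaling on an exact linear law predicts a * 70", {
  lin <- as_series_table(exact_panel(4, 1))
  two <- scale_two_species(lin, pair = c("mouse", "monkey"))
  expect_equal(two$predicted_cl, 4 * 70, tolerance = 1e-9)
  expect_error(scale_two_species(series_of("DMOT4039A"),
                                 pair = c("rat", "monkey")),
               "absent")
})

test_that("one-species scaling is the weight-ratio power rule", {
  dnib <- series_of("DNIB0600A")
  monkey <- scale_one_species(dnib, species = "monkey", exponents = 1.0)
  expect_equal(monkey$predicted_cl, 931)
  rat <- scale_one_species(dnib, species = "rat", exponents = 1.0)
  expect_equal(rat$predicted_cl, 3.98 * 280, tolerance = 1e-12)
  expect_equal(round(rat$predicted_cl), 1114)
  # exponent 1.0 equals linear per-kg extrapolation for every series
  e1 <- scale_one_species(d_all, exponents = 1.0)
  for (i in seq_len(nrow(e1))) {
    animals <- series_of(e1$drug[i], e1$analyte[i])$animals[[1]]
    row <- animals[animals$species == e1$detail[i], ]
    expect_equal(e1$predicted_cl[i],
                 row$clearance_ml_per_day * 70 / row$body_weight_kg)
  }
})

test_that("a source species weighing 70 kg returns its own clearance", {
  reg <- rbind(species_constants(),
               data.frame(species = "humanzee", body_weight_kg = 70,
                          brain_weight_g = 1400, mlp_years = 90))
  dat <- as_series_table(
    flat_panel(species = c("humanzee", "human"), cl = c(123, 456)), reg
  )
  for (e in c(0.75, 1, 1.3)) {
    got <- scale_one_species(dat, reg, species = "humanzee", exponents = e)
    expect_equal(got$predicted_cl, 123)
  }
})

test_that("one-species guards reject human sources and bad exponents", {
  expect_error(scale_one_species(d3, species = "human"), "human")
  expect_error(scale_one_species(d3, exponents = numeric(0)), "non-empty")
  expect_error(scale_one_species(d3, exponents = c(1, -1)), "positive")
})

test_that("exponent averaging matches the mean of single-exponent predictions", {
  dnib <- series_of("DNIB0600A")
  single <- scale_one_species_average(dnib, species = "monkey",
                                      exponents = 1.0)
  expect_equal(single$predicted_cl,
               scale_one_species(dnib, species = "monkey",
                                 exponents = 1.0)$predicted_cl)
  avg <- scale_one_species_average(dnib, species = "mouse")
  direct <- mean(0.18 * 3500^c(0.85, 1.0, 1.1))
  expect_equal(avg$predicted_cl, direct, tolerance = 1e-12)
  expect_equal(round(avg$predicted_cl), 747)
  dmot <- scale_one_species(series_of("DMOT4039A"), species = "mouse",
                            exponents = 0.85)
  expect_equal(dmot$predicted_cl, 196, tolerance = 1 / 196)
})
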