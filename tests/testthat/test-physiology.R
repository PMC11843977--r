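test_that("packaged mouse physiology reproduces the printed table values", {
  sp <- mouse_physiology()
  org <- sp$organs
  rownames(org) <- org$organ
  # volumes as printed (L)
  expect_equal(org["testis", "epithelial_volume"], 1.74e-4)
  expect_equal(org["epididymis", "luminal_volume"], 2.14e-5)
  expect_equal(org["testis", "rete_testis_volume"], 1.56e-6)
  expect_equal(org["seminal_vesicle", "interstitial_volume"], 1.44e-6)
  # flows canonicalized from L/min to L/h
  expect_equal(org["testis", "plasma_flow"], 0.00099 * 60)
  expect_equal(org["testis", "blood_cell_flow"], 0.00081 * 60)
  # round trip back to the printed unit is exact
  expect_equal(convert_units(org["testis", "plasma_flow"], "L/h", "L/min"), 0.00099)
})

test_that("derived quantities follow the stated rules", {
  sp <- mouse_physiology()
  org <- sp$organs
  # lymph flow = plasma flow / 200, exactly, for every organ
  expect_equal(org$lymph_flow, org$plasma_flow / 200)
  # endosomal volume = 0.5% of organ total for the MRT organs (the tables
  # satisfy the rule by construction)
  mrt <- org[org$organ %in% MRT_ORGANS, ]
  expect_equal(mrt$endosomal_volume / mrt$total_volume, rep(0.005, nrow(mrt)),
               tolerance = 0.05)
  # circulatory closure: lung plasma flow = organ flows + its own lymph
  lung <- org[org$organ == "lung", ]
  expect_equal(lung$plasma_flow,
               sum(org$plasma_flow[org$organ != "lung"]) + lung$lymph_flow,
               tolerance = 1e-12)
})

test_that("structural and validation errors are raised on bad inputs", {
  expect_error(load_species_physiology("mouse", source = write_mrt_subset("testis")),
               "structural error.*testis")
  # negative value in a user file
  src <- read.csv(system.file("extdata", "mrt_physiology.csv", package = "mrtpbpk"))
  src$value[src$organ == "testis" & src$field == "plasma_flow"] <- -1
  bad <- tempfile(fileext = ".csv")
  write.csv(src, bad, row.names = FALSE)
  expect_error(load_species_physiology("mouse", source = bad), "negative")
  expect_error(load_species_physiology("dog"))
  expect_error(allometric_scale(1, 0, 1, 0.75), "positive")
})

test_that("allometric scaling follows the power law and is multiplicative", {
  expect_equal(allometric_scale(0.5, 1, 2, 1.0), 1.0)
  expect_equal(allometric_scale(3.7, 0.25, 0.25, 0.75), 3.7)
  # frozen from direct evaluation: 0.003078 * (0.25/0.028)^0.75
  expect_equal(allometric_scale(0.003078, 0.028, 0.25, 0.75), 0.0158984,
               tolerance = 1e-4)
  # mouse -> rat -> human equals mouse -> human
  v <- 0.123
  expect_equal(
    allometric_scale(allometric_scale(v, 0.028, 0.25, 0.75), 0.25, 71, 0.75),
    allometric_scale(v, 0.028, 71, 0.75),
    tolerance = 1e-12
  )
})

test_that("validator reports warnings for the packaged tables and findings for edits", {
  f <- validate_physiology(mouse_physiology())
  expect_true(all(f$level == "warning"))
  expect_true(any(grepl("Blood Flow", f$message)))

  sp <- mouse_physiology()
  sp$organs$lymph_flow[sp$organs$organ == "testis"] <-
    2 * sp$organs$plasma_flow[sp$organs$organ == "testis"]
  f <- validate_physiology(sp)
  expect_true(any(f$level == "error" & f$field == "lymph_flow"))

  sp <- mouse_physiology()
  sp$organs$interstitial_volume[1] <- -1e-6
  f <- validate_physiology(sp)
  expect_true(any(f$level == "error" & f$field == "interstitial_volume"))
})

test_that("species translation uses printed values where available and flags anomalies", {
  rat <- load_species_physiology("rat")
  org <- rat$organs
  rownames(org) <- org$organ
  expect_equal(org["testis", "epithelial_volume"], 1.18e-3)
  expect_equal(org["testis", "plasma_flow"], 4.28e-3 * 60)
  # platform organs scale allometrically from the mouse set
  msp <- mouse_physiology()$organs
  expect_equal(org["heart", "plasma_flow"],
               msp$plasma_flow[msp$organ == "heart"] * (0.25 / 0.028)^0.75)
  expect_equal(org["heart", "total_volume"],
               msp$total_volume[msp$organ == "heart"] * (0.25 / 0.028))
  # human table ingested as printed; the oversized testis epithelial volume
  # and the blood-cell/plasma flow anomaly of the seminal vesicle surface
  # as validator warnings, not errors
  hum <- load_species_physiology("human")
  horg <- hum$organs
  expect_equal(horg$epithelial_volume[horg$organ == "testis"], 0.092)
  f <- validate_physiology(hum)
  expect_true(all(f$level == "warning"))
  expect_true(any(f$organ == "seminal_vesicle" & f$field == "blood_cell_flow"))
})

test_that("unit conversion round-trips are exact and classes are enforced", {
  x <- c(0.00099, 0.003762, 8.459e-6)
  expect_identical(convert_units(convert_units(x, "L/min", "L/h"), "L/h", "L/min"), x)
  expect_equal(convert_units(1, "day", "min"), 1440)
  expect_error(convert_units(1, "L", "h"), "classes")
})
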