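test_that("dilution series follow the fold geometry exactly", {
  ds <- build_dilution_series(4, 2, 5)
  expect_equal(ds$concentrations, c(4, 2, 1, 0.5, 0.25))

  expect_equal(build_dilution_series(10, 3, 1)$concentrations, 10)

  # a ten-level 3-fold screen row spans 10x down to ~5.08e-4x of GI50
  ds10 <- build_dilution_series(10, 3, 10)
  expect_equal(ds10$concentrations[10], 10 / 3^9)
  expect_equal(ds10$concentrations[10], 5.08e-4, tolerance = 2e-3)

  # round trip: first/last ratio is fold^(n-1) to machine precision
  for (fold in c(2, 3, 7.5)) {
    ds <- build_dilution_series(1.23e-6, fold, 8)
    expect_equal(ds$concentrations[1] / ds$concentrations[8], fold^7)
    expect_true(all(diff(ds$concentrations) < 0))
  }

  expect_error(build_dilution_series(0, 3, 10), "start")
  expect_error(build_dilution_series(1, 1, 10), "fold")
  expect_error(build_dilution_series(1, 3, 0), "n_levels")
})

test_that("half-effect column index converts to concentration", {
  expect_equal(column_to_concentration(
    screen_annotation("a", 1, dm_column = 2)), 10)
  expect_equal(column_to_concentration(
    screen_annotation("a", 1, dm_column = 4)), 10 / 3)
  expect_equal(column_to_concentration(
    screen_annotation("a", 1, dm_column = 9)), 10 * 3^(-3.5))
  expect_equal(column_to_concentration(
    screen_annotation("a", 2e-8, dm_column = 6)), 10 * 2e-8 * 3^(-2))
  expect_error(column_to_concentration(screen_annotation("a", 1)),
               "dm_column")
})

test_that("screen layouts place dilution rows with duplicates and controls", {
  lay <- build_screen_layout(list(screen_annotation("d1", 1e-7)),
                             control_wells = paste0("P", 1:4))
  expect_s3_class(lay, "plate_layout")
  expect_equal(nrow(lay$wells), 24)   # 10 levels x 2 duplicates + 4 controls
  expect_equal(sum(lay$wells$role == "treated"), 20)
  expect_equal(sum(lay$wells$role == "control"), 4)
  # each concentration appears `duplicates` times
  expect_true(all(table(lay$wells$conc_1[lay$wells$role == "treated"]) == 2))
  # top dose is 10x GI50, molar
  expect_equal(max(lay$wells$conc_1, na.rm = TRUE), 1e-6)

  # controls only
  lay0 <- build_screen_layout(list(), control_wells = c("A1", "B1"))
  expect_equal(nrow(lay0$wells), 2)
  expect_true(all(lay0$wells$role == "control"))

  # full screen plate: 16 drugs x 10 levels x 2 duplicates fits a 384 plate
  drugs <- lapply(1:16, function(i) screen_annotation(paste0("d", i), 1e-8))
  lay16 <- build_screen_layout(drugs)
  expect_equal(sum(lay16$wells$role == "treated"), 320)
  expect_false(anyDuplicated(lay16$wells$well) > 0)

  expect_error(build_screen_layout(lapply(1:17, function(i)
    screen_annotation(paste0("d", i), 1e-8))), "16")
  expect_error(
    build_screen_layout(list(screen_annotation("d", 1e-8)),
                        control_wells = "A1"), "collide")
})

test_that("combination layouts build the duplicated core plus edges", {
  a <- screen_annotation("A", 1e-6); b <- screen_annotation("B", 1e-6)
  cl <- build_combination_layout(a, b, centerA = 1, centerB = 1)
  w <- cl$wells
  core <- w[!is.na(w$drug_1) & !is.na(w$drug_2), ]
  expect_equal(nrow(core), 50)           # 5x5 pairs x 2 duplicates
  expect_equal(length(unique(core$replicate_group)), 25)
  # single-agent wells carry their drug in the first slot
  single <- w[!is.na(w$drug_1) & is.na(w$drug_2) & w$role == "treated", ]
  edgeA <- single[single$drug_1 == "A", ]
  edgeB <- single[single$drug_1 == "B", ]
  expect_equal(length(unique(edgeA$replicate_group)), 5)
  expect_equal(length(unique(edgeB$replicate_group)), 5)
  expect_false(anyDuplicated(w$well) > 0)

  # explicit start reproduces the 4 -> 0.25 uM two-fold ladder (in molar)
  cl2 <- build_combination_layout(a, b, 1, 1, startA = 4, startB = 4)
  concs <- sort(unique(cl2$wells$conc_1[!is.na(cl2$wells$drug_1)]))
  expect_equal(concs, c(0.25, 0.5, 1, 2, 4) * 1e-6)

  cl3 <- build_combination_layout(a, b, 1, 1, n_levels = 2, duplicates = 1,
                                  n_controls = 1)
  core3 <- cl3$wells[!is.na(cl3$wells$drug_1) & !is.na(cl3$wells$drug_2), ]
  expect_equal(nrow(core3), 4)

  expect_error(build_combination_layout(a, b, 1, 1, n_levels = 12),
               "plate")
})

test_that("virtual plates average duplicates independent of order", {
  lay <- build_combination_layout(screen_annotation("A", 1e-6),
                                  screen_annotation("B", 1e-6), 1, 1)
  wells <- lay$wells$well
  scores <- setNames(seq_along(wells) * 1.0, wells)
  vp <- assemble_virtual_plate(scores, lay)
  expect_s3_class(vp, "virtual_plate")
  # every group of 2 duplicates averaged
  expect_true(all(vp$n_wells[vp$replicate_group != "control"] == 2))
  grp <- lay$wells$replicate_group == "A1xB1"
  expect_equal(vp$score[vp$replicate_group == "A1xB1"],
               mean(scores[lay$wells$well[grp]]))
  # order invariance
  vp2 <- assemble_virtual_plate(rev(scores), lay)
  expect_equal(vp[order(vp$replicate_group), ],
               vp2[order(vp2$replicate_group), ], ignore_attr = TRUE)
  # identity for singleton groups
  l1 <- build_screen_layout(list(screen_annotation("d", 1e-8)),
                            duplicates = 1, control_wells = "P1")
  s1 <- setNames(rep(2, nrow(l1$wells)), l1$wells$well)
  expect_true(all(assemble_virtual_plate(s1, l1)$score == 2))
  # missing scores are listed
  expect_error(assemble_virtual_plate(scores[-(1:2)], lay), "no score")
})

test_that("layouts round-trip through CSV and JSON with validation", {
  lay <- build_screen_layout(list(screen_annotation("d1", 1e-7)),
                             control_wells = paste0("P", 1:4))
  csv <- tempfile(fileext = ".csv"); json <- tempfile(fileext = ".json")
  write_plate_layout(lay, csv)
  write_plate_layout(lay, json)
  for (back in list(read_plate_layout(csv), read_plate_layout(json))) {
    expect_equal(back$wells[order(back$wells$well),
                            c("well", "role", "drug_1", "conc_1",
                              "replicate_group")],
                 lay$wells[order(lay$wells$well),
                           c("well", "role", "drug_1", "conc_1",
                             "replicate_group")],
                 ignore_attr = TRUE)
  }
  # corrupt file fails validation
  bad <- lay$wells
  bad$conc_1[bad$role == "treated"][1] <- -1
  badcsv <- tempfile(fileext = ".csv")
  write.csv(bad[c("well", "role", "drug_1", "conc_1", "drug_2", "conc_2",
                  "replicate_group")], badcsv, row.names = FALSE, na = "")
  expect_error(read_plate_layout(badcsv), "positive")
})

test_that("well addresses validate plate bounds", {
  expect_equal(well_name(1, 1), "A1")
  expect_equal(well_name("P", 24), "P24")
  pw <- parse_well(c("B12", "p3"))
  expect_equal(pw$row, c(2, 16))
  expect_equal(pw$column, c(12, 3))
  expect_error(parse_well("Q1"), "malformed|outside")
  expect_error(parse_well("A25"), "outside")
  expect_error(well_name(17, 1), "bounds")
})
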