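test_that("Bliss prediction follows the printed product of fractions", {
  # zero factor at zero dose
  expect_equal(bliss_predict(0, 5, 1, 2, 1, 3), 0)
  expect_equal(bliss_predict(5, 0, 1, 2, 1, 3), 0)
  # both drugs at their median effect: 0.5 * 0.5
  expect_equal(bliss_predict(1, 0.8, 1, 2, 0.8, 3), 0.25)
  # factorization against independently computed single-drug curves
  set.seed(21)
  D1 <- matrix(runif(25, 0.01, 10), 5)
  D2 <- matrix(runif(25, 0.01, 10), 5)
  f <- bliss_predict(D1, D2, 1.3, 1.7, 0.6, 2.4)
  oracle <- fractional_effect(D1, 1.3, 1.7) * fractional_effect(D2, 0.6, 2.4)
  expect_lt(max(abs(f - oracle)), 1e-12)
  # conventional independence form reduces to the single-drug curve
  expect_equal(bliss_predict(2, 0, 1, 2, 1, 3, convention = "independence"),
               fractional_effect(2, 1, 2))
})

test_that("Loewe prediction solves the additivity condition", {
  # sham combination: zero partner dose gives the single-drug curve
  for (D in c(0.05, 0.5, 2, 20)) {
    expect_lt(abs(loewe_predict(D, 0, 1, 2, 0.7, 3) -
                    fractional_effect(D, 1, 2)), 1e-8)
    expect_lt(abs(loewe_predict(0, D, 1, 2, 0.7, 3) -
                    fractional_effect(D, 0.7, 3)), 1e-8)
  }
  # identical drugs: dose-additive closed form
  for (pair in list(c(0.3, 0.4), c(1, 1), c(5, 0.01))) {
    expect_lt(abs(loewe_predict(pair[1], pair[2], 1, 2, 1, 2) -
                    fractional_effect(sum(pair), 1, 2)), 1e-8)
  }
  # half of each Dm with equal slopes lands exactly on f = 0.5
  expect_equal(loewe_predict(0.5, 0.4, 1, 2, 0.8, 2), 0.5, tolerance = 1e-8)
  # root satisfies the condition at return
  f <- loewe_predict(0.7, 1.3, 1, 1.4, 2, 2.6)
  expect_lt(abs(phenoscreen:::loewe_condition(f, 0.7, 1.3, 1, 1.4, 2, 2.6)),
            1e-8)
  # monotone non-decreasing in each dose, continuous across the grid
  d <- seq(0.05, 5, length.out = 30)
  f1 <- loewe_predict(d, 1, 1, 2, 1.5, 1.3)
  f2 <- loewe_predict(1, d, 1, 2, 1.5, 1.3)
  expect_true(all(diff(f1) > 0))
  expect_true(all(diff(f2) > 0))
  expect_lt(max(abs(diff(f1))), 0.2)
  # zero doses
  expect_equal(loewe_predict(0, 0, 1, 2, 1, 2), 0)
})

test_that("combination predictions are invariant to per-drug unit rescaling", {
  D1 <- c(0.2, 1, 3); D2 <- c(0.5, 0.8, 2)
  for (c1 in c(1e-6, 1e3)) {
    expect_equal(loewe_predict(D1 * c1, D2, 1 * c1, 1.4, 0.8, 2),
                 loewe_predict(D1, D2, 1, 1.4, 0.8, 2), tolerance = 1e-9)
    expect_equal(bliss_predict(D1 * c1, D2, 1 * c1, 1.4, 0.8, 2),
                 bliss_predict(D1, D2, 1, 1.4, 0.8, 2), tolerance = 1e-12)
  }
})

test_that("the combination index measures departure from additivity", {
  # points on the Loewe isobole score CI = 1
  f <- loewe_predict(0.6, 0.9, 1, 1.5, 1.2, 2.5)
  expect_equal(combination_index(0.6, 0.9, f, 1, 1.5, 1.2, 2.5), 1,
               tolerance = 1e-8)
  # sham combination: single drug at its own curve
  f1 <- fractional_effect(2, 1, 1.5)
  expect_equal(combination_index(2, 0, f1, 1, 1.5, 1.2, 2.5), 1,
               tolerance = 1e-10)
  # halving both doses at fixed effect halves CI
  ci <- combination_index(0.6, 0.9, 0.4, 1, 1.5, 1.2, 2.5)
  expect_equal(combination_index(0.3, 0.45, 0.4, 1, 1.5, 1.2, 2.5), ci / 2)
  expect_error(combination_index(1, 1, 1, 1, 1, 1, 1), "strictly inside")
})

test_that("edge fits recover each drug's parameters from the matrix", {
  cm <- combo_fixture("bliss", Dm1 = 1, s1 = 1.2, Dm2 = 0.8, s2 = 2)
  ef <- fit_single_drug_edges(cm)
  expect_equal(ef$fit_1$Dm, 1, tolerance = 0.05)
  expect_equal(ef$fit_1$s, 1.2, tolerance = 0.05)
  expect_equal(ef$fit_2$Dm, 0.8, tolerance = 0.05)
  expect_equal(ef$fit_2$s, 2, tolerance = 0.05)
  # a matrix missing an edge is rejected
  cm2 <- cm
  cm2$edge_scores_1 <- cm2$edge_scores_1[1, , drop = FALSE]
  expect_error(fit_single_drug_edges(cm2), "edge")
})

test_that("joint four-parameter fits are self-consistent per model", {
  truth <- c(Dm1 = 1, s1 = 1.2, Dm2 = 0.8, s2 = 2)
  cmb <- combo_fixture("bliss")
  jb <- fit_combination_joint(cmb, model = "bliss")
  for (nm in names(truth))
    expect_equal(jb[[nm]], unname(truth[nm]), tolerance = 1e-3)

  cml <- combo_fixture("loewe")
  jl <- fit_combination_joint(cml, model = "loewe")
  expect_lt(jl$rss, 1e-10)
  for (nm in names(truth))
    expect_equal(jl[[nm]], unname(truth[nm]), tolerance = 1e-3)

  # model mismatch strictly increases the residual
  jx <- fit_combination_joint(cml, model = "bliss")
  expect_gt(jx$rss, jl$rss)

  cm8 <- combo_fixture("bliss", n_levels = 2)
  expect_error(fit_combination_joint(cm8, model = "bliss"), ">= 8")
})

test_that("synergy reports separate null surfaces from planted synergy", {
  cml <- combo_fixture("loewe")
  jl <- fit_combination_joint(cml, model = "loewe")
  rep0 <- synergy_report(cml, jl, seed = 5)
  expect_equal(rep0$mean_residual, 0, tolerance = 1e-10)
  expect_gt(rep0$p_value, 0.05)
  # CI of a perfectly additive grid is 1 wherever defined
  expect_true(all(abs(rep0$ci_map[!is.na(rep0$ci_map)] - 1) < 1e-6))

  # planted synergy: +0.2 in the interior cells
  cms <- cml
  cms$observed_f[2:4, 2:4] <- pmin(cms$observed_f[2:4, 2:4] + 0.2, 1)
  reps <- synergy_report(cms, jl, seed = 5)
  expect_lt(reps$p_value, 0.05)
  expect_true(reps$max_cell[1] %in% 2:4 && reps$max_cell[2] %in% 2:4)

  # all-zero residuals: report is exactly null
  expect_equal(rep0$max_abs_residual, 0, tolerance = 1e-10)
})

test_that("virtual combination plates flow into matrices and fits", {
  # scores on a synthetic combination block, Loewe-generated
  lay <- build_combination_layout(screen_annotation("A", 1e-6),
                                  screen_annotation("B", 1e-6),
                                  centerA = 1, centerB = 0.8, fold = 2)
  truth <- c(Dm1 = 1e-6, s1 = 1.5, Dm2 = 0.8e-6, s2 = 2)
  B0 <- 2; A0 <- 6
  w <- lay$wells
  # per-well doses on each drug's own axis (single-agent wells carry their
  # drug in the first slot)
  dA <- ifelse(!is.na(w$drug_1) & w$drug_1 == "A", w$conc_1, 0)
  dB <- ifelse(!is.na(w$drug_2) & w$drug_2 == "B", w$conc_2,
               ifelse(!is.na(w$drug_1) & w$drug_1 == "B", w$conc_1, 0))
  f <- loewe_predict(dA, dB, truth["Dm1"], truth["s1"], truth["Dm2"],
                     truth["s2"])
  scores <- setNames(A0 * f + B0, w$well)
  vp <- assemble_virtual_plate(scores, lay)
  cm <- as_combination_matrix(vp)
  expect_equal(dim(cm$observed_f), c(5L, 5L))
  jf <- fit_combination_joint(cm, model = "loewe")
  # recovered on the molar scale of the layout; the block-wise score
  # normalization (A from the observed maximum, below the true asymptote)
  # biases the fit slightly, so residuals are small but not exactly null
  expect_equal(jf$Dm1, 1e-6, tolerance = 0.15)
  expect_equal(jf$Dm2, 0.8e-6, tolerance = 0.15)
  rep <- synergy_report(cm, jf, seed = 3)
  expect_lt(rep$max_abs_residual, 0.06)
  expect_lt(abs(rep$mean_residual), 0.03)
})
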