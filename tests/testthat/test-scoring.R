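test_that("PCA-route distances equal the direct inverse-covariance form", {
  for (seed in 1:20) {
    sp <- rand_spec(p = 8, seed = seed)
    x <- simulate_control_population(sp, 300, seed = seed + 100)
    m <- fit_control_model(x, trim_quantile = 1)  # plain PCA, no trimming
    expect_equal(m$retained, 8)
    d <- mahalanobis_score(x, m)
    xd <- as.matrix(x)
    oracle <- sqrt(mahalanobis(xd, colMeans(xd), cov(xd)))
    expect_lt(max(abs(d - oracle) / oracle), 1e-8)
  }
})

test_that("Mahalanobis scores satisfy their defining identities", {
  sp <- diag_spec(p = 5)
  x <- simulate_control_population(sp, 400, seed = 1)
  m <- fit_control_model(x, trim_quantile = 1)
  # the center scores 0
  center_rec <- as.data.frame(as.list(setNames(m$center * m$scale,
                                               m$attribute_names)))
  expect_equal(mahalanobis_score(center_rec, m), 0)
  # one-attribute model: D counts control SDs
  x1 <- data.frame(a = rnorm(500, 10, 2))
  m1 <- fit_control_model(x1, trim_quantile = 1)
  mu <- mean(x1$a); sigma <- sd(x1$a)
  expect_equal(mahalanobis_score(data.frame(a = mu + 2 * sigma), m1), 2)
  expect_true(all(mahalanobis_score(x, m) >= 0))
  expect_error(mahalanobis_score(data.frame(bogus = 1), m), "attribute")
})

test_that("scores are invariant to rescaling an attribute", {
  sp <- rand_spec(p = 6, seed = 3)
  x <- simulate_control_population(sp, 500, seed = 4)
  y <- simulate_treated_population(sp, 2, 50, seed = 5)$records
  m <- fit_control_model(x, trim_quantile = 1)
  d0 <- mahalanobis_score(y, m)
  x2 <- x; y2 <- y
  x2$attr3 <- x2$attr3 * 1e6; y2$attr3 <- y2$attr3 * 1e6
  d1 <- mahalanobis_score(y2, fit_control_model(x2, trim_quantile = 1))
  expect_lt(max(abs(d1 - d0) / d0), 1e-8)
})

test_that("robust trimming rejects planted artifacts, not the null", {
  # clean data: trimmed fraction at most twice the nominal tail
  set.seed(6)
  x <- as.data.frame(MASS::mvrnorm(2000, c(0, 0), diag(2)))
  m <- fit_control_model(x)
  expect_lte(m$n_trimmed / 2000, 2 * (1 - 0.975))

  # 5% gross outliers at 20 sigma: all trimmed, center recovered
  xo <- x; xo[1:100, ] <- 20
  mo <- fit_control_model(xo)
  d2 <- mahalanobis_score(xo[1:100, ], mo, squared = TRUE)
  expect_true(all(d2 > qchisq(0.975, 2)))
  expect_lt(sqrt(sum((mo$center * mo$scale - colMeans(x[101:2000, ]))^2)),
            0.1)

  # perfectly correlated attribute pair absorbs one rank
  xc <- x; xc$V3 <- xc$V1 * 2 + 1
  expect_equal(fit_control_model(xc, trim_quantile = 1)$retained, 2)

  expect_error(fit_control_model(data.frame(a = rep(1, 100), b = rnorm(100))),
               "zero-variance")
  expect_error(fit_control_model(x[1:2, ]), "more controls")
})

test_that("null squared distances are chi-square distributed", {
  sp <- default_feature_spec()
  x <- simulate_control_population(sp, 5000, seed = 7)
  m <- fit_control_model(x)
  d2 <- mahalanobis_score(x, m, squared = TRUE)
  expect_gt(suppressWarnings(
    stats::ks.test(d2, "pchisq", df = m$retained)$p.value), 0.01)
  # outlier flagging calibrated at the 0.999 tail
  rate <- mean(flag_outliers(x, m, quantile = 0.999))
  expect_lt(rate, 0.004)
  # the center is never flagged; a 50-sigma artifact always is
  center_rec <- as.data.frame(as.list(setNames(m$center * m$scale,
                                               m$attribute_names)))
  expect_false(flag_outliers(center_rec, m))
  art <- x[1, ]; art[] <- as.numeric(x[1, ]) + 50 * sp$control_sd
  expect_true(flag_outliers(art, m))
})

test_that("attribute contributions decompose the squared distance", {
  # diagonal model: c_j = z_j^2 / sum z^2
  x <- as.data.frame(MASS::mvrnorm(2000, rep(0, 4), diag(4)))
  m <- fit_control_model(x, trim_quantile = 1)
  rec <- x[7, ]
  co <- attribute_contributions(rec, m)
  z <- (as.numeric(rec) / m$scale - m$center)
  # project through the model's own covariance: diagonal up to sampling noise
  expect_equal(sum(co), 1)
  expect_equal(as.numeric(co), unname(z^2 / sum(z^2)), tolerance = 0.1)

  # signed contributions always sum to 1, correlated case included
  sp <- rand_spec(p = 8, seed = 9)
  xc <- simulate_control_population(sp, 500, seed = 10)
  mc <- fit_control_model(xc)
  for (i in 1:25)
    expect_equal(sum(attribute_contributions(xc[i, ], mc)), 1)

  # zero distance has no direction
  center_rec <- as.data.frame(as.list(setNames(mc$center * mc$scale,
                                               mc$attribute_names)))
  expect_error(attribute_contributions(center_rec, mc), "distance 0")
})

test_that("a planted 4-sigma attribute shift is top-ranked almost always", {
  p <- 8
  x <- as.data.frame(MASS::mvrnorm(3000, rep(0, p), diag(p)))
  colnames(x) <- paste0("attr", 1:p)
  m <- fit_control_model(x)
  set.seed(12)
  hits <- 0
  for (i in 1:200) {
    rec <- rnorm(p); rec[3] <- rec[3] + 4
    names(rec) <- paste0("attr", 1:p)
    top <- rank_contributions(attribute_contributions(rec, m))$attribute[1]
    hits <- hits + (top == "attr3")
  }
  expect_gte(hits / 200, 0.95)
})

test_that("well scores are outlier-robust medians", {
  x1 <- data.frame(a = rnorm(1000, 0, 1))
  m1 <- fit_control_model(x1, trim_quantile = 1)
  mk <- function(d) data.frame(a = m1$center * m1$scale + d * m1$scale)
  ws <- score_well(mk(c(1, 2, 3)), m1, well = "A1")
  expect_equal(ws$score, 2)
  # a flagged artifact at distance 100 does not move the median
  ws2 <- score_well(mk(c(1, 2, 3, 100)), m1)
  expect_equal(ws2$score, 2)
  expect_equal(ws2$n_outliers, 1)
  # a coherent saturating shift is scored, not discarded
  ws3 <- score_well(mk(rep(50, 20)), m1)
  expect_equal(ws3$score, 50, tolerance = 1e-6)
  expect_false(ws3$empty)
})

test_that("plate scoring flags treated rows and spares controls", {
  sp <- default_feature_spec()
  lay <- build_screen_layout(list(screen_annotation("drug", 1e-7)),
                             n_levels = 10,
                             control_wells = paste0("P", 1:6))
  sim <- simulate_dose_response_plate(sp, lay, cells_per_well = 60,
                                      seed = 13, dose_scale = 1e6)
  ps <- score_plate(sim$cells, lay)
  expect_s3_class(ps, "plate_scores")
  ws <- ps$well_scores
  treated_top <- ws$score[ws$well %in% c("A1", "A2")]  # saturating doses
  ctrl <- ws$score[grepl("^P", ws$well)]
  expect_true(min(treated_top) > max(ctrl))
  # duplicates at equal dose score alike
  expect_equal(ws$score[ws$well == "A1"], ws$score[ws$well == "A2"],
               tolerance = 0.15)
  # grid aligns scores to plate geometry
  expect_equal(ps$grid["A", 1], ws$score[ws$well == "A1"])
  expect_error(score_plate(sim$cells,
                           build_screen_layout(list(screen_annotation("d", 1e-7)))),
               "control")
})

test_that("control models round-trip through JSON", {
  sp <- rand_spec(p = 5, seed = 14)
  x <- simulate_control_population(sp, 400, seed = 15)
  m <- fit_control_model(x)
  path <- tempfile(fileext = ".json")
  write_control_model(m, path)
  m2 <- read_control_model(path)
  expect_equal(mahalanobis_score(x, m2), mahalanobis_score(x, m))
  expect_equal(m2$trim_history, m$trim_history)
})
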