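test_that("the BOS score is strength over body weight in newtons", {
  s <- compute_bos(7848, bos_patient(80), g_N_per_kg = 9.81)
  expect_equal(s$weight_N, 784.8)
  expect_equal(s$value, 10)
  # homogeneity: doubling body weight halves the score
  expect_equal(compute_bos(7848, bos_patient(160))$value, 5)
  expect_error(compute_bos(-1, bos_patient(80)), "positive")
  expect_error(bos_patient(0), "positive")
  expect_error(bos_patient(70, pain_score = 11), "pain")
})

test_that("risk classification uses the 7.5/8.5 thresholds with a closed moderate band", {
  expect_equal(classify_risk(7.0), "high")
  expect_equal(classify_risk(8.0), "moderate")
  expect_equal(classify_risk(9.0), "low")
  # tie rule: thresholds themselves are moderate
  expect_equal(classify_risk(7.5), "moderate")
  expect_equal(classify_risk(8.5), "moderate")
  expect_equal(classify_risk(8.5 + 1e-9), "low")
  expect_equal(classify_risk(7.5 - 1e-9), "high")
  # step function: severity is monotone non-increasing in the score
  sev <- c(high = 3, moderate = 2, low = 1)
  vals <- seq(5, 10, by = 0.1)
  expect_true(all(diff(sev[vapply(vals, classify_risk, "")]) <= 0))
})

test_that("database statistics match a brute-force count", {
  db <- data.frame(bos_score = c(6, 6.5, 9, 10),
                   fractured_6mo = c(TRUE, FALSE, FALSE, FALSE))
  st <- database_stats(db, cut = 7.5)
  expect_equal(st$ppv, 0.5)
  expect_equal(st$npv, 1.0)
  expect_equal(st$sensitivity, 1.0)
  expect_equal(st$specificity, 2 / 3)
  # perfect separation
  db2 <- data.frame(bos_score = c(5, 6, 9, 11),
                    fractured_6mo = c(TRUE, TRUE, FALSE, FALSE))
  st2 <- database_stats(db2)
  expect_equal(st2$ppv, 1.0)
  expect_equal(st2$npv, 1.0)
  # empty stratum yields NA, not an error
  db3 <- data.frame(bos_score = c(9, 10), fractured_6mo = c(FALSE, FALSE))
  expect_true(is.na(database_stats(db3)$ppv))
})

test_that("percentiles use mid-rank ties and are order invariant", {
  db <- data.frame(bos_score = c(4, 6, 8, 10, 12),
                   fractured_6mo = rep(FALSE, 5))
  expect_equal(database_stats(db, score = 8)$percentile, 50)
  expect_equal(database_stats(db, score = 3)$percentile, 0)
  expect_equal(database_stats(db, score = 13)$percentile, 100)
  perm <- db[c(4, 1, 5, 3, 2), ]
  expect_equal(database_stats(perm, score = 8), database_stats(db, score = 8))
})

test_that("the packaged synthetic database reproduces the prior-cohort metrics", {
  db <- load_score_database()
  st <- database_stats(db)
  expect_equal(round(100 * st$sensitivity), 100)
  expect_equal(round(100 * st$specificity), 74)
  expect_equal(round(100 * st$ppv), 39)
  expect_equal(round(100 * st$npv), 100)
})

test_that("the report carries the category, predictive values and caution text", {
  db <- load_score_database()
  score <- compute_bos(5000, bos_patient(75))
  cat <- classify_risk(score)
  out <- withr::local_tempdir()
  sim <- list(curve = data.frame(displacement_mm = c(0, 0.1, 0.2),
                                 force_N = c(0, 2500, 5000)),
              F_max_N = 5000, plastic_elements_at_peak = c(3L, 7L),
              eqpl_at_peak = numeric(10))
  rep <- render_report(score, cat, db, sim, mesh = NULL, out_dir = out)
  expect_equal(rep$risk_category, cat)
  expect_true(is.numeric(rep$ppv) && is.numeric(rep$npv))
  expect_equal(rep$plastic_elements_at_peak, c(3L, 7L))
  expect_match(rep$caution, "does not necessarily coincide")
  md <- readLines(file.path(out, "report.md"))
  expect_true(any(grepl(cat, md)))
  js <- jsonlite::read_json(file.path(out, "report.json"))
  expect_equal(js$risk_category, cat)
  # empty database: percentile panel replaced by a notice
  rep2 <- render_report(score, cat, db = NULL, sim, out_dir = out)
  expect_null(rep2$percentile)
  expect_match(rep2$database_notice, "omitted")
  # missing simulation: warning, report still rendered
  expect_warning(render_report(score, cat, db, simulation = NULL,
                               out_dir = out), "without figure")
})
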