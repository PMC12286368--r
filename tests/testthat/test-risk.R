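test_that("hazard quotient and cancer risk are the defining ratios", {
  expect_equal(hazard_quotient(0.003, 0.003), 1.0)
  expect_equal(hazard_quotient(1.563e-2, 0.003), 5.21)
  expect_equal(hazard_quotient(0, 0.003), 0)
  expect_error(hazard_quotient(0.1, 0), "positive")
  expect_error(hazard_quotient(-0.1, 0.003), "non-negative")

  expect_equal(cancer_risk(0, 1.5), 0)
  expect_equal(cancer_risk(1e-3, 1.5), 1.5e-3)
  # reported South-adult As CR back-implies its CDI at OSF 1.5
  expect_equal(cancer_risk(4.69e-3 / 1.5, 1.5), 4.69e-3)
  expect_error(cancer_risk(1e-3, -1), "positive")
})

test_that("hazard index and total cancer risk are exact sums", {
  ref <- mashhad_reference()
  south_adult <- ref$hq$hq[ref$hq$region == "South" & ref$hq$cohort == "adult"]
  expect_equal(hazard_index(south_adult), 7.6446, tolerance = 1e-12)
  south_child <- ref$hq$hq[ref$hq$region == "South" & ref$hq$cohort == "child"]
  expect_equal(hazard_index(south_child), 8.7673, tolerance = 1e-12)
  expect_equal(hazard_index(rep(0, 10)), 0)
  expect_error(hazard_index(numeric(0)), "empty")

  expect_equal(total_cancer_risk(c(4.83e-3, 6.95e-5)), 4.8995e-3)
  expect_equal(signif(total_cancer_risk(c(4.83e-3, 6.95e-5)), 3), 4.90e-3)
  expect_equal(total_cancer_risk(c(4.45e-3, 5.31e-5)), 4.5031e-3)
  expect_equal(total_cancer_risk(c(0, 0)), 0)
  expect_error(total_cancer_risk(numeric(0)), "empty")
})

test_that("every reported HQ column sums exactly to its reported HI", {
  ref <- mashhad_reference()
  for (i in seq_len(nrow(ref$hi))) {
    col <- ref$hq[ref$hq$region == ref$hi$region[i] &
                    ref$hq$cohort == ref$hi$cohort[i], ]
    expect_equal(hazard_index(col$hq), ref$hi$hi[i], tolerance = 1e-12,
                 label = paste(ref$hi$region[i], ref$hi$cohort[i]))
  }
})

test_that("reported TCRs equal their component sums except the West-adult row", {
  ref <- mashhad_reference()
  for (i in seq_len(nrow(ref$tcr))) {
    comp <- ref$cr[ref$cr$region == ref$tcr$region[i] &
                     ref$cr$cohort == ref$tcr$cohort[i], ]
    s <- total_cancer_risk(comp$cr)
    if (ref$tcr$region[i] == "West" && ref$tcr$cohort[i] == "adult") {
      # known inconsistency in the reported row: 4.23e-3 vs component sum
      expect_equal(s, 4.7698e-3, tolerance = 1e-12)
      expect_gt(abs(s - ref$tcr$tcr[i]) / ref$tcr$tcr[i], 0.1)
    } else {
      # totals were rounded from unrounded components, so the sums of the
      # reported components agree to about half a unit in the third figure
      expect_equal(s, ref$tcr$tcr[i], tolerance = 2e-3,
                   label = paste(ref$tcr$region[i], ref$tcr$cohort[i]))
    }
  }
})

test_that("classification flags follow the thresholds and stay monotone", {
  rec <- rbind(make_records(value = 2),                      # As, HQ >> 1
               make_records(bakery_id = "N-02", element = "Zn", value = 0.5))
  fit <- risk_assessment(rec, params = default_exposure_params())
  cl <- classify_risk(fit)
  expect_true(all(cl$elements$hq_flag[cl$elements$element == "As"]))
  expect_false(any(cl$elements$hq_flag[cl$elements$element == "Zn"]))
  expect_true(all(cl$index$hi_flag))
  expect_equal(unique(cl$index$tcr_class), "unacceptable")

  # a sub-threshold CR is only in the acceptable range, not unacceptable
  loose <- threshold_policy(hq_limit = 200, cr_unacceptable = 1)
  cl2 <- classify_risk(fit, loose)
  expect_false(any(cl2$index$hi_flag))
  expect_equal(unique(cl2$index$tcr_class), "acceptable_range")
  expect_error(threshold_policy(cr_de_minimis = 1e-3), "below")

  # monotone: raising any HQ never un-flags a row
  base <- classify_risk(fit)$elements
  boosted <- fit
  boosted$risk$hq <- boosted$risk$hq * 10
  boosted$index$hi <- boosted$index$hi * 10
  up <- classify_risk(boosted)$elements
  expect_true(all(up$hq_flag >= base$hq_flag))
})

test_that("HI scales linearly with IR and inversely with BW", {
  rec <- small_study(seed = 5)
  p1 <- list(adult = toy_params(IR = 0.4, BW = 70, ED = 10, AT = 3650))
  p2 <- list(adult = toy_params(IR = 0.8, BW = 70, ED = 10, AT = 3650))
  p3 <- list(adult = toy_params(IR = 0.4, BW = 35, ED = 10, AT = 3650))
  h1 <- risk_assessment(rec, params = p1)$index$hi
  h2 <- risk_assessment(rec, params = p2)$index$hi
  h3 <- risk_assessment(rec, params = p3)$index$hi
  expect_equal(h2, 2 * h1)
  expect_equal(h3, 2 * h1)
})

test_that("summary reproduces the cross-region aggregates and ratios", {
  ref <- mashhad_reference()
  child_hi <- ref$hi$hi[ref$hi$cohort == "child"]
  expect_equal(round(mean(child_hi), 3), 8.047)
  adult_tcr <- ref$tcr$tcr[ref$tcr$cohort == "adult"]
  expect_equal(signif(mean(adult_tcr), 3), 4.42e-3)

  # single region with equal cohort HIs gives ratio one
  rec <- make_records(value = 1)
  p <- list(adult = toy_params(cohort = "adult"),
            child = toy_params(cohort = "child"))
  s <- summary(risk_assessment(rec, params = p))
  expect_equal(s$hi_ratio$ratio, 1.0)
  expect_true(all(s$by_cohort$min_hi <= s$by_cohort$mean_hi &
                    s$by_cohort$mean_hi <= s$by_cohort$max_hi))

  # cohort missing: no ratio
  s1 <- summary(risk_assessment(rec, params = list(adult = toy_params())))
  expect_null(s1$hi_ratio)
})

test_that("elements without an RfD are skipped with a warning, not zeroed", {
  rec <- rbind(make_records(value = 1),
               make_records(bakery_id = "N-02", element = "Zn", value = 1))
  tox <- default_tox_profiles()
  tox$rfd[tox$element == "Zn"] <- NA
  p <- list(adult = default_exposure_params()$adult)
  expect_warning(fit <- risk_assessment(rec, params = p, tox = tox), "Zn")
  expect_true(all(is.na(fit$risk$hq[fit$risk$element == "Zn"])))
  # HI is the As quotient alone, not As plus a zero term for Zn
  expect_equal(fit$index$hi, ADULT_FACTOR / 0.003)
})
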