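test_that("the generator realises the survey design combinatorics", {
  rec <- generate_study(default_study_config(seed = 1))
  expect_equal(nrow(rec), 5 * 18 * 3 * 12)
  counts <- table(rec$element)
  expect_true(all(counts == 270))  # 3 stages x 90 bakeries per element
  expect_equal(length(unique(paste(rec$region, rec$bakery_id))), 90)
  expect_setequal(unique(rec$stage), bread_stages())
})

test_that("generation is deterministic in the seed and leaves the RNG alone", {
  a <- generate_study(default_study_config(seed = 42))
  b <- generate_study(default_study_config(seed = 42))
  expect_identical(a, b)
  c <- generate_study(default_study_config(seed = 43))
  expect_false(identical(a$value, c$value))

  set.seed(99)
  before <- .Random.seed
  invisible(generate_study(default_study_config(seed = 1)))
  expect_identical(.Random.seed, before)
})

test_that("censoring depends only on the configured element set", {
  rec <- generate_study(default_study_config(seed = 2))
  expect_true(all(rec$censored[rec$element %in% c("Hg", "Pb")]))
  expect_false(any(rec$censored[!rec$element %in% c("Hg", "Pb")]))
  expect_equal(unique(rec$lod[rec$element == "Pb"]), 0.01)

  cfg <- default_study_config(seed = 2)
  cfg$censored_elements <- character(0)
  rec2 <- generate_study(cfg)
  expect_false(any(rec2$censored))
})

test_that("invalid configurations are rejected naming the field", {
  cfg <- default_study_config()
  cfg$bakeries_per_region <- 0
  expect_error(generate_study(cfg), "bakeries_per_region")
  cfg <- default_study_config()
  cfg$elements <- c("As", "Mn")
  expect_error(generate_study(cfg), "elements")
  cfg <- default_study_config()
  cfg$sigma_log <- -0.1
  expect_error(generate_study(cfg), "sigma_log")
  cfg <- default_study_config()
  cfg$bread_type_probs <- c(sangak = 0.5, barbari = 0.2)
  expect_error(generate_study(cfg), "bread_type_probs")
})

test_that("empirical moments recover the configured parameters at large n", {
  cfg <- default_study_config(seed = 3)
  cfg$elements <- "As"
  cfg$censored_elements <- character(0)
  cfg$bakeries_per_region <- 2000  # 10,000 bakeries in total
  rec <- generate_study(cfg)
  flour <- rec[rec$stage == "flour" & rec$region == "North", ]
  target_mean <- cfg$bread_mean[["As"]] * cfg$region_factors$As[["North"]] /
    (cfg$dough_mult[["As"]] * cfg$bread_mult[["As"]])
  expect_equal(mean(flour$value), target_mean, tolerance = 0.1)
  spec <- fit_distribution(flour$value, "lognormal", "C_As")
  expect_equal(spec$parameters$meanlog,
               log(target_mean) - cfg$sigma_log^2 / 2, tolerance = 0.1)
  expect_equal(spec$parameters$sdlog, cfg$sigma_log, tolerance = 0.1)

  # pooled bread mean approaches the configured target under region factors
  bread <- rec[rec$stage == "bread", ]
  pooled_target <- cfg$bread_mean[["As"]] * mean(unlist(cfg$region_factors$As))
  expect_equal(mean(bread$value), pooled_target, tolerance = 0.1)
})

test_that("the default study reproduces the survey's qualitative pattern", {
  rec <- generate_study(default_study_config(seed = 4))
  bread <- rec[rec$stage == "bread" & !rec$censored, ]
  means <- sort(tapply(bread$value, bread$element, mean), decreasing = TRUE)
  expect_setequal(names(means)[1:3], c("Fe", "Zn", "Al"))
  expect_setequal(names(means)[(length(means) - 1):length(means)],
                  c("Co", "V"))

  # arsenic alone drives the adult hazard quotient above one
  fit <- risk_assessment(rec)
  hq_as <- fit$risk$hq[fit$risk$element == "As" & fit$risk$cohort == "adult"]
  expect_true(all(hq_as > 1))

  # grand-mean flour share sits near the design's 83/14.5/2.5 decomposition
  tab <- suppressMessages(apportionment_table(rec))
  grand <- tab[tab$element == "(mean)", ]
  expect_equal(grand$flour_pct, 83, tolerance = 5 / 83)
})

test_that("region-varying elements are detectable across replicate surveys", {
  detected <- vapply(1:50, function(i) {
    rec <- generate_study(default_study_config(seed = 7000 + i))
    bread <- rec[rec$stage == "bread" & rec$element == "As", ]
    kruskal.test(bread$value, factor(bread$region))$p.value < 0.05
  }, logical(1))
  expect_gte(mean(detected), 0.95)
})
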