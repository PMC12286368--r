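# tiny in-code fixtures shared across test files

make_records <- function(region = "North", bakery_id = "N-01", stage = "bread",
                         bread_type = "sangak", element = "As", value = 1,
                         censored = FALSE, lod = 0.02) {
  data.frame(region = region, bakery_id = bakery_id, stage = stage,
             bread_type = bread_type, element = element, value = value,
             censored = censored, lod = lod, stringsAsFactors = FALSE)
}

# single-cohort exposure bundle with unit-friendly numbers
toy_params <- function(IR = 1, EF = 365, ED = 1, BW = 1, AT = 365,
                       cohort = "adult") {
  exposure_params(cohort, IR = IR, EF = EF, ED = ED, BW = BW, AT = AT)
}

# the printed adult/child intake factors, frozen from hand arithmetic:
# 0.420*365*70/(70*10550) and 0.210*365*6/(20*2100)
ADULT_FACTOR <- 10731 / 738500
CHILD_FACTOR <- 459.9 / 42000

small_study <- function(seed = 1) {
  cfg <- default_study_config(seed = seed)
  generate_study(cfg)
}
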