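test_that("survey generation hits configured sizes, shares and weights", {
  cfg <- small_cfg()
  sv <- generate_survey(cfg)
  expect_equal(nrow(sv), cfg$n_records)
  expect_true(all(sv$survey_weight > 0))
  expect_equal(sum(sv$survey_weight), cfg$total_population)
  expect_true(all(sv$age_group %in% c("45-49", "50-54", "55-59", "60-64")))

  # weighted group shares within half a percentage point of targets
  grp <- classify_groups(sv)
  shares <- tapply(grp$survey_weight, grp$lf_group, sum) / sum(grp$survey_weight)
  for (g in names(cfg$group_shares)) {
    expect_lt(abs(shares[[g]] - cfg$group_shares[[g]]), 0.005)
  }

  # main condition present whenever out of the labour force through
  # ill-health; hours band only for the employed
  expect_true(all(!is.na(sv$main_condition[sv$labour_force_status ==
                                             "NILF_ill_health"])))
  expect_true(all(is.na(sv$hours_band[!sv$labour_force_status %in%
                                        c("FT", "PT")])))
  expect_true(all(!is.na(sv$hours_band[sv$labour_force_status %in%
                                         c("FT", "PT")])))
})

test_that("generation is deterministic given the seed and empty at n = 0", {
  cfg <- small_cfg(n = 400L, donors = 400L, seed = 99L)
  expect_identical(generate_survey(cfg), generate_survey(cfg))
  expect_identical(generate_donor_pool(cfg), generate_donor_pool(cfg))

  cfg0 <- generator_config(n_records = 0L)
  sv0 <- generate_survey(cfg0)
  expect_equal(nrow(sv0), 0L)
  expect_true("survey_weight" %in% names(sv0))

  # a different seed changes records but preserves target shares
  cfg2 <- small_cfg(n = 3000L, seed = 77L)
  sv2 <- classify_groups(generate_survey(cfg2))
  expect_false(identical(sv2$survey_weight,
                         classify_groups(generate_survey(small_cfg()))$survey_weight))
  shares <- tapply(sv2$survey_weight, sv2$lf_group, sum) / sum(sv2$survey_weight)
  for (g in names(cfg2$group_shares)) {
    expect_lt(abs(shares[[g]] - cfg2$group_shares[[g]]), 0.005)
  }
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(group_shares = c(FT_no_arth = 0.9,
                                                 PT_no_arth = 0.2)),
               "sum to more than 1")
  expect_error(generator_config(n_records = 3L), "infeasible")
  expect_error(generator_config(tax_schedule = tibble::tibble(
    threshold = numeric(0), rate = numeric(0))), "tax schedule")
  expect_error(generator_config(group_shares = c(bogus = 0.1)), "unknown group")
})

test_that("donor-pool economics respect the accounting identity and tax rules", {
  dn <- cached("small_donors", function() generate_donor_pool(small_cfg()))
  expect_equal(dn$weekly_total_income,
               dn$weekly_earnings + dn$weekly_other_income + dn$weekly_welfare,
               tolerance = 1e-12)
  expect_true(all(dn$weekly_welfare >= 0))

  # below the tax-free threshold no tax is due
  low <- dn$weekly_earnings + dn$weekly_other_income < 18200 / 52
  expect_true(all(dn$weekly_tax[low] == 0))

  # zero earnings and zero welfare: total is exactly other income
  zz <- dn$weekly_earnings == 0 & dn$weekly_welfare == 0
  expect_true(any(zz))
  expect_equal(dn$weekly_total_income[zz], dn$weekly_other_income[zz])

  # the NILF-arthritis welfare median is the flat disability pension
  # rate and its tax is zero
  nilf <- dn$labour_force_status == "NILF_ill_health" & dn$receives_dsp
  expect_equal(weighted_median(dn$weekly_welfare[nilf]), 311.67)
  expect_true(all(dn$weekly_tax[dn$weekly_earnings == 0 &
                                  dn$weekly_other_income == 0] == 0))
})

test_that("group income medians are calibrated to targets at full survey size", {
  cfg <- generator_config(seed = 314L)
  up <- uprate_profile(full_imputed(), uprating_rule(), cfg$reference_year)
  med <- summarize_groups(up)
  for (g in cfg$median_targets$group) {
    target <- cfg$median_targets$income[cfg$median_targets$group == g]
    got <- med$median[med$group == g & med$outcome == "income"][1]
    expect_lt(abs(got - target) / target, 0.05)
  }
  # rule-based welfare medians are reproduced exactly
  expect_equal(med$median[med$group == "NILF_arth" & med$outcome == "welfare"][1],
               311.67)
})

test_that("benchmarks carry the projection-year populations and add up", {
  cfg <- small_cfg()
  bm <- generate_benchmarks(cfg)
  b30 <- dplyr::filter(tibble::as_tibble(bm), year == 2030)
  # grand totals per constraint variable all equal the year's population
  for (v in unique(b30$variable)) {
    expect_equal(sum(b30$target[b30$variable == v]), 7130000)
  }
  b15 <- dplyr::filter(tibble::as_tibble(bm), year == 2015)
  expect_equal(sum(b15$target[b15$variable == "lf_group"]), 5945000)
  expect_error(generate_benchmarks(cfg, years = 2040), "unknown projection year")

  # an all-flat growth path yields identical benchmarks in every year
  flat_shares <- plycost:::default_group_share_path()
  flat_shares[, ] <- flat_shares[, "2015"]
  flat <- generate_benchmarks(
    cfg, years = c(2015, 2030),
    population_path = c("2015" = 5945000, "2030" = 5945000),
    group_share_path = flat_shares)
  ft <- tibble::as_tibble(flat)
  expect_equal(ft$target[ft$year == 2015], ft$target[ft$year == 2030])
})

test_that("disease-trend multipliers scale arthritis cells and conserve totals", {
  cfg <- small_cfg()
  bm <- generate_benchmarks(cfg, years = 2020)
  # identity multipliers change nothing
  same <- apply_disease_trend(bm, tibble::tibble(year = 2020, multiplier = 1))
  expect_equal(tibble::as_tibble(same), tibble::as_tibble(bm))

  up <- apply_disease_trend(bm, tibble::tibble(year = 2020, multiplier = 1.1))
  b0 <- dplyr::filter(tibble::as_tibble(bm), variable == "lf_group")
  b1 <- dplyr::filter(tibble::as_tibble(up), variable == "lf_group")
  arth <- b0$level %in% c("FT_arth", "PT_arth", "NILF_arth")
  expect_equal(b1$target[arth], b0$target[arth] * 1.1)
  expect_equal(sum(b1$target), sum(b0$target))
  expect_error(
    apply_disease_trend(bm, tibble::tibble(year = 2020, multiplier = -1)),
    ">= 0")
})

test_that("lost-PLY flag follows the ICD-10 M00-M19 definition", {
  df <- tibble::tibble(
    labour_force_status = c("NILF_ill_health", "FT", "NILF_ill_health",
                            "NILF_ill_health", "NILF_other"),
    main_condition = c("M05", "M05", "I21", "M19", NA)
  )
  expect_identical(flag_lost_ply(df), c(TRUE, FALSE, FALSE, TRUE, FALSE))
  # M20+ (other musculoskeletal) is outside the arthritis range
  df2 <- tibble::tibble(labour_force_status = "NILF_ill_health",
                        main_condition = "M54")
  expect_false(flag_lost_ply(df2))
  expect_error(flag_lost_ply(tibble::tibble(
    labour_force_status = "FT", main_condition = "bad!")), "malformed")
})
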