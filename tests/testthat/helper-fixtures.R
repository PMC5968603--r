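# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

small_cfg <- function(n = 3000L, donors = 6000L, seed = 11L) {
  generator_config(n_records = n, n_donors = donors, seed = seed)
}

# Small imputed survey at 2015 weights, shared across test files.
small_imputed <- function() {
  cached("small_imputed", function() {
    cfg <- small_cfg()
    sv <- classify_groups(generate_survey(cfg))
    dn <- generate_donor_pool(cfg)
    impute_economics(sv, dn, fallback_policy(), seed = 5L)
  })
}

# Full-size imputed survey (25,104 records) under default study
# conditions, shared by the calibration and median-target checks.
full_imputed <- function() {
  cached("full_imputed", function() {
    cfg <- generator_config(seed = 314L)
    sv <- classify_groups(generate_survey(cfg))
    dn <- generate_donor_pool(cfg)
    impute_economics(sv, dn, fallback_policy(), seed = 9L)
  })
}

# Hand-built person table for costing unit tests: one reference group
# with constant outcomes plus one lost-PLY person, so counterfactual
# predictions are known exactly.
constant_groups_data <- function(ft_income = 1308.88, nilf_income = 321.87,
                                 nilf_weight = 1000, n_ft = 20) {
  tibble::tibble(
    labour_force_status = c(rep("FT", n_ft), "NILF_ill_health"),
    main_condition = c(rep(NA_character_, n_ft), "M06"),
    age_group = "50-54", sex = "female", education = "degree+",
    weekly_total_income = c(rep(ft_income, n_ft), nilf_income),
    weekly_welfare = c(rep(0, n_ft), 311.67),
    weekly_tax = c(rep(170, n_ft), 0),
    survey_weight = c(rep(10, n_ft), nilf_weight)
  ) |>
    classify_groups()
}

# Parameter-recovery generator: covariate-balanced groups, degenerate
# welfare (flat 312 for the lost-PLY group), no other income, and a
# single-bracket tax schedule solved so the injected full-time-vs-NILF
# gaps are exactly -700 (income), +312 (welfare) and -170 (tax) AU$/wk
# at the 2015 reference year.
recovery_config <- function(n = 5000L, seed = 1L) {
  defl <- 1.01^2
  ft_income <- 1012
  earn_med_annual <- 52 * ft_income / defl
  rate <- 170 / (defl * (earn_med_annual - 18200) / 52)
  rules <- default_welfare_rules_recovery()
  generator_config(
    n_records = n, n_donors = n,
    group_shares = c(FT_no_arth = 0.40, FT_arth = 0.05, PT_no_arth = 0.15,
                     PT_arth = 0.05, NILF_arth = 0.06, unemployed = 0.02,
                     NILF_ill_other = 0.03),
    median_targets = tibble::tribble(
      ~group,        ~income, ~welfare, ~tax,
      "FT_no_arth",  ft_income,   0,      170,
      "FT_arth",     900,         0,        0,
      "PT_no_arth",  600,         0,        0,
      "PT_arth",     550,         0,        0,
      "NILF_arth",   312,       312,        0
    ),
    income_dispersion = c(FT_no_arth = 0.5, FT_arth = 0.5, PT_no_arth = 0.5,
                          PT_arth = 0.5, NILF_arth = 0.5, unemployed = 0.5,
                          NILF_other = 0.5, NILF_ill_other = 0.5),
    welfare_rules = rules,
    tax_schedule = tibble::tibble(threshold = c(0, 18200),
                                  rate = c(0, rate)),
    medicare_levy = 0, levy_threshold = Inf,
    covariate_effects = balanced_covariates(),
    other_income = list(
      employed = list(prob = 0, meanlog = 0, sdlog = 1),
      nonworking = list(prob = 0, meanlog = 0, sdlog = 1)
    ),
    seed = seed
  )
}

default_welfare_rules_recovery <- function() {
  rules <- plycost:::default_welfare_rules()
  rules$dsp_rate <- 312
  rules$nilf_arth_probs <- c(dsp = 1, dsp_ftb = 0, none = 0)
  rules$employed_ftb_prob <- c(FT = 0, PT = 0)
  rules
}

# Injected population truths of recovery_config(), at the 2015 reference
# year.
recovery_truth <- c(weekly_total_income = -700, weekly_welfare = 312,
                    weekly_tax = -170)

# Brute-force fallback-depth oracle: enumerate, per ladder step, the
# set of donor cells by pasting the remaining matching variables, and
# report for each recipient the first step whose cell is non-empty.
# Independent of the implementation's split/index/sampling machinery.
oracle_depths <- function(recipients, donors, policy = fallback_policy()) {
  vars_at_depth <- Reduce(setdiff, policy$drop_order,
                          init = plycost:::MATCH_VARS, accumulate = TRUE)
  cell_of <- function(df, vars) {
    cols <- lapply(vars, function(v) {
      x <- as.character(df[[v]])
      ifelse(is.na(x), "<NA>", x)
    })
    do.call(paste, c(cols, sep = "\r"))
  }
  out <- rep(NA_integer_, nrow(recipients))
  for (d in seq_along(vars_at_depth)) {
    vars <- vars_at_depth[[d]]
    donor_cells <- unique(cell_of(donors, vars))
    hit <- is.na(out) & cell_of(recipients, vars) %in% donor_cells
    out[hit] <- d - 1L
  }
  out
}
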