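#' Generate a synthetic pooled survey of persons aged 45-64
#'
#' Emulates the structure of a pooled 2003/2009 national disability
#' survey: person-level records carrying demographics, socioeconomic
#' matching variables, labour-force status (including "not in the labour
#' force due to own ill-health"), a main chronic condition (ICD-10
#' category) and a survey weight. Group sizes are apportioned
#' deterministically to the configured shares (largest-remainder method),
#' so weighted group shares land within a fraction of a percentage point
#' of their targets; weights are mildly dispersed and scaled so they sum
#' exactly to the configured weighted population.
#'
#' The survey carries no economic variables: weekly income, welfare and
#' tax are attached later by donor imputation (see
#' [generate_donor_pool()] and [impute_economics()]). The income quintile
#' band, pension flags and hours band *are* part of the survey record, as
#' they are matching variables.
#'
#' @param config A [generator_config()].
#' @return A tibble with one row per person record.
#' @examples
#' cfg <- generator_config(n_records = 500, n_donors = 1000)
#' sv <- generate_survey(cfg)
#' dplyr::count(sv, labour_force_status)
#' @export
generate_survey <- function(config) {
  validate_config(config)
  pop <- gen_population(config$n_records, config,
                        seed = derive_seed(config$seed, "survey"),
                        id_prefix = "S")
  pop$record_id <- pop$unit_id
  dplyr::select(pop, "record_id", "survey_year", "age_group", "sex",
                "education", "income_unit_type", "home_ownership",
                "labour_force_status", "main_condition", "hours_band",
                "receives_age_pension", "receives_dsp", "income_quintile",
                "survey_weight")
}

#' Generate a tax-transfer donor pool
#'
#' Donor records carry the ten matching variables plus a full weekly
#' economic profile (earnings, other income, welfare, tax and total, in
#' real base-year AU$), emulating a static tax-transfer microsimulation
#' snapshot. Incomes are drawn from per-group log-normal distributions
#' whose location is calibrated so group medians land on the configured
#' targets; welfare is rule-based (flat payment rates by status) and tax
#' is computed by applying the configured schedule to annualised taxable
#' income and dividing back to weekly.
#'
#' @param config A [generator_config()]; `n_donors` controls cell
#'   coverage (more donors, fewer fallback matches).
#' @return A tibble with one row per donor.
#' @export
generate_donor_pool <- function(config) {
  validate_config(config)
  pop <- gen_population(config$n_donors, config,
                        seed = derive_seed(config$seed, "donors"),
                        id_prefix = "D")
  pop$donor_id <- pop$unit_id
  dplyr::select(pop, "donor_id", "labour_force_status", "income_unit_type",
                "income_quintile", "receives_age_pension", "receives_dsp",
                "sex", "age_group", "hours_band", "education",
                "home_ownership", "weekly_earnings", "weekly_other_income",
                "weekly_welfare", "weekly_total_income", "weekly_tax")
}

# Shared generative mechanism for survey persons and donors. Draws the
# full record including economics; generate_survey() drops the economic
# columns (they are imputed back from donors downstream), keeping the
# income quintile and receipt flags that derive from them.
gen_population <- function(n, config, seed, id_prefix = "P") {
  if (n == 0L) {
    out <- tibble::tibble(
      unit_id = character(), survey_year = integer(), group = character(),
      age_group = character(), sex = character(), education = character(),
      income_unit_type = character(), home_ownership = character(),
      labour_force_status = character(), main_condition = character(),
      hours_band = character(), receives_age_pension = logical(),
      receives_dsp = logical(), income_quintile = integer(),
      survey_weight = numeric(), weekly_earnings = numeric(),
      weekly_other_income = numeric(), weekly_welfare = numeric(),
      weekly_total_income = numeric(), weekly_tax = numeric()
    )
    return(out)
  }
  set.seed(seed)

  shares <- config$group_shares
  shares <- c(shares, NILF_other = max(0, 1 - sum(shares)))
  counts <- apportion(n, shares)
  group <- rep(names(counts), counts)
  group <- group[sample.int(n)] # shuffle so record order carries no signal
  eff <- config$covariate_effects
  mix <- eff$mix

  draw_cat <- function(levels, probs_by_group) {
    idx <- vapply(seq_len(n), function(i) {
      sample.int(length(levels), 1L, prob = probs_by_group[group[i], ])
    }, integer(1))
    levels[idx]
  }
  age_group <- draw_cat(AGE_GROUPS, mix$age)
  education <- draw_cat(EDU_LEVELS, mix$education)
  sex <- ifelse(stats::runif(n) < mix$p_female[group], "female", "male")
  income_unit_type <- sample(IUT_LEVELS, n, replace = TRUE,
                             prob = c(0.20, 0.10, 0.45, 0.25))
  employed <- group %in% c("FT_no_arth", "FT_arth", "PT_no_arth", "PT_arth")
  home_ownership <- ifelse(stats::runif(n) < ifelse(employed, 0.75, 0.60),
                           "owner", "non-owner")
  survey_year <- sample(c(2003L, 2009L), n, replace = TRUE)

  labour_force_status <- dplyr::case_match(
    group,
    c("FT_no_arth", "FT_arth") ~ "FT",
    c("PT_no_arth", "PT_arth") ~ "PT",
    "unemployed" ~ "unemployed",
    c("NILF_arth", "NILF_ill_other") ~ "NILF_ill_health",
    "NILF_other" ~ "NILF_other"
  )
  arthritic <- group %in% c("FT_arth", "PT_arth", "NILF_arth")
  main_condition <- rep(NA_character_, n)
  main_condition[arthritic] <-
    sample(ARTHRITIS_CODES, sum(arthritic), replace = TRUE)
  ill_other <- group == "NILF_ill_other"
  main_condition[ill_other] <-
    sample(OTHER_CONDITION_CODES, sum(ill_other), replace = TRUE)
  other_cond <- !arthritic & !ill_other & stats::runif(n) < 0.30
  main_condition[other_cond] <-
    sample(OTHER_CONDITION_CODES, sum(other_cond), replace = TRUE)

  hours_band <- rep(NA_character_, n)
  ft <- labour_force_status == "FT"
  pt <- labour_force_status == "PT"
  hours_band[ft] <- sample(HOURS_FT, sum(ft), replace = TRUE, prob = c(0.7, 0.3))
  hours_band[pt] <- sample(HOURS_PT, sum(pt), replace = TRUE,
                           prob = c(0.30, 0.35, 0.35))

  econ <- gen_economics(group, age_group, education, config)

  receives_dsp <- econ$dsp
  receives_age_pension <- econ$age_pension
  income_quintile <- findInterval(econ$total, config$quintile_breaks) + 1L

  w <- stats::rlnorm(n, meanlog = 0, sdlog = 0.2)
  survey_weight <- w / sum(w) * config$total_population

  tibble::tibble(
    unit_id = sprintf("%s%06d", id_prefix, seq_len(n)),
    survey_year, group, age_group, sex, education, income_unit_type,
    home_ownership, labour_force_status, main_condition, hours_band,
    receives_age_pension, receives_dsp,
    income_quintile = as.integer(income_quintile), survey_weight,
    weekly_earnings = econ$earnings, weekly_other_income = econ$other,
    weekly_welfare = econ$welfare, weekly_total_income = econ$total,
    weekly_tax = econ$tax
  )
}

# Largest-remainder apportionment of n units to shares.
apportion <- function(n, shares) {
  raw <- n * shares / sum(shares)
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    top <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[top] <- counts[top] + 1
  }
  stats::setNames(as.integer(counts), names(shares))
}

# Weekly earnings, other income, welfare and tax at base-year (2013)
# levels. Earnings are log-normal per group with covariate multipliers;
# the log-scale location is calibrated by root-finding on the realized
# draws so the group median of total income, once uprated to the
# reference year, lands on the configured target (total income mixes
# earnings with welfare and other income, so a closed-form log-normal
# location would miss the target for welfare-heavy groups). Welfare is
# rule-based; tax applies the annual schedule to annualised taxable
# (non-welfare) income.
gen_economics <- function(group, age_group, education, config) {
  n <- length(group)
  eff <- config$covariate_effects
  rules <- config$welfare_rules
  defl <- (1 + config$income_growth)^(config$reference_year - config$base_year)
  targets <- config$median_targets

  earnings <- numeric(n)
  other <- numeric(n)
  welfare <- numeric(n)
  dsp <- logical(n)
  age_pension <- logical(n)

  oi <- config$other_income
  draw_other <- function(idx, pars) {
    on <- stats::runif(length(idx)) < pars$prob
    v <- numeric(length(idx))
    v[on] <- stats::rlnorm(sum(on), pars$meanlog, pars$sdlog)
    v
  }

  for (g in unique(group)) {
    idx <- which(group == g)
    sigma <- config$income_dispersion[[g]]
    lf <- log(eff$education[education[idx]]) + log(eff$age[age_group[idx]])
    if (g %in% c("FT_no_arth", "FT_arth", "PT_no_arth", "PT_arth")) {
      target <- targets$income[targets$group == g]
      noise <- lf + stats::rnorm(length(idx), 0, sigma)
      other[idx] <- draw_other(idx, oi$employed)
      ftb_p <- rules$employed_ftb_prob[[substr(g, 1, 2)]]
      got <- stats::runif(length(idx)) < ftb_p
      welfare[idx] <- ifelse(got, rules$ftb_rate, 0)
      # solve the log-location so the realized reference-year median of
      # total income equals the target
      med_at <- function(loc) {
        stats::median(defl * (exp(loc + noise) + other[idx]) + welfare[idx])
      }
      loc <- stats::uniroot(function(l) med_at(l) - target,
                            c(log(target) - 8, log(target) + 4),
                            tol = 1e-10)$root
      earnings[idx] <- exp(loc + noise)
    } else if (g == "unemployed") {
      welfare[idx] <- rules$newstart_rate
      other[idx] <- draw_other(idx, oi$nonworking)
    } else if (g == "NILF_arth") {
      u <- stats::runif(length(idx))
      p <- rules$nilf_arth_probs
      welfare[idx] <- ifelse(u < p[["dsp"]], rules$dsp_rate,
                      ifelse(u < p[["dsp"]] + p[["dsp_ftb"]],
                             rules$dsp_rate + rules$ftb_rate, 0))
      dsp[idx] <- u < p[["dsp"]] + p[["dsp_ftb"]]
      other[idx] <- draw_other(idx, oi$nonworking)
      # scale the small other-income component towards the group's
      # total-income median target (bounded best effort: welfare is
      # rule-based and dominates this group's income)
      target <- targets$income[targets$group == g]
      med_at <- function(s) {
        stats::median(welfare[idx] + defl * s * other[idx])
      }
      if (length(idx) > 1 && any(other[idx] > 0) &&
          med_at(0) < target && med_at(50) > target) {
        s <- stats::uniroot(function(s) med_at(s) - target, c(0, 50),
                            tol = 1e-10)$root
        other[idx] <- s * other[idx]
      }
    } else if (g == "NILF_ill_other") {
      got <- stats::runif(length(idx)) < rules$nilf_ill_other_dsp_prob
      welfare[idx] <- ifelse(got, rules$dsp_rate, 0)
      dsp[idx] <- got
      other[idx] <- draw_other(idx, oi$nonworking)
    } else { # NILF_other: early retirees, carers, age pensioners
      got <- stats::runif(length(idx)) < rules$nilf_other_pension_prob
      old <- age_group[idx] == "60-64"
      welfare[idx] <- ifelse(got, ifelse(old, rules$age_pension_rate,
                                         rules$dsp_rate * 0.9), 0)
      age_pension[idx] <- got & old
      other[idx] <- draw_other(idx, oi$nonworking)
    }
  }

  taxable_annual <- 52 * (earnings + other)
  tax <- (annual_tax(taxable_annual, config$tax_schedule) +
            medicare_levy(taxable_annual, config$medicare_levy,
                          config$levy_threshold)) / 52
  total <- earnings + other + welfare
  list(earnings = earnings, other = other, welfare = welfare,
       tax = tax, total = total, dsp = dsp, age_pension = age_pension)
}

# Median of log(f_edu) + log(f_age) + sigma*Z over a group's covariate
# mix: solved by root-finding on the exact mixture CDF so that group
# earnings medians are calibrated analytically, not by trial draws.
mixture_median_shift <- function(g, sigma, eff) {
  pe <- eff$mix$education[g, ]
  pa <- eff$mix$age[g, ]
  lf <- outer(log(eff$education), log(eff$age), "+")
  pw <- outer(pe, pa)
  cdf <- function(m) sum(pw * stats::pnorm((m - lf) / sigma)) - 0.5
  lo <- min(lf) - 6 * sigma
  hi <- max(lf) + 6 * sigma
  stats::uniroot(cdf, c(lo, hi), tol = 1e-10)$root
}

# Progressive annual income tax from a threshold/marginal-rate table.
annual_tax <- function(income, schedule) {
  stopifnot(nrow(schedule) >= 1)
  tax <- numeric(length(income))
  thr <- schedule$threshold
  rate <- schedule$rate
  upper <- c(thr[-1], Inf)
  for (b in seq_along(thr)) {
    tax <- tax + rate[b] * pmax(0, pmin(income, upper[b]) - thr[b])
  }
  tax
}

medicare_levy <- function(income, rate, threshold) {
  ifelse(income > threshold, rate * income, 0)
}

#' Generate projection-year calibration benchmarks
#'
#' Produces, per projection year, the benchmark cell totals that the
#' calibration reweighting targets: age-by-sex population totals,
#' labour-force-by-arthritis analysis-cell totals, and marginal totals
#' for education, home ownership and disability-pension receipt. Totals
#' grow along configurable paths; defaults are calibrated to the
#' published weighted populations (5,945,000 / 6,374,000 / 6,677,000 /
#' 7,130,000 for 2015/2020/2025/2030) and group-share trajectories, and
#' embed the arthritis prevalence trend in the arthritis-cell shares.
#' An explicit trend-multiplier table (default all ones, i.e. the
#' embedded trend) is attached for scenario adjustment via
#' [apply_disease_trend()].
#'
#' @param config A [generator_config()]; benchmark marginals for
#'   education, home ownership and DSP receipt are derived from its
#'   covariate mixes and welfare rules so the constraint system is
#'   consistent with the generated survey.
#' @param years Projection years, a subset of those in
#'   `population_path`.
#' @param population_path Named numeric vector of weighted population
#'   totals per projection year.
#' @param group_share_path Matrix of analysis-group population shares
#'   (groups in rows, years in columns). Residual shares are allocated
#'   proportionally to the base-year residual composition.
#' @return A `plycost_benchmarks` object: a tibble with columns `year`,
#'   `variable`, `level`, `target`, with the trend-multiplier table as
#'   attribute `trend`.
#' @export
generate_benchmarks <- function(config,
                                years = c(2015L, 2020L, 2025L, 2030L),
                                population_path = c(
                                  "2015" = 5945000, "2020" = 6374000,
                                  "2025" = 6677000, "2030" = 7130000
                                ),
                                group_share_path = default_group_share_path()) {
  unknown <- setdiff(as.character(years), names(population_path))
  if (length(unknown))
    stop("unknown projection year(s): ", paste(unknown, collapse = ", "))
  mix <- config$covariate_effects$mix
  rules <- config$welfare_rules

  base_shares <- config$group_shares
  base_shares <- c(base_shares, NILF_other = max(0, 1 - sum(base_shares)))
  residual_base <- base_shares[RESIDUAL_GROUPS]

  one_year <- function(yr) {
    pop <- population_path[[as.character(yr)]]
    gs <- group_share_path[, as.character(yr)]
    residual <- 1 - sum(gs)
    if (residual < 0) stop("group share path exceeds 1 in ", yr)
    shares <- c(gs, residual * residual_base / sum(residual_base))
    shares <- shares[ALL_GROUPS]

    # joint age x sex from per-group independence of the generator
    pf <- mix$p_female[ALL_GROUPS]
    age_f <- colSums(shares * pf * mix$age[ALL_GROUPS, ])
    age_m <- colSums(shares * (1 - pf) * mix$age[ALL_GROUPS, ])
    age_sex_tbl <- tibble::tibble(
      variable = "age_group:sex",
      level = c(paste0(AGE_GROUPS, ":female"), paste0(AGE_GROUPS, ":male")),
      target = pop * c(age_f, age_m)
    )
    group_tbl <- tibble::tibble(
      variable = "lf_group", level = ALL_GROUPS, target = pop * shares
    )
    edu_share <- colSums(shares * mix$education[ALL_GROUPS, ])
    edu_tbl <- tibble::tibble(
      variable = "education", level = EDU_LEVELS, target = pop * edu_share
    )
    employed_share <- sum(shares[c("FT_no_arth", "FT_arth", "PT_no_arth", "PT_arth")])
    own_share <- 0.75 * employed_share + 0.60 * (1 - employed_share)
    own_tbl <- tibble::tibble(
      variable = "home_ownership", level = c("owner", "non-owner"),
      target = pop * c(own_share, 1 - own_share)
    )
    p <- rules$nilf_arth_probs
    dsp_share <- shares[["NILF_arth"]] * (p[["dsp"]] + p[["dsp_ftb"]]) +
      shares[["NILF_ill_other"]] * rules$nilf_ill_other_dsp_prob
    dsp_tbl <- tibble::tibble(
      variable = "receives_dsp", level = c("TRUE", "FALSE"),
      target = pop * c(dsp_share, 1 - dsp_share)
    )
    dplyr::bind_rows(age_sex_tbl, group_tbl, edu_tbl, own_tbl, dsp_tbl) |>
      dplyr::mutate(year = as.integer(yr), .before = 1)
  }

  out <- purrr::map_dfr(sort(unique(as.integer(years))), one_year)
  attr(out, "trend") <- tibble::tibble(
    year = sort(unique(as.integer(years))), multiplier = 1
  )
  attr(out, "arthritis_levels") <- c("FT_arth", "PT_arth", "NILF_arth")
  class(out) <- c("plycost_benchmarks", class(out))
  out
}

# Published analysis-group share trajectories (percent of the weighted
# 45-64 population) for the four projection years.
default_group_share_path <- function() {
  m <- rbind(
    FT_no_arth = c(0.4898, 0.4972, 0.4996, 0.5049),
    FT_arth    = c(0.0516, 0.0532, 0.0537, 0.0531),
    PT_no_arth = c(0.1736, 0.1811, 0.1894, 0.1879),
    PT_arth    = c(0.0313, 0.0327, 0.0333, 0.0331),
    NILF_arth  = c(0.0091, 0.0091, 0.0088, 0.0085)
  )
  colnames(m) <- c("2015", "2020", "2025", "2030")
  m
}

#' Scale arthritis benchmark cells by a prevalence trend
#'
#' Multiplies the arthritis-cell targets of each year's benchmarks by the
#' year's trend multiplier and rescales the non-arthritis cells of the
#' same constraint variable so the year's population total is preserved
#' to machine precision.
#'
#' @param benchmarks A [generate_benchmarks()] result.
#' @param multipliers Tibble with columns `year` and `multiplier`
#'   (non-negative).
#' @return The adjusted `plycost_benchmarks` object.
#' @export
apply_disease_trend <- function(benchmarks, multipliers) {
  stopifnot(all(c("year", "multiplier") %in% names(multipliers)))
  if (any(multipliers$multiplier < 0)) stop("trend multipliers must be >= 0")
  arth <- attr(benchmarks, "arthritis_levels")
  out <- benchmarks
  for (i in seq_len(nrow(multipliers))) {
    yr <- multipliers$year[i]
    m <- multipliers$multiplier[i]
    sel <- out$year == yr & out$variable == "lf_group"
    if (!any(sel)) next
    g <- out[sel, ]
    is_arth <- g$level %in% arth
    total <- sum(g$target)
    new_arth <- g$target[is_arth] * m
    rest <- total - sum(new_arth)
    if (rest < 0 || any(new_arth < 0))
      stop("trend multiplier ", m, " drives benchmark cells negative in ", yr)
    g$target[is_arth] <- new_arth
    g$target[!is_arth] <- g$target[!is_arth] * rest / sum(g$target[!is_arth])
    out[sel, ] <- g
  }
  out
}

#' Derive analysis groups and the lost-PLY flag
#'
#' `classify_groups()` adds the labour-force-by-arthritis analysis cell
#' (`lf_group`), an arthritis indicator, and the lost-PLY flag to a
#' person table. `flag_lost_ply()` implements the lost-PLY definition: a
#' person is counted as having lost a productive life year to arthritis
#' if and only if they are not in the labour force due to their own
#' ill-health *and* their main chronic condition is arthritis or a
#' related disorder (ICD-10 categories M00-M19).
#'
#' @param data A person tibble with `labour_force_status` and
#'   `main_condition` columns.
#' @return `classify_groups()`: the tibble with `arthritis`, `lost_ply`
#'   and `lf_group` columns added. `flag_lost_ply()`: a logical vector.
#' @examples
#' df <- tibble::tibble(
#'   labour_force_status = c("NILF_ill_health", "FT", "NILF_ill_health"),
#'   main_condition = c("M05", "M05", "I21")
#' )
#' flag_lost_ply(df) # TRUE FALSE FALSE
#' @export
classify_groups <- function(data) {
  arth <- is_arthritis_code(data$main_condition)
  lfs <- data$labour_force_status
  cell <- dplyr::case_when(
    lfs == "FT" & arth ~ "FT_arth",
    lfs == "FT" ~ "FT_no_arth",
    lfs == "PT" & arth ~ "PT_arth",
    lfs == "PT" ~ "PT_no_arth",
    lfs == "NILF_ill_health" & arth ~ "NILF_arth",
    lfs == "NILF_ill_health" ~ "NILF_ill_other",
    lfs == "unemployed" ~ "unemployed",
    TRUE ~ "NILF_other"
  )
  dplyr::mutate(data,
                arthritis = !!arth,
                lf_group = factor(!!cell, levels = ALL_GROUPS),
                lost_ply = !!(lfs == "NILF_ill_health" & arth))
}

#' @rdname classify_groups
#' @export
flag_lost_ply <- function(data) {
  is_arthritis_code(data$main_condition) &
    data$labour_force_status == "NILF_ill_health"
}

# TRUE for ICD-10 categories M00-M19 ("arthritis and related
# disorders"), compared on the 3-character category. NA codes (no
# condition) are FALSE; malformed codes are an error.
is_arthritis_code <- function(code) {
  chk <- !is.na(code)
  if (any(chk & !grepl("^[A-Z][0-9]{2}", code)))
    stop("malformed ICD-10 code(s): ",
         paste(unique(code[chk & !grepl("^[A-Z][0-9]{2}", code)]), collapse = ", "))
  out <- rep(FALSE, length(code))
  num <- suppressWarnings(as.integer(substr(code[chk], 2, 3)))
  out[chk] <- substr(code[chk], 1, 1) == "M" & num <= 19
  out
}
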