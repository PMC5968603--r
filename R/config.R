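# Labour-force-by-arthritis analysis cells. The five reported groups come
# first; the remaining three absorb the rest of the 45-64 population
# (unemployed, not in the labour force for reasons other than ill-health,
# and out of the labour force through ill-health with a main condition
# other than arthritis).
ANALYSIS_GROUPS <- c("FT_no_arth", "FT_arth", "PT_no_arth", "PT_arth", "NILF_arth")
RESIDUAL_GROUPS <- c("unemployed", "NILF_other", "NILF_ill_other")
ALL_GROUPS <- c(ANALYSIS_GROUPS, RESIDUAL_GROUPS)

AGE_GROUPS <- c("45-49", "50-54", "55-59", "60-64")
EDU_LEVELS <- c("none-post-school", "certificate/diploma", "degree+")
IUT_LEVELS <- c("single", "single-dep", "couple", "couple-dep")
LFS_LEVELS <- c("FT", "PT", "unemployed", "NILF_ill_health", "NILF_other")
HOURS_FT <- c("35-44", "45+")
HOURS_PT <- c("1-15", "16-24", "25-34")

# ICD-10 chronic condition categories used for synthetic main conditions.
ARTHRITIS_CODES <- c("M05", "M06", "M13", "M15", "M16", "M17", "M19")
OTHER_CONDITION_CODES <- c("M54", "I25", "I21", "E11", "F32", "J44", "G35")

#' Configuration of the synthetic survey and donor-pool generator
#'
#' The generator emulates the statistical structure of a pooled 2003/2009
#' national disability survey of the population aged 45-64, with economic
#' variables (weekly income, welfare and tax in real 2013 AU$) carried by
#' a tax-transfer donor pool. Defaults reproduce the study conditions the
#' package is calibrated to: 25,104 survey records weighting up to a
#' 5,945,000-person population in 2015, group shares and median weekly
#' income/welfare/tax per labour-force-by-arthritis cell taken from the
#' published 2015 column, and a simplified 2013-style progressive income
#' tax schedule with a Medicare levy.
#'
#' Monetary medians in `median_targets` are stated at `reference_year`
#' (2015) levels; the generator deflates earnings, other income and tax
#' back to `base_year` (2013) at `income_growth` per annum so that a
#' pipeline which uprates to 2015 reproduces the targets. Welfare rates
#' have no real growth and are used as given.
#'
#' @param n_records Number of survey person records (default 25,104).
#' @param n_donors Number of donor-pool records (default 40,000).
#' @param total_population Weighted population represented by the survey
#'   in the reference year (default 5,945,000).
#' @param group_shares Named vector of target population shares for the
#'   labour-force-by-arthritis cells; must sum to at most 1, the
#'   remainder is assigned to the `NILF_other` residual group.
#' @param median_targets Tibble with columns `group`, `income`,
#'   `welfare`, `tax`: target median weekly amounts (AU$, reference-year
#'   level) per analysis group.
#' @param income_dispersion Named vector of log-scale standard deviations
#'   of earnings (or other income for the non-employed) per group.
#' @param welfare_rules List of flat weekly payment rates and receipt
#'   probabilities (DSP-like pension, unemployment allowance, family
#'   benefit); welfare is rule-based, matching the degenerate welfare
#'   medians observed in this population.
#' @param tax_schedule Tibble with columns `threshold` (annual AU$) and
#'   `rate` (marginal rate above that threshold).
#' @param medicare_levy,levy_threshold Flat levy rate applied to annual
#'   taxable income above `levy_threshold`.
#' @param covariate_effects List with `education` and `age` named
#'   multipliers applied to earnings, and `mix`, a list of per-group
#'   education/age/sex distributions. Set `effects = FALSE` via
#'   [balanced_covariates()] for covariate-balanced simulation designs.
#' @param other_income List controlling the small non-labour,
#'   non-welfare income component (receipt probability and log-normal
#'   parameters per employment state).
#' @param quintile_breaks Weekly-income cut points defining the five
#'   income quintile bands used as a matching variable.
#' @param income_growth,base_year,reference_year Real growth rate and
#'   years used to deflate reference-year monetary targets to the base
#'   year of the economic data.
#' @param seed Integer RNG seed; every generator draw derives from it.
#' @return An object of class `plycost_config` (a named list).
#' @seealso [generate_survey()], [generate_donor_pool()],
#'   [generate_benchmarks()]
#' @export
generator_config <- function(n_records = 25104L,
                             n_donors = 40000L,
                             total_population = 5945000,
                             group_shares = c(
                               FT_no_arth = 0.4898, FT_arth = 0.0516,
                               PT_no_arth = 0.1736, PT_arth = 0.0313,
                               NILF_arth = 0.0091, unemployed = 0.0199,
                               NILF_ill_other = 0.0479
                             ),
                             median_targets = default_median_targets(),
                             income_dispersion = c(
                               FT_no_arth = 0.80, FT_arth = 0.70,
                               PT_no_arth = 0.85, PT_arth = 0.75,
                               NILF_arth = 1.00, unemployed = 1.00,
                               NILF_other = 1.00, NILF_ill_other = 1.00
                             ),
                             welfare_rules = default_welfare_rules(),
                             tax_schedule = default_tax_schedule(),
                             medicare_levy = 0.015,
                             levy_threshold = 20542,
                             covariate_effects = default_covariate_effects(),
                             other_income = default_other_income(),
                             quintile_breaks = c(330, 620, 1000, 1520),
                             income_growth = 0.01,
                             base_year = 2013L,
                             reference_year = 2015L,
                             seed = 20300101L) {
  cfg <- list(
    n_records = as.integer(n_records), n_donors = as.integer(n_donors),
    total_population = total_population, group_shares = group_shares,
    median_targets = median_targets, income_dispersion = income_dispersion,
    welfare_rules = welfare_rules, tax_schedule = tax_schedule,
    medicare_levy = medicare_levy, levy_threshold = levy_threshold,
    covariate_effects = covariate_effects, other_income = other_income,
    quintile_breaks = quintile_breaks, income_growth = income_growth,
    base_year = as.integer(base_year), reference_year = as.integer(reference_year),
    seed = as.integer(seed)
  )
  class(cfg) <- "plycost_config"
  validate_config(cfg)
  cfg
}

#' @export
print.plycost_config <- function(x, ...) {
  cat("<plycost_config>\n")
  cat("  survey records:", x$n_records, " donors:", x$n_donors, "\n")
  cat("  weighted population:", format(x$total_population, big.mark = ","),
      "at", x$reference_year, "\n")
  cat("  analysis-group shares:",
      paste(names(x$group_shares), sprintf("%.2f%%", 100 * x$group_shares),
            collapse = ", "), "\n")
  invisible(x)
}

default_median_targets <- function() {
  tibble::tribble(
    ~group,        ~income, ~welfare, ~tax,
    "FT_no_arth",  1308.88,     0.00, 243.18,
    "FT_arth",     1180.65,     0.00, 184.99,
    "PT_no_arth",   602.86,     0.00,  19.08,
    "PT_arth",      551.77,     0.00,   0.00,
    "NILF_arth",    321.87,   311.67,   0.00
  )
}

# 2013-style resident individual income tax brackets (annual AU$).
default_tax_schedule <- function() {
  tibble::tibble(
    threshold = c(0, 18200, 37000, 80000, 180000),
    rate = c(0, 0.19, 0.325, 0.37, 0.45)
  )
}

default_welfare_rules <- function() {
  list(
    dsp_rate = 311.67,        # disability pension, AU$/week
    newstart_rate = 255.25,   # unemployment allowance
    age_pension_rate = 355.40,
    ftb_rate = 170.00,        # family benefit top-up
    employed_ftb_prob = c(FT = 0.10, PT = 0.35),
    nilf_arth_probs = c(dsp = 0.85, dsp_ftb = 0.10, none = 0.05),
    nilf_ill_other_dsp_prob = 0.90,
    nilf_other_pension_prob = 0.55
  )
}

# Earnings multipliers by education and age band, and per-group covariate
# mixes. The lost-PLY group is older and less educated than full-time
# workers, so covariate adjustment closes part of the raw median income
# gap, as in the study population.
default_covariate_effects <- function() {
  list(
    education = c("none-post-school" = 0.60, "certificate/diploma" = 1.00,
                  "degree+" = 1.50),
    age = c("45-49" = 1.05, "50-54" = 1.00, "55-59" = 0.95, "60-64" = 0.78),
    mix = list(
      education = rbind(
        FT_no_arth    = c(0.25, 0.40, 0.35),
        FT_arth       = c(0.35, 0.40, 0.25),
        PT_no_arth    = c(0.25, 0.40, 0.35),
        PT_arth       = c(0.40, 0.40, 0.20),
        NILF_arth     = c(0.55, 0.35, 0.10),
        unemployed    = c(0.25, 0.40, 0.35),
        NILF_other    = c(0.45, 0.35, 0.20),
        NILF_ill_other = c(0.50, 0.35, 0.15)
      ),
      age = rbind(
        FT_no_arth    = c(0.30, 0.28, 0.23, 0.19),
        FT_arth       = c(0.20, 0.25, 0.28, 0.27),
        PT_no_arth    = c(0.30, 0.28, 0.23, 0.19),
        PT_arth       = c(0.18, 0.24, 0.28, 0.30),
        NILF_arth     = c(0.15, 0.20, 0.30, 0.35),
        unemployed    = c(0.30, 0.28, 0.23, 0.19),
        NILF_other    = c(0.10, 0.15, 0.30, 0.45),
        NILF_ill_other = c(0.14, 0.20, 0.30, 0.36)
      ),
      p_female = c(
        FT_no_arth = 0.42, FT_arth = 0.45, PT_no_arth = 0.68,
        PT_arth = 0.66, NILF_arth = 0.60, unemployed = 0.50,
        NILF_other = 0.62, NILF_ill_other = 0.55
      )
    )
  )
}

#' Covariate-balanced generator settings for simulation designs
#'
#' Returns a `covariate_effects` list with all earnings multipliers at 1
#' and identical covariate mixes in every group, so that labour-force
#' groups are exchangeable on age, sex and education. Used in
#' parameter-recovery simulations where the injected group gaps are the
#' estimand.
#'
#' @return A list suitable for the `covariate_effects` argument of
#'   [generator_config()].
#' @export
balanced_covariates <- function() {
  eff <- default_covariate_effects()
  eff$education[] <- 1
  eff$age[] <- 1
  for (g in rownames(eff$mix$education)) {
    eff$mix$education[g, ] <- c(1, 1, 1) / 3
    eff$mix$age[g, ] <- rep(0.25, 4)
    eff$mix$p_female[g] <- 0.5
  }
  eff
}

default_other_income <- function() {
  list(
    employed = list(prob = 0.40, meanlog = log(50), sdlog = 1.0),
    nonworking = list(prob = 0.55, meanlog = log(25), sdlog = 1.0)
  )
}

validate_config <- function(cfg) {
  if (cfg$n_records < 0) stop("n_records must be non-negative")
  shares <- cfg$group_shares
  unknown <- setdiff(names(shares), ALL_GROUPS)
  if (length(unknown)) stop("unknown group(s) in group_shares: ",
                            paste(unknown, collapse = ", "))
  if (any(shares < 0)) stop("group shares must be non-negative")
  if (sum(shares) > 1 + 1e-12)
    stop("configuration error: group shares sum to more than 1 (",
         signif(sum(shares), 6), ")")
  if (cfg$n_records > 0 && cfg$n_records < length(shares) + 1)
    stop("infeasible design: fewer records than labour-force groups")
  mt <- cfg$median_targets
  if (!all(c("group", "income", "welfare", "tax") %in% names(mt)))
    stop("median_targets must have columns group, income, welfare, tax")
  if (any(mt$income < 0) || any(mt$welfare < 0))
    stop("median targets must be non-negative")
  if (nrow(cfg$tax_schedule) == 0)
    stop("configuration error: empty tax schedule")
  invisible(cfg)
}

#' Published national reference projections used as reporting inputs
#'
#' The printed national projection table this package is calibrated to:
#' weighted 45-64 population, lost-PLY headcounts, missing workers,
#' national cost components (AU$ millions per year, real 2013 dollars),
#' projected and lost GDP, and counterfactual destination percentages,
#' for 2015/2020/2025/2030. These published values serve as inputs to the
#' reporting arithmetic (growth percentages, GDP ratios, population
#' shares) and as calibration anchors for the synthetic generator; the
#' package does not re-estimate them from the confidential source data.
#'
#' @return A tibble with one row per projection year.
#' @examples
#' ref <- plycost_reference()
#' percent_change(ref$ply_headcount[ref$year == 2015],
#'                ref$ply_headcount[ref$year == 2030])
#' @export
plycost_reference <- function() {
  path <- system.file("extdata", "reference_projections.csv",
                      package = "plycost", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}
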