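#' Real-growth uprating rule for monetary amounts
#'
#' Earnings, other income and taxes grow at a real rate per annum from
#' the 2013 base year of the economic data; welfare payments have no
#' real growth (they are indexed to prices only). All amounts remain
#' expressed in real 2013 Australian dollars.
#'
#' @param income_growth Real growth rate per annum for earnings and
#'   other income (default 0.01).
#' @param tax_growth Real growth rate per annum for tax (default 0.01).
#' @param welfare_growth Real growth rate per annum for welfare payments
#'   (default 0).
#' @param base_year Base year of the economic data (2013).
#' @return An object of class `plycost_uprating`.
#' @export
uprating_rule <- function(income_growth = 0.01, tax_growth = 0.01,
                          welfare_growth = 0, base_year = 2013L) {
  stopifnot(income_growth >= -1, tax_growth >= -1, welfare_growth >= -1)
  structure(list(income_growth = income_growth, tax_growth = tax_growth,
                 welfare_growth = welfare_growth,
                 base_year = as.integer(base_year)),
            class = "plycost_uprating")
}

#' Uprate weekly economic profiles to a projection year
#'
#' Multiplies earnings and other income by `(1 + income_growth)^t`, tax
#' by `(1 + tax_growth)^t` and welfare by `(1 + welfare_growth)^t`,
#' where `t` is the number of years since the base year, then recomputes
#' total income so the accounting identity `total = earnings + other +
#' welfare` holds exactly. Uprating is multiplicative and composable:
#' uprating 2013 to 2020 and then 2020 to 2030 equals uprating 2013 to
#' 2030.
#'
#' @param data Tibble carrying the five weekly economic columns.
#' @param rule An [uprating_rule()].
#' @param target_year Projection year, at or after the rule's base year.
#' @return The tibble with uprated economic columns.
#' @examples
#' df <- tibble::tibble(weekly_earnings = 100, weekly_other_income = 0,
#'                      weekly_welfare = 311.67, weekly_total_income = 411.67,
#'                      weekly_tax = 10)
#' uprate_profile(df, uprating_rule(), 2015)$weekly_earnings # 102.01
#' @export
uprate_profile <- function(data, rule = uprating_rule(), target_year) {
  stopifnot(inherits(rule, "plycost_uprating"))
  t <- as.integer(target_year) - rule$base_year
  if (t < 0) stop("target_year precedes the uprating base year")
  fi <- (1 + rule$income_growth)^t
  ft <- (1 + rule$tax_growth)^t
  fw <- (1 + rule$welfare_growth)^t
  dplyr::mutate(data,
    weekly_earnings = .data$weekly_earnings * fi,
    weekly_other_income = .data$weekly_other_income * fi,
    weekly_welfare = .data$weekly_welfare * fw,
    weekly_tax = .data$weekly_tax * ft,
    weekly_total_income = .data$weekly_earnings + .data$weekly_other_income +
      .data$weekly_welfare
  )
}
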