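# The ten matching variables, in their fixed documented order. Equality
# on all ten defines cell identity for exact-cell (hot-deck) matching.
MATCH_VARS <- c("labour_force_status", "income_unit_type", "income_quintile",
                "receives_age_pension", "receives_dsp", "sex", "age_group",
                "hours_band", "education", "home_ownership")

#' Build exact-match keys over the ten matching variables
#'
#' Projects person or donor records onto the ordered tuple of the ten
#' matching variables (labour force status, income unit type, income
#' quintile, Age Pension receipt, DSP receipt, sex, age group, hours
#' band, education, home ownership) and serialises it as a single key
#' string. Records with equal keys belong to the same matching cell.
#' `hours_band` is structurally missing for the non-employed and encoded
#' as a distinct level, so non-employed persons only match non-employed
#' donors; every other field must be non-missing.
#'
#' @param data A tibble containing the ten matching variables.
#' @param vars Variables to include (defaults to all ten; fallback
#'   matching passes subsets).
#' @return A character vector of keys, one per row.
#' @examples
#' cfg <- generator_config(n_records = 50, n_donors = 50)
#' sv <- generate_survey(cfg)
#' head(build_match_key(sv))
#' @export
build_match_key <- function(data, vars = MATCH_VARS) {
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars))
    stop("matching variable(s) absent from data: ",
         paste(missing_vars, collapse = ", "))
  cols <- lapply(vars, function(v) {
    x <- data[[v]]
    if (v == "hours_band") {
      x <- ifelse(is.na(x), "<none>", x)
    } else if (anyNA(x)) {
      stop("missing values in matching variable: ", v)
    }
    as.character(x)
  })
  do.call(paste, c(cols, sep = "|"))
}

#' Fallback ladder for empty matching cells
#'
#' When a recipient's full ten-variable cell contains no donor, matching
#' variables are dropped one at a time in the configured order until a
#' donor is found. Labour force status is the analysis's stratifier and
#' is never dropped, so the default ladder ends at a status-only match,
#' which succeeds whenever every labour-force stratum holds at least one
#' donor. The default order drops the least outcome-predictive variables
#' first: home ownership, income unit type, Age Pension receipt, hours
#' band, education, then DSP receipt, income quintile, sex and age
#' group.
#'
#' @param drop_order Character vector of matching variables to drop, in
#'   order.
#' @return An object of class `plycost_fallback`.
#' @export
fallback_policy <- function(drop_order = c("home_ownership",
                                           "income_unit_type",
                                           "receives_age_pension",
                                           "hours_band", "education",
                                           "receives_dsp",
                                           "income_quintile",
                                           "sex", "age_group")) {
  if ("labour_force_status" %in% drop_order)
    stop("fallback policy must never drop labour_force_status")
  unknown <- setdiff(drop_order, MATCH_VARS)
  if (length(unknown))
    stop("unknown matching variable(s) in fallback policy: ",
         paste(unknown, collapse = ", "))
  structure(list(drop_order = drop_order), class = "plycost_fallback")
}

#' Impute economic profiles by exact-cell donor matching
#'
#' Attaches a weekly economic profile (earnings, other income, welfare,
#' total income, tax) to every recipient by hot-deck matching against
#' the donor pool on the ten matching variables. Within a cell holding
#' several donors one is drawn uniformly at random (seeded); if a
#' recipient's cell is empty, the fallback ladder drops matching
#' variables one at a time until a donor is found, and the depth used is
#' recorded per recipient for audit.
#'
#' Imputation is a pure function of (recipients, donors, policy, seed):
#' re-running it reproduces the same donor assignment.
#'
#' @param recipients Person tibble (e.g. from [generate_survey()]).
#' @param donors Donor tibble (e.g. from [generate_donor_pool()]).
#' @param policy A [fallback_policy()].
#' @param seed Integer seed for donor tie-breaking.
#' @return The recipients tibble with the five economic columns plus
#'   `donor_id` and `fallback_depth` appended.
#' @export
impute_economics <- function(recipients, donors, policy = fallback_policy(),
                             seed = 1L) {
  if (nrow(donors) == 0) stop("donor pool is empty")
  stopifnot(inherits(policy, "plycost_fallback"))
  n <- nrow(recipients)
  econ_cols <- c("weekly_earnings", "weekly_other_income", "weekly_welfare",
                 "weekly_total_income", "weekly_tax")

  var_sets <- purrr::accumulate(policy$drop_order, setdiff,
                                .init = MATCH_VARS)
  depth_max <- length(var_sets) - 1L

  assigned <- rep(NA_integer_, n)
  depth <- rep(NA_integer_, n)
  set.seed(seed)
  u <- stats::runif(n) # one tie-break draw per recipient, fixed up front

  for (d in seq_along(var_sets)) {
    todo <- which(is.na(assigned))
    if (!length(todo)) break
    vars <- var_sets[[d]]
    rkey <- build_match_key(recipients[todo, , drop = FALSE], vars)
    dkey <- build_match_key(donors, vars)
    cells <- split(seq_len(nrow(donors)), dkey)
    hit <- rkey %in% names(cells)
    if (any(hit)) {
      rows <- todo[hit]
      pool <- cells[rkey[hit]]
      pick <- purrr::map2_int(pool, u[rows],
                              function(ids, uu) ids[ceiling(uu * length(ids))])
      assigned[rows] <- pick
      depth[rows] <- d - 1L
    }
  }
  if (anyNA(assigned)) {
    bad <- which(is.na(assigned))[1]
    stop("unmatched recipient after exhausting fallback ladder; key: ",
         build_match_key(recipients[bad, , drop = FALSE],
                         var_sets[[length(var_sets)]]))
  }

  out <- recipients
  for (col in econ_cols) out[[col]] <- donors[[col]][assigned]
  out$donor_id <- if ("donor_id" %in% names(donors)) {
    donors$donor_id[assigned]
  } else {
    as.character(assigned)
  }
  out$fallback_depth <- depth
  out
}
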