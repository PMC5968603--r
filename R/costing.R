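#' Weighted group summaries of weekly income, welfare and tax
#'
#' Produces the per-group summary table of the analysis: weighted
#' headcount (with a copy rounded to the nearest 1,000 as printed in
#' national tables), weighted share of the total population, and
#' weighted mean, standard deviation and lower weighted median of each
#' weekly economic outcome, for the labour-force-by-arthritis analysis
#' groups.
#'
#' @param data Person tibble with `lf_group` (see [classify_groups()]),
#'   a weight column and the weekly economic columns.
#' @param year Optional projection year label carried into the output.
#' @param groups Groups to report (default: the five analysis groups;
#'   the share denominator is always the whole table).
#' @param weight_col Name of the weight column.
#' @return A tibble with one row per group and outcome.
#' @export
summarize_groups <- function(data, year = NULL, groups = ANALYSIS_GROUPS,
                             weight_col = "survey_weight") {
  w_all <- data[[weight_col]]
  total <- sum(w_all)
  outcomes <- c(income = "weekly_total_income", welfare = "weekly_welfare",
                tax = "weekly_tax")
  rows <- purrr::map_dfr(groups, function(g) {
    sel <- data$lf_group == g
    if (!any(sel)) {
      warning("empty group in summary: ", g)
      return(tibble::tibble(
        group = g, n_records = 0L, weighted_count = 0,
        weighted_count_rounded = 0, share_pct = 0,
        outcome = names(outcomes), mean = NA_real_, sd = NA_real_,
        median = NA_real_
      ))
    }
    w <- w_all[sel]
    purrr::map_dfr(names(outcomes), function(oc) {
      x <- data[[outcomes[[oc]]]][sel]
      tibble::tibble(
        group = g, n_records = sum(sel), weighted_count = sum(w),
        weighted_count_rounded = round_1000(sum(w)),
        share_pct = share_pct(sum(w), total), outcome = oc,
        mean = weighted_mean(x, w), sd = weighted_sd(x, w),
        median = weighted_median(x, w)
      )
    })
  })
  if (!is.null(year)) rows <- dplyr::mutate(rows, year = as.integer(year), .before = 1)
  rows
}

# Weighted median (tau = 0.5) regression of an outcome on analysis-group
# indicators plus covariates, restricted to the five analysis groups
# with full-time-no-arthritis as the reference level. Errors on a
# rank-deficient design, naming the collinear term.
qr_group_fit <- function(data, outcome, covariates = c("age_group", "sex",
                                                       "education"),
                         weight_col = "survey_weight") {
  df <- dplyr::filter(data, .data$lf_group %in% ANALYSIS_GROUPS)
  if (!any(df$lf_group == "FT_no_arth"))
    stop("reference group (full-time, no arthritis) is empty")
  present <- intersect(ANALYSIS_GROUPS, unique(as.character(df$lf_group)))
  df$lf_group <- factor(as.character(df$lf_group), levels = present)
  rhs <- paste(c("lf_group", covariates), collapse = " + ")
  fml <- stats::as.formula(paste(outcome, "~", rhs))
  X <- stats::model.matrix(fml, df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("degenerate design; collinear term(s): ", paste(bad, collapse = ", "))
  }
  method <- if (nrow(df) <= 5000) "br" else "fn"
  # medians of rule-based outcomes (flat welfare rates) are legitimately
  # non-unique; keep that solver note out of the way
  withCallingHandlers(
    quantreg::rq(fml, tau = 0.5, data = df,
                 weights = df[[weight_col]], method = method),
    warning = function(w) {
      if (grepl("nonunique", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }
  )
}

#' Covariate-adjusted median differences against full-time workers
#' without arthritis
#'
#' Fits a weighted median (quantile, tau = 0.5) regression of a weekly
#' economic outcome on the labour-force-by-arthritis group indicators
#' plus covariates (age group, sex and education by default). Each group
#' coefficient is the adjusted difference in median outcome between that
#' group and the full-time-without-arthritis reference; 95% confidence
#' intervals come from a seeded case-resampling percentile bootstrap.
#' Without covariates the design is saturated in the group indicators
#' and each coefficient equals the difference of within-group weighted
#' medians.
#'
#' The reference group row is reported with an estimate of exactly 0.
#' Percentile bootstrap intervals of a median can be asymmetric and need
#' not cover the point estimate.
#'
#' @inheritParams summarize_groups
#' @param outcome Economic outcome column, e.g. `"weekly_total_income"`.
#' @param covariates Adjustment covariates; `NULL` for the saturated
#'   groups-only design.
#' @param reps Bootstrap replications (study convention: 1000).
#' @param seed Integer seed for the bootstrap.
#' @return An object of class `plycost_adjdiff`; its [tidy()] method
#'   (also the stored `$estimates` tibble) has one row per group with
#'   `estimate`, `conf_low`, `conf_high` and `significant`.
#' @export
adjusted_median_difference <- function(data, outcome,
                                       covariates = c("age_group", "sex",
                                                      "education"),
                                       year = NULL, reps = 1000L, seed = 1L,
                                       weight_col = "survey_weight") {
  fit <- qr_group_fit(data, outcome, covariates, weight_col)
  coefs <- stats::coef(fit)

  # case-resampling bootstrap on a prebuilt design matrix: one rq.wfit
  # per resample, avoiding the formula interface in the hot loop
  df <- dplyr::filter(data, .data$lf_group %in% ANALYSIS_GROUPS)
  present <- intersect(ANALYSIS_GROUPS, unique(as.character(df$lf_group)))
  terms <- paste0("lf_group", setdiff(present, "FT_no_arth"))
  df$lf_group <- factor(as.character(df$lf_group), levels = present)
  rhs <- paste(c("lf_group", covariates), collapse = " + ")
  fml <- stats::as.formula(paste(outcome, "~", rhs))
  X <- stats::model.matrix(fml, df)
  y <- df[[outcome]]
  w <- df[[weight_col]]
  method <- if (nrow(df) <= 5000) "br" else "fn"
  n <- nrow(df)
  set.seed(seed)
  draws <- matrix(NA_real_, reps, length(terms))
  for (r in seq_len(reps)) {
    idx <- sample.int(n, n, replace = TRUE)
    b <- tryCatch(
      quantreg::rq.wfit(X[idx, , drop = FALSE], y[idx], tau = 0.5,
                        weights = w[idx], method = method)$coefficients,
      error = function(e) NULL
    )
    if (!is.null(b)) draws[r, ] <- b[terms]
  }
  ci <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975),
              na.rm = TRUE, names = FALSE)
  est <- tibble::tibble(
    outcome = outcome,
    group = c("FT_no_arth", sub("^lf_group", "", terms)),
    estimate = c(0, unname(coefs[terms])),
    conf_low = c(0, ci[1, ]),
    conf_high = c(0, ci[2, ])
  )
  est$significant <- est$conf_low > 0 | est$conf_high < 0
  est$significant[est$group == "FT_no_arth"] <- FALSE
  if (!is.null(year)) est <- dplyr::mutate(est, year = as.integer(year), .before = 1)
  structure(list(estimates = est, fit = fit, outcome = outcome,
                 covariates = covariates, reps = reps, seed = seed),
            class = "plycost_adjdiff")
}

#' @export
print.plycost_adjdiff <- function(x, ...) {
  cat("<plycost_adjdiff> adjusted median differences for", x$outcome, "\n")
  print(x$estimates)
  invisible(x)
}

#' Tidy adjusted median differences
#'
#' @param x A [adjusted_median_difference()] result.
#' @param ... Unused.
#' @return `tidy()`: the per-group estimate table. `glance()`: a one-row
#'   model summary.
#' @export
tidy.plycost_adjdiff <- function(x, ...) x$estimates

#' @rdname tidy.plycost_adjdiff
#' @export
glance.plycost_adjdiff <- function(x, ...) {
  tibble::tibble(outcome = x$outcome,
                 covariates = paste(x$covariates, collapse = "+"),
                 n = length(x$fit$residuals), reps = x$reps)
}

#' Counterfactual labour-force destination probabilities
#'
#' Estimates the probabilities that a person with lost PLYs due to
#' arthritis would be in full-time work, part-time work or unemployment
#' absent their condition: the weighted destination distribution of
#' labour-force participants without arthritis, standardised to the
#' age-by-sex profile of the lost-PLY group. The unemployment
#' probability is taken as the complement so the three probabilities sum
#' to one exactly. If a lost-PLY age-sex stratum holds no non-arthritis
#' participants, the unstandardised distribution is used with a warning.
#'
#' @inheritParams summarize_groups
#' @return A one-row tibble with `p_ft`, `p_pt`, `p_unemp` (and `year`
#'   if given).
#' @export
estimate_counterfactual_probs <- function(data, year = NULL,
                                          weight_col = "survey_weight") {
  dest_levels <- c("FT", "PT", "unemployed")
  pool <- dplyr::filter(data, !.data$arthritis,
                        .data$labour_force_status %in% dest_levels)
  if (nrow(pool) == 0) stop("no non-arthritis labour-force participants")
  lost <- dplyr::filter(data, .data$lost_ply)

  dest_dist <- function(d) {
    w <- d[[weight_col]]
    p_ft <- sum(w[d$labour_force_status == "FT"]) / sum(w)
    p_pt <- sum(w[d$labour_force_status == "PT"]) / sum(w)
    c(p_ft = p_ft, p_pt = p_pt)
  }

  if (nrow(lost) == 0) {
    p <- dest_dist(pool)
  } else {
    strata <- dplyr::count(lost, .data$age_group, .data$sex,
                           wt = .data[[weight_col]], name = "w_lost")
    cond <- dplyr::group_by(pool, .data$age_group, .data$sex) |>
      dplyr::group_modify(~ tibble::as_tibble(as.list(dest_dist(.x)))) |>
      dplyr::ungroup()
    joined <- dplyr::left_join(strata, cond, by = c("age_group", "sex"))
    if (anyNA(joined$p_ft)) {
      warning("empty non-arthritis stratum; using unstandardised ",
              "destination distribution")
      p <- dest_dist(pool)
    } else {
      share <- joined$w_lost / sum(joined$w_lost)
      p <- c(p_ft = sum(share * joined$p_ft),
             p_pt = sum(share * joined$p_pt))
    }
  }
  out <- tibble::tibble(p_ft = p[["p_ft"]], p_pt = p[["p_pt"]],
                        p_unemp = 1 - p[["p_ft"]] - p[["p_pt"]])
  if (!is.null(year)) out <- dplyr::mutate(out, year = as.integer(year), .before = 1)
  out
}

#' National annual costs of lost PLYs due to arthritis
#'
#' Aggregates the individual-level gaps between observed and
#' counterfactual economic outcomes of people with lost PLYs into
#' national annual figures (AU$ millions per year, real 2013 dollars).
#' For each lost-PLY person the counterfactual weekly income, welfare
#' and tax in the full-time and part-time destinations are predicted
#' from the covariate-adjusted median-regression fits (so
#' counterfactuals are adjusted for age, sex and education); the
#' unemployment destination contributes no earnings gap and a welfare
#' level equal to the unemployment-allowance rule. Components are
#' weighted by the person's calibrated weight, mixed over the
#' destination probabilities, annualised at 52 weeks and reported with
#' seeded case-resampling percentile bootstrap confidence intervals (the
#' regression counterfactuals are refit in every resample; the
#' destination probabilities are a fixed input).
#'
#' @inheritParams adjusted_median_difference
#' @param probs A one-row tibble from [estimate_counterfactual_probs()].
#' @param unemp_welfare Weekly welfare rate of the counterfactual
#'   unemployment destination (AU$/week).
#' @return An object of class `plycost_national`; [tidy()] gives one row
#'   per component (`lost_income`, `extra_welfare`, `lost_tax`) with the
#'   point estimate and 95% CI in AU$ millions per year.
#' @export
national_costs <- function(data, probs, year = NULL,
                           covariates = c("age_group", "sex", "education"),
                           reps = 1000L, seed = 1L,
                           unemp_welfare = 255.25,
                           weight_col = "survey_weight") {
  stopifnot(all(c("p_ft", "p_pt", "p_unemp") %in% names(probs)))
  p_ft <- probs$p_ft[1]; p_pt <- probs$p_pt[1]; p_unemp <- probs$p_unemp[1]

  point <- function(d) {
    lost <- dplyr::filter(d, .data$lost_ply)
    if (nrow(lost) == 0) {
      return(c(lost_income = 0, extra_welfare = 0, lost_tax = 0))
    }
    fit_i <- qr_group_fit(d, "weekly_total_income", covariates, weight_col)
    fit_w <- qr_group_fit(d, "weekly_welfare", covariates, weight_col)
    fit_t <- qr_group_fit(d, "weekly_tax", covariates, weight_col)
    # counterfactual prediction for a destination group; a destination
    # with zero probability contributes nothing and needs no stratum
    cf <- function(fit, level, p) {
      if (p == 0) return(rep(0, nrow(lost)))
      levs <- fit$xlevels$lf_group
      if (!level %in% levs)
        stop("missing counterfactual prediction stratum: ", level)
      nd <- dplyr::mutate(lost, lf_group = factor(level, levels = levs))
      stats::predict(fit, newdata = nd)
    }
    c_ft_i <- cf(fit_i, "FT_no_arth", p_ft)
    c_pt_i <- cf(fit_i, "PT_no_arth", p_pt)
    c_ft_w <- cf(fit_w, "FT_no_arth", p_ft)
    c_pt_w <- cf(fit_w, "PT_no_arth", p_pt)
    c_ft_t <- cf(fit_t, "FT_no_arth", p_ft)
    c_pt_t <- cf(fit_t, "PT_no_arth", p_pt)
    w <- lost[[weight_col]]
    gap_i <- p_ft * (c_ft_i - lost$weekly_total_income) +
      p_pt * (c_pt_i - lost$weekly_total_income)
    gap_w <- p_ft * (lost$weekly_welfare - c_ft_w) +
      p_pt * (lost$weekly_welfare - c_pt_w) +
      p_unemp * (lost$weekly_welfare - unemp_welfare)
    gap_t <- p_ft * (c_ft_t - lost$weekly_tax) +
      p_pt * (c_pt_t - lost$weekly_tax) +
      p_unemp * (0 - lost$weekly_tax)
    c(lost_income = sum(w * gap_i) * 52 / 1e6,
      extra_welfare = sum(w * gap_w) * 52 / 1e6,
      lost_tax = sum(w * gap_t) * 52 / 1e6)
  }

  est <- point(data)
  boot <- bootstrap_cis(data, point, reps = reps, seed = seed)
  out <- tibble::tibble(
    component = names(est), estimate = unname(est),
    conf_low = boot$conf_low[match(names(est), boot$term)],
    conf_high = boot$conf_high[match(names(est), boot$term)]
  )
  if (!is.null(year)) out <- dplyr::mutate(out, year = as.integer(year), .before = 1)
  structure(list(costs = out, probs = probs, year = year, reps = reps,
                 seed = seed), class = "plycost_national")
}

#' @export
print.plycost_national <- function(x, ...) {
  cat("<plycost_national> annual national costs (AU$ millions, real 2013)\n")
  print(x$costs)
  invisible(x)
}

#' Tidy national cost estimates
#'
#' @param x A [national_costs()] result.
#' @param ... Unused.
#' @return The per-component cost tibble.
#' @export
tidy.plycost_national <- function(x, ...) x$costs

#' Percentile bootstrap confidence intervals by case resampling
#'
#' Resamples survey records with replacement (each record carries its
#' weight), recomputes the statistic on every resample, and reports the
#' percentile interval. Deterministic given the seed.
#'
#' @param data Tibble of records; the resampling unit is the row.
#' @param statistic Function of a resampled tibble returning a (possibly
#'   named) numeric vector; must succeed on every resample.
#' @param reps Number of bootstrap replications (>= 1).
#' @param seed Integer RNG seed.
#' @param conf Confidence level (default 0.95).
#' @return A tibble with one row per statistic component: `term`,
#'   `estimate` (on the full data), `conf_low`, `conf_high`.
#' @examples
#' d <- tibble::tibble(x = rnorm(50))
#' bootstrap_cis(d, function(df) c(mean = mean(df$x)), reps = 200, seed = 1)
#' @export
bootstrap_cis <- function(data, statistic, reps = 1000L, seed = 1L,
                          conf = 0.95) {
  if (reps < 1) stop("reps must be at least 1")
  n <- nrow(data)
  est <- statistic(data)
  nm <- names(est)
  if (is.null(nm)) nm <- paste0("stat", seq_along(est))
  set.seed(seed)
  idx <- matrix(sample.int(n, n * reps, replace = TRUE), nrow = n)
  draws <- matrix(NA_real_, reps, length(est))
  for (r in seq_len(reps)) {
    draws[r, ] <- statistic(data[idx[, r], , drop = FALSE])
  }
  alpha <- (1 - conf) / 2
  tibble::tibble(
    term = nm, estimate = unname(est),
    conf_low = apply(draws, 2, stats::quantile, probs = alpha, names = FALSE),
    conf_high = apply(draws, 2, stats::quantile, probs = 1 - alpha,
                      names = FALSE)
  )
}
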