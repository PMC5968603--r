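#' Configuration of a full pipeline run
#'
#' Bundles every stage's settings: the synthetic-data generator, the
#' projection years, the uprating rule, calibration settings, bootstrap
#' replications and one master seed from which all stage seeds (survey,
#' donors, matching, bootstraps) are derived, so stages can be re-run in
#' isolation reproducibly.
#'
#' @param years Projection years (non-empty subset of
#'   2015/2020/2025/2030 under the default benchmark paths).
#' @param generator A [generator_config()]; its seed is overridden by
#'   the master seed.
#' @param uprating An [uprating_rule()].
#' @param policy A [fallback_policy()].
#' @param bounds,tol Calibration weight bounds and tolerance.
#' @param reps Bootstrap replications for adjusted differences and
#'   national costs (study convention: 1000).
#' @param gdp_per_fte,pt_fte_factor GDP attribution settings;
#'   `gdp_per_fte` is stated at the uprating rule's base year (2013) and
#'   grows at the rule's income growth rate, mirroring real earnings
#'   growth.
#' @param seed Master seed.
#' @return An object of class `plycost_run_config`.
#' @export
run_config <- function(years = c(2015L, 2020L, 2025L, 2030L),
                       generator = generator_config(),
                       uprating = uprating_rule(),
                       policy = fallback_policy(),
                       bounds = c(0.1, 10), tol = 1e-6,
                       reps = 1000L,
                       gdp_per_fte = 136100, pt_fte_factor = 0.5,
                       seed = 20300101L) {
  if (length(years) == 0) stop("years must be non-empty")
  structure(list(years = as.integer(years), generator = generator,
                 uprating = uprating, policy = policy, bounds = bounds,
                 tol = tol, reps = as.integer(reps),
                 gdp_per_fte = gdp_per_fte, pt_fte_factor = pt_fte_factor,
                 seed = as.integer(seed)),
            class = "plycost_run_config")
}

#' Read a pipeline run configuration from a YAML file
#'
#' Recognised top-level fields: `seed`, `years`, `reps`, `n_records`,
#' `n_donors`, `bounds`, `tol`, `gdp_per_fte`, `pt_fte_factor`;
#' unspecified fields keep their [run_config()] defaults.
#'
#' @param path Path to a YAML file.
#' @return A `plycost_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  gen_args <- y[intersect(names(y), c("n_records", "n_donors"))]
  args <- y[intersect(names(y), c("seed", "years", "reps", "bounds", "tol",
                                  "gdp_per_fte", "pt_fte_factor"))]
  args$generator <- do.call(generator_config, gen_args)
  do.call(run_config, args)
}

#' Run the full microsimulation pipeline
#'
#' Executes every stage in order: generate the synthetic survey and
#' donor pool, impute economic profiles by donor matching, build
#' projection benchmarks, then per projection year calibrate the two
#' survey years separately to half the year's benchmark totals and pool
#' them, uprate monetary amounts, and compute the group summary table,
#' the covariate-adjusted median differences, the counterfactual
#' destination probabilities, the national annual costs and the GDP
#' impact, together with headline growth metrics. Deterministic for a
#' fixed configuration.
#'
#' @param config A [run_config()].
#' @return An object of class `plycost_results`: a list of tibbles
#'   (`summaries`, `differences`, `probs`, `national`, `gdp`,
#'   `metrics`, `calibration`) plus the imputed person table and the
#'   configuration.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "plycost_run_config"))
  gen <- config$generator
  gen$seed <- derive_seed(config$seed, "generator")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  survey <- stage("generate", classify_groups(generate_survey(gen)))
  donors <- stage("generate", generate_donor_pool(gen))
  imputed <- stage("impute", impute_economics(
    survey, donors, config$policy, seed = derive_seed(config$seed, "matching")
  ))
  imputed$design_weight <- imputed$survey_weight
  benchmarks <- stage("benchmarks", generate_benchmarks(gen, config$years))

  summaries <- list(); differences <- list(); probs_l <- list()
  national <- list(); cal_diag <- list()
  for (yr in config$years) {
    cons_y <- dplyr::filter(tibble::as_tibble(benchmarks), .data$year == yr)
    w <- imputed$design_weight
    for (sy in c(2003L, 2009L)) {
      sel <- imputed$survey_year == sy
      half <- dplyr::mutate(cons_y, target = .data$target / 2)
      cal <- stage("calibrate", calibrate_weights(
        imputed[sel, ], half, weight_col = "design_weight",
        bounds = config$bounds, tol = config$tol
      ))
      w[sel] <- cal$weights
      cal_diag[[paste(yr, sy)]] <- dplyr::mutate(glance(cal),
                                                 year = yr, survey_year = sy,
                                                 .before = 1)
    }
    data_y <- imputed
    data_y$survey_weight <- w
    data_y <- stage("uprate", uprate_profile(data_y, config$uprating, yr))

    summaries[[as.character(yr)]] <- stage("summarize",
      summarize_groups(data_y, year = yr))
    differences[[as.character(yr)]] <- purrr::map_dfr(
      c("weekly_total_income", "weekly_welfare", "weekly_tax"),
      function(oc) {
        stage("adjust", tidy(adjusted_median_difference(
          data_y, oc, year = yr, reps = config$reps,
          seed = derive_seed(config$seed, paste0("adjdiff-", yr, "-", oc))
        )))
      })
    probs_y <- stage("probs", estimate_counterfactual_probs(data_y, year = yr))
    probs_l[[as.character(yr)]] <- probs_y
    national[[as.character(yr)]] <- stage("national", tidy(national_costs(
      data_y, probs_y, year = yr, reps = config$reps,
      seed = derive_seed(config$seed, paste0("national-", yr)),
      unemp_welfare = gen$welfare_rules$newstart_rate
    )))
  }
  summaries <- dplyr::bind_rows(summaries)
  differences <- dplyr::bind_rows(differences)
  probs <- dplyr::bind_rows(probs_l)
  national <- dplyr::bind_rows(national)
  calibration <- dplyr::bind_rows(cal_diag)

  headcounts <- summaries |>
    dplyr::filter(.data$group == "NILF_arth", .data$outcome == "income") |>
    dplyr::select("year", "weighted_count", "weighted_count_rounded",
                  "share_pct")
  ref <- plycost_reference()
  gdp_in <- dplyr::inner_join(
    dplyr::select(ref, "year", projected_gdp = "projected_gdp_m",
                  "missing_workers"),
    probs, by = "year"
  ) |>
    dplyr::filter(.data$year %in% config$years) |>
    dplyr::mutate(
      missing_ft = .data$missing_workers * .data$p_ft /
        (.data$p_ft + .data$p_pt),
      missing_pt = .data$missing_workers * .data$p_pt /
        (.data$p_ft + .data$p_pt)
    )
  # GDP per FTE grows with real earnings from the base year
  gdp <- stage("gdp", purrr::map_dfr(seq_len(nrow(gdp_in)), function(i) {
    fte_value <- config$gdp_per_fte *
      (1 + config$uprating$income_growth)^(gdp_in$year[i] -
                                             config$uprating$base_year)
    gdp_impact(gdp_in[i, ], gdp_per_fte = fte_value,
               pt_fte_factor = config$pt_fte_factor)
  }))

  metrics <- pipeline_metrics(headcounts, national, gdp)

  structure(list(
    config = config, persons = imputed, benchmarks = benchmarks,
    summaries = summaries, differences = differences, probs = probs,
    national = national, gdp = gdp, headcounts = headcounts,
    metrics = metrics, calibration = calibration
  ), class = "plycost_results")
}

# Headline growth metrics computed from the run's own first and last
# projection years.
pipeline_metrics <- function(headcounts, national, gdp) {
  y0 <- min(headcounts$year); y1 <- max(headcounts$year)
  m <- list(first_year = y0, last_year = y1)
  hc <- function(y) headcounts$weighted_count_rounded[headcounts$year == y]
  nc <- function(comp, y) {
    national$estimate[national$component == comp & national$year == y]
  }
  m$ply_headcount_first <- hc(y0)
  m$ply_headcount_last <- hc(y1)
  if (y1 > y0) {
    m$ply_headcount_pct_change <- percent_change(hc(y0), hc(y1))
    for (comp in unique(national$component)) {
      m[[paste0(comp, "_pct_change")]] <- percent_change(nc(comp, y0),
                                                         nc(comp, y1))
    }
    m$lost_gdp_pct_change <- percent_change(
      gdp$lost_gdp[gdp$year == y0], gdp$lost_gdp[gdp$year == y1]
    )
  }
  m
}

#' @export
print.plycost_results <- function(x, ...) {
  cat("<plycost_results> years:", paste(x$config$years, collapse = ", "), "\n")
  cat("  lost-PLY headcounts (rounded):",
      paste(x$headcounts$weighted_count_rounded, collapse = ", "), "\n")
  cat("  national lost income (AU$m):",
      paste(round(x$national$estimate[x$national$component == "lost_income"]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Render a results table in its published shape
#'
#' @param results A [run_pipeline()] result.
#' @param table_id 1 (group summaries), 2 (adjusted median differences),
#'   3 (national costs) or 4 (GDP impact).
#' @return A tibble with currency to 2 decimals and counts to the
#'   nearest 1,000. Column headers carry the real-2013-AU$ unit.
#' @export
render_table <- function(results, table_id) {
  stopifnot(inherits(results, "plycost_results"))
  if (!table_id %in% 1:4) stop("table_id must be 1, 2, 3 or 4")
  empty_err <- function(df, stage) {
    if (is.null(df) || nrow(df) == 0)
      stop("results contain no output from stage: ", stage)
    df
  }
  money <- function(x) round_half_away(x, 2)
  if (table_id == 1) {
    empty_err(results$summaries, "summarize") |>
      dplyr::transmute(
        .data$year, .data$group, .data$outcome,
        weighted_population = .data$weighted_count_rounded,
        share_pct = .data$share_pct,
        mean_2013aud_wk = money(.data$mean),
        sd_2013aud_wk = money(.data$sd),
        median_2013aud_wk = money(.data$median)
      )
  } else if (table_id == 2) {
    empty_err(results$differences, "adjust") |>
      dplyr::transmute(
        .data$year, .data$outcome, .data$group,
        difference_2013aud_wk = money(.data$estimate),
        conf_low = money(.data$conf_low), conf_high = money(.data$conf_high),
        .data$significant
      )
  } else if (table_id == 3) {
    empty_err(results$national, "national") |>
      dplyr::transmute(
        .data$year, .data$component,
        impact_2013aud_m = money(.data$estimate),
        conf_low = money(.data$conf_low), conf_high = money(.data$conf_high)
      )
  } else {
    empty_err(results$gdp, "gdp") |>
      dplyr::transmute(
        .data$year,
        projected_gdp_2013aud_m = money(.data$projected_gdp),
        lost_gdp_2013aud_m = money(.data$lost_gdp),
        pct_gain = .data$pct_gain
      )
  }
}

#' Write a results bundle to disk
#'
#' Writes tables 1-4 as CSV, the headline metrics as JSON, and a run log
#' (seeds and calibration diagnostics) to a directory.
#'
#' @param results A [run_pipeline()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in 1:4) {
    readr::write_csv(render_table(results, i),
                     file.path(dir, paste0("table", i, ".csv")))
  }
  jsonlite::write_json(results$metrics, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  log <- c(
    paste("master seed:", results$config$seed),
    paste("generator seed:", derive_seed(results$config$seed, "generator")),
    paste("matching seed:", derive_seed(results$config$seed, "matching")),
    utils::capture.output(as.data.frame(results$calibration))
  )
  writeLines(log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
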