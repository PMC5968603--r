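#' GDP loss attributable to missing workers
#'
#' Converts missing full-time and part-time workers into lost GDP using
#' an average-product formula: each full-time worker contributes one
#' full-time-equivalent (FTE) worker-year, each part-time worker a
#' configurable fraction of one, and the loss is GDP per FTE times the
#' missing FTEs. Absolute published GDP losses are treated as externally
#' given projections; this formula documents the attribution used for
#' scenario arithmetic.
#'
#' @param missing_ft,missing_pt Counts of missing full-time and
#'   part-time workers (non-negative).
#' @param gdp_per_fte GDP per full-time-equivalent worker-year (AU$).
#' @param pt_fte_factor FTE fraction of a part-time worker, in (0, 1].
#' @return Lost GDP in AU$ millions.
#' @examples
#' compute_gdp_loss(39000, 14000, 128000, 0.5) # 5888
#' @export
compute_gdp_loss <- function(missing_ft, missing_pt, gdp_per_fte,
                             pt_fte_factor = 0.5) {
  if (any(c(missing_ft, missing_pt, gdp_per_fte) < 0))
    stop("inputs must be non-negative")
  if (any(pt_fte_factor <= 0 | pt_fte_factor > 1))
    stop("pt_fte_factor must be in (0, 1]")
  gdp_per_fte * (missing_ft + pt_fte_factor * missing_pt) / 1e6
}

#' Potential percentage gain in GDP
#'
#' The potential percent gain in total GDP if missing workers were kept
#' in the labour force: lost GDP over projected GDP, in percent, rounded
#' half away from zero to two decimals (the printed convention).
#'
#' @param lost_gdp Lost GDP (AU$ millions, >= 0).
#' @param projected_gdp Projected total GDP (AU$ millions, > 0).
#' @return Percent gain to 2 decimals.
#' @examples
#' pct_gain(6208, 1483861) # 0.42
#' pct_gain(8191, 2149073) # 0.38
#' @export
pct_gain <- function(lost_gdp, projected_gdp) {
  if (any(projected_gdp <= 0)) stop("projected_gdp must be positive")
  round_half_away(lost_gdp / projected_gdp * 100, 2)
}

#' GDP impact table for missing workers
#'
#' Builds the GDP-impact table from a projections table: lost GDP from
#' the average-product formula and the potential percentage gain in
#' GDP. When `lost_gdp` is already present in `projections` (externally
#' given, as for the published projections) it is used as-is and only
#' the ratio is recomputed.
#'
#' @param projections Tibble with columns `year`, `projected_gdp`
#'   (AU$ millions), `missing_ft`, `missing_pt` and optionally
#'   `lost_gdp`.
#' @param gdp_per_fte GDP per FTE worker-year (AU$, base-2013 level); ignored when
#'   `lost_gdp` is supplied.
#' @param pt_fte_factor FTE fraction of a part-time worker.
#' @return A tibble with columns `year`, `projected_gdp`, `missing_ft`,
#'   `missing_pt`, `lost_gdp`, `pct_gain`.
#' @export
gdp_impact <- function(projections, gdp_per_fte = 136100,
                       pt_fte_factor = 0.5) {
  need <- c("year", "projected_gdp", "missing_ft", "missing_pt")
  missing_cols <- setdiff(need, names(projections))
  if (length(missing_cols))
    stop("projections table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  out <- tibble::as_tibble(projections)
  if (!"lost_gdp" %in% names(out)) {
    out$lost_gdp <- compute_gdp_loss(out$missing_ft, out$missing_pt,
                                     gdp_per_fte, pt_fte_factor)
  }
  out$pct_gain <- pct_gain(out$lost_gdp, out$projected_gdp)
  dplyr::select(out, "year", "projected_gdp", "missing_ft", "missing_pt",
                "lost_gdp", "pct_gain")
}
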