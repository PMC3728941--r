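#' Published summary totals from the Gulf-of-Mexico Kemp's ridley tracking study
#'
#' The raw 1998-2011 telemetry data behind the study were never deposited,
#' but its printed summary totals are inputs this package can work with:
#' tracking-day totals, per-site-class residence days, mean daily location
#' counts, mean 50% core-area sizes, and the grid dimensions of the habitat
#' regression. These feed [reported_study_summary()], which recomputes the
#' derived percentages and ratios the study reports.
#'
#' @return A list of named totals:
#' \describe{
#'   \item{tracking_days_total}{6009 turtle tracking days over 31 animals.}
#'   \item{foraging_days_total}{2641 days at all labelled foraging sites.}
#'   \item{foraging_days_by_site}{days at F, F1, F2, F3 sites.}
#'   \item{daily_locations_by_site}{mean daily locations at F, F1, F2, F3.}
#'   \item{mean_area_km2_by_site}{mean 50% core-area size (km^2) per label.}
#'   \item{n_turtles, n_faf, n_usgom}{cohort size, animals with foraging-area
#'     fidelity, and FAF animals whose final site lay in US Gulf waters.}
#'   \item{grid_cells_total, grid_subsample_fraction}{habitat grid size and
#'     the random cell subsampling fraction.}
#'   \item{glm_coefficients}{log-link GLM coefficients for foraging days per
#'     cell: intercept, distance to release (km), distance to mainland (km),
#'     annual SST (deg C), bathymetry (m), NPP (mg C/m^2/day).}
#' }
#' @export
reported_totals <- function() {
  list(
    tracking_days_total = 6009,
    foraging_days_total = 2641,
    foraging_days_by_site = c(F = 1820, F1 = 547, F2 = 251, F3 = 22),
    daily_locations_by_site = c(F = 1215, F1 = 437, F2 = 222, F3 = 22),
    mean_area_km2_by_site = c(F = 660.8, F1 = 1314.7, F2 = 1739.0, F3 = 1413.5),
    n_turtles = 31,
    n_faf = 24,
    n_usgom = 22,
    mean_travel_km = 793.1,
    grid_cells_total = 778,
    grid_subsample_fraction = 0.2,
    glm_coefficients = c(intercept = 20.2033,
                         dist_release_km = -0.0008,
                         dist_mainland_km = 0.0060,
                         sst_c = -0.8138,
                         bathy_m = -0.0026,
                         npp = 0.0009)
  )
}

#' Derived summary statistics from the published totals
#'
#' Recomputes, from the totals in [reported_totals()], the headline derived
#' quantities of the study's summary layer: the percentage of tracking days
#' spent in foraging mode, the F1/F, F2/F and F3/F mean core-area ratios,
#' the percentage of mean daily locations at final (F) sites, the percentage
#' of site-faithful animals whose final site lay in US Gulf waters, and the
#' habitat-grid subsample size. Every value is an arithmetic consequence of
#' the printed totals; nothing is fitted.
#'
#' @param totals a list shaped like [reported_totals()].
#' @return named numeric vector of derived summary statistics.
#' @export
reported_study_summary <- function(totals = reported_totals()) {
  c(pct_tracking_days_foraging =
      100 * totals$foraging_days_total / totals$tracking_days_total,
    f1_f_area_ratio = unname(totals$mean_area_km2_by_site["F1"] /
                               totals$mean_area_km2_by_site["F"]),
    f2_f_area_ratio = unname(totals$mean_area_km2_by_site["F2"] /
                               totals$mean_area_km2_by_site["F"]),
    f3_f_area_ratio = unname(totals$mean_area_km2_by_site["F3"] /
                               totals$mean_area_km2_by_site["F"]),
    pct_daily_locations_f =
      100 * unname(totals$daily_locations_by_site["F"]) /
        sum(totals$daily_locations_by_site),
    pct_usgom = 100 * totals$n_usgom / totals$n_faf,
    grid_subsample_n = floor(totals$grid_subsample_fraction *
                               totals$grid_cells_total))
}
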