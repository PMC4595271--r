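#' Published phenophase climate records for the CL and GT regions
#'
#' The per-phenophase meteorological measurements for the Changli (CL,
#' eastern China) and Gaotai (GT, western China) vineyards in the 2010 and
#' 2011 growing seasons: phenophase duration (days), cumulative radiation
#' (kJ/m2), growing degree days, sunshine duration (h), rainfall (mm) and
#' mean day-night temperature difference (degrees C). One row per
#' (region, year, phenophase); season totals are recomputed with
#' [season_summary()], not stored.
#'
#' @return data.frame with columns `region`, `year`, `phenophase`, `days`,
#'   `rad_kj_m2`, `gdd`, `sunshine_h`, `rainfall_mm`, `temp_diff_c`.
#' @export
#' @examples
#' cl11 <- subset(climate_regional_records(), region == "CL" & year == 2011)
#' season_summary(cl11)
climate_regional_records <- function() {
  ph <- c("Flowering", "Berry development", "Veraison", "Ripening")
  rows <- rbind(
    # region, year, days, rad, gdd, sunshine, rainfall, temp_diff
    data.frame(region = "CL", year = 2011L, phenophase = ph,
               days = c(13, 48, 24, 36),
               rad_kj_m2 = c(31508, 110124, 46340, 69717),
               gdd = c(127.70, 575.30, 353.40, 394.00),
               sunshine_h = c(132.00, 250.70, 101.60, 290.70),
               rainfall_mm = c(3.50, 181.10, 342.70, 28.00),
               temp_diff_c = c(11.39, 6.42, 5.60, 9.73)),
    data.frame(region = "GT", year = 2011L, phenophase = ph,
               days = c(7, 53, 17, 25),
               rad_kj_m2 = c(12253, 81898, 28011, 38491),
               gdd = c(99.90, 739.00, 180.70, 191.00),
               sunshine_h = c(64.10, 525.30, 126.90, 221.70),
               rainfall_mm = c(0.00, 25.70, 48.80, 6.40),
               temp_diff_c = c(16.10, 14.60, 12.70, 13.30)),
    data.frame(region = "CL", year = 2010L, phenophase = ph,
               days = c(5, 51, 20, 34),
               rad_kj_m2 = c(11537, 87562, 30430, 43105),
               gdd = c(47.40, 671.80, 232.10, 363.80),
               sunshine_h = c(55.80, 320.70, 106.90, 182.40),
               rainfall_mm = c(0.00, 162.90, 219.50, 159.70),
               temp_diff_c = c(10.40, 6.60, 6.70, 7.90)),
    data.frame(region = "GT", year = 2010L, phenophase = ph,
               days = c(6, 62, 16, 25),
               rad_kj_m2 = c(17608, 138144, 34442, 34589),
               gdd = c(87.10, 884.10, 178.80, 142.10),
               sunshine_h = c(79.30, 612.60, 168.20, 161.20),
               rainfall_mm = c(0.00, 32.60, 9.40, 65.70),
               temp_diff_c = c(17.60, 14.30, 15.82, 11.50)))
  rows$phenophase <- as.character(rows$phenophase)
  rownames(rows) <- NULL
  rows
}

.climate_additive <- c("days", "rad_kj_m2", "gdd", "sunshine_h", "rainfall_mm")

#' Season summary of phenophase climate records
#'
#' Sums the additive metrics (days, radiation, GDD, sunshine, rainfall) over
#' the phenophases of one region-year and reports the season day-night
#' temperature difference as the unweighted arithmetic mean over phenophases
#' (optionally weighted by phenophase duration), rounded half-up to 2
#' decimals for reporting.
#'
#' @param records phenophase rows for a single region-year (layout of
#'   [climate_regional_records()]); any subset of the four phenophases is
#'   accepted, duplicates are an error.
#' @param weight_temp_by_days use a days-weighted mean for the temperature
#'   difference (default FALSE).
#' @return one-row data.frame: `region`, `year`, `n_phenophases`, the five
#'   additive totals, and `temp_diff_c`.
#' @export
season_summary <- function(records, weight_temp_by_days = FALSE) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  if (length(unique(records$region)) != 1 ||
      length(unique(records$year)) != 1)
    stop("records must cover a single region-year")
  if (anyDuplicated(records$phenophase))
    stop("duplicate phenophase record")
  if (any(records$days < 0) ||
      any(as.matrix(records[, .climate_additive]) < 0, na.rm = TRUE))
    stop("climate magnitudes must be non-negative")
  totals <- colSums(records[, .climate_additive, drop = FALSE])
  td <- if (weight_temp_by_days)
    sum(records$temp_diff_c * records$days) / sum(records$days)
  else mean(records$temp_diff_c)
  out <- data.frame(region = records$region[1], year = records$year[1],
                    n_phenophases = nrow(records), t(totals),
                    temp_diff_c = round_half_up(td, 2),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Contrast two season summaries
#'
#' Per-metric signed differences (`b - a`) and ratios (`b / a`) between two
#' same-year season summaries; a zero denominator yields a missing ratio,
#' never an error.
#'
#' @param a,b one-row season summaries from [season_summary()] for the same
#'   year.
#' @return data.frame with one row per metric: `metric`, `a`, `b`,
#'   `difference`, `ratio`.
#' @export
region_contrast <- function(a, b) {
  if (a$year != b$year) stop("summaries are from different years")
  metrics <- c(.climate_additive, "temp_diff_c")
  va <- as.numeric(a[1, metrics])
  vb <- as.numeric(b[1, metrics])
  data.frame(metric = metrics, a = va, b = vb, difference = vb - va,
             ratio = ifelse(va == 0, NA_real_, vb / va),
             stringsAsFactors = FALSE)
}
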