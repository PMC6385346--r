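#' Merge bi-monthly (15-day) composites to monthly means
#'
#' Satellite leaf-area products are often delivered as two composites per
#' month. This reduces them to a single monthly value by averaging the
#' composites that fall in the same calendar month; months with a single
#' composite pass through unchanged, and months whose composites are all
#' missing are kept as `NA` (flagged missing, never treated as zero).
#'
#' @param data A data frame of composites with at least `year` and `month`
#'   columns plus the value column; any further columns (e.g. `lat`, `lon`)
#'   are treated as grid identifiers and preserved.
#' @param value Column holding the composite values (default `value`).
#' @return A tibble with one row per (grid cell, year, month) and the
#'   monthly mean in `value`.
#' @examples
#' x <- tibble::tibble(year = 2000, month = c(1, 1, 2), value = c(2, 3, 1.7))
#' bimonthly_to_monthly(x)
#' @export
bimonthly_to_monthly <- function(data, value = value) {
  check_columns(data, c("year", "month"), "composite data")
  val <- as_name(enquo(value))
  keys <- setdiff(names(data), val)
  counts <- dplyr::count(data, dplyr::across(dplyr::all_of(keys)))
  if (any(counts$n > 2)) {
    abort("more than two composites found in a single month")
  }
  data %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) %>%
    dplyr::summarise(
      value = if (all(is.na(.data[[val]]))) NA_real_ else
        mean(.data[[val]], na.rm = TRUE),
      .groups = "drop"
    )
}

#' Annual maximum leaf area index
#'
#' Reduces a monthly LAI series to its annual maximum (LAI_max), the
#' greenness metric used throughout the analysis. A year is retained only if
#' it has at least `min_months` non-missing months (default 6); otherwise its
#' LAI_max is `NA`.
#'
#' @param data Data frame with `year`, `month` and a value column.
#' @param value Column holding monthly LAI (default `value`).
#' @param min_months Minimum number of non-missing months for a year to
#'   yield a value.
#' @return Tibble with columns `year`, `lai_max`.
#' @export
annual_lai_max <- function(data, value = value, min_months = 6) {
  check_columns(data, c("year", "month"), "monthly LAI")
  val <- as_name(enquo(value))
  data %>%
    dplyr::group_by(.data$year) %>%
    dplyr::summarise(
      lai_max = {
        v <- .data[[val]]
        if (sum(!is.na(v)) >= min_months) max(v, na.rm = TRUE) else NA_real_
      },
      .groups = "drop"
    )
}

#' Area-weighted mean over a latitude band
#'
#' Collapses a gridded monthly field to one scalar per time step by
#' cosine-of-latitude weighting over a closed latitude band (default the
#' northern high latitudes, 60-90 degrees N). Cell membership is decided by
#' the cell-centre latitude; masked (`NA`) cells are excluded and the
#' weights renormalised, so a spatially uniform field returns its value
#' exactly under any mask.
#'
#' @param data Data frame with `year`, `month`, `lat`, `lon` and a value
#'   column. Latitudes in degrees north, strictly within \[-90, 90\].
#' @param value Column holding the field values (default `value`).
#' @param band Closed latitude band `c(south, north)` in degrees north.
#' @return Tibble with `year`, `month`, `value` (the band mean; `NA` when
#'   every cell in a time step is masked).
#' @export
band_weighted_mean <- function(data, value = value, band = c(60, 90)) {
  check_columns(data, c("year", "month", "lat", "lon"), "gridded field")
  val <- as_name(enquo(value))
  if (any(abs(data$lat) > 90)) abort("latitudes must lie within [-90, 90]")
  sub <- dplyr::filter(data, .data$lat >= band[1], .data$lat <= band[2])
  if (nrow(sub) == 0) abort("latitude band contains no grid cells")
  sub %>%
    dplyr::group_by(.data$year, .data$month) %>%
    dplyr::summarise(
      value = {
        v <- .data[[val]]
        w <- cos(.data$lat * pi / 180)
        ok <- !is.na(v)
        if (!any(ok)) NA_real_ else sum(w[ok] * v[ok]) / sum(w[ok])
      },
      .groups = "drop"
    )
}

#' Growing degree days above 0 degrees C
#'
#' Converts a monthly-mean 2-m temperature series (already reduced to one
#' value per month, e.g. a band mean) to annual growing degree days above
#' 0 degrees C: the sum over months of days-in-month times the monthly mean
#' temperature, counting only months whose mean is above zero. This captures
#' both the warming signal and the lengthening of the growing season.
#'
#' @param data Data frame with `year`, `month` and a temperature column in
#'   degrees C.
#' @param value Temperature column (default `value`).
#' @param calendar Calendar used for days-in-month: `"gregorian"` (default,
#'   observations), `"365_day"` or `"360_day"` (model calendars).
#' @param allow_partial If `FALSE` (default) every year must have all 12
#'   months; if `TRUE`, the sum runs over the months present.
#' @return Tibble with `year`, `gdd0` (degree-days, always >= 0).
#' @export
compute_gdd0 <- function(data, value = value, calendar = "gregorian",
                         allow_partial = FALSE) {
  check_columns(data, c("year", "month"), "monthly temperature")
  val <- as_name(enquo(value))
  if (!allow_partial) {
    bad <- data %>%
      dplyr::group_by(.data$year) %>%
      dplyr::summarise(n = sum(!is.na(.data[[val]])), .groups = "drop") %>%
      dplyr::filter(.data$n < 12)
    if (nrow(bad) > 0) {
      abort(sprintf(
        "GDD0 requires all 12 monthly means; incomplete year(s): %s (set allow_partial = TRUE to override)",
        paste(bad$year, collapse = ", ")))
    }
  }
  data %>%
    dplyr::filter(!is.na(.data[[val]])) %>%
    dplyr::mutate(days = days_in_month(.data$month, .data$year, calendar)) %>%
    dplyr::group_by(.data$year) %>%
    dplyr::summarise(
      gdd0 = sum(.data$days * .data[[val]] * (.data[[val]] > 0)),
      .groups = "drop"
    )
}

#' Standardise an annual series to zero mean and unit variance
#'
#' Centres on the mean and scales by the population standard deviation
#' (divisor n), the convention used consistently for the driver PCA.
#'
#' @param data Data frame with a `year` column and the series column.
#' @param value Series column (default `value`).
#' @param divisor `"n"` (population, default) or `"n-1"` (sample).
#' @return Tibble with `year` and the standardised `value`.
#' @export
standardize_series <- function(data, value = value, divisor = c("n", "n-1")) {
  divisor <- match.arg(divisor)
  check_columns(data, "year", "annual series")
  val <- as_name(enquo(value))
  v <- data[[val]]
  if (anyNA(v)) abort("standardize_series: series contains missing values")
  s <- if (divisor == "n") sd_pop(v) else sd(v)
  if (s == 0) abort("cannot standardise a constant series (zero variance)")
  tibble::tibble(year = data$year, value = (v - mean(v)) / s)
}
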