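#' Read a NOAA/ESRL-style monthly CO2 record
#'
#' Parses the whitespace-delimited monthly surface CO2 text format
#' (columns: site code, year, month, value; comment lines start with `#`;
#' missing values coded `-999.99`).
#'
#' @param path Path to the text file.
#' @return Tibble with `site`, `year`, `month`, `ppm` (`NA` where flagged
#'   missing).
#' @export
read_noaa_monthly <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- vapply(parts, length, integer(1)) < 4
  if (any(bad)) abort("read_noaa_monthly: malformed line(s) with fewer than 4 fields")
  out <- tibble::tibble(
    site = vapply(parts, `[[`, character(1), 1),
    year = as.integer(vapply(parts, `[[`, character(1), 2)),
    month = as.integer(vapply(parts, `[[`, character(1), 3)),
    ppm = as.numeric(vapply(parts, `[[`, character(1), 4))
  )
  out$ppm[out$ppm <= -999] <- NA_real_
  out
}

#' Read a generic monthly CO2 CSV (year, month, ppm)
#'
#' @param path Path to a CSV file with columns `year`, `month`, `ppm`.
#' @return Tibble with `year`, `month`, `ppm`.
#' @export
read_co2_csv <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path))
  check_columns(out, c("year", "month", "ppm"), "CO2 CSV")
  out
}

#' Read an annual-mean CO2 CSV (year, ppm)
#'
#' @param path Path to a CSV file with columns `year`, `ppm`.
#' @return Tibble with `year`, `ppm`.
#' @export
read_annual_co2_csv <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path))
  check_columns(out, c("year", "ppm"), "annual CO2 CSV")
  out
}

# arrange a station record on a complete contiguous monthly axis
complete_monthly <- function(rec) {
  check_columns(rec, c("year", "month", "ppm"), "station record")
  rec <- dplyr::arrange(rec, .data$year, .data$month)
  if (anyDuplicated(rec[c("year", "month")])) {
    abort("station record has duplicated months")
  }
  axis <- tidyr::expand_grid(year = seq(min(rec$year), max(rec$year)),
                             month = 1:12)
  dplyr::left_join(axis, rec[c("year", "month", "ppm")],
                   by = c("year", "month"))
}

#' Detrended mean seasonal cycle of a station CO2 record
#'
#' Removes the long-term trend with a centred 12-month (2x12) running mean,
#' then averages the residual anomalies by calendar month over the chosen
#' epoch. The monthly anomalies sum to approximately zero; comparing two
#' epochs shows how the seasonal cycle (in particular the late-summer
#' minimum) has deepened over time.
#'
#' @param rec Station record: data frame with `year`, `month`, `ppm`.
#' @param epoch Year range `c(first, last)` over which anomalies are
#'   averaged; must cover at least 4 complete years and have at most 20%
#'   missing months.
#' @return Tibble with `month`, `anomaly` (ppm).
#' @export
seasonal_cycle <- function(rec, epoch) {
  full <- complete_monthly(rec)
  if (epoch[2] - epoch[1] + 1 < 4) abort("seasonal_cycle: epoch must cover at least 4 years")
  # centred 2x12 running mean: removes a linear trend exactly and any pure
  # 12-month periodic up to its mean
  w <- c(0.5, rep(1, 11), 0.5) / 12
  trend <- stats::filter(full$ppm, w, sides = 2)
  full$anomaly <- full$ppm - as.numeric(trend)
  sub <- dplyr::filter(full, .data$year >= epoch[1], .data$year <= epoch[2])
  if (mean(is.na(sub$ppm)) > 0.2) {
    abort("seasonal_cycle: more than 20% of months missing in the epoch")
  }
  sub %>%
    dplyr::group_by(.data$month) %>%
    dplyr::summarise(anomaly = mean(.data$anomaly, na.rm = TRUE),
                     .groups = "drop")
}

#' Change in the summertime CO2 drawdown slope
#'
#' The month-to-month first difference of a station CO2 record is most
#' negative when photosynthetic uptake strengthens fastest; its annual
#' minimum is the drawdown slope (ppm per month). This statistic needs no
#' detrending: a constant offset or a pure linear trend only shifts every
#' difference by the same constant monthly increment. Each yearly series is
#' lightly smoothed with a 2-year moving window, and the change over the
#' record is the mean over the last 5 years minus the mean over the first 5
#' years, with the two 5-year standard deviations combined in quadrature.
#'
#' Gaps of at most `max_gap` consecutive months are filled by linear
#' interpolation; a year touched by a longer gap is dropped from the yearly
#' series.
#'
#' @param rec Station record: data frame with `year`, `month`, `ppm`.
#' @param window Optional year range `c(first, last)` to analyse (default:
#'   the full record).
#' @param max_gap Longest gap (months) filled by interpolation (default 2).
#' @param avg_years Length of the end-windows averaged for the change
#'   (default 5).
#' @return Object of class `drawdown_result`: `yearly` (tibble `year`,
#'   `slope`, `slope_smooth`, `min_month`), `change`, `change_sd`,
#'   `window`.
#' @export
drawdown_change <- function(rec, window = NULL, max_gap = 2, avg_years = 5) {
  full <- complete_monthly(rec)
  if (!is.null(window)) {
    full <- dplyr::filter(full, .data$year >= window[1], .data$year <= window[2])
  }
  if (mean(is.na(full$ppm)) > 0.1) {
    abort("drawdown_change: more than 10% of months missing in the window")
  }
  ppm <- zoo::na.approx(full$ppm, na.rm = FALSE, maxgap = max_gap)
  # forward first difference, assigned to the left month
  d <- c(diff(ppm), NA_real_)
  full$dppm <- d

  yearly <- full %>%
    dplyr::filter(.data$year < max(.data$year) | .data$month < 12) %>%
    dplyr::group_by(.data$year) %>%
    dplyr::summarise(
      slope = if (anyNA(.data$dppm)) NA_real_ else min(.data$dppm),
      min_month = if (anyNA(.data$dppm)) NA_integer_ else
        .data$month[which.min(.data$dppm)],
      .groups = "drop"
    ) %>%
    dplyr::filter(!is.na(.data$slope))
  if (nrow(yearly) < 2 * avg_years) {
    abort("drawdown_change: too few complete years for the change statistic")
  }
  summerless <- mean(yearly$min_month %in% 5:9) < 0.5
  if (summerless) {
    warn("drawdown_change: the derivative minimum does not fall in a consistent summer season; proceeding on the global minimum")
  }
  # 2-year moving window: mean of the year and its predecessor; first year
  # keeps its single value
  s <- yearly$slope
  yearly$slope_smooth <- c(s[1], (s[-1] + s[-length(s)]) / 2)

  first <- utils::head(yearly$slope_smooth, avg_years)
  last <- utils::tail(yearly$slope_smooth, avg_years)
  structure(list(
    yearly = yearly,
    change = mean(last) - mean(first),
    change_sd = sqrt(sd(first)^2 + sd(last)^2),
    window = range(yearly$year),
    avg_years = avg_years
  ), class = "drawdown_result")
}

#' @export
print.drawdown_result <- function(x, ...) {
  cat(sprintf(
    "CO2 drawdown-slope change %d-%d: %.3f +/- %.3f ppm/month\n",
    x$window[1], x$window[2], x$change, x$change_sd))
  invisible(x)
}

#' @describeIn drawdown_change Yearly drawdown slopes as a tibble.
#' @param x A `drawdown_result`.
#' @param ... Unused.
#' @export
tidy.drawdown_result <- function(x, ...) x$yearly

#' @describeIn drawdown_change One-row summary (change, sd, window).
#' @export
glance.drawdown_result <- function(x, ...) {
  tibble::tibble(change = x$change, change_sd = x$change_sd,
                 first_year = x$window[1], last_year = x$window[2],
                 n_years = nrow(x$yearly))
}

#' @export
autoplot.drawdown_result <- function(object, ...) {
  ggplot2::ggplot(object$yearly, ggplot2::aes(.data$year, .data$slope)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$slope_smooth),
                       colour = "steelblue") +
    ggplot2::labs(x = "Year", y = "Drawdown slope (ppm/month)",
                  subtitle = sprintf("change: %.3f ± %.3f ppm/month",
                                     object$change, object$change_sd)) +
    ggplot2::theme_minimal()
}

#' Seasonal-cycle amplitude (convenience diagnostic)
#'
#' Yearly peak-to-trough amplitude of the detrended record. The drawdown
#' slope is the preferred GPP proxy (the amplitude is also sensitive to
#' wintertime respiration); this is provided for comparison only.
#'
#' @param rec Station record (`year`, `month`, `ppm`).
#' @return Tibble with `year`, `amplitude` (ppm).
#' @export
cycle_amplitude <- function(rec) {
  full <- complete_monthly(rec)
  w <- c(0.5, rep(1, 11), 0.5) / 12
  trend <- stats::filter(full$ppm, w, sides = 2)
  full$anomaly <- full$ppm - as.numeric(trend)
  full %>%
    dplyr::group_by(.data$year) %>%
    dplyr::summarise(
      amplitude = if (anyNA(.data$anomaly)) NA_real_ else
        max(.data$anomaly) - min(.data$anomaly),
      .groups = "drop"
    )
}
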