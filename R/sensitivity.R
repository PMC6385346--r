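#' Greening sensitivity: linear regression with a prescribed error model
#'
#' Fits `y = a + b x` by ordinary least squares and reports the slope `b'`
#' (the greening sensitivity when `y` is LAI_max and `x` the proxy driver
#' omega) with the error conventions used throughout the constraint:
#' residual variance `s^2` with divisor `N - 2`, slope standard error
#' `sigma_b = s / (sigma_x * sqrt(N))`, and intercept standard error
#' `sigma_a = s * sqrt(1/N + xbar^2 / (sigma_x^2 N))`, where `sigma_x` is by
#' default the population (divisor-N) standard deviation of `x`, matching
#' the divisor-n covariance used in the driver PCA. `sd_divisor = "n-1"`
#' switches to the sample convention.
#'
#' @param data Data frame holding aligned annual series (rows with `NA` in
#'   either variable are dropped).
#' @param x,y Predictor and response columns (defaults `x`, `y`).
#' @param sd_divisor Convention for `sigma_x`: `"n"` (default) or `"n-1"`.
#' @return Object of class `greening_fit`: slope, intercept, their standard
#'   errors, residual scale `s`, `n`, and the data used.
#' @examples
#' d <- tibble::tibble(x = 0:2, y = c(0, 1, 3))
#' fit <- fit_greening(d)
#' tidy(fit)
#' @export
fit_greening <- function(data, x = x, y = y, sd_divisor = c("n", "n-1")) {
  sd_divisor <- match.arg(sd_divisor)
  xv <- as_name(enquo(x))
  yv <- as_name(enquo(y))
  check_columns(data, c(xv, yv), "regression data")
  keep <- !is.na(data[[xv]]) & !is.na(data[[yv]])
  xs <- data[[xv]][keep]
  ys <- data[[yv]][keep]
  n <- length(xs)
  if (n < 3) abort("fit_greening: need at least 3 points (residual variance undefined below)")
  sxx <- sum((xs - mean(xs))^2)
  if (sxx == 0) abort("fit_greening: predictor is constant")

  slope <- sum((xs - mean(xs)) * (ys - mean(ys))) / sxx
  intercept <- mean(ys) - slope * mean(xs)
  res <- ys - intercept - slope * xs
  s2 <- sum(res^2) / (n - 2)
  s <- sqrt(s2)
  sigma_x <- if (sd_divisor == "n") sqrt(sxx / n) else sqrt(sxx / (n - 1))
  sigma_b <- s / (sigma_x * sqrt(n))
  sigma_a <- s * sqrt(1 / n + mean(xs)^2 / (sigma_x^2 * n))

  structure(list(
    slope = slope, intercept = intercept,
    sigma_b = sigma_b, sigma_a = sigma_a,
    s = s, n = n, sd_divisor = sd_divisor,
    data = tibble::tibble(x = xs, y = ys, fitted = intercept + slope * xs,
                          residual = res),
    vars = c(x = xv, y = yv)
  ), class = "greening_fit")
}

#' @export
print.greening_fit <- function(x, ...) {
  cat(sprintf("Linear sensitivity fit (%s ~ %s, N = %d)\n",
              x$vars["y"], x$vars["x"], x$n))
  cat(sprintf("  slope b' = %.6g +/- %.3g\n", x$slope, x$sigma_b))
  cat(sprintf("  intercept a = %.6g +/- %.3g, residual s = %.3g\n",
              x$intercept, x$sigma_a, x$s))
  invisible(x)
}

#' @describeIn fit_greening Coefficient table (term, estimate, std.error).
#' @export
tidy.greening_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = c(x$sigma_a, x$sigma_b)
  )
}

#' @describeIn fit_greening One-row fit summary (r.squared, sigma, nobs).
#' @export
glance.greening_fit <- function(x, ...) {
  tss <- sum((x$data$y - mean(x$data$y))^2)
  tibble::tibble(
    r.squared = if (tss > 0) 1 - sum(x$data$residual^2) / tss else NA_real_,
    sigma = x$s,
    slope = x$slope,
    sigma_b = x$sigma_b,
    nobs = x$n
  )
}

#' @export
autoplot.greening_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "steelblue") +
    ggplot2::labs(x = object$vars[["x"]], y = object$vars[["y"]],
                  subtitle = sprintf("b' = %.4g ± %.3g", object$slope,
                                     object$sigma_b)) +
    ggplot2::theme_minimal()
}

# ---- Mann-Kendall trend test ------------------------------------------------

# Kendall statistic S and tie-corrected variance
mk_statistic <- function(v) {
  n <- length(v)
  s <- 0L
  for (i in seq_len(n - 1)) {
    s <- s + sum(sign(v[(i + 1):n] - v[i]))
  }
  ties <- table(v)
  ties <- ties[ties > 1]
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  list(S = s, var_S = var_s, n = n, has_ties = length(ties) > 0)
}

# exact two-sided p for tie-free series: Mahonian distribution of S
mk_exact_p <- function(S, n) {
  counts <- 1
  for (k in 2:n) {
    new <- rep(0, length(counts) + k - 1)
    for (j in 0:(k - 1)) {
      idx <- seq_along(counts) + j
      new[idx] <- new[idx] + counts
    }
    counts <- new
  }
  # counts[i] = permutations with i-1 discordant pairs; S = n(n-1)/2 - 2*(i-1)
  s_vals <- n * (n - 1) / 2 - 2 * (seq_along(counts) - 1)
  p_right <- sum(counts[s_vals >= abs(S)]) / sum(counts)
  min(1, 2 * p_right)
}

#' Mann-Kendall trend test
#'
#' Nonparametric monotone-trend test on an annual series. For `n >= 10` (or
#' whenever ties are present) the tie-corrected normal approximation with
#' continuity correction is used; for shorter tie-free series the exact null
#' distribution of the Kendall S statistic is evaluated, so tiny-series
#' results are exact.
#'
#' @param v Numeric vector (one value per year).
#' @return List with `S`, `var_S`, `z`, `p.value`, `n`.
#' @export
mk_test <- function(v) {
  v <- v[!is.na(v)]
  n <- length(v)
  if (n < 3) abort("mk_test: need at least 3 values")
  st <- mk_statistic(v)
  if (st$var_S == 0) {
    return(list(S = st$S, var_S = 0, z = 0, p.value = 1, n = n))
  }
  z <- (st$S - sign(st$S)) / sqrt(st$var_S)
  if (n < 10 && !st$has_ties) {
    p <- mk_exact_p(st$S, n)
  } else {
    p <- 2 * pnorm(-abs(z))
  }
  list(S = st$S, var_S = st$var_S, z = z, p.value = p, n = n)
}

#' Classify greening and browning trends per pixel
#'
#' Applies the Mann-Kendall test to each pixel's summer-mean LAI series and
#' labels it `greening` (significant positive S), `browning` (significant
#' negative S), `none` (not significant at `p_threshold`), or `barren`
#' (fewer than `min_years` usable years, or the series never exceeds
#' `lai_floor`, the sparse-vegetation mask threshold).
#'
#' @param data Data frame with `lat`, `lon`, `year` and a value column of
#'   per-pixel annual (e.g. June-August mean) LAI.
#' @param value Value column (default `value`).
#' @param p_threshold Two-sided significance level (default 0.1).
#' @param min_years Minimum usable years per pixel (default 10).
#' @param lai_floor Pixels whose series never exceeds this LAI are labelled
#'   barren (default 0, i.e. only all-zero/missing pixels).
#' @return Tibble with `lat`, `lon`, `S`, `p.value`, `label`.
#' @export
classify_trends <- function(data, value = value, p_threshold = 0.1,
                            min_years = 10, lai_floor = 0) {
  check_columns(data, c("lat", "lon", "year"), "pixel series")
  val <- as_name(enquo(value))
  data %>%
    dplyr::group_by(.data$lat, .data$lon) %>%
    dplyr::summarise(
      res = list({
        v <- .data[[val]][order(.data$year)]
        v_ok <- v[!is.na(v)]
        if (length(v_ok) < min_years || all(v_ok <= lai_floor)) {
          tibble::tibble(S = NA_integer_, p.value = NA_real_, label = "barren")
        } else {
          mk <- mk_test(v)
          lab <- if (mk$p.value >= p_threshold || mk$S == 0) "none"
                 else if (mk$S > 0) "greening" else "browning"
          tibble::tibble(S = mk$S, p.value = mk$p.value, label = lab)
        }
      }),
      .groups = "drop"
    ) %>%
    tidyr::unnest("res")
}

#' Summer (June-August) mean LAI per pixel and year
#'
#' Convenience reduction feeding [classify_trends()].
#'
#' @param data Gridded monthly field (`year`, `month`, `lat`, `lon`, value).
#' @param value Value column (default `value`).
#' @param months Months to average (default `6:8`).
#' @return Tibble `lat`, `lon`, `year`, `value`.
#' @export
summer_mean <- function(data, value = value, months = 6:8) {
  check_columns(data, c("year", "month", "lat", "lon"), "gridded field")
  val <- as_name(enquo(value))
  data %>%
    dplyr::filter(.data$month %in% months) %>%
    dplyr::group_by(.data$lat, .data$lon, .data$year) %>%
    dplyr::summarise(value = mean(.data[[val]], na.rm = TRUE),
                     .groups = "drop") %>%
    dplyr::mutate(value = ifelse(is.nan(.data$value), NA_real_, .data$value))
}
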