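#' Proxy driver from principal-component reduction of CO2 and GDD0
#'
#' Atmospheric CO2 and growing degree days co-vary strongly in the northern
#' high latitudes (the radiative effect of rising CO2), which frustrates any
#' clean factor separation. Instead of attributing the greening signal to
#' either driver, the analysis works with the one-dimensional projection of
#' maximum shared variance: each driver series is standardised (divisor n),
#' the 2x2 covariance matrix `C = X'X / n` is eigendecomposed, and the first
#' principal component `omega = X u1` becomes the proxy driver.
#'
#' The sign of an eigenvector is arbitrary; here `u1` is oriented so that
#' its loading on the CO2 driver is positive, making "sensitivity to omega"
#' mean the response to *increasing* CO2 and warmth for every dataset, which
#' keeps sensitivities comparable across ensemble members.
#'
#' @param data Data frame with a `year` column and the two driver columns,
#'   one row per year (equal, overlapping year ranges by construction).
#' @param co2,gdd0 Driver columns (defaults `co2`, `gdd0`).
#' @return An object of class `driver_pca`: a list with `omega` (tibble
#'   `year`, `omega`), `rotation` (2x2 eigenvector matrix, columns `u1`,
#'   `u2`), `eigenvalues` (descending; they sum to 2), `center`, `scale`,
#'   and `drivers` (the column names used).
#' @examples
#' d <- tibble::tibble(year = 2001:2010, co2 = 370 + 2 * (1:10),
#'                     gdd0 = 900 + 5 * (1:10) + sin(1:10) * 20)
#' pca <- driver_pca(d)
#' tidy(pca)
#' @export
driver_pca <- function(data, co2 = co2, gdd0 = gdd0) {
  co2v <- as_name(enquo(co2))
  gddv <- as_name(enquo(gdd0))
  check_columns(data, c("year", co2v, gddv), "driver data")
  if (anyNA(data[[co2v]]) || anyNA(data[[gddv]])) {
    abort("driver_pca: driver series contain missing values")
  }
  if (anyDuplicated(data$year)) abort("driver_pca: duplicated years")
  n <- nrow(data)
  if (n < 3) abort("driver_pca: need at least 3 years")

  ctr <- c(mean(data[[co2v]]), mean(data[[gddv]]))
  scl <- c(sd_pop(data[[co2v]]), sd_pop(data[[gddv]]))
  if (any(scl == 0)) abort("driver_pca: constant driver series")
  X <- cbind((data[[co2v]] - ctr[1]) / scl[1],
             (data[[gddv]] - ctr[2]) / scl[2])
  C <- crossprod(X) / n
  eig <- eigen(C, symmetric = TRUE)
  if (abs(eig$values[1] - eig$values[2]) < 1e-12) {
    abort("driver_pca: degenerate (isotropic) covariance; the two eigenvalues coincide and the leading direction is undefined")
  }
  u <- eig$vectors
  # orient u1 so the CO2 loading is positive
  if (u[1, 1] < 0) u[, 1] <- -u[, 1]
  if (u[1, 2] < 0) u[, 2] <- -u[, 2]
  omega <- drop(X %*% u[, 1])

  structure(list(
    omega = tibble::tibble(year = data$year, omega = omega),
    rotation = `dimnames<-`(u, list(c(co2v, gddv), c("u1", "u2"))),
    eigenvalues = eig$values,
    center = setNames(ctr, c(co2v, gddv)),
    scale = setNames(scl, c(co2v, gddv)),
    drivers = c(co2v, gddv)
  ), class = "driver_pca")
}

#' @export
print.driver_pca <- function(x, ...) {
  cat("Driver PCA (", paste(x$drivers, collapse = " + "), ")\n", sep = "")
  cat(sprintf("  eigenvalues: %.4f, %.4f (leading mode explains %.1f%%)\n",
              x$eigenvalues[1], x$eigenvalues[2], 50 * x$eigenvalues[1]))
  cat(sprintf("  u1 loadings: %s = %.4f, %s = %.4f\n",
              x$drivers[1], x$rotation[1, 1], x$drivers[2], x$rotation[2, 1]))
  cat(sprintf("  omega: %d years (%d-%d), var %.4f\n",
              nrow(x$omega), min(x$omega$year), max(x$omega$year),
              sd_pop(x$omega$omega)^2))
  invisible(x)
}

#' @describeIn driver_pca One row per driver with its loadings on each mode
#'   and the mode eigenvalues.
#' @param x A `driver_pca` object.
#' @param ... Unused.
#' @export
tidy.driver_pca <- function(x, ...) {
  tibble::tibble(
    driver = rep(x$drivers, 2),
    component = rep(c("PC1", "PC2"), each = 2),
    loading = c(x$rotation[, 1], x$rotation[, 2]),
    eigenvalue = rep(x$eigenvalues, each = 2)
  )
}

#' @describeIn driver_pca One-row summary: leading eigenvalue and explained
#'   variance fraction.
#' @export
glance.driver_pca <- function(x, ...) {
  tibble::tibble(
    lambda1 = x$eigenvalues[1],
    lambda2 = x$eigenvalues[2],
    prop_var = x$eigenvalues[1] / sum(x$eigenvalues),
    n_years = nrow(x$omega)
  )
}

#' @export
autoplot.driver_pca <- function(object, ...) {
  ggplot2::ggplot(object$omega, ggplot2::aes(.data$year, .data$omega)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Year", y = expression(omega ~ "(first PC, dimensionless)"),
                  title = "Proxy driver: first PC of CO2 and GDD0") +
    ggplot2::theme_minimal()
}
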