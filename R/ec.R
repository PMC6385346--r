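#' Fit the cross-ensemble emergent relationship
#'
#' Unweighted ordinary least squares of a projected quantity `y` (here
#' Delta-GPP at doubled CO2, Pg C yr-1) on an observable `x` (historical
#' LAI_max sensitivity) across ensemble members, with the Pearson
#' correlation and its two-sided p-value. Per-member x error bars are
#' carried along for display but deliberately not used as weights: the
#' emergent fit treats every member equally.
#'
#' @param points Data frame of ensemble members with columns `sensitivity`
#'   and `dgpp` (optionally `member`, `sigma_b`, `dgpp_sd`).
#' @return Object of class `ec_relation` with `slope`, `intercept`, `r`,
#'   `p.value`, `n`, the `points`, and (after [ec_bootstrap()]) the
#'   bootstrap line set and `sigma_f()` contour half-width function.
#' @export
fit_emergent <- function(points) {
  check_columns(points, c("sensitivity", "dgpp"), "ensemble points")
  x <- points$sensitivity
  y <- points$dgpp
  if (anyNA(x) || anyNA(y)) abort("fit_emergent: missing values in ensemble points")
  if (any(!is.finite(x))) abort("fit_emergent: non-finite sensitivities")
  n <- length(x)
  if (n < 3) abort("fit_emergent: need at least 3 members")
  if (length(unique(x)) < 2) abort("fit_emergent: constant sensitivities")
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  r <- cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  structure(list(
    slope = slope, intercept = intercept, r = r, p.value = p, n = n,
    points = tibble::as_tibble(points),
    boot = NULL, m = NULL, seed = NULL
  ), class = "ec_relation")
}

# vectorised OLS over a matrix of resample indices (rows = resamples)
boot_fit_lines <- function(x, y, idx) {
  xm <- matrix(x[idx], nrow = nrow(idx))
  ym <- matrix(y[idx], nrow = nrow(idx))
  xbar <- rowMeans(xm)
  ybar <- rowMeans(ym)
  sxx <- rowSums((xm - xbar)^2)
  slope <- rowSums((xm - xbar) * (ym - ybar)) / sxx
  cbind(slope = slope, intercept = ybar - slope * xbar, sxx = sxx)
}

#' Bootstrap confidence contours for the emergent relationship
#'
#' Because the ensemble is small, the uncertainty of the emergent line is
#' estimated by bootstrapping: members are resampled with replacement (same
#' size as the original sample), the least-squares line is refit, and the
#' procedure repeats until the median best-fit line stabilises — at least
#' `m_min` resamples, continuing until the median slope and median intercept
#' each change by less than `tol` (relative) from one resample count to the
#' next. Resamples without at least two distinct x values are redrawn. The
#' 68% confidence contour half-width `sigma_f(x)` is half the central 68%
#' spread (16th to 84th percentile) of the bootstrap-line predictions at x.
#'
#' @param points Ensemble points as for [fit_emergent()].
#' @param m_min Minimum number of bootstrap resamples (default 100).
#' @param tol Relative convergence threshold on the median line (default
#'   0.01, i.e. 1%).
#' @param m_max Resample budget; non-convergence raises an error reporting
#'   the last relative change (default 10000).
#' @param seed Integer seed; fixes all resampling, so the same seed gives
#'   bit-identical contours.
#' @return An `ec_relation` (as [fit_emergent()]) with `boot` (tibble of
#'   retained lines), `m`, `seed`, and `sigma_f(x)`, a vectorised function
#'   returning the contour half-width.
#' @export
ec_bootstrap <- function(points, m_min = 100, tol = 0.01, m_max = 10000,
                         seed = 1L) {
  rel <- fit_emergent(points)
  x <- points$sensitivity
  y <- points$dgpp
  n <- length(x)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)

  draw_valid <- function(k) {
    idx <- matrix(sample.int(n, k * n, replace = TRUE), nrow = k)
    bad <- apply(idx, 1, function(i) length(unique(x[i])) < 2)
    while (any(bad)) {
      idx[bad, ] <- matrix(sample.int(n, sum(bad) * n, replace = TRUE),
                           nrow = sum(bad))
      bad <- apply(idx, 1, function(i) length(unique(x[i])) < 2)
    }
    idx
  }

  lines <- boot_fit_lines(x, y, draw_valid(m_min))[, 1:2, drop = FALSE]
  rel_change <- function(cur, prev) {
    denom <- pmax(abs(prev), .Machine$double.eps)
    abs(cur - prev) / denom
  }
  med_prev <- c(median(lines[1:(m_min - 1), 1]), median(lines[1:(m_min - 1), 2]))
  med_cur <- c(median(lines[, 1]), median(lines[, 2]))
  change <- rel_change(med_cur, med_prev)
  m <- m_min
  while (any(change >= tol) && m < m_max) {
    new_line <- boot_fit_lines(x, y, draw_valid(1))[, 1:2, drop = FALSE]
    lines <- rbind(lines, new_line)
    m <- m + 1
    med_prev <- med_cur
    med_cur <- c(median(lines[, 1]), median(lines[, 2]))
    change <- rel_change(med_cur, med_prev)
  }
  if (any(change >= tol)) {
    abort(sprintf(
      "ec_bootstrap: median line not converged after %d resamples (last relative change: slope %.3g, intercept %.3g)",
      m, change[1], change[2]))
  }

  boot <- tibble::tibble(slope = lines[, 1], intercept = lines[, 2])
  rel$boot <- boot
  rel$m <- m
  rel$seed <- seed
  rel$sigma_f <- function(xq) {
    pred <- outer(boot$slope, xq) + boot$intercept  # m x length(xq)
    apply(pred, 2, function(p) {
      q <- quantile(p, c(0.16, 0.84), names = FALSE, type = 7)
      (q[2] - q[1]) / 2
    })
  }
  rel
}

#' Construct an emergent relation directly from line parameters
#'
#' Mainly for analysis of idealised settings: builds an `ec_relation` from a
#' known line and a known contour half-width, bypassing ensemble fitting.
#'
#' @param slope,intercept Line parameters (y per unit x; y units).
#' @param sigma_f Either a single non-negative number (constant contour
#'   half-width) or a vectorised function of x.
#' @return An `ec_relation`.
#' @export
emergent_relation <- function(slope, intercept, sigma_f) {
  sf <- if (is.function(sigma_f)) sigma_f else {
    stopifnot(sigma_f >= 0)
    function(xq) rep(sigma_f, length(xq))
  }
  structure(list(
    slope = slope, intercept = intercept, r = NA_real_, p.value = NA_real_,
    n = NA_integer_, points = NULL, boot = NULL, m = NULL, seed = NULL,
    sigma_f = sf
  ), class = "ec_relation")
}

#' @export
print.ec_relation <- function(x, ...) {
  cat("Emergent relationship\n")
  cat(sprintf("  y = %.4g + %.4g x", x$intercept, x$slope))
  if (!is.na(x$r)) cat(sprintf("   (n = %d, r = %.3f, p = %.2g)", x$n, x$r, x$p.value))
  cat("\n")
  if (!is.null(x$boot)) {
    cat(sprintf("  bootstrap: m = %d lines (seed %s)\n", x$m, format(x$seed)))
  }
  invisible(x)
}

#' @describeIn fit_emergent One row per ensemble member with fitted value
#'   and residual.
#' @param x An `ec_relation`.
#' @param ... Unused.
#' @export
tidy.ec_relation <- function(x, ...) {
  if (is.null(x$points)) abort("tidy.ec_relation: no ensemble points stored")
  dplyr::mutate(x$points,
                fitted = x$intercept + x$slope * .data$sensitivity,
                residual = .data$dgpp - .data$fitted)
}

#' @describeIn fit_emergent One-row summary (slope, intercept, r, p, n,
#'   bootstrap m).
#' @export
glance.ec_relation <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept, r = x$r,
                 p.value = x$p.value, n = x$n,
                 m_boot = x$m %||% NA_integer_)
}

#' @export
autoplot.ec_relation <- function(object, ...) {
  if (is.null(object$points)) abort("autoplot.ec_relation: no ensemble points stored")
  pts <- object$points
  xr <- range(pts$sensitivity)
  xg <- seq(xr[1] - 0.15 * diff(xr), xr[2] + 0.15 * diff(xr), length.out = 200)
  band <- tibble::tibble(x = xg, fit = object$intercept + object$slope * xg)
  p <- ggplot2::ggplot(pts, ggplot2::aes(.data$sensitivity, .data$dgpp))
  if (!is.null(object$sigma_f)) {
    sf <- object$sigma_f(xg)
    band$lo <- band$fit - sf
    band$hi <- band$fit + sf
    p <- p + ggplot2::geom_ribbon(data = band,
      ggplot2::aes(x = .data$x, ymin = .data$lo, ymax = .data$hi),
      inherit.aes = FALSE, fill = "steelblue", alpha = 0.25)
  }
  p +
    ggplot2::geom_line(data = band, ggplot2::aes(.data$x, .data$fit),
                       inherit.aes = FALSE, colour = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Historical LAI_max sensitivity (m2 m-2 per unit omega)",
                  y = "Delta GPP at 2xCO2 (Pg C yr-1)",
                  subtitle = if (!is.na(object$r))
                    sprintf("r = %.2f, p = %.2g", object$r, object$p.value)) +
    ggplot2::theme_minimal()
}

# ---- observation PDF and the constraint ------------------------------------

#' Gaussian PDF of the observed sensitivity
#'
#' Wraps the observed slope and its standard error as a Gaussian density
#' over the observable. A zero standard error yields a point-mass sentinel
#' that [ec_constrain()] handles as the delta-function limit.
#'
#' @param fit A `greening_fit`, or a numeric mean (with `sd` supplied).
#' @param sd Standard error of the observation (ignored when `fit` is a
#'   `greening_fit`).
#' @return Object of class `obs_pdf` with `mean`, `sd`, `point_mass`.
#' @export
observation_pdf <- function(fit, sd = NULL) {
  if (inherits(fit, "greening_fit")) {
    m <- fit$slope
    s <- fit$sigma_b
  } else {
    if (is.null(sd)) abort("observation_pdf: supply sd with a numeric mean")
    m <- fit
    s <- sd
  }
  if (s < 0) abort("observation_pdf: negative standard error")
  structure(list(mean = m, sd = s, point_mass = (s == 0)), class = "obs_pdf")
}

#' @export
print.obs_pdf <- function(x, ...) {
  if (x$point_mass) {
    cat(sprintf("Observation: point mass at %.6g\n", x$mean))
  } else {
    cat(sprintf("Observation PDF: Gaussian(%.6g, sd %.3g)\n", x$mean, x$sd))
  }
  invisible(x)
}

#' Constrain the projection PDF with the observed sensitivity
#'
#' Combines the observation PDF `P(x)` with the emergent relationship's
#' conditional density `P(y|x)` — Gaussian around the best-fit line with
#' the bootstrap contour half-width `sigma_f(x)` as standard deviation —
#' into the constrained projection PDF
#' `P(y) = integral P(y|x) P(x) dx`,
#' evaluated by trapezoidal quadrature on an x-grid spanning the
#' observation mean +/- `span` standard deviations. The posterior mean and
#' standard deviation are moments of the gridded `P(y)`. If the raw
#' posterior integral deviates from 1 by more than 1e-4 the grids are
#' refined once (doubled span and density); a second failure is an error.
#'
#' @param obs An `obs_pdf`.
#' @param relation An `ec_relation` with contours (from [ec_bootstrap()] or
#'   [emergent_relation()]).
#' @param nx,ny Number of x- and y-grid nodes (default 2001 each).
#' @param span Half-width of the x-grid in observation standard deviations
#'   (default 5).
#' @return Object of class `ec_constraint`: `grid` (tibble `y`, `density`),
#'   `mean`, `sd`, plus the inputs.
#' @export
ec_constrain <- function(obs, relation, nx = 2001, ny = 2001, span = 5) {
  stopifnot(inherits(obs, "obs_pdf"), inherits(relation, "ec_relation"))
  if (is.null(relation$sigma_f)) {
    abort("ec_constrain: relation has no confidence contours; run ec_bootstrap() first")
  }
  f <- function(xq) relation$intercept + relation$slope * xq

  if (obs$point_mass) {
    sf <- relation$sigma_f(obs$mean)
    if (sf <= 0) abort("ec_constrain: sigma_f is zero at a point-mass observation; the posterior is degenerate")
    mu <- f(obs$mean)
    yg <- seq(mu - span * sf, mu + span * sf, length.out = ny)
    dens <- dnorm(yg, mu, sf)
    dens <- dens / trapz(yg, dens)
    out <- list(grid = tibble::tibble(y = yg, density = dens),
                mean = trapz(yg, yg * dens),
                sd = sqrt(max(0, trapz(yg, yg^2 * dens) - trapz(yg, yg * dens)^2)),
                obs = obs, relation = relation, nx = 1L, ny = ny, span = span)
    return(structure(out, class = "ec_constraint"))
  }

  compute <- function(nx, ny, span) {
    xg <- seq(obs$mean - span * obs$sd, obs$mean + span * obs$sd,
              length.out = nx)
    sf <- relation$sigma_f(xg)
    if (any(sf <= 0)) {
      abort("ec_constrain: sigma_f must be positive on the support of the observation PDF")
    }
    px <- dnorm(xg, obs$mean, obs$sd)
    mu <- f(xg)
    yg <- seq(min(mu) - span * max(sf), max(mu) + span * max(sf),
              length.out = ny)
    # P(y_j) = int dnorm(y_j; mu(x), sf(x)) px(x) dx
    dens <- vapply(yg, function(yj) {
      trapz(xg, dnorm(yj, mu, sf) * px)
    }, numeric(1))
    list(yg = yg, dens = dens, total = trapz(yg, dens))
  }

  res <- compute(nx, ny, span)
  if (abs(res$total - 1) > 1e-4) {
    res <- compute(2 * nx - 1, 2 * ny - 1, 2 * span)
    if (abs(res$total - 1) > 1e-4) {
      abort(sprintf(
        "ec_constrain: posterior integral %.6f deviates from 1 after grid refinement",
        res$total))
    }
  }
  dens <- res$dens / res$total
  yg <- res$yg
  m1 <- trapz(yg, yg * dens)
  m2 <- trapz(yg, yg^2 * dens)
  structure(list(
    grid = tibble::tibble(y = yg, density = dens),
    mean = m1, sd = sqrt(max(0, m2 - m1^2)),
    obs = obs, relation = relation, nx = nx, ny = ny, span = span
  ), class = "ec_constraint")
}

#' @export
print.ec_constraint <- function(x, ...) {
  cat(sprintf("Emergent-constraint posterior: %.4g +/- %.3g\n", x$mean, x$sd))
  invisible(x)
}

#' @describeIn ec_constrain The gridded posterior density as a tibble.
#' @param x An `ec_constraint`.
#' @param ... Unused.
#' @export
tidy.ec_constraint <- function(x, ...) x$grid

#' @describeIn ec_constrain One-row summary (posterior mean, sd, grid size).
#' @export
glance.ec_constraint <- function(x, ...) {
  tibble::tibble(mean = x$mean, sd = x$sd, nx = x$nx, ny = x$ny,
                 span = x$span)
}

#' Unweighted ensemble-mean Gaussian PDF
#'
#' The unconstrained reference: a Gaussian with the unweighted multi-model
#' mean and the ensemble (sample) standard deviation of the projected
#' quantity.
#'
#' @param points Ensemble points with a `dgpp` column.
#' @return List of class `ensemble_pdf` with `mean`, `sd`, `n`,
#'   `point_mass` (`TRUE` when all members agree exactly).
#' @export
ensemble_pdf <- function(points) {
  check_columns(points, "dgpp", "ensemble points")
  y <- points$dgpp
  if (anyNA(y)) abort("ensemble_pdf: missing dgpp values")
  if (length(y) < 2) abort("ensemble_pdf: need at least 2 members")
  s <- sd(y)
  structure(list(mean = mean(y), sd = s, n = length(y), point_mass = (s == 0)),
            class = "ensemble_pdf")
}

#' @export
print.ensemble_pdf <- function(x, ...) {
  cat(sprintf("Ensemble Gaussian PDF: %.4g +/- %.3g (n = %d)\n",
              x$mean, x$sd, x$n))
  invisible(x)
}

#' @export
autoplot.ec_constraint <- function(object, ensemble = NULL, ...) {
  g <- object$grid
  p <- ggplot2::ggplot(g, ggplot2::aes(.data$y, .data$density)) +
    ggplot2::geom_area(fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_line(colour = "steelblue")
  if (!is.null(ensemble)) {
    ens <- tibble::tibble(y = g$y,
                          density = dnorm(g$y, ensemble$mean, ensemble$sd))
    p <- p + ggplot2::geom_line(data = ens, colour = "firebrick")
  }
  p + ggplot2::labs(x = "Delta GPP at 2xCO2 (Pg C yr-1)", y = "Density",
                    subtitle = sprintf("constrained: %.2f ± %.2f",
                                       object$mean, object$sd)) +
    ggplot2::theme_minimal()
}

#' Scale a GPP enhancement to an NPP enhancement
#'
#' Converts the constrained GPP flux change at doubled CO2 to a net primary
#' production change comparable with atmospheric-inversion estimates:
#' `dF_NPP = b * (dCO2 / CO2_pi) * dF_GPP`, with `b` the standard GPP-to-NPP
#' conversion factor 0.5 (10% relative uncertainty) and `dCO2` the
#' atmospheric CO2 increase over the comparison period. Relative
#' uncertainties of the GPP estimate and the conversion factor combine in
#' quadrature.
#'
#' @param dgpp GPP flux change (Pg C yr-1).
#' @param dgpp_sd Its standard deviation.
#' @param dco2 CO2 increase over the comparison period (ppm).
#' @param co2_pi Pre-industrial CO2 concentration (ppm, default 284).
#' @param b GPP-to-NPP conversion factor (default 0.5).
#' @param b_rel_sd Relative uncertainty of `b` (default 0.1).
#' @return Tibble with `dnpp`, `dnpp_sd`.
#' @examples
#' gpp_to_npp(3.4, 0.2, dco2 = 56.8)
#' @export
gpp_to_npp <- function(dgpp, dgpp_sd = 0, dco2, co2_pi = 284, b = 0.5,
                       b_rel_sd = 0.1) {
  if (co2_pi <= 0 || dco2 < 0) abort("gpp_to_npp: CO2 concentrations must be positive")
  dnpp <- b * (dco2 / co2_pi) * dgpp
  rel_gpp <- if (dgpp != 0) dgpp_sd / abs(dgpp) else 0
  dnpp_sd <- abs(dnpp) * sqrt(rel_gpp^2 + b_rel_sd^2)
  tibble::tibble(dnpp = dnpp, dnpp_sd = dnpp_sd)
}
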