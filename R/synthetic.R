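# run expr with a fixed RNG state, restoring the caller's state afterwards
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Configuration for a synthetic model ensemble
#'
#' Describes an ensemble of `n_members` members, each with a latent LAI_max
#' sensitivity drawn uniformly on `sens_range`, an annual driver pair
#' (smoothly rising CO2 plus growing degree days with interannual
#' variability) from which the proxy driver omega is computed, an LAI_max
#' series `lai_level + sensitivity * omega + noise`, and a projected GPP
#' change on a true emergent line `dgpp = line_intercept + line_slope *
#' sensitivity + residual`. A pseudo-observational record with a known true
#' sensitivity is generated the same way. Defaults emulate the seven-member
#' CMIP5-like setting: sensitivities spanning 0.022-0.075 m2 m-2 per unit
#' omega, an observation near 0.045, model years 1971-2005 and
#' observational years 1982-2016.
#'
#' @param n_members Number of ensemble members (>= 3).
#' @param sens_range Range `c(low, high)` of latent sensitivities
#'   (m2 m-2 per unit omega); a degenerate range (low = high) is allowed
#'   and gives the collinear case.
#' @param line_slope,line_intercept True emergent line mapping sensitivity
#'   to Delta-GPP (Pg C yr-1).
#' @param resid_sd Gaussian residual sd around the emergent line
#'   (Pg C yr-1).
#' @param years,obs_years Calendar years of the member and observation
#'   series.
#' @param lai_noise_sd Gaussian noise sd on annual LAI_max (m2 m-2).
#' @param obs_sensitivity True sensitivity of the pseudo-observation.
#' @param obs_noise_sd LAI_max noise sd of the pseudo-observation.
#' @param dgpp_sd Reported interannual sd of each member's Delta-GPP
#'   (display/error-bar value).
#' @param lai_level Baseline LAI_max level (m2 m-2).
#' @param seed Integer seed fixing all randomness.
#' @return A validated list of class `ensemble_config`.
#' @export
ensemble_config <- function(n_members = 7,
                            sens_range = c(0.022, 0.075),
                            line_slope = 60, line_intercept = 0.7,
                            resid_sd = 0.25,
                            years = 1971:2005, obs_years = 1982:2016,
                            lai_noise_sd = 0.05,
                            obs_sensitivity = 0.045, obs_noise_sd = 0.05,
                            dgpp_sd = 0.3, lai_level = 1.2, seed = 42L) {
  stopifnot(n_members >= 3, length(sens_range) == 2,
            sens_range[1] <= sens_range[2],
            resid_sd >= 0, lai_noise_sd >= 0, obs_noise_sd >= 0,
            length(years) >= 3, length(obs_years) >= 3)
  structure(as.list(environment()), class = "ensemble_config")
}

# smooth CO2 ramp plus GDD0 ramp with interannual variability; the GDD0
# variability keeps the 2x2 driver covariance anisotropic
sim_drivers <- function(years) {
  i <- seq_along(years) - 1
  tibble::tibble(
    year = years,
    co2 = 330 + 1.6 * i + 0.01 * i^2,
    gdd0 = 900 + 6 * i + rnorm(length(years), sd = 25)
  )
}

sim_member_series <- function(years, sensitivity, lai_level, lai_noise_sd) {
  drv <- sim_drivers(years)
  pca <- driver_pca(drv)
  drv$omega <- pca$omega$omega
  drv$lai_max <- lai_level + sensitivity * drv$omega +
    rnorm(length(years), sd = lai_noise_sd)
  drv
}

#' Generate a synthetic model ensemble with known ground truth
#'
#' Draws the ensemble described by an [ensemble_config()]: per-member
#' driver/LAI series, Delta-GPP values on the true emergent line, and a
#' pseudo-observation. Deterministic under the config seed. With all noise
#' set to zero the analysis pipeline recovers every latent sensitivity and
#' the emergent line exactly.
#'
#' @param cfg An `ensemble_config`.
#' @return List of class `ec_sim`: `members` (tibble with `member`,
#'   `sensitivity` (latent), `dgpp`, `dgpp_sd` and a `series` list-column of
#'   annual tibbles `year`, `co2`, `gdd0`, `omega`, `lai_max`),
#'   `observation` (list with `series` and `true_sensitivity`), and `truth`
#'   (latents, line, config).
#' @export
sim_ensemble <- function(cfg) {
  stopifnot(inherits(cfg, "ensemble_config"))
  with_seed(cfg$seed, {
    sens <- runif(cfg$n_members, cfg$sens_range[1], cfg$sens_range[2])
    members <- tibble::tibble(
      member = sprintf("member_%02d", seq_len(cfg$n_members)),
      sensitivity = sens,
      dgpp = cfg$line_intercept + cfg$line_slope * sens +
        rnorm(cfg$n_members, sd = cfg$resid_sd),
      dgpp_sd = cfg$dgpp_sd,
      series = purrr::map(sens, function(s) {
        sim_member_series(cfg$years, s, cfg$lai_level, cfg$lai_noise_sd)
      })
    )
    obs_series <- sim_member_series(cfg$obs_years, cfg$obs_sensitivity,
                                    cfg$lai_level, cfg$obs_noise_sd)
    list(
      members = members,
      observation = list(series = obs_series,
                         true_sensitivity = cfg$obs_sensitivity),
      truth = list(sensitivities = sens,
                   line_slope = cfg$line_slope,
                   line_intercept = cfg$line_intercept,
                   dgpp_at_obs = cfg$line_intercept +
                     cfg$line_slope * cfg$obs_sensitivity,
                   config = cfg)
    ) |> structure(class = "ec_sim")
  })
}

#' Configuration for a synthetic station CO2 record
#'
#' Monthly concentrations
#' `ppm = baseline + trend * t + A(t) * sin(2 pi (month - phase) / 12) + noise`
#' with `t` in years from the record start and a linearly growing seasonal
#' amplitude `A(t) = amplitude + deepening * t`, emulating the phenomenology
#' of the high-latitude stations: a rising trend, a late-summer minimum with
#' the steepest photosynthetic drawdown in June-July (the default phase 12),
#' and a deepening seasonal cycle. Defaults give a drawdown-slope change of
#' roughly -0.7 ppm/month over 30 years, the order observed at Point Barrow.
#'
#' @param years Calendar years (default 1974-2005, a 32-year record).
#' @param baseline Concentration at the record start (ppm).
#' @param trend Linear growth rate (ppm/yr).
#' @param amplitude Initial seasonal amplitude (ppm).
#' @param deepening Amplitude growth rate (ppm/yr); must keep the
#'   amplitude non-negative over the record.
#' @param phase Phase month of the sinusoid; the seasonal minimum falls at
#'   `phase - 3` (mod 12).
#' @param noise_sd White-noise sd (ppm).
#' @param seed Integer seed.
#' @return A validated list of class `station_config`.
#' @export
station_config <- function(years = 1974:2005, baseline = 330, trend = 1.7,
                           amplitude = 8, deepening = 0.045, phase = 12,
                           noise_sd = 0.2, seed = 42L) {
  stopifnot(amplitude >= 0, noise_sd >= 0, length(years) >= 2)
  if (amplitude + deepening * (length(years) - 1) < 0) {
    abort("station_config: deepening would drive the amplitude negative over the record")
  }
  structure(as.list(environment()), class = "station_config")
}

station_value <- function(cfg, year_index, month) {
  t <- year_index + (month - 1) / 12
  a <- cfg$amplitude + cfg$deepening * t
  cfg$baseline + cfg$trend * t + a * sin(2 * pi * (month - cfg$phase) / 12)
}

#' Generate a synthetic station CO2 record
#'
#' @param cfg A [station_config()].
#' @return List of class `station_sim`: `record` (tibble `site`, `year`,
#'   `month`, `ppm`) and `truth` (the config plus
#'   `drawdown_change(window)`, a function returning the analytic
#'   drawdown-slope change over a year window by exact differencing of the
#'   noiseless generator).
#' @export
sim_station <- function(cfg) {
  stopifnot(inherits(cfg, "station_config"))
  grid <- tidyr::expand_grid(year = cfg$years, month = 1:12)
  i <- match(grid$year, cfg$years) - 1
  clean <- station_value(cfg, i, grid$month)
  rec <- with_seed(cfg$seed, tibble::tibble(
    site = "SYN",
    year = grid$year, month = grid$month,
    ppm = clean + rnorm(nrow(grid), sd = cfg$noise_sd)
  ))

  analytic_change <- function(window = range(cfg$years), avg_years = 5) {
    yrs <- seq(window[1], window[2])
    mins <- vapply(yrs, function(y) {
      iy <- match(y, cfg$years) - 1
      # forward differences for months 1..12 (December uses next January)
      cur <- station_value(cfg, iy, 1:12)
      nxt <- c(cur[-1], station_value(cfg, iy + 1, 1))
      min(nxt - cur)
    }, numeric(1))
    mean(utils::tail(mins, avg_years)) - mean(utils::head(mins, avg_years))
  }

  structure(list(
    record = rec,
    truth = list(config = cfg, drawdown_change = analytic_change)
  ), class = "station_sim")
}

#' Generate a synthetic gridded monthly temperature field
#'
#' Sinusoidal annual cycle per latitude (July warmest), a meridional
#' gradient, a linear warming trend, and optional white noise — enough
#' structure to exercise the band-mean and GDD0 reductions against closed
#' forms (e.g. a uniform constant +10 C field gives GDD0 = 3650 under a
#' 365-day calendar, and a uniform warming of `warming` C/yr with all
#' months above freezing gives a GDD0 trend of `365 * warming`).
#'
#' @param years Calendar years.
#' @param lats,lons Grid cell-centre coordinates (degrees).
#' @param base_temp Annual-mean temperature at 60 N (degrees C).
#' @param lat_gradient Cooling per degree latitude north of 60 (C/deg).
#' @param amplitude Seasonal half-amplitude (C).
#' @param warming Linear warming trend (C/yr).
#' @param noise_sd White-noise sd (C).
#' @param seed Integer seed.
#' @return Tibble (`year`, `month`, `lat`, `lon`, `value`) in degrees C.
#' @export
sim_temperature <- function(years, lats = seq(62.5, 87.5, by = 5),
                            lons = seq(0, 300, by = 60),
                            base_temp = 2, lat_gradient = 0.5,
                            amplitude = 15, warming = 0, noise_sd = 0,
                            seed = 42L) {
  grid <- tidyr::expand_grid(year = years, month = 1:12, lat = lats, lon = lons)
  clean <- base_temp - lat_gradient * (grid$lat - 60) +
    amplitude * cos(2 * pi * (grid$month - 7) / 12) +
    warming * (grid$year - years[1])
  with_seed(seed, {
    grid$value <- clean + if (noise_sd > 0) rnorm(nrow(grid), sd = noise_sd) else 0
  })
  grid
}
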