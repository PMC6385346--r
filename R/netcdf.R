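#' Read a CF monthly lat/lon field from NetCDF into a long tibble
#'
#' Reads one variable from a CF-convention NetCDF file with latitude,
#' longitude and time dimensions, auto-detecting the dimension order from
#' the file metadata. Time is interpreted from the `units` attribute
#' (`"months since YYYY-MM..."` or `"days since YYYY-MM-DD"`; for day
#' units each step is mapped to its calendar month). Values equal to the
#' variable's `_FillValue`/`missing_value` are returned as `NA`.
#'
#' @param path Path to the NetCDF file.
#' @param var Variable name; defaults to the first non-coordinate variable.
#' @return Tibble with `year`, `month`, `lat`, `lon`, `value`.
#' @export
read_monthly_field <- function(path, var = NULL) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  if (is.null(var)) var <- names(nc$var)[1]
  v <- nc$var[[var]]
  if (is.null(v)) abort(sprintf("variable '%s' not found in %s", var, path))
  dimnames_nc <- vapply(v$dim, function(d) d$name, character(1))
  find_dim <- function(patterns) {
    hit <- which(tolower(dimnames_nc) %in% patterns)
    if (length(hit) != 1) abort(sprintf(
      "cannot identify dimension (%s) in %s", paste(patterns, collapse = "/"),
      paste(dimnames_nc, collapse = ", ")))
    hit
  }
  i_lat <- find_dim(c("lat", "latitude", "y"))
  i_lon <- find_dim(c("lon", "longitude", "x"))
  i_time <- find_dim(c("time", "t"))
  lats <- v$dim[[i_lat]]$vals
  lons <- v$dim[[i_lon]]$vals
  tvals <- v$dim[[i_time]]$vals
  tunits <- v$dim[[i_time]]$units

  if (grepl("^months since", tunits)) {
    origin <- as.integer(strsplit(sub("months since\\s+", "", tunits), "-")[[1]][1:2])
    total <- (origin[1] * 12 + origin[2] - 1) + round(tvals)
    year <- total %/% 12
    month <- total %% 12 + 1
  } else if (grepl("^days since", tunits)) {
    origin <- as.Date(sub("days since\\s+", "", tunits))
    dates <- origin + tvals
    year <- as.integer(format(dates, "%Y"))
    month <- as.integer(format(dates, "%m"))
  } else {
    abort(sprintf("unsupported time units '%s'", tunits))
  }

  arr <- ncdf4::ncvar_get(nc, var, collapse_degen = FALSE)
  # reorder to (lat, lon, time)
  arr <- aperm(arr, c(i_lat, i_lon, i_time))
  out <- tidyr::expand_grid(time_index = seq_along(tvals), lon = lons, lat = lats)
  out$value <- as.vector(arr)  # lat fastest, then lon, then time
  out$year <- year[out$time_index]
  out$month <- month[out$time_index]
  dplyr::select(out, "year", "month", "lat", "lon", "value")
}

#' Write a long monthly field tibble to a CF NetCDF file
#'
#' Inverse of [read_monthly_field()]; used for round-trip checks and to
#' export classified trend layers.
#'
#' @param data Tibble with `year`, `month`, `lat`, `lon` and a value column.
#' @param path Output path.
#' @param var Variable name to write.
#' @param units Units attribute for the variable.
#' @param value Value column (default `value`).
#' @return `path`, invisibly.
#' @export
write_monthly_field <- function(data, path, var = "field", units = "1",
                                value = value) {
  val <- as_name(enquo(value))
  check_columns(data, c("year", "month", "lat", "lon", val), "gridded field")
  lats <- sort(unique(data$lat))
  lons <- sort(unique(data$lon))
  times <- dplyr::distinct(data, .data$year, .data$month) %>%
    dplyr::arrange(.data$year, .data$month)
  t0y <- times$year[1]
  tvals <- (times$year - t0y) * 12 + times$month - 1
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", lats)
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", lons)
  dim_time <- ncdf4::ncdim_def("time", sprintf("months since %d-01", t0y),
                               tvals, unlim = TRUE)
  fill <- 1e30
  vdef <- ncdf4::ncvar_def(var, units, list(dim_lat, dim_lon, dim_time),
                           missval = fill)
  nc <- ncdf4::nc_create(path, vdef)
  on.exit(ncdf4::nc_close(nc))
  arr <- array(fill, dim = c(length(lats), length(lons), nrow(times)))
  idx <- cbind(match(data$lat, lats), match(data$lon, lons),
               match(paste(data$year, data$month),
                     paste(times$year, times$month)))
  vals <- data[[val]]
  vals[is.na(vals)] <- fill
  arr[idx] <- vals
  ncdf4::ncvar_put(nc, vdef, arr)
  invisible(path)
}

#' Read an ensemble-points CSV
#'
#' Columns: `member`, `sensitivity`, `sigma_b`, `dgpp`, `dgpp_sd`.
#'
#' @param path Path to the CSV file.
#' @return Tibble of ensemble points.
#' @export
read_ensemble_csv <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path))
  check_columns(out, c("member", "sensitivity", "sigma_b", "dgpp", "dgpp_sd"),
                "ensemble CSV")
  out
}
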