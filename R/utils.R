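# internal numerics shared across modules

# trapezoidal integral of y over x (x strictly increasing)
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# cumulative trapezoid, same length as x, starting at 0
cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2))
}

# population standard deviation (divisor n)
sd_pop <- function(x) {
  x <- x[!is.na(x)]
  sqrt(sum((x - mean(x))^2) / length(x))
}

check_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(data)
}

# days per month under a named calendar
days_in_month <- function(month, year, calendar = c("gregorian", "365_day", "360_day")) {
  calendar <- match.arg(calendar)
  base <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  if (calendar == "360_day") return(rep(30L, length(month)))
  d <- base[month]
  if (calendar == "gregorian") {
    leap <- (year %% 4 == 0 & year %% 100 != 0) | (year %% 400 == 0)
    d[month == 2 & leap] <- 29L
  }
  d
}
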