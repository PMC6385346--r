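test_that("the linear error model matches its closed forms", {
  # perfect fit: zero residual scale and slope error
  d <- tibble::tibble(x = 1:5, y = 2 * (1:5))
  fit <- fit_greening(d)
  expect_equal(fit$slope, 2)
  expect_equal(fit$s, 0)
  expect_equal(fit$sigma_b, 0)

  # closed-form oracle on three points
  fit <- fit_greening(tibble::tibble(x = 0:2, y = c(0, 1, 3)))
  expect_equal(fit$slope, 1.5)
  expect_equal(fit$intercept, -1 / 6)
  expect_equal(fit$s^2, 1 / 6)
  expect_equal(fit$sigma_b, sqrt(1 / 12))
})

test_that("slope and errors agree with lm under both sigma_x conventions", {
  set.seed(21)
  d <- tibble::tibble(x = rnorm(20), y = 1 + 0.5 * rnorm(20) + 2 * x)
  fit <- fit_greening(d)
  ref <- summary(lm(y ~ x, data = d))
  expect_equal(fit$slope, unname(ref$coefficients["x", "Estimate"]))
  expect_equal(fit$intercept, unname(ref$coefficients["(Intercept)", "Estimate"]))
  # population sigma_x makes sigma_b = s / sqrt(Sxx): identical to lm's SE
  expect_equal(fit$sigma_b, unname(ref$coefficients["x", "Std. Error"]))
  expect_equal(fit$s, ref$sigma)
  # the n-1 convention shrinks sigma_b by sqrt((n-1)/n)
  fit1 <- fit_greening(d, sd_divisor = "n-1")
  expect_equal(fit1$sigma_b, fit$sigma_b * sqrt((20 - 1) / 20))
})

test_that("sigma_b calibrates the sampling spread of the slope at N = 35", {
  set.seed(99)
  n <- 35
  x <- seq(-1, 1, length.out = n)
  slopes <- numeric(2000)
  sigma_b <- numeric(2000)
  for (i in seq_along(slopes)) {
    fit <- fit_greening(tibble::tibble(x = x, y = 0.3 + 1.2 * x + rnorm(n, sd = 0.4)))
    slopes[i] <- fit$slope
    sigma_b[i] <- fit$sigma_b
  }
  expect_lt(abs(sd(slopes) / mean(sigma_b) - 1), 0.15)
  expect_lt(abs(mean(slopes) - 1.2), 0.01)
})

test_that("degenerate regression inputs error", {
  expect_error(fit_greening(tibble::tibble(x = c(1, 1, 1), y = 1:3)), "constant")
  expect_error(fit_greening(tibble::tibble(x = 1:2, y = 1:2)), "at least 3")
})

test_that("Mann-Kendall S matches the brute-force pair count", {
  set.seed(5)
  for (k in 1:20) {
    v <- sample(1:6, 12, replace = TRUE)  # plenty of ties
    expect_equal(mk_test(v)$S, oracle_kendall_s(v))
  }
  inc <- 1:10
  mk <- mk_test(inc)
  expect_equal(mk$S, 45)
  expect_equal(mk$var_S, 125)
  expect_equal(mk$z, (45 - 1) / sqrt(125))
  expect_lt(mk$p.value, 0.1)
})

test_that("exact small-n Mann-Kendall null matches enumeration", {
  # enumerate all permutations of 1..5 and compare tail probabilities
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 5), ]
  s_all <- apply(perms, 1, oracle_kendall_s)
  for (v in list(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5), c(1, 3, 2, 5, 4))) {
    s <- oracle_kendall_s(v)
    p_exact <- min(1, 2 * mean(s_all >= abs(s)))
    expect_equal(mk_test(v)$p.value, p_exact)
  }
})

test_that("trend classification is invariant under monotone transforms and antisymmetric", {
  set.seed(8)
  grid <- tidyr::expand_grid(lat = c(61, 63), lon = c(0, 10), year = 2000:2014) |>
    dplyr::mutate(value = 0.5 + 0.03 * (year - 2000) * (lat == 61) + rnorm(dplyr::n(), sd = 0.05))
  base <- classify_trends(grid)
  mono <- classify_trends(dplyr::mutate(grid, value = exp(3 * value) - 1))
  expect_equal(base$label, mono$label)
  expect_equal(base$p.value, mono$p.value)

  flipped <- classify_trends(dplyr::mutate(grid, value = -value), lai_floor = -Inf)
  swap <- c(greening = "browning", browning = "greening", none = "none",
            barren = "barren")
  expect_equal(unname(swap[base$label]), flipped$label)
})

test_that("constant, short, and barren pixels are labelled correctly", {
  expect_equal(mk_test(rep(2, 12))$p.value, 1)
  grid <- tidyr::expand_grid(lat = 61, lon = c(0, 10, 20), year = 2000:2014) |>
    dplyr::mutate(value = dplyr::case_when(
      lon == 0 ~ 0,                          # bare ground
      lon == 10 ~ 1,                         # constant vegetation
      TRUE ~ 0.5 + 0.05 * (year - 2000)      # strong greening
    ))
  out <- classify_trends(grid)
  expect_equal(out$label[out$lon == 0], "barren")
  expect_equal(out$label[out$lon == 10], "none")
  expect_equal(out$label[out$lon == 20], "greening")
  short <- dplyr::filter(grid, year < 2005)
  expect_equal(unique(classify_trends(short)$label), "barren")
})

test_that("summer means reduce the field to JJA averages per pixel", {
  f <- tidyr::expand_grid(year = 2000:2001, month = 1:12, lat = 61, lon = 0) |>
    dplyr::mutate(value = ifelse(month %in% 6:8, month, 0))
  out <- summer_mean(f)
  expect_equal(out$value, c(7, 7))
})
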