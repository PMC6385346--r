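collinear_points <- function(n = 7, slope = 50, intercept = 1) {
  tibble::tibble(member = paste0("m", seq_len(n)),
                 sensitivity = seq(0.02, 0.08, length.out = n),
                 sigma_b = 0.002,
                 dgpp = intercept + slope * seq(0.02, 0.08, length.out = n),
                 dgpp_sd = 0.3)
}

test_that("the emergent fit recovers exact and noisy lines", {
  pts <- collinear_points()
  rel <- fit_emergent(pts)
  expect_equal(rel$slope, 50)
  expect_equal(rel$intercept, 1)
  expect_equal(rel$r, 1)
  expect_equal(rel$p.value, 0)

  set.seed(31)
  noisy <- dplyr::mutate(pts, dgpp = dgpp + rnorm(7, sd = 0.2))
  rel <- fit_emergent(noisy)
  se_slope <- summary(lm(dgpp ~ sensitivity, data = noisy))$coefficients[2, 2]
  expect_lt(abs(rel$slope - 50), 2 * se_slope)

  expect_error(fit_emergent(dplyr::mutate(pts, sensitivity = 0.05)), "constant")
  expect_error(fit_emergent(pts[1:2, ]), "at least 3")
})

test_that("bootstrap contours are deterministic and collapse for collinear data", {
  pts <- collinear_points()
  set.seed(777)  # contaminate global RNG state; seeded bootstrap must ignore it
  a <- ec_bootstrap(pts, seed = 11)
  b <- ec_bootstrap(pts, seed = 11)
  expect_identical(a$boot, b$boot)
  expect_identical(a$sigma_f(c(0.02, 0.05, 0.09)), b$sigma_f(c(0.02, 0.05, 0.09)))
  # all resampled fits of collinear points are the same line
  expect_equal(a$sigma_f(seq(0, 0.1, length.out = 5)), rep(0, 5))
  expect_equal(unique(round(a$boot$slope, 10)), 50)
  expect_gte(a$m, 100)

  set.seed(5)
  noisy <- dplyr::mutate(pts, dgpp = dgpp + rnorm(7, sd = 0.2))
  r1 <- ec_bootstrap(noisy, seed = 3)
  expect_true(all(r1$sigma_f(seq(0.02, 0.08, 0.01)) > 0))
  # best-fit line lies inside its own 68% band at every node
  xg <- seq(0.02, 0.08, 0.01)
  pred <- r1$intercept + r1$slope * xg
  med <- apply(outer(r1$boot$slope, xg) + r1$boot$intercept, 2, median)
  expect_true(all(abs(pred - med) <= r1$sigma_f(xg) + 1e-12))
})

test_that("observation PDFs are normalized Gaussians with a point-mass sentinel", {
  o <- observation_pdf(0, 1)
  expect_false(o$point_mass)
  expect_equal(round(dnorm(0, o$mean, o$sd), 4), 0.3989)
  g <- seq(-8, 8, length.out = 2001)
  dens <- dnorm(g, o$mean, o$sd)
  expect_equal(sum(diff(g) * (dens[-1] + dens[-length(dens)]) / 2), 1,
               tolerance = 1e-6)
  expect_true(observation_pdf(0.045, 0)$point_mass)
  fit <- fit_greening(tibble::tibble(x = 0:2, y = c(0, 1, 3)))
  of <- observation_pdf(fit)
  expect_equal(of$mean, 1.5)
  expect_equal(of$sd, sqrt(1 / 12))
})

test_that("the constraint matches the Gaussian convolution closed form", {
  slope <- 60; intercept <- 0.7; sf <- 0.3; ob <- 0.006
  rel <- emergent_relation(slope, intercept, sf)
  post <- ec_constrain(observation_pdf(0.045, ob), rel)
  expect_equal(post$mean, intercept + slope * 0.045, tolerance = 1e-4)
  expect_equal(post$sd, sqrt(sf^2 + slope^2 * ob^2), tolerance = 1e-4)
  # posterior integrates to one on its grid
  expect_equal(trapz_test(post$grid$y, post$grid$density), 1, tolerance = 1e-6)
})

test_that("point-mass observations give the delta-function limit", {
  rel <- emergent_relation(60, 0.7, 0.3)
  post <- ec_constrain(observation_pdf(0.045, 0), rel)
  expect_equal(post$mean, 0.7 + 60 * 0.045, tolerance = 1e-6)
  expect_equal(post$sd, 0.3, tolerance = 1e-4)
})

test_that("the gridded constraint agrees with a Monte-Carlo sampler", {
  set.seed(17)
  rel <- emergent_relation(45, 1, function(x) 0.2 + 2 * abs(x - 0.04))
  obs <- observation_pdf(0.05, 0.01)
  post <- ec_constrain(obs, rel)
  draws <- oracle_constrain_samples(0.05, 0.01, 45, 1, rel$sigma_f, n = 1e6)
  expect_lt(ks_grid_vs_sample(post$grid$y, post$grid$density, draws), 0.01)
})

test_that("ensemble Gaussian PDF uses unweighted moments", {
  pts <- tibble::tibble(dgpp = c(1, 3))
  e <- ensemble_pdf(pts)
  expect_equal(e$mean, 2)
  expect_equal(e$sd, sd(c(1, 3)))
  expect_true(ensemble_pdf(tibble::tibble(dgpp = c(2, 2, 2)))$point_mass)
  expect_error(ensemble_pdf(tibble::tibble(dgpp = 1)), "at least 2")
  set.seed(3)
  y <- rnorm(7, 2, 1.5)
  e7 <- ensemble_pdf(tibble::tibble(dgpp = y))
  expect_equal(e7$mean, mean(y))
  expect_equal(e7$sd, sd(y))
})

test_that("translation of the ensemble shifts the posterior mean exactly", {
  pts <- collinear_points()
  set.seed(41)
  pts$dgpp <- pts$dgpp + rnorm(7, sd = 0.2)
  obs <- observation_pdf(0.05, 0.004)
  base <- ec_constrain(obs, ec_bootstrap(pts, seed = 2))
  shifted <- dplyr::mutate(pts, dgpp = dgpp + 1.3)
  post2 <- ec_constrain(obs, ec_bootstrap(shifted, seed = 2))
  expect_equal(post2$mean - base$mean, 1.3, tolerance = 1e-8)
  expect_equal(post2$sd, base$sd, tolerance = 1e-8)
})

test_that("a constraining observation shrinks the projection spread", {
  cfg <- ensemble_config(seed = 13)
  sim <- sim_ensemble(cfg)
  pts <- ensemble_points(sim)
  obs <- observation_pdf(estimate_sensitivity(sim$observation$series))
  post <- ec_constrain(obs, ec_bootstrap(pts, seed = 13))
  ens <- ensemble_pdf(pts)
  expect_lt(post$sd, ens$sd)
})

test_that("GPP-to-NPP scaling follows the conversion identity", {
  expect_equal(gpp_to_npp(0, 0, dco2 = 56.8)$dnpp, 0)
  out <- gpp_to_npp(3.4, 0, dco2 = 56.8, co2_pi = 284, b = 0.5, b_rel_sd = 0)
  expect_equal(out$dnpp, 0.34)
  expect_equal(out$dnpp_sd, 0)
  # relative uncertainties combine in quadrature
  out <- gpp_to_npp(3.4, 0.2, dco2 = 56.8)
  expect_equal(out$dnpp_sd, 0.34 * sqrt((0.2 / 3.4)^2 + 0.1^2))
  expect_error(gpp_to_npp(3.4, 0.2, dco2 = 56.8, co2_pi = -1), "positive")
})
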