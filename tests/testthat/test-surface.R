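# evaluate a raw-coefficient quadratic
quad <- function(b, T, C)
  b[1] + b[2] * T + b[3] * C + b[4] * T^2 + b[5] * C^2 + b[6] * T * C

# dense-grid oracle for the bounded maximum
grid_max <- function(fit, n = 201L) {
  tg <- seq(fit$bounds$temperature[1], fit$bounds$temperature[2],
            length.out = n)
  cg <- seq(fit$bounds$rate[1], fit$bounds$rate[2], length.out = n)
  g <- expand.grid(T = tg, C = cg)
  v <- predict(fit, g$T, g$C)
  i <- which.max(v)
  c(T = g$T[i], C = g$C[i], val = v[i])
}

design_pts <- function() {
  g <- expand.grid(T = c(300, 500, 700), C = c(10, 20, 30))
  rbind(g, data.frame(T = 450, C = 17))  # break exact collinearity patterns
}

test_that("fit recovers a known quadratic exactly with R^2 = 1", {
  b <- c(2, 0.01, 0.4, -2e-5, -0.011, 1e-5)
  d <- design_pts()
  fit <- fit_quadratic(d$T, d$C, quad(b, d$T, d$C))
  expect_equal(unname(coef(fit)), b, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(predict(fit, 555, 12.3), quad(b, 555, 12.3),
               tolerance = 1e-8)
})

test_that("six points in general position interpolate exactly", {
  set.seed(31)
  T <- c(300, 500, 700, 350, 650, 480)
  C <- c(10, 30, 20, 25, 12, 18)
  y <- rnorm(6)
  fit <- fit_quadratic(T, C, y)
  expect_equal(predict(fit, T, C), y, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-8)
})

test_that("noisy scores give R^2 < 1 and coefficients near truth", {
  set.seed(101)
  b <- c(1, 0.012, 0.3, -1.2e-5, -7.5e-3, 0)
  g <- expand.grid(T = seq(300, 700, by = 50), C = seq(10, 30, by = 2.5))
  y <- quad(b, g$T, g$C) + rnorm(nrow(g), 0, 0.05)
  fit <- fit_quadratic(g$T, g$C, y)
  expect_lt(fit$r_squared, 1)
  expect_gt(fit$r_squared, 0.9)
  se <- sqrt(diag(vcov(fit$model)))
  # compare in the centered/scaled basis where the se's live
  sc <- fit$scaling
  u <- (g$T - sc$ct) / sc$st; v <- (g$C - sc$cc) / sc$sc
  ref <- coef(lm(quad(b, g$T, g$C) ~ u + v + I(u^2) + I(v^2) + I(u * v)))
  expect_true(all(abs(coef(fit$model) - ref) <= 3 * se))
})

test_that("degenerate designs are rejected with informative errors", {
  expect_error(fit_quadratic(1:5, 1:5, 1:5), "at least 6")
  expect_error(fit_quadratic(rep(500, 7), 1:7, rnorm(7)), "single value")
  d <- design_pts()
  expect_error(fit_quadratic(d$T, d$C, rep(2, nrow(d))), "constant")
  expect_error(fit_quadratic(c(NA, d$T[-1]), d$C, rnorm(nrow(d))),
               "non-finite")
})

test_that("bounded optimizer agrees with the dense-grid oracle", {
  d <- design_pts()
  bounds <- list(temperature = c(300, 700), rate = c(10, 30))
  cell <- c(400 / 200, 20 / 200)  # one grid cell at n = 201

  # concave paraboloid centered inside: analytic optimum
  b <- c(0, 0.02, 0.8, -2e-5, -2e-2, 0)   # center (500, 20)
  fit <- fit_quadratic(d$T, d$C, quad(b, d$T, d$C), bounds = bounds)
  opt <- optimize_surface(fit)
  expect_equal(opt$temperature, 500, tolerance = 1e-6)
  expect_equal(opt$rate, 20, tolerance = 1e-6)
  expect_false(any(opt$at_boundary))

  # monotone plane: corner maximum
  bp <- c(0, 0.01, 0.2, 0, 0, 0)
  fitp <- fit_quadratic(d$T, d$C, quad(bp, d$T, d$C) + 1e-9 * d$T^2,
                        bounds = bounds)
  optp <- optimize_surface(fitp)
  expect_equal(c(optp$temperature, optp$rate), c(700, 30))
  expect_true(all(optp$at_boundary))

  # saddle: grid-verified edge maximum
  bs <- c(0, -0.004, 0.3, 4e-6, -8e-3, 0)
  fits <- fit_quadratic(d$T, d$C, quad(bs, d$T, d$C), bounds = bounds)
  opts <- optimize_surface(fits)
  g <- grid_max(fits)
  expect_lte(abs(opts$temperature - g["T"]), cell[1])
  expect_lte(abs(opts$rate - g["C"]), cell[2])
  expect_gte(opts$predicted_score, g["val"] - 1e-9)

  # random quadratics: optimizer never loses to the grid
  set.seed(77)
  for (rep in 1:20) {
    br <- c(0, runif(2, -0.5, 0.5), runif(1, -5e-5, 5e-5),
            runif(1, -0.05, 0.05), runif(1, -1e-4, 1e-4))
    fr <- fit_quadratic(d$T, d$C, quad(br, d$T, d$C), bounds = bounds)
    orr <- optimize_surface(fr)
    gr <- grid_max(fr)
    expect_gte(orr$predicted_score, gr["val"] - 1e-9)
    # and never scores below any fitted design point
    expect_gte(orr$predicted_score, max(predict(fr, d$T, d$C)) - 1e-9)
  }
})

test_that("affine rescaling of the factors leaves the optimum invariant", {
  d <- design_pts()
  b <- c(3, 0.015, 0.5, -1.8e-5, -1.4e-2, 5e-6)
  y <- quad(b, d$T, d$C)
  bounds <- list(temperature = c(300, 700), rate = c(10, 30))
  fit <- fit_quadratic(d$T, d$C, y, bounds = bounds)
  opt <- optimize_surface(fit)
  # rescale T, C to [0,1], fit, optimize, map back
  u <- (d$T - 300) / 400; v <- (d$C - 10) / 20
  fit01 <- fit_quadratic(u, v, y,
                         bounds = list(temperature = 0:1, rate = 0:1))
  opt01 <- optimize_surface(fit01)
  expect_equal(300 + 400 * opt01$temperature, opt$temperature,
               tolerance = 1e-6)
  expect_equal(10 + 20 * opt01$rate, opt$rate, tolerance = 1e-6)
})

test_that("recommendation band brackets the optimum", {
  d <- design_pts()
  b <- c(0, 0.02, 0.8, -2e-5, -2e-2, 0)
  fit <- fit_quadratic(d$T, d$C, quad(b, d$T, d$C),
                       bounds = list(temperature = c(300, 700),
                                     rate = c(10, 30)))
  band <- recommendation_band(fit)
  opt <- optimize_surface(fit)
  expect_true(band$temperature[1] <= opt$temperature &&
                opt$temperature <= band$temperature[2])
  expect_true(band$rate[1] <= opt$rate && opt$rate <= band$rate[2])
})
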