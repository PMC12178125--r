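#' Fit a quadratic response surface score ~ (temperature, rate)
#'
#' Ordinary least squares on the full second-order model
#' `score = b0 + bT*T + bC*C + bTT*T^2 + bCC*C^2 + bTC*T*C`.
#' Internally the coordinates are centered and scaled for conditioning;
#' the reported coefficients are back-transformed to raw units. Requires
#' at least 6 points in general position.
#'
#' @param temperature,rate,score numeric vectors of equal length (one
#'   element per fitted design point). Rows with `NA` temperature (an
#'   untreated control has no pyrolysis temperature) must be excluded by
#'   the caller.
#' @param bounds list with `temperature` and `rate` range vectors used
#'   later for bounded optimization (defaults to the observed ranges).
#' @return object of class `surface_fit` with `coefficients` (named b0,
#'   bT, bC, bTT, bCC, bTC), `r_squared`, `n_points`, `bounds`, `model`
#'   (the underlying `lm`).
#' @export
fit_quadratic <- function(temperature, rate, score, bounds = NULL) {
  ok <- is.finite(temperature) & is.finite(rate) & is.finite(score)
  if (!all(ok)) stop("non-finite design points; drop controls before fitting")
  n <- length(score)
  if (length(temperature) != n || length(rate) != n)
    stop("temperature, rate and score must have equal length")
  if (n < 6L) stop("a full quadratic needs at least 6 points (got ", n, ")")
  if (diff(range(score)) == 0)
    stop("scores are constant: R-squared is undefined")
  # center/scale for conditioning
  ct <- mean(temperature); st <- stats::sd(temperature)
  cc <- mean(rate); sc <- stats::sd(rate)
  if (st == 0 || sc == 0)
    stop("design is collinear: ",
         if (st == 0) "temperature" else "rate", " takes a single value")
  u <- (temperature - ct) / st
  v <- (rate - cc) / sc
  X <- cbind(u = u, v = v, uu = u^2, vv = v^2, uv = u * v)
  if (qr(cbind(1, X))$rank < 6L)
    stop("rank-deficient quadratic design (collinear T/C terms)")
  fit <- stats::lm(score ~ u + v + I(u^2) + I(v^2) + I(u * v),
                   data = data.frame(score = score, u = u, v = v))
  b <- stats::coef(fit)
  names(b) <- c("b0", "bu", "bv", "buu", "bvv", "buv")
  # back-transform to raw T, C
  bTT <- b[["buu"]] / st^2
  bCC <- b[["bvv"]] / sc^2
  bTC <- b[["buv"]] / (st * sc)
  bT <- b[["bu"]] / st - 2 * bTT * ct - bTC * cc
  bC <- b[["bv"]] / sc - 2 * bCC * cc - bTC * ct
  b0 <- b[["b0"]] - b[["bu"]] * ct / st - b[["bv"]] * cc / sc +
    bTT * ct^2 + bCC * cc^2 + bTC * ct * cc
  coefs <- c(b0 = b0, bT = bT, bC = bC, bTT = bTT, bCC = bCC, bTC = bTC)
  r2 <- summary(fit)$r.squared
  if (is.null(bounds))
    bounds <- list(temperature = range(temperature), rate = range(rate))
  structure(list(coefficients = coefs, r_squared = r2, n_points = n,
                 bounds = bounds, model = fit,
                 scaling = list(ct = ct, st = st, cc = cc, sc = sc)),
            class = "surface_fit")
}

#' @export
coef.surface_fit <- function(object, ...) object$coefficients

#' @export
print.surface_fit <- function(x, ...) {
  cat("Quadratic surface fit on", x$n_points, "points, R^2 =",
      round(x$r_squared, 4), "\n")
  print(signif(x$coefficients, 6))
  invisible(x)
}

#' Predict from a quadratic surface fit
#'
#' @param object a [fit_quadratic()] result.
#' @param temperature,rate numeric vectors (recycled to equal length).
#' @param ... unused.
#' @return predicted scores.
#' @export
predict.surface_fit <- function(object, temperature, rate, ...) {
  b <- object$coefficients
  b[["b0"]] + b[["bT"]] * temperature + b[["bC"]] * rate +
    b[["bTT"]] * temperature^2 + b[["bCC"]] * rate^2 +
    b[["bTC"]] * temperature * rate
}

#' Maximize a fitted quadratic surface over a rectangle
#'
#' Exact bounded optimization of the quadratic: if the Hessian is
#' negative definite and the stationary point lies inside the bounds it
#' is the maximizer; otherwise the maximum lies on the boundary and is
#' found among the four edge-restricted 1-D quadratic maxima and the
#' corners.
#'
#' @param fit a [fit_quadratic()] result.
#' @param bounds optional override of the fit's rectangle, a list with
#'   `temperature` and `rate` ranges.
#' @return object of class `optimum_scheme`: `temperature`, `rate`,
#'   `predicted_score`, `at_boundary` (logical per axis).
#' @export
optimize_surface <- function(fit, bounds = fit$bounds) {
  b <- fit$coefficients
  tb <- sort(bounds$temperature); cb <- sort(bounds$rate)
  cand <- as.matrix(expand.grid(T = tb, C = cb))        # corners
  H <- matrix(c(2 * b[["bTT"]], b[["bTC"]], b[["bTC"]], 2 * b[["bCC"]]),
              2, 2)
  # interior stationary point
  if (abs(det(H)) > 1e-300) {
    sp <- solve(H, -c(b[["bT"]], b[["bC"]]))
    negdef <- H[1, 1] < 0 && det(H) > 0
    if (negdef && sp[1] >= tb[1] && sp[1] <= tb[2] &&
        sp[2] >= cb[1] && sp[2] <= cb[2])
      cand <- rbind(cand, sp)
  }
  # edge maxima: fix one coordinate, maximize the 1-D quadratic
  edge1d <- function(a2, a1) {
    # a2 x^2 + a1 x: stationary point if concave
    if (a2 < 0) -a1 / (2 * a2) else NA_real_
  }
  for (Tv in tb) {  # vertical edges: quadratic in C
    x <- edge1d(b[["bCC"]], b[["bC"]] + b[["bTC"]] * Tv)
    if (is.finite(x) && x >= cb[1] && x <= cb[2])
      cand <- rbind(cand, c(Tv, x))
  }
  for (Cv in cb) {  # horizontal edges: quadratic in T
    x <- edge1d(b[["bTT"]], b[["bT"]] + b[["bTC"]] * Cv)
    if (is.finite(x) && x >= tb[1] && x <= tb[2])
      cand <- rbind(cand, c(x, Cv))
  }
  val <- predict(fit, cand[, 1], cand[, 2])
  best <- which.max(val)
  Topt <- cand[best, 1]; Copt <- cand[best, 2]
  structure(list(temperature = unname(Topt), rate = unname(Copt),
                 predicted_score = unname(val[best]),
                 at_boundary = c(temperature = Topt %in% tb,
                                 rate = Copt %in% cb)),
            class = "optimum_scheme")
}

#' @export
print.optimum_scheme <- function(x, ...) {
  cat(sprintf("optimum: T = %.1f degC, C = %.2f t/ha, predicted score %.4f\n",
              x$temperature, x$rate, x$predicted_score))
  if (any(x$at_boundary))
    cat("  (on the boundary:",
        paste(names(x$at_boundary)[x$at_boundary], collapse = ", "), ")\n")
  invisible(x)
}

#' Near-optimal recommendation band
#'
#' Bounding box of the region of the factor rectangle whose predicted
#' score is within `tol` (relative) of the maximum, evaluated on a dense
#' grid. Reported as ranges, mirroring how scheme recommendations are
#' stated in practice ("400-500 degC, 18-20 t/ha") rather than as a
#' single point.
#'
#' @param fit a [fit_quadratic()] result.
#' @param bounds rectangle (defaults to the fit's).
#' @param tol relative tolerance below the maximum (default 0.01).
#' @param n grid resolution per axis (default 201).
#' @return list with `temperature` and `rate` ranges and the grid
#'   `maximum`.
#' @export
recommendation_band <- function(fit, bounds = fit$bounds, tol = 0.01,
                                n = 201L) {
  tg <- seq(bounds$temperature[1], bounds$temperature[2], length.out = n)
  cg <- seq(bounds$rate[1], bounds$rate[2], length.out = n)
  grid <- expand.grid(T = tg, C = cg)
  val <- predict(fit, grid$T, grid$C)
  vmax <- max(val)
  keep <- val >= vmax - tol * abs(vmax)
  list(temperature = range(grid$T[keep]), rate = range(grid$C[keep]),
       maximum = vmax)
}
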