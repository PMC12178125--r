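#' Configuration for the synthetic factorial trial generator
#'
#' Describes a two-factor factorial trial (pyrolysis temperature by
#' application rate, plus an optional untreated control) in which every
#' indicator responds as a quadratic surface with a single apex — the
#' "rise then fall" response observed in the field — plus independent
#' replicate noise. Positive indicators are concave (peak at the apex),
#' negative indicators convex (trough at the apex: the favourable, low
#' value occurs there).
#'
#' The default emulates the biochar trial: 300/500/700 degC by 10/20/30
#' t/ha plus CK, two years, ten indicators with apexes at (500, 20) and
#' magnitudes matching the published tables; noise sd is 2% of each
#' indicator's surface range over the design region. Net income (Z12) is
#' not sampled independently: it is derived from the synthetic yield via
#' the economics accounting (tuber price 1600 CNY/t, fixed costs 17115
#' CNY/ha = water 580 + fertilizer 4535 + other 12000, plus
#' `biochar_price` CNY/t of biochar in year 1), so accounting identities
#' hold in synthetic data too. Set `derive_economics = FALSE` to sample
#' Z12 from its own configured surface instead.
#'
#' @param temperature_levels,rate_levels strictly increasing factor
#'   levels.
#' @param include_control add a CK row (rate 0, no temperature)?
#' @param years number of trial years.
#' @param surfaces data.frame with one row per indicator: columns
#'   `indicator_id`, `orientation`, `T0`, `C0` (apex), `peak` (value at
#'   the apex), `curv_T`, `curv_C` (second-order coefficients per axis;
#'   negative for positive indicators, positive for negative ones),
#'   `noise_sd` (replicate noise sd; `NA` = 2% of surface range).
#' @param derive_economics derive Z12 from Z11 via the price/cost
#'   schedule (only meaningful when both ids are present)?
#' @param tuber_price CNY per tonne of yield.
#' @param fixed_costs CNY/ha of non-biochar inputs.
#' @param biochar_price CNY per tonne of biochar, charged in year 1 only
#'   (0 by default: a steady-state system in which the amendment is
#'   already in place).
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(temperature_levels = c(300, 500, 700),
                             rate_levels = c(10, 20, 30),
                             include_control = TRUE,
                             years = 2L,
                             surfaces = default_surfaces(),
                             derive_economics = TRUE,
                             tuber_price = 1600,
                             fixed_costs = 580 + 4535 + 12000,
                             biochar_price = 0) {
  stopifnot(length(temperature_levels) >= 1L, length(rate_levels) >= 1L,
            !is.unsorted(temperature_levels, strictly = TRUE),
            !is.unsorted(rate_levels, strictly = TRUE),
            years >= 1L)
  need <- c("indicator_id", "orientation", "T0", "C0", "peak",
            "curv_T", "curv_C", "noise_sd")
  if (!all(need %in% names(surfaces)))
    stop("surfaces must have columns: ", paste(need, collapse = ", "))
  bad <- (surfaces$orientation == "positive" &
            (surfaces$curv_T > 0 | surfaces$curv_C > 0)) |
         (surfaces$orientation == "negative" &
            (surfaces$curv_T < 0 | surfaces$curv_C < 0))
  if (any(bad))
    stop("curvature signs inconsistent with orientation for: ",
         paste(surfaces$indicator_id[bad], collapse = ", "))
  if (any(surfaces$noise_sd < 0, na.rm = TRUE))
    stop("noise_sd must be >= 0")
  structure(list(temperature_levels = temperature_levels,
                 rate_levels = rate_levels,
                 include_control = include_control,
                 years = as.integer(years),
                 surfaces = surfaces,
                 derive_economics = derive_economics,
                 tuber_price = tuber_price,
                 fixed_costs = fixed_costs,
                 biochar_price = biochar_price),
            class = "synthetic_config")
}

#' Default per-indicator response surfaces
#'
#' Ten indicators matching the potato evaluation system, all peaking at
#' (500 degC, 20 t/ha), with peak values and spans on the order of the
#' published tables. `noise_sd = NA` means 2% of the indicator's surface
#' range over the design region.
#'
#' @return a `data.frame` suitable for [synthetic_config()].
#' @export
default_surfaces <- function() {
  m <- potato_indicator_meta()
  pos <- m$orientation == "positive"
  # peak (best) values and a curvature giving a realistic span:
  # value drops by curv*(dT^2) from apex to the design corner
  peak <- c(Z11 = 47, Z12 = 58000, Z21 = 19.5, Z22 = 23.5, Z23 = 0.29,
            Z31 = 15, Z32 = 60, Z41 = 60, Z42 = 25, Z43 = 180)
  # span over the region (apex to worst corner), per indicator
  span <- c(Z11 = 10, Z12 = 18000, Z21 = 3.3, Z22 = 4.5, Z23 = 0.14,
            Z31 = 3.5, Z32 = 14, Z41 = 35, Z42 = 10, Z43 = 60)
  # worst corner offset from (500, 20): dT = 200, dC = 10
  # split the span evenly across the two axes
  cT <- (span / 2) / 200^2
  cC <- (span / 2) / 10^2
  sgn <- ifelse(pos, -1, 1)
  data.frame(indicator_id = m$indicator_id,
             orientation = m$orientation,
             T0 = 500, C0 = 20,
             peak = unname(peak[m$indicator_id]),
             curv_T = sgn * unname(cT[m$indicator_id]),
             curv_C = sgn * unname(cC[m$indicator_id]),
             noise_sd = NA_real_,
             stringsAsFactors = FALSE)
}

# surface value of one indicator at (T, C); for the control (no
# temperature) the temperature term is dropped, i.e. the surface is
# evaluated at the apex temperature with C = 0
.surface_value <- function(srow, temperature, rate) {
  dT2 <- if (is.na(temperature)) 0 else (temperature - srow$T0)^2
  srow$peak + srow$curv_T * dT2 + srow$curv_C * (rate - srow$C0)^2
}

.surface_range <- function(srow, config) {
  tt <- range(config$temperature_levels)
  cc <- range(config$rate_levels)
  if (config$include_control) cc[1] <- 0
  corners <- expand.grid(T = tt, C = cc)
  v <- mapply(function(T, C) .surface_value(srow, T, C),
              corners$T, corners$C)
  v <- c(v, srow$peak)
  diff(range(v))
}

#' Generate synthetic trial tables
#'
#' One [trial_table()] per year: each cell is the indicator's quadratic
#' surface at the treatment's (temperature, rate) plus an independent
#' Gaussian noise draw; the control uses the rate-0 surface value. Noise
#' draws that push a nonnegative indicator below zero are clipped at 0
#' (counted in the `clipped` attribute). Deterministic for a fixed seed.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed (set once for the whole run).
#' @return list of [trial_table()], length `config$years`, with a
#'   `clipped` attribute counting clipped draws.
#' @export
generate_trial <- function(config = synthetic_config(), seed = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(as.integer(seed))
  s <- config$surfaces
  design <- .synthetic_design(config)
  meta <- indicator_meta(s$indicator_id, orientation = s$orientation)
  nsd <- s$noise_sd
  for (i in seq_len(nrow(s)))
    if (is.na(nsd[i]))
      nsd[i] <- 0.02 * .surface_range(s[i, ], config)
  clipped <- 0L
  derive <- config$derive_economics &&
    all(c("Z11", "Z12") %in% s$indicator_id)
  out <- vector("list", config$years)
  for (y in seq_len(config$years)) {
    vals <- matrix(NA_real_, nrow(design), nrow(s),
                   dimnames = list(design$treatment_id, s$indicator_id))
    for (j in seq_len(nrow(s))) {
      mu <- mapply(function(T, C) .surface_value(s[j, ], T, C),
                   design$temperature, design$rate)
      x <- mu + stats::rnorm(length(mu), 0, nsd[j])
      if (all(s$peak[j] >= 0)) {
        clipped <- clipped + sum(x < 0)
        x <- pmax(x, 0)
      }
      vals[, j] <- x
    }
    if (derive) {
      biochar_cost <- if (y == 1L) config$biochar_price * design$rate else 0
      vals[, "Z12"] <- vals[, "Z11"] * config$tuber_price -
        config$fixed_costs - biochar_cost
    }
    out[[y]] <- trial_table(vals, meta = meta, design = design,
                            year = as.character(y))
  }
  if (clipped > 0L)
    warning(clipped, " noise draw(s) clipped at 0")
  attr(out, "clipped") <- clipped
  out
}

.synthetic_design <- function(config) {
  grid <- expand.grid(ci = seq_along(config$rate_levels),
                      ti = seq_along(config$temperature_levels))
  ids <- paste0("C", grid$ci, "T", grid$ti)
  temperature <- config$temperature_levels[grid$ti]
  rate <- config$rate_levels[grid$ci]
  if (config$include_control) {
    ids <- c("CK", ids)
    temperature <- c(NA, temperature)
    rate <- c(0, rate)
  }
  treatment_design(ids, temperature, rate)
}

#' Ground-truth optimum of a synthetic configuration
#'
#' Per indicator, the configured apex `(T0, C0)`. The composite optimum
#' is located by a dense-grid oracle over the configured factor ranges:
#' each indicator's surface is min-max standardized over the grid
#' (orientation applied, so 1 is always best), surfaces are averaged
#' with equal weights, and the grid argmax is returned.
#'
#' @param config a [synthetic_config()].
#' @param n grid resolution per axis.
#' @return list with `per_indicator` (data.frame of apexes) and
#'   `composite` (named vector `temperature`, `rate`).
#' @export
true_optimum <- function(config = synthetic_config(), n = 201L) {
  s <- config$surfaces
  tg <- seq(min(config$temperature_levels), max(config$temperature_levels),
            length.out = n)
  cg <- seq(min(config$rate_levels), max(config$rate_levels),
            length.out = n)
  grid <- expand.grid(T = tg, C = cg)
  acc <- numeric(nrow(grid))
  for (i in seq_len(nrow(s))) {
    v <- mapply(function(T, C) .surface_value(s[i, ], T, C),
                grid$T, grid$C)
    rng <- range(v)
    g <- if (diff(rng) == 0) rep(0.5, length(v))
         else if (s$orientation[i] == "positive") (v - rng[1]) / diff(rng)
         else (rng[2] - v) / diff(rng)
    acc <- acc + g
  }
  best <- which.max(acc)
  list(per_indicator = data.frame(indicator_id = s$indicator_id,
                                  T0 = s$T0, C0 = s$C0,
                                  stringsAsFactors = FALSE),
       composite = c(temperature = grid$T[best], rate = grid$C[best]))
}

#' Read a synthetic-trial configuration from YAML
#'
#' Top-level YAML keys map to [synthetic_config()] arguments; a
#' `surfaces` key, when present, is a list of per-indicator records with
#' the columns of [default_surfaces()]. Missing keys fall back to the
#' package defaults. A shipped example lives at
#' `system.file("extdata", "example_synthetic.yaml", package = "pfce")`.
#'
#' @param path YAML path.
#' @return a [synthetic_config()].
#' @export
read_synthetic_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$surfaces))
    y$surfaces <- do.call(rbind, lapply(y$surfaces, as.data.frame))
  known <- names(formals(synthetic_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown synthetic config key(s): ", paste(unknown, collapse = ", "))
  do.call(synthetic_config, y)
}
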