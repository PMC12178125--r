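#' Leaf area index
#'
#' Ratio of total leaf area to the ground area the plants occupy.
#'
#' @param total_leaf_area leaf area, m2 (`>= 0`).
#' @param ground_area occupied ground area, m2 (`> 0`).
#' @return dimensionless LAI.
#' @export
leaf_area_index <- function(total_leaf_area, ground_area) {
  if (any(ground_area <= 0)) stop("ground_area must be > 0")
  if (any(total_leaf_area < 0)) stop("total_leaf_area must be >= 0")
  total_leaf_area / ground_area
}

#' Effective-rainfall policy
#'
#' A rainfall event of depth P mm contributes a*P of plant-available water.
#' The coefficient depends on the event size: a = 0 below 5 mm; for events
#' of 5-50 mm a lies in [0.8, 1.0]; above 50 mm in [0.70, 0.80]. Both band
#' boundaries (5 and 50 mm) belong to the middle band. The exact
#' within-band coefficient is site-specific, so the policy pins one value
#' per band and validates it against the band.
#'
#' @param mid coefficient for 5-50 mm events (default 0.9).
#' @param high coefficient for > 50 mm events (default 0.75).
#' @return a list of class `rainfall_policy`.
#' @export
rainfall_policy <- function(mid = 0.9, high = 0.75) {
  if (mid < 0.8 || mid > 1.0)
    stop("mid-band coefficient must lie in [0.8, 1.0]")
  if (high < 0.70 || high > 0.80)
    stop("high-band coefficient must lie in [0.70, 0.80]")
  structure(list(mid = mid, high = high), class = "rainfall_policy")
}

#' Effective rainfall of one or more events
#'
#' @param P numeric vector of event depths, mm (`>= 0`).
#' @param policy a [rainfall_policy()].
#' @return numeric vector of effective depths a*P, mm.
#' @export
effective_rainfall <- function(P, policy = rainfall_policy()) {
  if (any(P < 0)) stop("rainfall must be >= 0")
  a <- ifelse(P < 5, 0, ifelse(P <= 50, policy$mid, policy$high))
  a * P
}

#' Seasonal crop evapotranspiration from a simplified water balance
#'
#' ET = sum of effective rainfall + irrigation - soil-moisture change - deep
#' percolation. Groundwater recharge and surface runoff are taken as zero
#' (deep water table, flat terrain).
#'
#' @param rainfall_events numeric vector of event depths, mm.
#' @param irrigation total irrigation, mm (`>= 0`).
#' @param soil_moisture_change change in 0-100 cm profile storage from
#'   sowing to harvest, mm (may be negative).
#' @param deep_percolation mm.
#' @param policy a [rainfall_policy()].
#' @return ET in mm; an error if the balance closes at `<= 0`.
#' @export
crop_et <- function(rainfall_events = numeric(), irrigation = 0,
                    soil_moisture_change = 0, deep_percolation = 0,
                    policy = rainfall_policy()) {
  if (irrigation < 0) stop("irrigation must be >= 0")
  et <- sum(effective_rainfall(rainfall_events, policy)) + irrigation -
    soil_moisture_change - deep_percolation
  if (et <= 0)
    stop("water balance closes at ET <= 0; check inputs")
  et
}

#' Water use efficiency
#'
#' WUE = Y / (10 * ET): tuber yield in kg/ha divided by seasonal water use
#' in mm gives kg of yield per cubic metre of water (the factor 10 converts
#' mm over a hectare to m3).
#'
#' @param yield kg/ha (`>= 0`).
#' @param ET mm (`> 0`).
#' @return WUE in kg/m3.
#' @export
water_use_efficiency <- function(yield, ET) {
  if (any(ET <= 0)) stop("ET must be > 0")
  if (any(yield < 0)) stop("yield must be >= 0")
  yield / (10 * ET)
}

#' Fertilizer schedule and total nutrient input
#'
#' A schedule lists each product's application rate (kg/ha) and its
#' nutrient mass fraction; the total nutrient input FT is the sum of rate
#' times fraction over products. The default is the trial schedule: urea
#' (46% N) at 652.2 kg/ha, calcium superphosphate (46% P2O5) at 391.3
#' kg/ha and potassium sulfate (45% K2O) at 666.6 kg/ha.
#'
#' @param rates numeric product rates, kg/ha (`>= 0`).
#' @param fractions matching nutrient fractions in (0, 1].
#' @return list of class `fertilizer_schedule`.
#' @export
fertilizer_schedule <- function(rates = c(urea = 652.2,
                                          superphosphate = 391.3,
                                          potassium_sulfate = 666.6),
                                fractions = c(0.46, 0.46, 0.45)) {
  if (length(rates) != length(fractions))
    stop("rates and fractions must have the same length")
  if (any(rates < 0)) stop("rates must be >= 0")
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must lie in (0, 1]")
  structure(list(rates = rates, fractions = fractions),
            class = "fertilizer_schedule")
}

#' @describeIn fertilizer_schedule total N + P2O5 + K2O input, kg/ha.
#' @param schedule a `fertilizer_schedule`.
#' @export
fertilizer_total <- function(schedule = fertilizer_schedule()) {
  sum(schedule$rates * schedule$fractions)
}

#' Partial factor productivity of fertilizer
#'
#' PFP = yield / FT, kg of tuber per kg of nutrient applied.
#'
#' @param yield kg/ha.
#' @param FT total nutrient input, kg/ha (`> 0`).
#' @return PFP in kg/kg.
#' @export
partial_factor_productivity <- function(yield, FT) {
  if (any(FT <= 0)) stop("total fertilizer input must be > 0")
  yield / FT
}

#' Net income
#'
#' Gross income minus water fee, fertilizer input (including any biochar
#' purchase) and other inputs; may be negative.
#'
#' @param gross_income,water_fee,fertilizer_input,other_input CNY/ha;
#'   costs must be `>= 0`.
#' @return net income, CNY/ha.
#' @export
net_income <- function(gross_income, water_fee, fertilizer_input,
                       other_input) {
  if (any(c(water_fee, fertilizer_input, other_input) < 0))
    stop("costs must be >= 0")
  gross_income - water_fee - fertilizer_input - other_input
}

#' Soil nutrient accumulation in a profile
#'
#' Converts a layer concentration M (mg/kg) over thickness H (cm) at bulk
#' density B (g/cm3) into an areal stock C = M * H * B / 10 (kg/ha); the
#' profile total is the sum over layers. Vector arguments are recycled to
#' the longest length and summed.
#'
#' @param M concentration per layer, mg/kg.
#' @param H layer thickness, cm (default 20).
#' @param bulk_density g/cm3.
#' @return total accumulation over the supplied layers, kg/ha.
#' @export
nutrient_accumulation <- function(M, H = 20, bulk_density) {
  if (any(M < 0) || any(H < 0) || any(bulk_density < 0))
    stop("all arguments must be >= 0")
  sum(M * H * bulk_density / 10)
}

#' Percent contrast range of a focal treatment
#'
#' For a (typically two-year averaged) trial table, computes the percent
#' contrast of the focal treatment against every other treatment for one
#' indicator: `100 * (focal/other - 1)` for `direction = "increase"`, or
#' `100 * (1 - focal/other)` for `direction = "decrease"`, and returns the
#' range over comparators.
#'
#' @param table a [trial_table()].
#' @param indicator indicator id (column of `table`).
#' @param focal focal treatment id (excluded from the comparator set).
#' @param direction `"increase"` or `"decrease"`.
#' @param comparators optional subset of treatment ids to compare against
#'   (default: all non-focal treatments).
#' @return named numeric `c(min =, max =)`, in percent, plus a
#'   `"contrasts"` attribute with the per-comparator values.
#' @export
contrast_range <- function(table, indicator, focal,
                           direction = c("increase", "decrease"),
                           comparators = NULL) {
  direction <- match.arg(direction)
  stopifnot(inherits(table, "trial_table"))
  if (!indicator %in% colnames(table$values))
    stop("unknown indicator '", indicator, "'")
  if (!focal %in% rownames(table$values))
    stop("unknown focal treatment '", focal, "'")
  col <- table$values[, indicator]
  if (is.null(comparators))
    comparators <- setdiff(rownames(table$values), focal)
  comparators <- setdiff(comparators, character(0))
  if (!length(comparators)) stop("no comparator treatments")
  others <- col[comparators]
  if (any(others <= 0))
    stop("comparator value <= 0; percent contrast undefined")
  ratio <- col[[focal]] / others
  pct <- if (direction == "increase") 100 * (ratio - 1) else 100 * (1 - ratio)
  structure(c(min = min(pct), max = max(pct)), contrasts = pct)
}
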