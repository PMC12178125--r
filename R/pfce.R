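#' Multi-level fuzzy comprehensive evaluation of a trial table
#'
#' The full pipeline for one trial year: subjective AHP weights down the
#' indicator hierarchy (with the CR < 0.1 consistency gate), objective
#' entropy weights from the data, least-squares combination of the two,
#' fuzzy five-grade evaluation of every treatment, ranking by
#' comprehensive score, and (when the design carries the factor
#' coordinates) a quadratic response-surface fit of score on
#' (temperature, rate) with a bounded optimum and a near-optimal
#' recommendation band.
#'
#' Indicators in the hierarchy that are absent from the table are dropped
#' and the remaining AHP weights renormalized, with a warning: results
#' over an indicator subset are conditional on that subset.
#'
#' @param table a [trial_table()] (one year, or a multi-year average).
#' @param hierarchy judgment-matrix hierarchy as in [default_hierarchy()].
#' @param schemes named list of [grade_scheme()]; `NULL` uses
#'   data-driven quantile schemes from [default_grade_scheme()].
#' @param negative_alpha_policy passed to [combine_weights()].
#' @param fit_surface fit the response surface? (needs a design with >= 6
#'   non-control points; set `FALSE` to skip).
#' @param surface_bounds rectangle for the bounded optimum; defaults to
#'   the design's factor ranges.
#' @return object of class `pfce` with components `weights` (list: ahp,
#'   entropy, alpha, combined), `consistency`, `evaluations` (per
#'   treatment), `scores`, `ranking`, `surface` (a [fit_quadratic()]
#'   or `NULL`), `optimum`, `band`, `table`, `schemes`,
#'   `dropped_indicators`.
#' @export
pfce <- function(table, hierarchy = default_hierarchy(), schemes = NULL,
                 negative_alpha_policy = c("fallback_equal",
                                           "absolute_normalize"),
                 fit_surface = TRUE, surface_bounds = NULL) {
  stopifnot(inherits(table, "trial_table"))
  negative_alpha_policy <- match.arg(negative_alpha_policy)

  # --- subjective weights (consistency-gated), restricted to the table
  ahp <- ahp_hierarchy_weights(hierarchy)
  present <- colnames(table$values)
  dropped <- setdiff(names(ahp$weights), present)
  extra <- setdiff(present, names(ahp$weights))
  if (length(extra))
    stop("table has indicators outside the hierarchy: ",
         paste(extra, collapse = ", "))
  w_ahp <- ahp$weights[present]
  if (length(dropped)) {
    warning("indicators absent from the table; AHP weights renormalized ",
            "over the remaining ", length(present), ": ",
            paste(dropped, collapse = ", "))
    w_ahp <- w_ahp / sum(w_ahp)
  }

  # --- objective weights and combination
  ew <- entropy_weighting(table)
  w_em <- ew$weights[present]
  comb <- combine_weights(w_ahp, w_em,
                          negative_alpha_policy = negative_alpha_policy)

  # --- fuzzy evaluation per treatment
  if (is.null(schemes)) schemes <- default_grade_scheme(table)
  evals <- lapply(rownames(table$values), function(tr)
    fuzzy_evaluate(comb$weights, build_R(table$values[tr, ], schemes)))
  names(evals) <- rownames(table$values)
  scores <- vapply(evals, `[[`, 0, "score")
  # rank by score; ties deterministically by treatment id
  ord <- order(-scores, names(scores))
  ranking <- names(scores)[ord]

  # --- response surface over the factor space
  surface <- optimum <- band <- NULL
  if (fit_surface) {
    if (is.null(table$design))
      stop("fit_surface = TRUE requires a treatment design")
    d <- table$design
    keep <- !is.na(d$temperature)          # CK has no temperature
    if (sum(keep) >= 6L) {
      if (is.null(surface_bounds))
        surface_bounds <- list(temperature = range(d$temperature[keep]),
                               rate = range(d$rate[keep]))
      surface <- fit_quadratic(d$temperature[keep], d$rate[keep],
                               scores[d$treatment_id[keep]],
                               bounds = surface_bounds)
      optimum <- optimize_surface(surface)
      band <- recommendation_band(surface)
    } else {
      warning("fewer than 6 non-control design points; surface skipped")
    }
  }

  structure(list(weights = list(ahp = w_ahp, entropy = w_em,
                                alpha = comb$alpha, combined = comb$weights,
                                method_note = comb$method_note),
                 consistency = ahp$consistency,
                 entropy = ew,
                 evaluations = evals, scores = scores, ranking = ranking,
                 surface = surface, optimum = optimum, band = band,
                 table = table, schemes = schemes,
                 dropped_indicators = dropped),
            class = "pfce")
}

#' @export
print.pfce <- function(x, ...) {
  cat("Multi-level fuzzy comprehensive evaluation",
      if (nzchar(x$table$year)) paste0("(", x$table$year, ")"), "\n")
  cat(" indicators:", paste(names(x$weights$combined), collapse = " "), "\n")
  cat(sprintf(" alpha = (%.3f, %.3f) [%s]\n", x$weights$alpha[1],
              x$weights$alpha[2], x$weights$method_note))
  best <- x$ranking[1L]
  cat(sprintf(" best treatment: %s (score %.3f, grade %s)\n", best,
              x$scores[best], x$evaluations[[best]]$grade))
  if (!is.null(x$optimum))
    cat(sprintf(" surface optimum: %.0f degC, %.1f t/ha (R^2 = %.3f)\n",
                x$optimum$temperature, x$optimum$rate,
                x$surface$r_squared))
  invisible(x)
}

#' @export
summary.pfce <- function(object, ...) {
  sc <- object$scores[object$ranking]
  df <- data.frame(
    treatment = object$ranking,
    score = unname(sc),
    grade = vapply(object$evaluations[object$ranking], `[[`, "", "grade"),
    row.names = NULL, stringsAsFactors = FALSE)
  out <- list(ranking = df,
              weights = data.frame(
                indicator = names(object$weights$combined),
                ahp = unname(object$weights$ahp),
                entropy = unname(object$weights$entropy),
                combined = unname(object$weights$combined),
                row.names = NULL),
              alpha = object$weights$alpha,
              surface = object$surface, optimum = object$optimum,
              band = object$band)
  class(out) <- "summary.pfce"
  out
}

#' @export
print.summary.pfce <- function(x, ...) {
  cat("Weights (subjective / objective / combined):\n")
  print(transform(x$weights, ahp = round(ahp, 4),
                  entropy = round(entropy, 4),
                  combined = round(combined, 4)))
  cat("\nRanking by comprehensive score:\n")
  print(transform(x$ranking, score = round(score, 4)))
  if (!is.null(x$optimum)) {
    cat("\n")
    print(x$surface)
    print(x$optimum)
    if (!is.null(x$band))
      cat(sprintf("near-optimal band: %.0f-%.0f degC, %.1f-%.1f t/ha\n",
                  x$band$temperature[1], x$band$temperature[2],
                  x$band$rate[1], x$band$rate[2]))
  }
  invisible(x)
}

#' @export
coef.pfce <- function(object, ...) object$weights$combined

#' Score-surface plot of a fitted evaluation
#'
#' Filled contour of the fitted quadratic score surface over the factor
#' rectangle, with the design points and the bounded optimum overlaid.
#'
#' @param x a [pfce()] object with a fitted surface.
#' @param n grid resolution.
#' @param ... passed to [graphics::filled.contour()].
#' @export
plot.pfce <- function(x, n = 101L, ...) {
  if (is.null(x$surface)) stop("no fitted surface to plot")
  b <- x$surface$bounds
  tg <- seq(b$temperature[1], b$temperature[2], length.out = n)
  cg <- seq(b$rate[1], b$rate[2], length.out = n)
  z <- outer(tg, cg, function(T, C) predict(x$surface, T, C))
  d <- x$table$design
  keep <- !is.na(d$temperature)
  graphics::filled.contour(
    tg, cg, z, xlab = "pyrolysis temperature (degC)",
    ylab = "application rate (t/ha)",
    plot.axes = {
      graphics::axis(1); graphics::axis(2)
      graphics::points(d$temperature[keep], d$rate[keep], pch = 19)
      graphics::points(x$optimum$temperature, x$optimum$rate, pch = 4,
                       cex = 2, lwd = 2)
    }, ...)
  invisible(x)
}
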