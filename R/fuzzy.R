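#' Five-grade scheme for one indicator
#'
#' Thresholds C1..C5 anchor the five fuzzy grades (Excellent, Good,
#' Average, Poor, Very Poor). For a positive indicator the thresholds are
#' strictly decreasing (`C1 > ... > C5`: the best grade sits at high
#' values); for a negative indicator strictly increasing.
#'
#' @param indicator_id indicator label.
#' @param orientation `"positive"` or `"negative"`.
#' @param thresholds numeric length-5 vector C1..C5.
#' @return list of class `grade_scheme`.
#' @export
grade_scheme <- function(indicator_id, orientation, thresholds) {
  orientation <- match.arg(orientation, c("positive", "negative"))
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) != 5L || anyNA(thresholds))
    stop("thresholds must be 5 finite numbers C1..C5")
  d <- diff(thresholds)
  ok <- if (orientation == "positive") all(d < 0) else all(d > 0)
  if (!ok)
    stop("thresholds for a ", orientation, " indicator must be strictly ",
         if (orientation == "positive") "decreasing" else "increasing",
         " (indicator ", indicator_id, ")")
  structure(list(indicator_id = as.character(indicator_id),
                 orientation = orientation, thresholds = thresholds),
            class = "grade_scheme")
}

#' Grade labels, best to worst
#' @export
grade_labels <- function() c("Excellent", "Good", "Average", "Poor", "Very Poor")

#' Fuzzy membership of a value in the five grades
#'
#' Piecewise-linear membership family: the extreme grades saturate beyond
#' C1 and C5 (trapezoidal shoulders), interior grades are triangular with
#' apex at their threshold. Between two adjacent thresholds the value's
#' membership is split linearly between the two grades, so the five
#' memberships always sum to 1 (partition of unity).
#'
#' @param x scalar indicator value.
#' @param scheme a [grade_scheme()].
#' @return numeric length-5 membership vector, entries in [0,1], sum 1.
#' @export
membership <- function(x, scheme) {
  stopifnot(inherits(scheme, "grade_scheme"), length(x) == 1L, is.finite(x))
  k <- scheme$thresholds
  m <- numeric(5L)
  # walk toward worse grades: for positive indicators k decreases,
  # for negative it increases; handle both by comparing "badness"
  worse <- if (scheme$orientation == "positive") `<=` else `>=`
  if (!worse(x, k[1L])) { m[1L] <- 1; return(m) }
  if (worse(x, k[5L]))  { m[5L] <- 1; return(m) }
  for (j in 1:4) {
    lo <- k[j]; hi <- k[j + 1L]        # grade j anchor -> grade j+1 anchor
    between <- if (scheme$orientation == "positive")
      (x <= lo && x > hi) else (x >= lo && x < hi)
    if (between) {
      frac <- (x - hi) / (lo - hi)     # 1 at grade-j anchor, 0 at j+1
      m[j] <- frac
      m[j + 1L] <- 1 - frac
      return(m)
    }
  }
  stop("unreachable: value not bracketed by thresholds")  # nocov
}

#' Build the fuzzy evaluation matrix R
#'
#' One row per indicator, columns = the five grades; row i is the
#' membership vector of `values[i]` under `schemes[[i]]`.
#'
#' @param values named numeric vector of indicator values.
#' @param schemes named list of [grade_scheme()], covering every value.
#' @return matrix of class `membership_matrix` (rows sum to 1).
#' @export
build_R <- function(values, schemes) {
  if (is.null(names(values))) stop("values must be named by indicator")
  missing_s <- setdiff(names(values), names(schemes))
  if (length(missing_s))
    stop("no grade scheme for indicator(s): ",
         paste(missing_s, collapse = ", "))
  R <- t(vapply(names(values),
                function(id) membership(values[[id]], schemes[[id]]),
                numeric(5L)))
  dimnames(R) <- list(names(values), grade_labels())
  structure(R, class = c("membership_matrix", "matrix"))
}

#' Weighted-average fuzzy evaluation
#'
#' Aggregates the membership matrix with indicator weights:
#' `b_j = min(1, sum_i w_i r_ij)`, grades the result by maximum
#' membership (ties resolved toward the better grade and recorded), and
#' scores it on the 5..1 semantic scale (`score = sum b_j * (6 - j)`).
#' With weights summing to 1 and rows of R summing to 1, B is itself a
#' probability vector and the clamp at 1 is never active.
#'
#' @param weights named weight vector over the indicators (rows of `R`),
#'   summing to 1.
#' @param R a [build_R()] matrix.
#' @return list of class `evaluation_result`: `B` (grade memberships),
#'   `grade` (label), `grade_index`, `score` in [1,5], `tie` (logical).
#' @export
fuzzy_evaluate <- function(weights, R) {
  if (length(weights) != nrow(R))
    stop("weight length must equal the number of indicators in R")
  if (!is.null(names(weights)) && !is.null(rownames(R)) &&
      !identical(names(weights), rownames(R)))
    stop("weights and R rows are labelled differently")
  .check_weights(stats::setNames(weights, rownames(R)), "weights")
  B <- pmin(1, as.vector(t(weights) %*% R))
  names(B) <- grade_labels()
  top <- which(B == max(B))
  idx <- top[1L]                       # ties break toward the better grade
  score <- sum(B * (5:1))
  structure(list(B = B, grade = grade_labels()[idx], grade_index = idx,
                 score = score, tie = length(top) > 1L),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat("B =", paste(sprintf("%.3f", x$B), collapse = " "), "\n")
  cat(sprintf("grade: %s%s   score: %.3f\n", x$grade,
              if (x$tie) " (tie)" else "", x$score))
  invisible(x)
}

#' Quantile-based default grade schemes
#'
#' When no expert grade thresholds are available, anchors the five grades
#' at the 0.9, 0.7, 0.5, 0.3 and 0.1 quantiles of the observed values of
#' each indicator (orientation-ordered, so the best-grade anchor sits at
#' the favourable tail). Data-driven schemes grade treatments relative to
#' the observed spread, not against external standards; results under
#' them are method demonstrations. Tied quantiles are separated by a tiny
#' jitter (with a warning); a constant indicator is an error directing
#' the user to supply thresholds.
#'
#' @param table a [trial_table()].
#' @param levels quantile levels for C1..C5 of a positive indicator,
#'   strictly decreasing in favourability (default `c(.9,.7,.5,.3,.1)`).
#' @return named list of [grade_scheme()], one per indicator.
#' @export
default_grade_scheme <- function(table, levels = c(0.9, 0.7, 0.5, 0.3, 0.1)) {
  stopifnot(inherits(table, "trial_table"), length(levels) == 5L)
  schemes <- vector("list", ncol(table$values))
  names(schemes) <- colnames(table$values)
  for (j in seq_along(schemes)) {
    x <- table$values[, j]
    if (length(unique(x)) < 2L)
      stop("indicator '", names(schemes)[j], "' is constant; supply grade ",
           "thresholds explicitly")
    orient <- table$meta$orientation[j]
    lv <- if (orient == "positive") levels else rev(levels)
    q <- unname(stats::quantile(x, probs = lv, names = FALSE, type = 7))
    if (anyDuplicated(q)) {
      eps <- max(1e-9, diff(range(x)) * 1e-9)
      step <- if (orient == "positive") -eps else eps
      for (i in 2:5) {
        cmp <- if (orient == "positive") q[i] >= q[i - 1L] else q[i] <= q[i - 1L]
        if (cmp) q[i] <- q[i - 1L] + step
      }
      warning("tied quantiles for indicator '", names(schemes)[j],
              "' separated by jitter")
    }
    schemes[[j]] <- grade_scheme(names(schemes)[j], orient, q)
  }
  schemes
}

#' Read grade schemes from CSV
#'
#' Layout: columns `indicator_id, orientation, C1, C2, C3, C4, C5`.
#'
#' @param path CSV path.
#' @return named list of [grade_scheme()].
#' @export
read_grade_schemes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("indicator_id", "orientation", paste0("C", 1:5))
  if (!all(need %in% names(df)))
    stop("grade scheme file must have columns: ", paste(need, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i)
    grade_scheme(df$indicator_id[i], df$orientation[i],
                 as.numeric(df[i, paste0("C", 1:5)])))
  stats::setNames(out, df$indicator_id)
}
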