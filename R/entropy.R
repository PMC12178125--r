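#' Min-max standardization with orientation
#'
#' Maps each indicator column to [0, 1]: positive indicators by
#' `(x - min)/(max - min)`, negative indicators by `(max - x)/(max - min)`,
#' so 1 is always the best observed value and 0 the worst. Constant
#' columns cannot be scaled and are flagged instead of divided; downstream
#' entropy weighting assigns them zero weight.
#'
#' @param table a [trial_table()] with at least two treatments.
#' @return list of class `standardized_table`: `values` (matrix in [0,1];
#'   constant columns filled with 0), `constant` (logical per column),
#'   `meta`.
#' @export
minmax_standardize <- function(table) {
  stopifnot(inherits(table, "trial_table"))
  x <- table$values
  if (nrow(x) < 2L) stop("standardization needs at least 2 treatments")
  ranges <- apply(x, 2L, range)
  span <- ranges[2L, ] - ranges[1L, ]
  constant <- span == 0
  g <- x
  for (j in seq_len(ncol(x))) {
    if (constant[j]) { g[, j] <- 0; next }
    if (table$meta$orientation[j] == "positive")
      g[, j] <- (x[, j] - ranges[1L, j]) / span[j]
    else
      g[, j] <- (ranges[2L, j] - x[, j]) / span[j]
  }
  structure(list(values = g, constant = constant, meta = table$meta,
                 min = ranges[1L, ], max = ranges[2L, ]),
            class = "standardized_table")
}

#' Entropy weights of indicators
#'
#' Objective weighting from data dispersion. On the standardized matrix G,
#' column shares P_ij = G_ij / sum_i G_ij give Shannon entropy
#' e_j = -(1/ln m) * sum_i P_ij ln P_ij (with 0 ln 0 := 0), divergence
#' d_j = 1 - e_j, and weights w_j = d_j / sum d_j. Indicators with more
#' dispersion across treatments carry more weight; constant columns get
#' d_j = 0 and hence zero weight.
#'
#' @param std a `standardized_table` from [minmax_standardize()], or a
#'   [trial_table()] (standardized internally).
#' @return list of class `entropy_weights`: `weights` (named, sums to 1),
#'   `entropy` (e_j), `divergence` (d_j), `constant`.
#' @export
entropy_weighting <- function(std) {
  if (inherits(std, "trial_table")) std <- minmax_standardize(std)
  stopifnot(inherits(std, "standardized_table"))
  g <- std$values
  m <- nrow(g)
  if (m < 2L) stop("entropy weighting needs at least 2 treatments")
  e <- numeric(ncol(g))
  names(e) <- colnames(g)
  for (j in seq_len(ncol(g))) {
    if (std$constant[j]) { e[j] <- 1; next }  # no information
    s <- sum(g[, j])
    if (s == 0) { e[j] <- 1; next }
    p <- g[, j] / s
    plogp <- ifelse(p > 0, p * log(p), 0)
    e[j] <- -sum(plogp) / log(m)
  }
  d <- 1 - e
  d[std$constant] <- 0
  if (sum(d) <= 0)
    stop("all indicators are constant: entropy weights are undefined")
  structure(list(weights = d / sum(d), entropy = e, divergence = d,
                 constant = std$constant),
            class = "entropy_weights")
}

#' @export
print.entropy_weights <- function(x, ...) {
  df <- data.frame(entropy = round(x$entropy, 4),
                   divergence = round(x$divergence, 4),
                   weight = round(x$weights, 4))
  print(df)
  invisible(x)
}

#' Per-indicator entropy diagnostics table
#'
#' Convenience export of the quantities behind the entropy weights (min,
#' max, entropy, divergence, weight per indicator), suitable for writing
#' to CSV.
#'
#' @param table a [trial_table()].
#' @return a `data.frame`, one row per indicator.
#' @export
entropy_diagnostics <- function(table) {
  std <- minmax_standardize(table)
  ew <- entropy_weighting(std)
  data.frame(indicator_id = colnames(table$values),
             min = std$min, max = std$max,
             entropy = ew$entropy, divergence = ew$divergence,
             weight = ew$weights, constant = ew$constant,
             row.names = NULL, stringsAsFactors = FALSE)
}
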