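#' Least-squares combination of two weight vectors
#'
#' Fuses a subjective (AHP) and an objective (entropy) weight vector into
#' `alpha1 * W1 + alpha2 * W2`. The combination coefficients solve the
#' deviation-minimizing normal equations
#' `[[W1'W1, W1'W2], [W2'W1, W2'W2]] alpha = [W1'W1, W2'W2]`,
#' after which alpha is normalized to sum 1. Two degenerate situations are
#' handled by policy: a singular system (W1 = W2) and a normalized alpha
#' with a negative component. The default policy (`"fallback_equal"`)
#' falls back to alpha = (0.5, 0.5) and records it;
#' `"absolute_normalize"` instead normalizes |alpha|.
#'
#' @param W1,W2 named weight vectors over the same labels in the same
#'   order, each summing to 1.
#' @param negative_alpha_policy `"fallback_equal"` or
#'   `"absolute_normalize"`.
#' @return list of class `combination_result`: `alpha` (length 2, sums to
#'   1), `weights` (combined vector, sums to 1), `method_note` (`"raw"`,
#'   `"normalized"` or `"fallback"`).
#' @export
combine_weights <- function(W1, W2,
                            negative_alpha_policy = c("fallback_equal",
                                                      "absolute_normalize")) {
  negative_alpha_policy <- match.arg(negative_alpha_policy)
  if (length(W1) != length(W2) ||
      !identical(names(W1), names(W2)) || is.null(names(W1)))
    stop("W1 and W2 must share the same labels in the same order")
  .check_weights(W1, "W1")
  .check_weights(W2, "W2")
  gram <- rbind(c(sum(W1 * W1), sum(W1 * W2)),
                c(sum(W2 * W1), sum(W2 * W2)))
  rhs <- c(sum(W1 * W1), sum(W2 * W2))
  note <- "raw"
  if (abs(det(gram)) < 1e-12) {
    alpha <- c(0.5, 0.5)
    note <- "fallback"
  } else {
    alpha <- solve(gram, rhs)
    if (abs(sum(alpha) - 1) > 1e-12) {
      alpha <- alpha / sum(alpha)
      note <- "normalized"
    }
    if (any(alpha < 0)) {
      if (negative_alpha_policy == "absolute_normalize") {
        alpha <- abs(alpha) / sum(abs(alpha))
        note <- "normalized"
      } else {
        alpha <- c(0.5, 0.5)
        note <- "fallback"
      }
    }
  }
  combined <- alpha[1L] * W1 + alpha[2L] * W2
  combined <- combined / sum(combined)
  structure(list(alpha = alpha, weights = combined, method_note = note),
            class = "combination_result")
}

#' @export
print.combination_result <- function(x, ...) {
  cat(sprintf("alpha = (%.4f, %.4f)  [%s]\n", x$alpha[1L], x$alpha[2L],
              x$method_note))
  print(round(x$weights, 4))
  invisible(x)
}
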