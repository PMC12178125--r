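#' Judgment matrix (pairwise comparisons on the Saaty 1-9 scale)
#'
#' Validates a square positive reciprocal matrix of pairwise importance
#' ratios: unit diagonal, `b[j,i] = 1/b[i,j]` (relative tolerance 1e-9),
#' all entries positive. Entries outside the Saaty set {1..9 and their
#' reciprocals} are legal but draw a warning.
#'
#' @param entries square numeric matrix.
#' @param labels criterion/indicator labels (default: dimnames or L1..Ln).
#' @return the validated matrix, of class `judgment_matrix`.
#' @export
judgment_matrix <- function(entries, labels = NULL) {
  entries <- as.matrix(entries)
  n <- nrow(entries)
  if (n != ncol(entries) || n < 1L) stop("judgment matrix must be square")
  if (is.null(labels))
    labels <- if (!is.null(rownames(entries))) rownames(entries)
              else paste0("L", seq_len(n))
  if (any(!is.finite(entries)) || any(entries <= 0)) {
    bad <- which(!is.finite(entries) | entries <= 0, arr.ind = TRUE)[1L, ]
    stop("non-positive entry at (", labels[bad[1L]], ", ", labels[bad[2L]], ")")
  }
  if (any(abs(diag(entries) - 1) > 1e-9))
    stop("diagonal entries must all be 1")
  rec <- abs(entries * t(entries) - 1) > 1e-9 * pmax(entries * t(entries), 1)
  if (any(rec)) {
    bad <- which(rec, arr.ind = TRUE)[1L, ]
    stop("entries (", labels[bad[1L]], ", ", labels[bad[2L]],
         ") and its transpose are not reciprocal")
  }
  saaty <- c(1:9, 1 / (2:9))
  off <- entries[upper.tri(entries)]
  if (length(off) && any(vapply(off, function(v)
        min(abs(v - saaty)) > 1e-6, TRUE)))
    warning("judgment matrix has entries outside the 1-9 Saaty scale")
  dimnames(entries) <- list(labels, labels)
  structure(entries, class = c("judgment_matrix", "matrix"))
}

#' AHP weights by the geometric-mean (root) method
#'
#' Each criterion's weight is the n-th root of its row product, normalized
#' to sum 1. For a perfectly consistent matrix this coincides with the
#' principal eigenvector.
#'
#' @param matrix a [judgment_matrix()].
#' @return named weight vector summing to 1.
#' @export
ahp_weights <- function(matrix) {
  matrix <- judgment_matrix(matrix)
  n <- nrow(matrix)
  # row geometric means via logs for numerical stability
  g <- exp(rowMeans(log(matrix)))
  w <- g / sum(g)
  names(w) <- rownames(matrix)
  w
}

#' Maximum-eigenvalue estimate from a weight vector
#'
#' lambda_i = (B w)_i / w_i averaged over rows; equals the matrix order for
#' a perfectly consistent matrix, and approximates the dominant eigenvalue
#' when `weights` approximates the principal eigenvector.
#'
#' @param matrix a [judgment_matrix()].
#' @param weights positive weights, same length as the matrix order.
#' @return scalar lambda_max estimate.
#' @export
lambda_max <- function(matrix, weights = ahp_weights(matrix)) {
  matrix <- judgment_matrix(matrix)
  if (length(weights) != nrow(matrix)) stop("dimension mismatch")
  if (any(weights <= 0)) stop("weights must be positive")
  mean((matrix %*% weights) / weights)
}

# RI lookup: random consistency index for matrix orders 1..10
.ahp_ri <- c(0, 0, 0.58, 0.9, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49)

#' Consistency check of a judgment matrix
#'
#' CI = (lambda_max - n)/(n - 1); CR = CI/RI with the tabulated random
#' index RI for orders up to 10. Orders 1 and 2 have RI = 0 and are always
#' consistent (CR set to 0). The matrix passes when CR < 0.1.
#'
#' @param matrix a [judgment_matrix()] of order at most 10.
#' @return list of class `consistency_report` with `lambda_max`, `CI`,
#'   `RI`, `CR` and `passes`.
#' @export
consistency <- function(matrix) {
  matrix <- judgment_matrix(matrix)
  n <- nrow(matrix)
  if (n > length(.ahp_ri))
    stop("consistency check supports orders up to ", length(.ahp_ri))
  lam <- lambda_max(matrix)
  ci <- if (n >= 2L) (lam - n) / (n - 1) else 0
  ri <- .ahp_ri[n]
  cr <- if (ri == 0) 0 else ci / ri
  structure(list(lambda_max = lam, CI = ci, RI = ri, CR = cr,
                 passes = cr < 0.1, order = n),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf(
    "order %d: lambda_max = %.4f, CI = %.4f, RI = %.2f, CR = %.4f (%s)\n",
    x$order, x$lambda_max, x$CI, x$RI, x$CR,
    if (x$passes) "passes, CR < 0.1" else "FAILS, CR >= 0.1"))
  invisible(x)
}

#' Compose hierarchy weights down to the leaf indicators
#'
#' Multiplies each criterion's weight by its within-criterion indicator
#' weights and flattens, so the leaf weights sum to 1.
#'
#' @param criteria named weight vector over criteria (sums to 1).
#' @param sub_weights named list (one element per criterion, same names)
#'   of within-criterion weight vectors, each summing to 1 and named by
#'   leaf indicator.
#' @return named leaf weight vector summing to 1.
#' @export
hierarchy_weights <- function(criteria, sub_weights) {
  if (is.null(names(criteria)) || is.null(names(sub_weights)))
    stop("criteria and sub_weights must be named")
  if (!setequal(names(criteria), names(sub_weights)))
    stop("criteria and sub_weights names differ: ",
         paste(symdiff <- union(setdiff(names(criteria), names(sub_weights)),
                                setdiff(names(sub_weights), names(criteria))),
               collapse = ", "))
  .check_weights(criteria, "criteria")
  out <- unlist(lapply(names(criteria), function(k) {
    sw <- sub_weights[[k]]
    .check_weights(sw, paste0("sub_weights$", k))
    criteria[[k]] * sw
  }))
  out
}

.check_weights <- function(w, what) {
  if (any(w < 0)) stop(what, " has a negative weight")
  if (abs(sum(w) - 1) > 1e-8)
    stop(what, " must sum to 1 (got ", format(sum(w)), ")")
  if (is.null(names(w)) || !all(nzchar(names(w))))
    stop(what, " must be fully named")
  invisible(w)
}

#' Aggregate several experts' judgment matrices
#'
#' Optional helper: combines matrices element-wise by the geometric mean,
#' which preserves reciprocity. Provided for panels of experts; the
#' package takes single matrices as the primary input.
#'
#' @param matrices list of [judgment_matrix()] of identical order/labels.
#' @return a single `judgment_matrix`.
#' @export
aggregate_judgments <- function(matrices) {
  stopifnot(length(matrices) >= 1L)
  ms <- lapply(matrices, judgment_matrix)
  ref <- dimnames(ms[[1L]])
  for (m in ms[-1L])
    if (!identical(dimnames(m), ref))
      stop("matrices must share order and labels")
  logsum <- Reduce(`+`, lapply(ms, log))
  judgment_matrix(exp(logsum / length(ms)), labels = ref[[1L]])
}

#' Example evaluation hierarchy for the potato indicator system
#'
#' Default pairwise-comparison matrices over the four criteria (economic
#' benefit Z1, tuber quality Z2, water/fertilizer efficiency Z3,
#' environmental benefit Z4) and their leaf indicators. These are
#' illustrative defaults, not elicited expert matrices: economic benefit
#' carries the greatest importance, mirroring the stated priorities of
#' local producers. All matrices pass the CR < 0.1 gate.
#'
#' @return named list with `criteria` (a [judgment_matrix()]) and `sub`
#'   (named list of judgment matrices per criterion, leaf-labelled).
#' @export
default_hierarchy <- function() {
  crit <- judgment_matrix(rbind(
    c(1,   3,   2,   4),
    c(1/3, 1,   1/2, 2),
    c(1/2, 2,   1,   3),
    c(1/4, 1/2, 1/3, 1)
  ), labels = c("Z1", "Z2", "Z3", "Z4"))
  sub <- list(
    Z1 = judgment_matrix(rbind(c(1, 2), c(1/2, 1)),
                         labels = c("Z11", "Z12")),
    Z2 = judgment_matrix(rbind(c(1, 2, 3), c(1/2, 1, 2), c(1/3, 1/2, 1)),
                         labels = c("Z21", "Z22", "Z23")),
    Z3 = judgment_matrix(rbind(c(1, 2), c(1/2, 1)),
                         labels = c("Z31", "Z32")),
    Z4 = judgment_matrix(rbind(c(1, 2, 2), c(1/2, 1, 1), c(1/2, 1, 1)),
                         labels = c("Z41", "Z42", "Z43"))
  )
  list(criteria = crit, sub = sub)
}

#' Leaf weights of a hierarchy of judgment matrices
#'
#' Runs the full subjective-weighting chain: validates every matrix,
#' enforces the CR < 0.1 consistency gate, extracts geometric-mean weights
#' at each level and composes them down to the leaves.
#'
#' @param hierarchy list with elements `criteria` and `sub` as returned by
#'   [default_hierarchy()].
#' @return list with `weights` (leaf weight vector), `criteria_weights`,
#'   and `consistency` (named list of [consistency()] reports).
#' @export
ahp_hierarchy_weights <- function(hierarchy = default_hierarchy()) {
  crit <- judgment_matrix(hierarchy$criteria)
  mats <- c(list(criteria = crit), hierarchy$sub)
  reports <- lapply(mats, consistency)
  failed <- names(reports)[!vapply(reports, `[[`, TRUE, "passes")]
  if (length(failed))
    stop("judgment matrix failed the consistency gate (CR >= 0.1): ",
         paste(failed, collapse = ", "))
  cw <- ahp_weights(crit)
  sw <- lapply(hierarchy$sub, ahp_weights)
  list(weights = hierarchy_weights(cw, sw[names(cw)]),
       criteria_weights = cw, consistency = reports)
}

#' Read a judgment matrix from CSV
#'
#' Square labelled layout: header row of labels, first column of labels,
#' numeric body. Entries may be fractions written as decimals.
#'
#' @param path CSV path.
#' @return a [judgment_matrix()].
#' @export
read_judgment_matrix <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, row.names = 1L)
  judgment_matrix(as.matrix(raw), labels = rownames(raw))
}
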