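# shared fixtures and independent oracles

# power-iteration dominant eigenvector/value of a positive matrix;
# independent of the package's geometric-mean weight extraction
power_iteration <- function(m, iters = 500L, tol = 1e-14) {
  v <- rep(1, nrow(m)) / nrow(m)
  lam <- NA_real_
  for (i in seq_len(iters)) {
    w <- as.vector(m %*% v)
    lam_new <- sum(w) / sum(v)
    w <- w / sum(w)
    if (max(abs(w - v)) < tol) { v <- w; lam <- lam_new; break }
    v <- w; lam <- lam_new
  }
  list(vector = v, value = lam)
}

# random reciprocal judgment matrix with entries on the Saaty scale
random_reciprocal <- function(n) {
  saaty <- c(1:9, 1 / (2:9))
  m <- diag(n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    m[i, j] <- sample(saaty, 1L)
    m[j, i] <- 1 / m[i, j]
  }
  m
}

# perfectly consistent matrix built from a weight vector
consistent_matrix <- function(w) outer(w, w, `/`)

# tiny trial table: values matrix with default meta/orientations
tiny_table <- function(values, orientation = "positive", year = "t") {
  if (is.null(colnames(values)))
    colnames(values) <- paste0("I", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- paste0("trt", seq_len(nrow(values)))
  trial_table(values,
              meta = indicator_meta(colnames(values),
                                    orientation = orientation),
              year = year)
}

# equal-weight hierarchy over the ten-indicator potato system
equal_hierarchy <- function() {
  ones <- function(n, labs) judgment_matrix(matrix(1, n, n), labels = labs)
  list(criteria = ones(4, c("Z1", "Z2", "Z3", "Z4")),
       sub = list(Z1 = ones(2, c("Z11", "Z12")),
                  Z2 = ones(3, c("Z21", "Z22", "Z23")),
                  Z3 = ones(2, c("Z31", "Z32")),
                  Z4 = ones(3, c("Z41", "Z42", "Z43"))))
}
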