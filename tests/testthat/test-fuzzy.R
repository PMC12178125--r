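pos_scheme <- function(th = c(90, 70, 50, 30, 10))
  grade_scheme("p", "positive", th)
neg_scheme <- function(th = c(10, 30, 50, 70, 90))
  grade_scheme("n", "negative", th)

test_that("grade scheme enforces orientation-consistent monotone thresholds", {
  expect_silent(pos_scheme())
  expect_silent(neg_scheme())
  expect_error(grade_scheme("x", "positive", c(10, 30, 50, 70, 90)),
               "strictly decreasing")
  expect_error(grade_scheme("x", "negative", c(90, 70, 50, 30, 10)),
               "strictly increasing")
  expect_error(grade_scheme("x", "positive", c(90, 70, 70, 30, 10)),
               "strictly")
})

test_that("membership saturates, peaks at thresholds, interpolates between", {
  s <- pos_scheme()
  expect_equal(membership(95, s), c(1, 0, 0, 0, 0))
  expect_equal(membership(90, s), c(1, 0, 0, 0, 0))
  expect_equal(membership(50, s), c(0, 0, 1, 0, 0))     # apex of grade 3
  expect_equal(membership(80, s), c(0.5, 0.5, 0, 0, 0)) # midway C2..C1
  expect_equal(membership(5, s), c(0, 0, 0, 0, 1))
  n <- neg_scheme()
  expect_equal(membership(5, n), c(1, 0, 0, 0, 0))      # small is best
  expect_equal(membership(50, n), c(0, 0, 1, 0, 0))
  expect_equal(membership(95, n), c(0, 0, 0, 0, 1))
  expect_equal(membership(80, n), c(0, 0, 0, 0.5, 0.5))
})

test_that("memberships are a partition of unity over random draws", {
  set.seed(19)
  for (rep in 1:500) {
    th <- sort(runif(5, -50, 50), decreasing = TRUE)
    if (anyDuplicated(th)) next
    orient <- sample(c("positive", "negative"), 1)
    s <- grade_scheme("r", orient,
                      if (orient == "positive") th else rev(th))
    for (x in runif(20, -80, 80)) {
      m <- membership(x, s)
      expect_equal(sum(m), 1, tolerance = 1e-12)
      expect_true(all(m >= 0 & m <= 1))
    }
  }
})

test_that("membership row score is monotone in a positive indicator", {
  s <- pos_scheme()
  xs <- seq(0, 100, by = 0.5)
  scores <- vapply(xs, function(x) sum(membership(x, s) * (5:1)), 0)
  expect_true(all(diff(scores) >= -1e-12))
})

test_that("build_R stacks membership rows in order", {
  s <- list(a = pos_scheme(), b = neg_scheme())
  R <- build_R(c(a = 95, b = 5), s)
  expect_equal(dim(R), c(2L, 5L))
  expect_equal(unname(R[, 1]), c(1, 1))
  R2 <- build_R(c(a = 80, b = 80), s)
  expect_equal(unname(R2["a", ]), c(0.5, 0.5, 0, 0, 0))
  expect_equal(unname(R2["b", ]), c(0, 0, 0, 0.5, 0.5))
  expect_error(build_R(c(a = 1, c = 2), s), "no grade scheme")
  R1 <- build_R(c(a = 42), s["a"])
  expect_equal(unname(R1[1, ]), membership(42, s$a))
})

test_that("weighted-average evaluation grades and scores correctly", {
  onesR <- matrix(c(1, 0, 0, 0, 0), 3, 5, byrow = TRUE,
                  dimnames = list(c("x", "y", "z"), grade_labels()))
  class(onesR) <- c("membership_matrix", "matrix")
  r <- fuzzy_evaluate(c(x = 0.2, y = 0.5, z = 0.3), onesR)
  expect_equal(unname(r$B), c(1, 0, 0, 0, 0))
  expect_equal(r$grade, "Excellent")
  expect_equal(r$score, 5)

  R <- rbind(c(1, 0, 0, 0, 0), c(0, 1, 0, 0, 0))
  rownames(R) <- c("x", "y"); colnames(R) <- grade_labels()
  r2 <- fuzzy_evaluate(c(x = 0.5, y = 0.5), R)
  expect_equal(unname(r2$B), c(0.5, 0.5, 0, 0, 0))
  expect_equal(r2$score, 4.5)
  expect_true(r2$tie)
  expect_equal(r2$grade, "Excellent")  # tie resolved toward better grade

  # uniform memberships score the scale midpoint
  Ru <- matrix(0.2, 1, 5, dimnames = list("x", grade_labels()))
  expect_equal(fuzzy_evaluate(c(x = 1), Ru)$score, 3)
  expect_error(fuzzy_evaluate(c(x = 0.5), onesR), "length")
})

test_that("scores stay in [1,5] and the min-clamp is never active", {
  set.seed(23)
  for (rep in 1:50) {
    k <- sample(2:10, 1)
    w <- runif(k); w <- w / sum(w); names(w) <- paste0("i", 1:k)
    vals <- runif(k, -10, 110); names(vals) <- names(w)
    schemes <- lapply(names(w), function(id)
      grade_scheme(id, "positive", sort(runif(5, 0, 100),
                                        decreasing = TRUE)))
    names(schemes) <- names(w)
    R <- build_R(vals, schemes)
    res <- fuzzy_evaluate(w, R)
    expect_true(res$score >= 1 - 1e-9 && res$score <= 5 + 1e-9)
    expect_equal(sum(res$B), 1, tolerance = 1e-9)
    expect_true(all(as.vector(t(w) %*% unclass(R)) <= 1 + 1e-12))
  }
})

test_that("quantile default schemes sit at the stated quantiles", {
  t <- tiny_table(cbind(a = 1:10))
  s <- default_grade_scheme(t)
  expect_equal(s$a$thresholds,
               unname(quantile(1:10, c(0.9, 0.7, 0.5, 0.3, 0.1))))
  tn <- tiny_table(cbind(a = 1:10), orientation = "negative")
  sn <- default_grade_scheme(tn)
  expect_equal(sn$a$thresholds,
               unname(quantile(1:10, c(0.1, 0.3, 0.5, 0.7, 0.9))))
  expect_error(default_grade_scheme(tiny_table(cbind(a = rep(2, 5)))),
               "constant")
  # two distinct values: jitter keeps the scheme strictly monotone
  expect_warning(s2 <- default_grade_scheme(
    tiny_table(cbind(a = c(1, 1, 1, 10, 10)))), "jitter")
  expect_true(all(diff(s2$a$thresholds) < 0))
})

test_that("grade schemes round-trip through CSV", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("indicator_id,orientation,C1,C2,C3,C4,C5",
               "a,positive,90,70,50,30,10",
               "b,negative,10,30,50,70,90"), f)
  s <- read_grade_schemes(f)
  expect_equal(s$a$thresholds, c(90, 70, 50, 30, 10))
  expect_equal(s$b$orientation, "negative")
})
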