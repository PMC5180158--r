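# Construct an ellipse_summary directly from a centroid and covariance,
# for geometry cases with known closed forms.
ellipse_from_cov <- function(centroid, S, label = "g") {
  structure(list(label = label, centroid = centroid, cov = S, n = Inf,
                 SEA = pi * sqrt(det(S)), SEAc = pi * sqrt(det(S))),
            class = "ellipse_summary")
}

test_that("standard ellipse area matches the hand-computed cross fixture", {
  g <- group_observations("cross", c(1, -1, 0, 0), c(0, 0, 1, -1))
  es <- standard_ellipse(g)
  expect_equal(es$cov, diag(2 / 3, 2), ignore_attr = TRUE)
  expect_equal(es$SEA, 2 * pi / 3)
  expect_equal(es$SEAc, es$SEA * 3 / 2)  # n = 4
  # scaled cross has exact identity sample covariance, SEA = pi
  g2 <- group_observations("unit", sqrt(1.5) * c(1, -1, 0, 0),
                           sqrt(1.5) * c(0, 0, 1, -1))
  expect_equal(standard_ellipse(g2)$SEA, pi)
})

test_that("SEAc/SEA equals (n-1)/(n-2) and large-sample SEA approaches pi", {
  for (n in c(5, 17, 60)) {
    set.seed(n)
    es <- standard_ellipse(group_observations("g", rnorm(n), rnorm(n)))
    expect_equal(es$SEAc / es$SEA, (n - 1) / (n - 2))
  }
  set.seed(100)
  big <- standard_ellipse(group_observations("big", rnorm(4000), rnorm(4000)))
  expect_equal(big$SEA, pi, tolerance = 0.05)
})

test_that("degenerate point clouds are rejected", {
  expect_error(standard_ellipse(group_observations("two", c(1, 2), c(1, 2))),
               "3 points")
  line <- group_observations("line", 1:5, 2 * (1:5) + 3)
  expect_error(standard_ellipse(line), "degenerate|collinear")
  same <- group_observations("same", rep(1, 4), rep(2, 4))
  expect_error(standard_ellipse(same), "degenerate|collinear")
})

test_that("SEA is invariant under rotation/translation and scales with det", {
  set.seed(7)
  x <- rnorm(40, 0, 1.3)
  y <- 0.5 * x + rnorm(40, 0, 0.8)
  base <- standard_ellipse(group_observations("g", x, y))$SEA
  th <- 0.6
  xr <- cos(th) * x - sin(th) * y + 10
  yr <- sin(th) * x + cos(th) * y - 4
  expect_equal(standard_ellipse(group_observations("r", xr, yr))$SEA, base)
  a <- 2.5; b <- 0.4
  expect_equal(standard_ellipse(group_observations("s", a * x, b * y))$SEA,
               base * a * b)
})

test_that("Bayesian SEA posterior concentrates on SEA as n grows", {
  err <- vapply(c(30, 300, 3000), function(n) {
    set.seed(n + 1)
    g <- group_observations("g", rnorm(n, 0, 1.2), rnorm(n, 5, 0.9))
    es <- sea_bayes(g, draws = 2000, seed = 2)
    abs(es$SEA_B[["50%"]] - es$SEA) / es$SEA
  }, 0)
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 0.05)
})

test_that("credible-interval width shrinks with sample size on nested data", {
  set.seed(31)
  x <- rnorm(3000); y <- rnorm(3000)
  widths <- vapply(c(30, 300, 3000), function(n) {
    es <- sea_bayes(group_observations("g", x[1:n], y[1:n]),
                    draws = 2000, seed = 3)
    (es$SEA_B[["97.5%"]] - es$SEA_B[["2.5%"]]) / es$SEA_B[["50%"]]
  }, 0)
  expect_true(all(diff(widths) < 0))
})

test_that("groups from one distribution have overlapping SEA_B intervals", {
  set.seed(37)
  g1 <- group_observations("a", rnorm(40, -17, 1), rnorm(40, 10, 1.4))
  g2 <- group_observations("b", rnorm(40, -17, 1), rnorm(40, 10, 1.4))
  e1 <- sea_bayes(g1, seed = 4)
  e2 <- sea_bayes(g2, seed = 5)
  expect_lt(max(e1$SEA_B[["2.5%"]], e2$SEA_B[["2.5%"]]),
            min(e1$SEA_B[["97.5%"]], e2$SEA_B[["97.5%"]]))
})

test_that("ellipse overlap handles identity, containment and separation", {
  a <- ellipse_from_cov(c(0, 0), diag(2))
  expect_equal(ellipse_overlap(a, a)$overlap, a$SEA)
  expect_equal(ellipse_overlap(a, a)$frac_a, 1)
  big <- ellipse_from_cov(c(0, 0), diag(4, 2))      # radius-2 circle
  ov <- ellipse_overlap(a, big)
  expect_equal(ov$overlap, pi)                      # inner circle contained
  expect_equal(ov$frac_b, pi / (4 * pi))
  far <- ellipse_from_cov(c(100, 100), diag(2))
  expect_equal(ellipse_overlap(a, far)$overlap, 0)
})

test_that("Monte-Carlo overlap is within 2% of the circle-circle lens", {
  a <- ellipse_from_cov(c(0, 0), diag(2))
  b <- ellipse_from_cov(c(1, 0), diag(2))
  lens <- 1.228370  # two unit circles, centres 1 apart
  ov_mc <- ellipse_overlap(a, b, draws = 200000, seed = 6)
  expect_equal(ov_mc$overlap, lens, tolerance = 0.02)
  ov_grid <- ellipse_overlap(a, b, method = "grid", grid_n = 500)
  expect_equal(ov_grid$overlap, lens, tolerance = 0.02)
})

test_that("overlap is symmetric and bounded by the smaller area", {
  set.seed(41)
  e1 <- standard_ellipse(group_observations(
    "a", rnorm(50, 0, 1.5), rnorm(50, 0, 0.8)))
  e2 <- standard_ellipse(group_observations(
    "b", rnorm(50, 1, 0.9), rnorm(50, 0.5, 1.2)))
  o12 <- ellipse_overlap(e1, e2, seed = 7)
  o21 <- ellipse_overlap(e2, e1, seed = 7)
  expect_equal(o12$overlap, o21$overlap, tolerance = 0.02)
  expect_lte(o12$overlap, min(e1$SEA, e2$SEA) + 1e-9)
})

test_that("niche_analysis returns per-group summaries and overlap matrix", {
  comm <- simulate_community(list(
    list(label = "manta", centroid = c(-16.8, 10.6),
         cov = diag(c(1.2, 2.2)), n = 40),
    list(label = "tuna", centroid = c(-16.5, 12), cov = diag(c(0.6, 0.8)),
         n = 30)), seed = 43)
  na <- niche_analysis(comm, draws = 1000, seed = 44)
  expect_equal(nrow(na$summaries), 2)
  expect_true(all(c("SEA", "SEAc", "SEA_B_50") %in% names(na$summaries)))
  expect_equal(na$overlap, t(na$overlap))
  expect_equal(unname(diag(na$overlap)), na$summaries$SEA)
})
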