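test_that("normalize_graph maps signals into the unit square", {
  p <- normalize_graph(c(0, 1, 0))
  expect_equal(p, cbind(x = c(0, 0.5, 1), y = c(0, 1, 0)))
  pc <- normalize_graph(c(5, 5, 5, 5))
  expect_equal(pc[, "y"], rep(0.5, 4))
  expect_error(normalize_graph(3), "at least 2")
})

test_that("normalization makes the graph affine-invariant", {
  set.seed(21)
  for (i in 1:20) {
    x <- cumsum(rnorm(200))
    a <- runif(1, 0.1, 50); b <- runif(1, -100, 100)
    expect_equal(normalize_graph(a * x + b), normalize_graph(x))
  }
})

test_that("box_count matches hand-derived counts under the grid convention", {
  diagonal <- cbind(c(0, 1), c(0, 1))
  expect_equal(box_count(diagonal, 1/4), 4)
  expect_equal(box_count_curve(diagonal, c(1/2, 1/4, 1/8))$N, c(2L, 4L, 8L))
  # horizontal line on a cell boundary: boundary belongs to the upper cells
  expect_equal(box_count(normalize_graph(c(5, 5, 5, 5)), 1/2), 2)
  expect_equal(box_count(matrix(c(0.3, 0.7), 1), 1/4), 1)  # single point
  expect_error(box_count(diagonal, 0.3), "divide")
  expect_error(box_count(cbind(2, 0.5), 1/2), "unit square")
})

test_that("fast counter equals the exhaustive scan on random polylines", {
  set.seed(101)
  for (i in 1:30) {
    poly <- random_polyline(50, graph = i %% 2 == 0)
    for (eps in c(1/2, 1/4, 1/8, 1/16)) {
      expect_identical(box_count(poly, eps),
                       as.integer(box_count_naive(poly, eps)))
    }
  }
})

test_that("the dyadic pyramid in box_count_curve matches per-scale counts", {
  set.seed(13)
  cases <- c(list(normalize_graph(c(0, 1, 0)), cbind(c(0, 1), c(0, 1)),
                  normalize_graph(c(5, 5, 5, 5))),
             lapply(1:15, function(i) normalize_graph(cumsum(rnorm(200)))))
  for (p in cases) {
    sc <- 2^-(1:min(6, floor(log2(nrow(p)))))
    expect_identical(box_count_curve(p, sc)$N,
                     vapply(sc, function(e) as.integer(box_count(p, e)),
                            integer(1)))
  }
})

test_that("box counts are monotone in scale", {
  set.seed(7)
  for (i in 1:20) {
    poly <- random_polyline(40, graph = i %% 2 == 0)
    curve <- box_count_curve(poly, 2^-(1:6))
    expect_true(all(diff(curve$N) >= 0))   # finer scale, more boxes
    expect_true(all(curve$N >= 1 & curve$N <= (1 / curve$eps)^2))
  }
})

test_that("estimate_fd recovers exact power-law slopes", {
  line <- data.frame(eps = c(1/2, 1/4, 1/8), N = c(2, 4, 8))
  expect_equal(estimate_fd(line)$D, 1, tolerance = 1e-12)
  plane <- data.frame(eps = c(1/2, 1/4, 1/8), N = c(4, 16, 64))
  fit <- estimate_fd(plane)
  expect_equal(fit$D, 2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_error(estimate_fd(data.frame(eps = c(1/2, 1/4), N = c(2, 4))),
               "at least 3")
  expect_error(estimate_fd(data.frame(eps = rep(1/4, 3), N = c(2, 4, 8))),
               "zero variance")
})

test_that("dyadic_scales respects the samples-per-column floor and cap", {
  expect_equal(dyadic_scales(2^14), 2^-(1:8))
  expect_equal(dyadic_scales(64), 2^-(1:5))    # floor(log2(32)) = 5
  expect_equal(dyadic_scales(2^14, cap = 10), 2^-(1:10))
  expect_error(dyadic_scales(3), "too short")
})

test_that("smooth and rough references bracket the dimension range", {
  smooth <- record_fd(seq(0, 1, length.out = 2^12))
  expect_gt(smooth$D, 0.95)
  expect_lt(smooth$D, 1.05)
  set.seed(9)
  rough <- record_fd(rnorm(2^14))   # white noise graph: nearly space-filling
  expect_gt(rough$D, smooth$D)
  expect_lt(rough$D, 2.01)
})
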