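test_that("product-limit estimates match closed forms on tiny inputs", {
  km <- km_estimate(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(km$time, c(1, 2, 3))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0), tolerance = 1e-14)

  km2 <- km_estimate(c(1, 2), c(TRUE, FALSE))
  expect_equal(km2$time, 1)
  expect_equal(km2$surv, 0.5)
  expect_equal(km_survival_at(km2, c(0.5, 1, 2, 10)), c(1, 0.5, 0.5, 0.5))

  # tie: the death is counted before the censoring in the risk set
  km3 <- km_estimate(c(2, 2), c(TRUE, FALSE))
  expect_equal(km3$surv, 0.5)
  expect_equal(km3$surv, brute_km(c(2, 2), c(TRUE, FALSE))$surv)

  expect_error(km_estimate(numeric(), logical()), "empty")
})

test_that("with no censoring the estimator equals 1 - ECDF", {
  set.seed(3)
  for (i in 1:20) {
    times <- sample(1:15, sample(3:12, 1), replace = TRUE)
    km <- km_estimate(times, rep(TRUE, length(times)))
    ecdf_fn <- stats::ecdf(times)
    for (t in unique(times)) {
      expect_equal(km_survival_at(km, t), 1 - ecdf_fn(t), tolerance = 1e-12)
    }
  }
})

test_that("product-limit output matches the brute-force oracle on random instances", {
  set.seed(2024)
  for (i in 1:1000) {
    n <- sample(1:12, 1)
    times <- sample(0:8, n, replace = TRUE) # heavy ties on purpose
    events <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(events)) events[sample(n, 1)] <- TRUE
    km <- km_estimate(times, events, horizon = 10)
    bk <- brute_km(times, events)
    expect_equal(km$time, bk$time)
    expect_equal(km$surv, bk$surv, tolerance = 1e-12)
    expect_true(all(diff(c(1, km$surv)) <= 1e-15)) # non-increasing
    expect_true(all(diff(km$n_risk) <= 0))
  }
})

test_that("the estimator is consistent for exponential survival", {
  set.seed(99)
  lambda <- 0.5 / 730
  n <- 2000
  death <- stats::rexp(n, lambda)
  censor <- pmin(stats::rexp(n, 1e-4), 730)
  times <- floor(pmin(death, censor))
  events <- death <= censor
  km <- km_estimate(times, events, horizon = 730)
  for (t in c(100, 365, 730)) {
    expect_lt(abs(km_survival_at(km, t) - exp(-lambda * t)), 0.03)
  }
})

test_that("local regression reproduces polynomials of its own degree exactly", {
  x <- seq(0, 10, length.out = 50)
  grid <- seq(0.5, 9.5, length.out = 21)
  for (span in c(0.3, 0.75, 1)) {
    fit <- loess_fit(x, 2 * x, span = span, degree = 1, grid = grid)
    expect_equal(fit$fitted, 2 * grid, tolerance = 1e-10)
  }
  fit_c <- loess_fit(x, rep(5, 50), span = 0.5, degree = 1, grid = grid)
  expect_equal(fit_c$fitted, rep(5, 21), tolerance = 1e-12)
  fit_q <- loess_fit(x, 3 * x^2 - x + 1, span = 0.6, degree = 2, grid = grid)
  expect_equal(fit_q$fitted, 3 * grid^2 - grid + 1, tolerance = 1e-8)
})

test_that("local regression matches an independent brute-force oracle", {
  set.seed(5)
  n <- 200
  x <- sort(stats::runif(n, 0, 6))
  y <- sin(x) + stats::rnorm(n, 0, 0.15)
  grid <- seq(0.2, 5.8, length.out = 40)
  fit <- loess_fit(x, y, span = 0.3, degree = 1, grid = grid)
  oracle <- brute_local_regression(x, y, span = 0.3, degree = 1, grid = grid)
  expect_lt(max(abs(fit$fitted - oracle)), 1e-9)
  expect_true(all(is.finite(fit$fitted)))

  fit2 <- loess_fit(x, y, span = 0.45, degree = 2, grid = grid)
  oracle2 <- brute_local_regression(x, y, span = 0.45, degree = 2, grid = grid)
  expect_lt(max(abs(fit2$fitted - oracle2)), 1e-9)

  expect_error(loess_fit(1:3, 1:3, span = 0.1, degree = 2), "too small|distinct")
})

test_that("kernel densities normalize, respect symmetry, and find modes", {
  set.seed(8)
  v <- stats::rnorm(300, 10, 2)
  d <- kde(v)
  integral <- sum(diff(d$grid) * (d$density[-1] + d$density[-length(d$density)]) / 2)
  expect_gt(integral, 0.98)
  expect_lt(integral, 1.02)
  expect_equal(d$bandwidth, stats::bw.nrd0(v))

  sym <- kde(c(-1, 1), grid = seq(-3, 3, length.out = 101))
  expect_lt(max(abs(sym$density - rev(sym$density))), 1e-12)

  two <- kde(c(stats::rnorm(200, 0, 0.3), stats::rnorm(200, 8, 0.3)),
    grid = seq(-2, 10, length.out = 256)
  )
  dens <- two$density
  modes <- sum(dens[2:255] > dens[1:254] & dens[2:255] > dens[3:256])
  expect_equal(modes, 2)

  expect_error(kde(rep(3, 10)), "distinct")
})

test_that("bubble statistics count cells exactly and suppress small cells", {
  v1 <- c(rep(TRUE, 3), rep(FALSE, 7)) # TT,TT,TF,FT,FT,FT,FF,FF,FF,FF
  v2 <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  pts <- bubble_stats(v1, v2, rep("A", 10), rep("2011", 10), minnum = 10)
  expect_equal(nrow(pts), 1)
  expect_equal(pts$n, 10)
  expect_equal(pts$n11, 2)
  expect_equal(pts$n10, 1)
  expect_equal(pts$n01, 3)
  expect_equal(pts$n00, 4)
  expect_equal(pts$p1, 0.3)
  expect_equal(pts$p2, 0.5)
  expect_equal(pts$n11 + pts$n10 + pts$n01 + pts$n00, pts$n)

  # n = 9 < default minnum = 10: suppressed
  pts9 <- bubble_stats(v1[1:9], v2[1:9], rep("A", 9), rep("2011", 9))
  expect_equal(nrow(pts9), 0)

  # rows with a missing indicator leave the denominator
  pts_na <- bubble_stats(
    c(v1, NA), c(v2, TRUE), rep("A", 11), rep("2011", 11),
    minnum = 0
  )
  expect_equal(pts_na$n, 10)

  expect_equal(nrow(bubble_stats(logical(), logical(), character(), character())), 0)
})

test_that("bubble suppression is monotone in the minimum count", {
  set.seed(13)
  v1 <- sample(c(TRUE, FALSE), 120, replace = TRUE)
  v2 <- sample(c(TRUE, FALSE), 120, replace = TRUE)
  g <- sample(c("A", "B", "C"), 120, replace = TRUE)
  p <- sample(c("2010", "2011"), 120, replace = TRUE)
  prev <- NULL
  for (m in c(0, 5, 10, 20, 40)) {
    pts <- bubble_stats(v1, v2, g, p, minnum = m)
    expect_true(all(pts$n >= m))
    expect_true(all(pts$n11 + pts$n10 + pts$n01 + pts$n00 == pts$n))
    if (!is.null(prev)) {
      expect_true(all(
        paste(pts$group, pts$period) %in% paste(prev$group, prev$period)
      ))
    }
    prev <- pts
  }
})
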