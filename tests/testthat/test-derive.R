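test_that("select_start_date honors first/last and excludes dateless subjects", {
  d <- as.Date(c("2010-01-01", "2011-01-01"))
  expect_equal(select_start_date(d, "first"), d[1])
  expect_equal(select_start_date(d, "last"), d[2])
  expect_equal(select_start_date(d[1], "first"), d[1])
  expect_equal(select_start_date(d[1], "last"), d[1])
  expect_warning(res <- select_start_date(as.Date(c(NA, NA)), "first"), "no non-missing")
  expect_true(is.na(res))
})

test_that("follow-up is the calendar-day count, truncated at maxtime", {
  # calendar-day oracle: R's Date arithmetic is exact day counting
  start <- as.Date("2010-01-01")
  death <- as.Date("2010-12-31")
  expect_equal(as.integer(death - start), 364)
  expect_equal(
    compute_follow_up(start, death, TRUE, 730),
    list(followup_day = 364L, event = TRUE)
  )
  # past the horizon: administratively censored at maxtime, event dropped
  expect_equal(
    compute_follow_up(start, as.Date("2013-01-01"), TRUE, 730),
    list(followup_day = 730L, event = FALSE)
  )
  expect_equal(
    compute_follow_up(start, start, TRUE, 730),
    list(followup_day = 0L, event = TRUE)
  )
  expect_error(
    compute_follow_up(start, start - 1, FALSE, 730, id = "P1"),
    "P1.*precedes"
  )
})

test_that("raising maxtime never shortens follow-up nor unflags early events", {
  set.seed(7)
  for (i in 1:50) {
    fu_raw <- sample(0:1500, 1)
    ev <- sample(c(TRUE, FALSE), 1)
    start <- as.Date("2010-01-01")
    end <- start + fu_raw
    a <- compute_follow_up(start, end, ev, 730)
    b <- compute_follow_up(start, end, ev, 1100)
    expect_gte(b$followup_day, a$followup_day)
    if (fu_raw <= 730) expect_equal(b$event, a$event)
  }
})

test_that("event attribution takes the freshest value within the window", {
  expect_equal(attribute_last_value(c(10, 300), c(50, 120), 400, 360), 120)
  expect_null(attribute_last_value(10, 50, 400, 360)) # gap 390 > 360
  expect_equal(attribute_last_value(40, 120, 400, 360), 120) # gap exactly 360
  # infinite window: last observation at or before the event
  days <- c(5, 80, 200)
  vals <- c(1, 2, 3)
  expect_equal(attribute_last_value(days, vals, 250, Inf), 3)
  expect_equal(attribute_last_value(days, vals, 100, Inf), 2)
  # zero window: only a same-day observation qualifies
  expect_null(attribute_last_value(days, vals, 250, 0))
  expect_equal(attribute_last_value(days, vals, 200, 0), 3)
  # observations after the event never qualify
  expect_null(attribute_last_value(c(10, 500), c(7, 9), 400, 360))
  expect_equal(attribute_last_value(c(390, 500), c(7, 9), 400, 360), 7)
})

test_that("plot-scale transforms are exact and guard their domains", {
  expect_equal(transform_values(400, "sqrt"), 20)
  expect_equal(transform_values(1000, "log10"), 3)
  expect_equal(transform_values(c(1, 2), "identity"), c(1, 2))
  expect_error(transform_values(0, "log"), "non-positive")
  expect_error(transform_values(-1, "sqrt"), "negative")
})

test_that("period labels discretize dates and sort chronologically as text", {
  d <- as.Date("2011-03-15")
  expect_equal(discretize_period(d, "year"), "2011")
  expect_equal(discretize_period(d, "quarter"), "2011-Q1")
  expect_equal(discretize_period(as.Date("2011-12-01"), "month"), "2011-12")
  dd <- seq(as.Date("2009-11-15"), as.Date("2012-02-01"), by = "month")
  for (p in c("year", "quarter", "month")) {
    labs <- discretize_period(dd, p)
    expect_equal(labs, sort(labs), info = p)
  }
})

test_that("baseline lookup picks the closest in-window value, earlier on ties", {
  anchor <- as.Date("2011-06-01")
  expect_equal(
    baseline_value(anchor + c(-30, 10), c(111, 222), anchor, 180, 30),
    222
  )
  expect_null(baseline_value(anchor - 300, 1, anchor, 180, 30))
  expect_equal(
    baseline_value(anchor + c(-5, 5), c(111, 222), anchor, 180, 30),
    111
  )
  # observations outside the asymmetric window are invisible
  expect_null(baseline_value(anchor + 31, 9, anchor, 180, 30))
  expect_equal(baseline_value(anchor - 180, 5, anchor, 180, 30), 5)
})

test_that("country-year aggregation matches brute-force counting", {
  out <- aggregate_country_year(
    rep("PER", 3), rep("2008", 3),
    c(TRUE, TRUE, FALSE)
  )
  expect_equal(out$numerator, 2L)
  expect_equal(out$denominator, 3L)
  expect_equal(out$proportion, 2 / 3, tolerance = 1e-12)

  # all-missing cell vanishes; singleton true cell is 1.0
  out2 <- aggregate_country_year(
    c("PER", "PER", "BRA"), c("2008", "2008", "2009"),
    c(NA, NA, TRUE)
  )
  expect_equal(nrow(out2), 1)
  expect_equal(out2$iso3, "BRA")
  expect_equal(out2$proportion, 1.0)

  set.seed(11)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    country <- sample(c("PER", "BRA", "HTI"), n, replace = TRUE)
    year <- sample(c("2007", "2008"), n, replace = TRUE)
    ind <- sample(c(TRUE, FALSE, NA), n, replace = TRUE)
    got <- aggregate_country_year(country, year, ind)
    want <- brute_country_year(country, year, ind)
    expect_equal(got$numerator, want$numerator)
    expect_equal(got$denominator, want$denominator)
    expect_equal(got$proportion, want$proportion, tolerance = 1e-12)
    expect_true(all(got$numerator <= got$denominator))
    expect_true(all(got$proportion >= 0 & got$proportion <= 1))
  }
})

test_that("add_baseline appends one baseline value per subject", {
  cohort <- load_tiny_cohort()
  out <- add_baseline(cohort,
    table = "basic", longtable = "lab_cd4",
    longvar = "cd4_v", longvardate = "cd4_d", anchor_col = "enrol_d",
    out_col = "cd4_base"
  )
  expect_equal(nrow(out), nrow(cohort$tables$basic))
  # every subject has a lab on the enrollment day itself in this fixture
  first_lab <- cohort$tables$lab_cd4[!duplicated(cohort$tables$lab_cd4$patient), ]
  expect_equal(out$cd4_base, first_lab$cd4_v[match(out$patient, first_lab$patient)])
})
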