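test_that("frame enumeration covers 0..maxtime with a forced terminal frame", {
  cohort <- load_tiny_cohort()
  f1 <- build_frames(cohort, tiny_panel1_spec(), frame_step = 1)
  expect_length(f1$frame_days, 731)
  expect_equal(f1$frame_days[1], 0L)
  expect_equal(f1$frame_days[731], 730L)

  f10 <- build_frames(cohort, tiny_panel1_spec(), frame_step = 10)
  expect_length(f10$frame_days, 75)
  expect_equal(f10$frame_days[73:75], c(720L, 730L, 730L))

  f73 <- build_frames(cohort, tiny_panel1_spec(), frame_step = 73)
  expect_equal(f73$frame_days[length(f73$frame_days)], 730L)

  empty_dir <- tempfile()
  dir.create(empty_dir)
  tabs <- tiny_cohort_tables()
  tabs <- lapply(tabs, function(df) df[0, , drop = FALSE])
  write_cohort_dir(tabs, empty_dir)
  empty <- load_cohort(empty_dir, names(tabs), date_cols = demo_date_cols)$cohort
  expect_error(build_frames(empty, tiny_panel1_spec()), "no subjects")
})

test_that("timelines encode truncation, start selection and death markers", {
  cohort <- load_tiny_cohort()
  tl <- build_timelines(cohort, tiny_panel1_spec())
  s <- tl$subjects
  expect_equal(nrow(s), 20)
  expect_true(all(s$followup_day <= 730))
  # survivors were followed past the horizon: censored at exactly maxtime
  expect_true(all(s$followup_day[!s$event] == 730))
  expect_equal(sum(s$event), 7)
  expect_true(all(tl$obs$day >= 0))
  expect_true(all(tl$obs$day <= s$followup_day[match(tl$obs$id, s$id)]))
  # marker invariants: at most one per death, value drawn from that
  # subject's own observations, inside the attribution window
  expect_lte(nrow(tl$markers), sum(s$event))
  for (i in seq_len(nrow(tl$markers))) {
    m <- tl$markers[i, ]
    own <- tl$obs[tl$obs$id == m$id, ]
    expect_true(m$value %in% own$value)
    expect_true(any(own$day <= m$day & m$day - own$day <= tl$window))
  }
})

test_that("the default event-axis limit is 1.4 times the highest group rate", {
  # fixture has known uncensored death fractions: 2/10 and 5/10
  cohort <- load_tiny_cohort()
  spec <- tiny_panel1_spec()
  tl <- build_timelines(cohort, spec)
  lim <- default_limits(tl, spec)
  expect_equal(lim$problim, c(0, 1.4 * 0.5), tolerance = 1e-12)

  # explicit problim passes through verbatim
  spec2 <- tiny_panel1_spec(problim = "c(0, 0.4)")
  expect_equal(default_limits(tl, spec2)$problim, c(0, 0.4))

  # default longitudinal limits are the 0.5th/99.5th percentiles
  expect_equal(
    default_limits(tl, spec)$longvarlim,
    unname(stats::quantile(tl$obs$value, c(0.005, 0.995)))
  )

  # a constant longitudinal value widens to a non-degenerate axis
  tabs <- tiny_cohort_tables()
  tabs$lab_cd4$cd4_v <- 300
  cohort_c <- local({
    d <- write_cohort_dir(tabs)
    load_cohort(d, names(tabs), date_cols = demo_date_cols)$cohort
  })
  tlc <- build_timelines(cohort_c, spec)
  expect_equal(default_limits(tlc, spec)$longvarlim, c(285, 315))
})

test_that("axis ticks stay on the original scale under transformation", {
  spec <- tiny_panel1_spec(
    longvartrans = "sqrt",
    longticks = "c(0,25,100,150,350,500,1000,2000,5000)"
  )
  t1 <- axis_ticks(spec, c(0, 1500))
  expect_equal(t1$labels, c(0, 25, 100, 150, 350, 500, 1000)) # 2000, 5000 dropped
  expect_equal(t1$at, sqrt(t1$labels))

  # default pretty breaks over (0, 100): the 1/2/5 ladder
  spec_d <- tiny_panel1_spec()
  t2 <- axis_ticks(spec_d, c(0, 100))
  expect_equal(t2$labels, pretty(c(0, 100), n = 5))
  expect_equal(t2$labels, c(0, 20, 40, 60, 80, 100))

  t3 <- axis_ticks(spec_d, c(0, 0))
  expect_equal(t3$at, 0)
  expect_equal(t3$labels, 0)
})

test_that("frames reveal monotonically and fix all statistical state upfront", {
  cohort <- load_tiny_cohort()
  fs <- build_frames(cohort, tiny_panel1_spec(), frame_step = 73)
  tl <- fs$timelines
  prev_obs <- -1
  for (fd in fs$frame_days) {
    n_obs <- sum(tl$obs$day <= fd)
    expect_gte(n_obs, prev_obs)
    prev_obs <- n_obs
  }
  # terminal frame shows everything
  last <- fs$frame_days[length(fs$frame_days)]
  expect_equal(sum(tl$obs$day <= last), nrow(tl$obs))
  expect_equal(sum(tl$markers$day <= last), nrow(tl$markers))

  # the event pane is exactly km_estimate output: the renderer adds nothing
  for (g in fs$groups) {
    sub <- tl$subjects[tl$subjects$group == g, ]
    km <- km_estimate(sub$followup_day, sub$event, horizon = tl$maxtime)
    expect_equal(fs$km[[g]]$time, km$time)
    expect_equal(fs$km[[g]]$surv, km$surv)
  }

  # fit-once contract: rebuilding with another frame step leaves curves alone
  fs2 <- build_frames(cohort, tiny_panel1_spec(), frame_step = 365)
  for (g in fs$groups) {
    expect_equal(fs2$loess[[g]]$fitted, fs$loess[[g]]$fitted)
  }
})

test_that("group subsetting and labels follow the spec", {
  cohort <- load_tiny_cohort()
  spec <- tiny_panel1_spec(
    groupsubset = "c(1)",
    grouplabels = "0 = No AIDS|1 = AIDS"
  )
  fs <- build_frames(cohort, spec, frame_step = 365)
  expect_equal(fs$groups, "1")
  expect_equal(unname(fs$labels), "AIDS")
  # unmapped values fall back to "Group <value>"
  fs2 <- build_frames(cohort, tiny_panel1_spec(), frame_step = 365)
  expect_equal(unname(fs2$labels), c("Group 0", "Group 1"))
})

test_that("rendering a frame is deterministic and respects the frame index", {
  cohort <- load_tiny_cohort()
  fs <- build_frames(cohort, tiny_panel1_spec(), frame_step = 365)
  f1 <- tempfile(fileext = ".png")
  f2 <- tempfile(fileext = ".png")
  render_panel1_frame(fs, 2, file = f1, width = 500, height = 450)
  render_panel1_frame(fs, 2, file = f2, width = 500, height = 450)
  expect_identical(
    unname(tools::md5sum(f1)), unname(tools::md5sum(f2))
  )
  expect_error(render_panel1_frame(fs, 99), "out of range")
  expect_equal(render_panel1_frame(fs, 1, file = tempfile(fileext = ".png")), 0L)
})
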