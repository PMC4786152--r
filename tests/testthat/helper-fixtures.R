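# In-code fixture builders shared across the suite.

# write a set of data frames as a cohort directory of CSV files
# (under the session tempdir, cleaned up when the test session ends)
write_cohort_dir <- function(tables, dir = tempfile("cohort")) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(tables)) {
    utils::write.csv(tables[[nm]], file.path(dir, paste0(nm, ".csv")),
      row.names = FALSE, na = ""
    )
  }
  dir
}

demo_cohort_dir <- function() {
  system.file("extdata", "democohort", package = "cohortviz")
}

demo_spec_path <- function(file) {
  system.file("extdata", "demospecs", file, package = "cohortviz")
}

demo_boundaries <- function() {
  system.file("extdata", "synthetic_boundaries.geojson", package = "cohortviz")
}

demo_date_cols <- list(
  basic = "enrol_d", lab_cd4 = "cd4_d", art = "art_sd", follow = "l_alive_d"
)

load_demo_cohort <- function() {
  load_cohort(demo_cohort_dir(),
    tables = c("basic", "lab_cd4", "art", "follow"),
    date_cols = demo_date_cols
  )
}

# a tiny deterministic cohort with hand-computable statistics:
# two groups, known death fractions, no censoring before the horizon
tiny_cohort_tables <- function(maxtime = 730) {
  n0 <- 10
  n1 <- 10
  id <- sprintf("S%02d", 1:(n0 + n1))
  aids <- c(rep(0, n0), rep(1, n1))
  start <- as.Date("2010-01-01")
  # group 0: deaths on days 100, 200; group 1: deaths on days 50,100,150,200,250
  death_day <- c(100, 200, rep(NA, 8), 50, 100, 150, 200, 250, rep(NA, 5))
  death <- as.integer(!is.na(death_day))
  end_day <- ifelse(is.na(death_day), maxtime + 100, death_day)
  lab_rows <- do.call(rbind, lapply(seq_along(id), function(i) {
    days <- seq(0, min(end_day[i], maxtime), by = 90)
    data.frame(
      patient = id[i],
      cd4_d = format(start + days, "%Y-%m-%d"),
      cd4_v = 100 + 10 * seq_along(days) + i, stringsAsFactors = FALSE
    )
  }))
  list(
    basic = data.frame(
      patient = id, site = "s1", country = "PER",
      enrol_d = format(start, "%Y-%m-%d"), aids_y = aids,
      stringsAsFactors = FALSE
    ),
    lab_cd4 = lab_rows,
    art = data.frame(
      patient = id, art_sd = format(start, "%Y-%m-%d"),
      stringsAsFactors = FALSE
    ),
    follow = data.frame(
      patient = id, death_y = death,
      l_alive_d = format(start + end_day, "%Y-%m-%d"),
      stringsAsFactors = FALSE
    )
  )
}

load_tiny_cohort <- function(dir = tempfile("cohort")) {
  write_cohort_dir(tiny_cohort_tables(), dir)
  load_cohort(dir,
    tables = c("basic", "lab_cd4", "art", "follow"),
    date_cols = demo_date_cols
  )$cohort
}

# minimal panel-1 spec built in code (no file round trip)
tiny_panel1_spec <- function(...) {
  dir <- tempfile()
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  rows <- c(
    id = "patient", longtablename = "lab_cd4", longvar = "cd4_v",
    longvardate = "cd4_d", eventtablename = "follow", event = "death_y",
    enddate = "l_alive_d", grouptablename = "basic", group = "aids_y",
    starttablename = "art", startdate = "art_sd", ...
  )
  path <- file.path(dir, "spec.csv")
  utils::write.csv(
    data.frame(name = names(rows), specification = unname(rows)),
    path,
    row.names = FALSE
  )
  parse_spec(path, "panel1")
}

write_spec_file <- function(rows, path = tempfile(fileext = ".csv")) {
  utils::write.csv(
    data.frame(name = names(rows), specification = unname(rows)),
    path,
    row.names = FALSE
  )
  path
}
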