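# Deterministic generator of HICDEP-style fixture cohorts with known ground
# truth. It emulates the structure of a multi-site Latin-American HIV cohort:
# staggered enrollment over calendar years, AIDS status at therapy start,
# square-root-scale CD4 recovery after ART initiation, exponential death
# hazards (higher with AIDS) and exponential plus administrative censoring.
# It is a test harness with recoverable parameters, not an epidemiological
# model of record.

#' Simulation parameters for a synthetic cohort
#'
#' Defaults describe a plausible regional cohort: ~35% of patients with
#' clinical AIDS at ART start, median baseline CD4 of 90 cells/uL (AIDS) vs
#' 250 cells/uL (no AIDS) with lognormal dispersion, square-root-scale CD4
#' recovery of about 1.3 sqrt-units per 100 days, quarterly lab visits, and
#' exponential death hazards of 6.8e-4/day (AIDS, about 22% cumulative
#' mortality over two years) vs 2e-4/day (no AIDS).
#'
#' @param n_subjects Number of subjects.
#' @param sites Data frame with columns `site` and `country` (ISO-3).
#' @param enrollment_years Inclusive range of enrollment calendar years.
#' @param p_aids Probability of clinical AIDS at ART start.
#' @param p_aids_unknown Probability of unknown AIDS status (coded 9).
#' @param baseline_cd4_median Named numeric, median baseline CD4 (cells/uL)
#'   for the `aids` and `no_aids` strata.
#' @param baseline_cd4_sdlog Lognormal dispersion (sd on the log scale).
#' @param recovery_slope Mean CD4 gain per 100 days on the square-root scale.
#' @param visit_interval Mean days between CD4 measurements.
#' @param hazard Named numeric, exponential death rate per day for `aids` and
#'   `no_aids`.
#' @param censor_rate Exponential dropout rate per day.
#' @param admin_censor_day Administrative censoring horizon in days after ART
#'   start (study close-out).
#' @param enrollment_trend Additive per-year drift in P(low baseline CD4 at
#'   enrollment); negative values emulate progressively earlier presentation.
#' @param p_low_cd4_start P(baseline CD4 < 200) in the first enrollment year.
#' @param seed Integer seed; every table is reproducible from it.
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(n_subjects = 500,
                       sites = data.frame(
                         site = c("vanguard", "andes", "carib"),
                         country = c("BRA", "PER", "HTI"),
                         stringsAsFactors = FALSE
                       ),
                       enrollment_years = c(2002, 2011),
                       p_aids = 0.35,
                       p_aids_unknown = 0.05,
                       baseline_cd4_median = c(aids = 90, no_aids = 250),
                       baseline_cd4_sdlog = 0.6,
                       recovery_slope = 1.3,
                       visit_interval = 90,
                       hazard = c(aids = 6.8e-4, no_aids = 2e-4),
                       censor_rate = 1e-4,
                       admin_censor_day = 1100,
                       enrollment_trend = -0.02,
                       p_low_cd4_start = 0.55,
                       seed = 20160310) {
  p <- list(
    n_subjects = n_subjects, sites = sites,
    enrollment_years = enrollment_years, p_aids = p_aids,
    p_aids_unknown = p_aids_unknown,
    baseline_cd4_median = baseline_cd4_median,
    baseline_cd4_sdlog = baseline_cd4_sdlog,
    recovery_slope = recovery_slope, visit_interval = visit_interval,
    hazard = hazard, censor_rate = censor_rate,
    admin_censor_day = admin_censor_day,
    enrollment_trend = enrollment_trend,
    p_low_cd4_start = p_low_cd4_start, seed = seed
  )
  stopifnot(
    p$n_subjects > 0, nrow(p$sites) > 0,
    p$p_aids >= 0, p$p_aids <= 1, p$p_aids + p$p_aids_unknown <= 1,
    all(p$hazard >= 0), p$censor_rate >= 0,
    length(p$enrollment_years) == 2,
    p$enrollment_years[1] <= p$enrollment_years[2]
  )
  structure(p, class = "sim_params")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate a HICDEP-style cohort
#'
#' Produces the four flat tables the visualization pipeline consumes:
#' `basic` (id, site, country, enrollment date, AIDS status), `art` (ART
#' start date = enrollment plus a short delay), `lab_cd4` (CD4 series at
#' roughly `visit_interval`-day spacing with square-root-scale linear
#' recovery plus Gaussian noise, values rounded to whole cells and floored
#' at 1), and `follow` (`death_y`, last-alive date). Death and dropout are
#' exponential from ART start; the earlier of death, dropout and the
#' administrative horizon ends follow-up. Baseline CD4 is drawn so that the
#' probability of presenting below 200 cells/uL drifts by
#' `enrollment_trend` per calendar year — a known ground truth the trend
#' plots should recover. Fully reproducible from `params$seed`.
#'
#' @param params A [sim_params()] object.
#' @return A `cohort_data` with tables `basic`, `lab_cd4`, `art`, `follow`.
#' @examples
#' cohort <- simulate_cohort(sim_params(n_subjects = 50))
#' cohort
#' @export
simulate_cohort <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$seed, {
    n <- params$n_subjects
    id <- sprintf("P%05d", seq_len(n))
    site_i <- sample.int(nrow(params$sites), n, replace = TRUE)
    years <- params$enrollment_years[1]:params$enrollment_years[2]
    year <- sample(years, n, replace = TRUE)
    enrol <- as.Date(sprintf("%d-01-01", year)) +
      floor(stats::runif(n) * 365)
    u <- stats::runif(n)
    aids <- ifelse(u < params$p_aids, 1L,
      ifelse(u < params$p_aids + params$p_aids_unknown, 9L, 0L)
    )
    art_sd <- enrol + floor(stats::runif(n, 0, 30))

    # baseline CD4: indicator for <200 follows the per-year drift, then a
    # lognormal draw truncated to the indicated side
    p_low <- pmin(pmax(
      params$p_low_cd4_start +
        params$enrollment_trend * (year - params$enrollment_years[1]),
      0.02
    ), 0.98)
    low <- stats::runif(n) < p_low
    med <- ifelse(aids == 1, params$baseline_cd4_median[["aids"]],
      params$baseline_cd4_median[["no_aids"]]
    )
    draw_trunc <- function(meanlog, below) {
      # inverse-CDF draw from the lognormal truncated at 200
      cut <- stats::plnorm(200, meanlog, params$baseline_cd4_sdlog)
      q <- if (below) stats::runif(1, 0, cut) else stats::runif(1, cut, 1)
      stats::qlnorm(q, meanlog, params$baseline_cd4_sdlog)
    }
    cd4_base <- vapply(seq_len(n), function(i) {
      draw_trunc(log(med[i]), low[i])
    }, numeric(1))
    cd4_base <- pmax(1, round(cd4_base))

    haz <- ifelse(aids == 1, params$hazard[["aids"]], params$hazard[["no_aids"]])
    t_death <- stats::rexp(n, pmax(haz, 1e-12))
    t_censor <- if (params$censor_rate > 0) {
      stats::rexp(n, params$censor_rate)
    } else {
      rep(Inf, n)
    }
    t_end <- pmin(t_death, t_censor, params$admin_censor_day)
    death <- as.integer(t_death <= pmin(t_censor, params$admin_censor_day))
    fu_day <- floor(t_end)

    lab <- lapply(seq_len(n), function(i) {
      days <- 0
      d <- 0
      repeat {
        d <- d + max(7, round(stats::rnorm(1, params$visit_interval, params$visit_interval / 4)))
        if (d > fu_day[i]) break
        days <- c(days, d)
      }
      # the drawn baseline IS the recorded day-0 measurement; visit noise
      # applies to the follow-up measurements only
      s <- sqrt(cd4_base[i]) + params$recovery_slope * days / 100 +
        c(0, stats::rnorm(length(days) - 1, 0, 1.2))
      data.frame(
        patient = id[i],
        cd4_d = format(art_sd[i] + days, "%Y-%m-%d"),
        cd4_v = pmax(1, round(pmax(0.5, s)^2)),
        stringsAsFactors = FALSE
      )
    })

    tables <- list(
      basic = data.frame(
        patient = id,
        site = params$sites$site[site_i],
        country = params$sites$country[site_i],
        enrol_d = format(enrol, "%Y-%m-%d"),
        aids_y = aids,
        stringsAsFactors = FALSE
      ),
      lab_cd4 = do.call(rbind, lab),
      art = data.frame(
        patient = id, art_sd = format(art_sd, "%Y-%m-%d"),
        stringsAsFactors = FALSE
      ),
      follow = data.frame(
        patient = id, death_y = death,
        l_alive_d = format(art_sd + fu_day, "%Y-%m-%d"),
        stringsAsFactors = FALSE
      )
    )
    date_cols <- list(
      basic = "enrol_d", lab_cd4 = "cd4_d",
      art = "art_sd", follow = "l_alive_d"
    )
    for (nm in names(tables)) {
      for (dc in intersect(date_cols[[nm]], names(tables[[nm]]))) {
        tables[[nm]][[dc]] <- parse_date(tables[[nm]][[dc]])$date
      }
      rownames(tables[[nm]]) <- NULL
    }
    structure(
      list(tables = tables, id_field = "patient", subjects = id),
      class = "cohort_data"
    )
  })
}

#' Write a simulated cohort as fixture files
#'
#' One comma-separated file per table, loadable by [load_cohort()] with an
#' empty error list. Refuses to overwrite existing files unless `force`.
#'
#' @param cohort A `cohort_data` (typically from [simulate_cohort()]).
#' @param dir Output directory, created when absent.
#' @param force Overwrite existing files.
#' @return Invisibly, the written paths.
#' @export
write_fixture <- function(cohort, dir, force = FALSE) {
  write_cohort(cohort, dir, force = force)
}
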