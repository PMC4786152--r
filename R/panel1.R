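# Plot class 1: animated longitudinal scatter + LOESS + marginal densities
# over a linked cumulative-event (Kaplan-Meier) pane, stratified by group.

group_palette <- function(groups) {
  n <- length(groups)
  stats::setNames(grDevices::hcl.colors(max(n, 2), palette = "Dark 2")[seq_len(n)], groups)
}

#' Derive per-subject timelines for the longitudinal/event panel
#'
#' Joins the start-date, group, event and longitudinal tables on the subject
#' identifier and applies the panel-1 rules: one start date per subject
#' (`starttype`), follow-up truncated at `maxtime` (administrative censoring),
#' `longsubset` applied to the longitudinal rows (default: non-missing
#' values), observation days clipped to `[0, followup_day]`, values
#' transformed by `longvartrans` for the plotting scale, and death markers
#' placed at (event day, last value) when the last value falls within
#' `long2eventwindow` days of the event.
#'
#' @param cohort A `cohort_data`.
#' @param spec A `panel1_spec`.
#' @return Object of class `panel1_timelines`: data frames `subjects`
#'   (`id`, `start`, `followup_day`, `event`, `group`), `obs`
#'   (`id`, `group`, `day`, `value`, `tvalue`) and `markers`
#'   (`id`, `group`, `day`, `value`, `tvalue`), plus `maxtime`, `window`,
#'   `trans` and `groups` (ordered unique group values).
#' @export
build_timelines <- function(cohort, spec) {
  stopifnot(inherits(cohort, "cohort_data"), inherits(spec, "panel1_spec"))
  require_spec_fields(spec, c(
    "longtablename", "longvar", "longvardate", "eventtablename", "event",
    "enddate", "grouptablename", "group", "starttablename", "startdate"
  ), "panel1")
  id <- if (!is.null(spec$id)) spec$id else cohort$id_field
  need <- c(spec$longtablename, spec$eventtablename, spec$grouptablename, spec$starttablename)
  absent <- setdiff(need, names(cohort$tables))
  if (length(absent) > 0) {
    stop("spec references table(s) not in the cohort: ", paste(absent, collapse = ", "),
      call. = FALSE
    )
  }

  start_tab <- cohort$tables[[spec$starttablename]]
  starts <- vapply(
    split(start_tab[[spec$startdate]], as.character(start_tab[[id]])),
    function(d) as.numeric(suppressWarnings(select_start_date(d, spec$starttype))),
    numeric(1)
  )
  starts <- as.Date(starts, origin = "1970-01-01")

  grp_tab <- cohort$tables[[spec$grouptablename]]
  grp <- vapply(
    split(as.character(grp_tab[[spec$group]]), as.character(grp_tab[[id]])),
    function(g) {
      g <- g[!is.na(g)]
      if (length(g)) g[1] else NA_character_
    }, character(1)
  )
  evt_tab <- cohort$tables[[spec$eventtablename]]
  evt_id <- as.character(evt_tab[[id]])
  end_date <- vapply(split(evt_tab[[spec$enddate]], evt_id), function(d) {
    d <- d[!is.na(d)]
    if (length(d)) as.numeric(max(d)) else NA_real_
  }, numeric(1))
  end_date <- as.Date(end_date, origin = "1970-01-01")
  evt_flag <- vapply(split(evt_tab[[spec$event]], evt_id), function(v) {
    any(!is.na(v) & (v == 1 | v == TRUE))
  }, logical(1))

  ids <- names(starts)[!is.na(starts)]
  ids <- ids[ids %in% names(end_date)[!is.na(end_date)]]
  dropped <- setdiff(names(starts), ids)
  if (length(dropped) > 0) {
    warning(length(dropped), " subject(s) dropped: no usable start or end date",
      call. = FALSE
    )
  }
  if (!is.null(spec$groupsubset)) {
    ids <- ids[!is.na(grp[ids]) & grp[ids] %in% spec$groupsubset]
  } else {
    ids <- ids[!is.na(grp[ids])]
  }
  if (length(ids) == 0) stop("no subjects left after filtering", call. = FALSE)

  fu <- lapply(ids, function(i) {
    compute_follow_up(starts[[i]], end_date[[i]], evt_flag[[i]], spec$maxtime, id = i)
  })
  subjects <- data.frame(
    id = ids,
    start = as.Date(vapply(ids, function(i) as.character(starts[[i]]), ""), "%Y-%m-%d"),
    followup_day = vapply(fu, function(f) f$followup_day, integer(1)),
    event = vapply(fu, function(f) f$event, logical(1)),
    group = unname(grp[ids]),
    stringsAsFactors = FALSE
  )
  rownames(subjects) <- NULL

  lg <- cohort$tables[[spec$longtablename]]
  keep <- if (!is.null(spec$longsubset)) {
    predicate_keep(spec$longsubset, lg)
  } else {
    !is.na(lg[[spec$longvar]])
  }
  lg <- lg[keep & as.character(lg[[id]]) %in% ids, , drop = FALSE]
  sub_idx <- match(as.character(lg[[id]]), subjects$id)
  day <- as.integer(lg[[spec$longvardate]] - subjects$start[sub_idx])
  vis <- !is.na(day) & day >= 0 & day <= subjects$followup_day[sub_idx]
  obs <- data.frame(
    id = as.character(lg[[id]])[vis],
    group = subjects$group[sub_idx][vis],
    day = day[vis],
    value = as.numeric(lg[[spec$longvar]])[vis],
    stringsAsFactors = FALSE
  )
  obs <- obs[order(obs$id, obs$day), , drop = FALSE]
  rownames(obs) <- NULL
  obs$tvalue <- transform_values(obs$value, spec$longvartrans)

  mk <- lapply(which(subjects$event), function(i) {
    rows <- obs$id == subjects$id[i]
    v <- attribute_last_value(
      obs$day[rows], obs$value[rows],
      subjects$followup_day[i], spec$long2eventwindow
    )
    if (is.null(v)) {
      return(NULL)
    }
    data.frame(
      id = subjects$id[i], group = subjects$group[i],
      day = subjects$followup_day[i], value = v, stringsAsFactors = FALSE
    )
  })
  mk <- mk[!vapply(mk, is.null, TRUE)]
  markers <- if (length(mk)) {
    do.call(rbind, mk)
  } else {
    data.frame(
      id = character(), group = character(), day = integer(),
      value = numeric(), stringsAsFactors = FALSE
    )
  }
  rownames(markers) <- NULL
  markers$tvalue <- transform_values(markers$value, spec$longvartrans)

  structure(
    list(
      subjects = subjects, obs = obs, markers = markers,
      maxtime = spec$maxtime, window = spec$long2eventwindow,
      trans = spec$longvartrans, groups = sort(unique(subjects$group))
    ),
    class = "panel1_timelines"
  )
}

#' Default axis limits for the longitudinal and event panes
#'
#' When the spec leaves them absent: the longitudinal-value limits default to
#' the 0.5th and 99.5th percentiles of the original-scale values, and the
#' event-probability limits to `(0, 1.4 x highest final group cumulative
#' event probability)`. Degenerate limits (equal endpoints) are widened by
#' plus/minus 5 percent of the value (plus/minus 1 when the value is 0).
#'
#' @param timelines A `panel1_timelines`.
#' @param spec A `panel1_spec` (its `longvarlim` / `problim`, when present,
#'   are passed through verbatim).
#' @return List with `longvarlim` (original scale) and `problim`.
#' @export
default_limits <- function(timelines, spec) {
  stopifnot(inherits(timelines, "panel1_timelines"))
  widen <- function(lim) {
    if (lim[1] < lim[2]) {
      return(lim)
    }
    v <- lim[1]
    if (v == 0) c(-1, 1) else v + c(-1, 1) * 0.05 * abs(v)
  }
  longvarlim <- spec$longvarlim
  if (is.null(longvarlim)) {
    longvarlim <- unname(stats::quantile(timelines$obs$value, c(0.005, 0.995), na.rm = TRUE))
  }
  longvarlim <- widen(longvarlim)
  problim <- spec$problim
  if (is.null(problim)) {
    rates <- vapply(timelines$groups, function(g) {
      sub <- timelines$subjects[timelines$subjects$group == g, ]
      km <- km_estimate(sub$followup_day, sub$event, horizon = timelines$maxtime)
      1 - km_survival_at(km, timelines$maxtime)
    }, numeric(1))
    top <- 1.4 * max(rates)
    if (top <= 0) top <- 0.1 # no events anywhere: keep a readable pane
    problim <- c(0, top)
  }
  list(longvarlim = longvarlim, problim = problim)
}

#' Tick positions and labels for the longitudinal axis
#'
#' Explicit `longticks` values are kept on the original scale as labels and
#' placed at their transformed positions; values outside the limits are
#' dropped. Without explicit ticks, roughly five "pretty" breaks (the
#' 1/2/5 x 10^k ladder) are taken over the original-scale range.
#'
#' @param spec A `panel1_spec`.
#' @param limits Original-scale axis limits (length-2 numeric).
#' @return List with `at` (transformed positions) and `labels`
#'   (original-scale values).
#' @export
axis_ticks <- function(spec, limits) {
  if (limits[1] == limits[2]) {
    return(list(at = transform_values(limits[1], spec$longvartrans), labels = limits[1]))
  }
  vals <- spec$longticks
  if (is.null(vals)) {
    vals <- pretty(limits, n = 5)
  }
  vals <- vals[vals >= limits[1] & vals <= limits[2]]
  list(at = transform_values(vals, spec$longvartrans), labels = vals)
}

#' Build the frame set for the longitudinal/event panel
#'
#' Fixed state (axis limits, ticks, per-group LOESS fit over the whole span,
#' per-group Kaplan-Meier curves, colors and labels) is computed once, so no
#' axis or curve changes shape between frames; each frame then only reveals
#' the observations, markers and curve segments up to its day.
#'
#' @param cohort A `cohort_data`.
#' @param spec A `panel1_spec`.
#' @param frame_step Days between frames (default 1, one frame per day).
#'   With a step above 1 the sequence always closes with an explicit
#'   terminal frame at `maxtime`, so the completed figure is the last frame
#'   whether or not the step divides `maxtime`.
#' @param loess_span,loess_degree Smoothing parameters passed to
#'   [loess_fit()].
#' @return Object of class `panel1_frames`; see [render_panel1_frame()].
#' @export
build_frames <- function(cohort, spec, frame_step = 1,
                         loess_span = 0.75, loess_degree = 1) {
  stopifnot(frame_step >= 1)
  tl <- build_timelines(cohort, spec)
  limits <- default_limits(tl, spec)
  ticks <- axis_ticks(spec, limits$longvarlim)
  tlim <- range(transform_values(limits$longvarlim, spec$longvartrans))
  groups <- tl$groups
  cols <- group_palette(groups)
  labels <- group_label_for(spec$grouplabels, groups)

  grid <- seq(0, tl$maxtime, length.out = 101)
  loess_curves <- stats::setNames(lapply(groups, function(g) {
    o <- tl$obs[tl$obs$group == g, ]
    if (length(unique(o$day)) < loess_degree + 2) {
      warning("group '", g, "': too few distinct days for a LOESS curve", call. = FALSE)
      return(NULL)
    }
    loess_fit(o$day, o$tvalue, span = loess_span, degree = loess_degree, grid = grid)
  }), groups)
  km_curves <- stats::setNames(lapply(groups, function(g) {
    sub <- tl$subjects[tl$subjects$group == g, ]
    km_estimate(sub$followup_day, sub$event, horizon = tl$maxtime)
  }), groups)

  frame_days <- seq(0, tl$maxtime, by = frame_step)
  if (frame_step > 1 || frame_days[length(frame_days)] != tl$maxtime) {
    # stepped animations close with an explicit terminal frame at maxtime,
    # so the completed figure is always the last file and the animation
    # holds on it (at step 1 every day, including maxtime, has its frame)
    frame_days <- c(frame_days, tl$maxtime)
  }

  structure(
    list(
      timelines = tl, spec = spec, frame_days = as.integer(frame_days),
      groups = groups, colors = cols, labels = labels,
      loess = loess_curves, km = km_curves,
      longvarlim = limits$longvarlim, tlim = tlim, problim = limits$problim,
      ticks = ticks
    ),
    class = "panel1_frames"
  )
}

#' @export
print.panel1_frames <- function(x, ...) {
  cat(sprintf(
    "<panel1_frames: %d frames (days 0..%d), %d subjects, groups: %s>\n",
    length(x$frame_days), x$timelines$maxtime, nrow(x$timelines$subjects),
    paste(x$labels, collapse = ", ")
  ))
  invisible(x)
}

# values entering the marginal density at a frame day: per subject, the last
# observed (transformed) value at or before the day, no older than the
# attribution window, among subjects still under follow-up at that day
margin_density_values <- function(frameset, group, frame_day) {
  tl <- frameset$timelines
  alive <- tl$subjects$id[tl$subjects$group == group &
    tl$subjects$followup_day >= frame_day]
  o <- tl$obs[tl$obs$id %in% alive & tl$obs$day <= frame_day &
    tl$obs$day >= frame_day - tl$window, ]
  if (nrow(o) == 0) {
    return(numeric())
  }
  o <- o[order(o$id, o$day), ]
  last <- !duplicated(o$id, fromLast = TRUE)
  o$tvalue[last]
}

#' Render one frame of the longitudinal/event panel
#'
#' Two vertically stacked panes share the time axis: the top pane shows
#' semi-transparent dots for observations up to the frame day, opaque X
#' markers for deaths, the per-group LOESS curves revealed up to the frame
#' day, and right-margin density curves of each group's current value
#' distribution; the bottom pane shows the per-group cumulative death
#' probability step curves up to the frame day. Axis state is identical
#' across frames.
#'
#' @param frameset A `panel1_frames`.
#' @param index Frame number (1-based).
#' @param file Output PNG path, or `NULL` to draw on the current device.
#' @param width,height Canvas size in pixels.
#' @return Invisibly, the frame day rendered.
#' @export
render_panel1_frame <- function(frameset, index, file = NULL, width = 800, height = 700) {
  stopifnot(inherits(frameset, "panel1_frames"))
  if (index < 1 || index > length(frameset$frame_days)) {
    stop("frame index out of range", call. = FALSE)
  }
  fd <- frameset$frame_days[index]
  tl <- frameset$timelines
  spec <- frameset$spec
  if (!is.null(file)) {
    grDevices::png(file, width = width, height = height)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  op <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(op), add = TRUE)
  graphics::layout(matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE),
    widths = c(4, 1), heights = c(3, 2)
  )

  # top-left: longitudinal scatter + LOESS
  graphics::par(mar = c(0.6, 4.5, 2.5, 0.3))
  graphics::plot(NA,
    xlim = c(0, tl$maxtime), ylim = frameset$tlim,
    xlab = "", ylab = spec$longlabel, axes = FALSE
  )
  graphics::axis(2, at = frameset$ticks$at, labels = frameset$ticks$labels, las = 1)
  graphics::box()
  graphics::title(main = sprintf("Day %d", fd), adj = 0)
  for (g in frameset$groups) {
    o <- tl$obs[tl$obs$group == g & tl$obs$day <= fd, ]
    if (nrow(o) > 0) {
      graphics::points(o$day, o$tvalue,
        pch = 16, cex = 0.55,
        col = grDevices::adjustcolor(frameset$colors[g], alpha.f = 0.2)
      )
    }
    m <- tl$markers[tl$markers$group == g & tl$markers$day <= fd, ]
    if (nrow(m) > 0) {
      graphics::points(m$day, m$tvalue, pch = 4, cex = 1.1, lwd = 2,
        col = frameset$colors[g]
      )
    }
    cv <- frameset$loess[[g]]
    if (!is.null(cv)) {
      sel <- cv$grid <= fd
      if (sum(sel) >= 2) {
        graphics::lines(cv$grid[sel], cv$fitted[sel],
          col = frameset$colors[g], lwd = 2.5
        )
      }
    }
  }

  # top-right: marginal densities (vertical)
  graphics::par(mar = c(0.6, 0.3, 2.5, 0.6))
  dens <- lapply(frameset$groups, function(g) {
    v <- margin_density_values(frameset, g, fd)
    if (length(unique(v)) < 2) {
      return(NULL)
    } # degenerate: skip this margin
    kde(v, grid = seq(frameset$tlim[1], frameset$tlim[2], length.out = 128))
  })
  xmax <- max(c(1e-9, unlist(lapply(dens, function(d) if (is.null(d)) NULL else d$density))))
  graphics::plot(NA,
    xlim = c(0, xmax * 1.05), ylim = frameset$tlim,
    axes = FALSE, xlab = "", ylab = ""
  )
  for (i in seq_along(frameset$groups)) {
    if (!is.null(dens[[i]])) {
      graphics::lines(dens[[i]]$density, dens[[i]]$grid,
        col = frameset$colors[frameset$groups[i]], lwd = 2
      )
    }
  }

  # bottom-left: cumulative event probability (1 - S)
  graphics::par(mar = c(4, 4.5, 0.8, 0.3))
  graphics::plot(NA,
    xlim = c(0, tl$maxtime), ylim = frameset$problim,
    xlab = spec$timelabel, ylab = spec$eventlabel, las = 1
  )
  for (g in frameset$groups) {
    km <- frameset$km[[g]]
    tt <- c(0, km$time[km$time <= fd], fd)
    pp <- c(0, 1 - km$surv[km$time <= fd], 1 - km_survival_at(km, fd))
    graphics::lines(tt, pp, type = "s", col = frameset$colors[g], lwd = 2.5)
  }
  graphics::legend("topleft",
    legend = frameset$labels, col = frameset$colors,
    lwd = 2.5, bty = "n", cex = 0.9
  )

  # bottom-right: empty corner
  graphics::par(mar = c(4, 0.3, 0.8, 0.6))
  graphics::plot.new()
  invisible(fd)
}

#' Render every frame of the longitudinal/event panel to PNG files
#'
#' @param frameset A `panel1_frames`.
#' @param out_dir Directory for the frame files (created if needed); files
#'   are named `panel_0001.png`, `panel_0002.png`, ... in frame order.
#' @param width,height Canvas size in pixels.
#' @return Character vector of file paths, in frame order.
#' @export
render_panel1_frames <- function(frameset, out_dir, width = 800, height = 700) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- file.path(out_dir, sprintf("panel_%04d.png", seq_along(frameset$frame_days)))
  for (i in seq_along(files)) {
    render_panel1_frame(frameset, i, file = files[i], width = width, height = height)
  }
  files
}
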