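# Plot classes 2-3: per-period bubble plots of two indicator proportions by
# group, with marginal allocation (mosaic) panels or darkening period trails.

#' Build the bubble series for plot classes 2 and 3
#'
#' Applies `vartablesubset`, evaluates the two indicator expressions,
#' discretizes the event date into periods, and computes one
#' [bubble_stats()] point per (group, period) with at least `minnum`
#' observed subjects. Periods whose points are all suppressed still occupy a
#' frame, keeping the time axis honest. Both the bubble/mosaic panel and the
#' trail panel are rendered from the same series.
#'
#' @param cohort A `cohort_data`.
#' @param spec A `bubble_spec`.
#' @return Object of class `bubble_series`: `points` (a `bubble_points` data
#'   frame), `periods` (ordered period labels), `groups`, `colors`,
#'   `max_n`, and the axis/category labels from the spec.
#' @export
build_bubble_series <- function(cohort, spec) {
  stopifnot(inherits(cohort, "cohort_data"), inherits(spec, "bubble_spec"))
  require_spec_fields(spec, c("vartable", "var1", "var2", "eventdate", "group"), "bubble")
  if (!spec$vartable %in% names(cohort$tables)) {
    stop("bubble spec references table not in the cohort: ", spec$vartable, call. = FALSE)
  }
  df <- cohort$tables[[spec$vartable]]
  if (!is.null(spec$vartablesubset)) {
    df <- df[predicate_keep(spec$vartablesubset, df), , drop = FALSE]
  }
  if (nrow(df) == 0) stop("no data after subsetting vartable", call. = FALSE)
  for (col in c(spec$eventdate, spec$group)) {
    if (!col %in% names(df)) {
      stop("bubble spec references unknown column '", col, "'", call. = FALSE)
    }
  }
  v1 <- evaluate_predicate(spec$var1, df)
  v2 <- evaluate_predicate(spec$var2, df)
  periods <- discretize_period(df[[spec$eventdate]], spec$eventperiod)
  groups <- as.character(df[[spec$group]])
  points <- bubble_stats(v1, v2, groups, periods, minnum = spec$minnum)
  all_periods <- sort(unique(periods[!is.na(periods)]))
  all_groups <- sort(unique(groups[!is.na(groups)]))
  lab_or <- function(x, d) if (is.null(x)) d else x
  structure(
    list(
      points = points, periods = all_periods, groups = all_groups,
      colors = group_palette(all_groups),
      max_n = max(c(1L, points$n)),
      var1label = lab_or(spec$var1label, "Proportion with indicator 1"),
      var2label = lab_or(spec$var2label, "Proportion with indicator 2"),
      var1label1 = lab_or(spec$var1label1, "Yes"),
      var1label0 = lab_or(spec$var1label0, "No"),
      var2label1 = lab_or(spec$var2label1, "Yes"),
      var2label0 = lab_or(spec$var2label0, "No")
    ),
    class = "bubble_series"
  )
}

#' @export
print.bubble_series <- function(x, ...) {
  cat(sprintf(
    "<bubble_series: %d point(s), %d period(s) (%s..%s), %d group(s)>\n",
    nrow(x$points), length(x$periods),
    x$periods[1], x$periods[length(x$periods)], length(x$groups)
  ))
  invisible(x)
}

#' Bubble radius scale
#'
#' Bubble *area* is proportional to the count, so the radius grows with
#' `sqrt(n)`: a bubble for four times the subjects has twice the radius.
#'
#' @param n Count(s).
#' @param max_n Count mapped to `max_radius`.
#' @param max_radius Radius (user units) of the largest bubble.
#' @return Radii.
#' @export
bubble_radius <- function(n, max_n, max_radius = 0.06) {
  max_radius * sqrt(n / max_n)
}

#' Mosaic geometry for a 2x2 contingency cell
#'
#' Column widths are proportional to the second indicator's marginal counts;
#' within each column, heights are proportional to the conditional split of
#' the first indicator. Returned rectangles tile the unit square.
#'
#' @param n11,n10,n01,n00 Cell counts (`nij` = var1 == i, var2 == j).
#' @return Data frame with columns `var1`, `var2`, `x0`, `x1`, `y0`, `y1`.
#' @export
mosaic_geometry <- function(n11, n10, n01, n00) {
  n <- n11 + n10 + n01 + n00
  stopifnot(n > 0)
  w1 <- (n11 + n01) / n # var2 == TRUE column
  cols <- list(
    `TRUE` = list(x0 = 0, x1 = w1, yes = n11, no = n01),
    `FALSE` = list(x0 = w1, x1 = 1, yes = n10, no = n00)
  )
  rows <- lapply(names(cols), function(k) {
    cc <- cols[[k]]
    tot <- cc$yes + cc$no
    hy <- if (tot > 0) cc$yes / tot else 0
    data.frame(
      var1 = c(TRUE, FALSE), var2 = as.logical(k),
      x0 = cc$x0, x1 = cc$x1,
      y0 = c(1 - hy, 0), y1 = c(1, 1 - hy),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Shades for a darkening bubble trail
#'
#' The current period keeps the group's base color (lightest); older bubbles
#' darken by linear interpolation of the HSV value toward 35 percent, so
#' luminance decreases strictly with age.
#'
#' @param base_col Base color of the group.
#' @param n_ages Number of trail steps (current period = age 0).
#' @return Vector of `n_ages` colors, age 0 first.
#' @export
trail_shades <- function(base_col, n_ages) {
  stopifnot(n_ages >= 1)
  hsv0 <- grDevices::rgb2hsv(grDevices::col2rgb(base_col))
  v0 <- max(hsv0[3, 1], 0.9) # start light so the darkening has room
  ages <- seq_len(n_ages) - 1
  denom <- max(n_ages - 1, 1)
  v <- v0 - (v0 - 0.35) * ages / denom
  grDevices::hsv(hsv0[1, 1], hsv0[2, 1], v)
}

draw_bubble <- function(x, y, r, col, border = "grey25") {
  # compensate the plot aspect so bubbles are circular on the device
  usr <- graphics::par("usr")
  pin <- graphics::par("pin")
  ry <- r * (usr[4] - usr[3]) / (usr[2] - usr[1]) * pin[1] / pin[2]
  a <- seq(0, 2 * pi, length.out = 72)
  graphics::polygon(x + r * cos(a), y + ry * sin(a), col = col, border = border)
}

#' Render one frame of the bubble + mosaic panel (plot class 2)
#'
#' Top pane: one bubble per group at (x = proportion with indicator 2,
#' y = proportion with indicator 1), area proportional to the denominator,
#' both axes fixed to `[0, 1]` in every frame. Bottom pane: per group, a
#' 2x2 mosaic of the joint indicator allocation.
#'
#' @param series A `bubble_series`.
#' @param period A period label present in `series$periods`.
#' @param file Output PNG path, or `NULL` for the current device.
#' @param width,height Canvas size in pixels.
#' @return Invisibly, the number of bubbles drawn.
#' @export
render_panel2_frame <- function(series, period, file = NULL, width = 800, height = 800) {
  stopifnot(inherits(series, "bubble_series"))
  if (!period %in% series$periods) stop("unknown period: ", period, call. = FALSE)
  if (!is.null(file)) {
    grDevices::png(file, width = width, height = height)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  op <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(op), add = TRUE)
  ng <- length(series$groups)
  graphics::layout(matrix(c(rep(1, ng), seq_len(ng) + 1), 2, ng, byrow = TRUE),
    heights = c(2.2, 1)
  )

  pts <- series$points[series$points$period == period, , drop = FALSE]
  graphics::par(mar = c(4, 4.5, 2.5, 1))
  graphics::plot(NA,
    xlim = c(0, 1), ylim = c(0, 1), las = 1,
    xlab = series$var2label, ylab = series$var1label
  )
  graphics::title(main = period, adj = 0)
  for (i in seq_len(nrow(pts))) {
    draw_bubble(pts$p2[i], pts$p1[i],
      bubble_radius(pts$n[i], series$max_n),
      col = grDevices::adjustcolor(series$colors[pts$group[i]], alpha.f = 0.65)
    )
  }
  if (nrow(pts) > 0) {
    graphics::text(pts$p2, pts$p1, labels = pts$group, cex = 0.75)
  }
  graphics::legend("topright",
    legend = series$groups,
    pt.bg = grDevices::adjustcolor(series$colors, alpha.f = 0.65),
    pch = 21, bty = "n", cex = 0.85
  )

  for (g in series$groups) {
    graphics::par(mar = c(2.5, 1.5, 2, 0.8))
    graphics::plot(NA,
      xlim = c(0, 1), ylim = c(0, 1), axes = FALSE,
      xlab = "", ylab = "", asp = NA
    )
    graphics::title(main = g, cex.main = 0.95)
    row <- pts[pts$group == g, , drop = FALSE]
    if (nrow(row) == 1) {
      geo <- mosaic_geometry(row$n11, row$n10, row$n01, row$n00)
      shade <- ifelse(geo$var1,
        series$colors[g],
        grDevices::adjustcolor(series$colors[g], alpha.f = 0.3)
      )
      graphics::rect(geo$x0, geo$y0, geo$x1, geo$y1, col = shade, border = "white", lwd = 2)
      graphics::mtext(c(series$var2label1, series$var2label0),
        side = 1,
        at = c(mean(c(geo$x0[1], geo$x1[1])), mean(c(geo$x0[3], geo$x1[3]))), cex = 0.6
      )
      graphics::mtext(series$var1label1, side = 2, at = 0.85, cex = 0.6, las = 1, line = 0)
    } else {
      graphics::text(0.5, 0.5, sprintf("n < minimum"), cex = 0.8, col = "grey40")
    }
    graphics::box(col = "grey80")
  }
  invisible(nrow(pts))
}

#' Render one frame of the bubble trail panel (plot class 3)
#'
#' One pane per group: bubbles for every period up to the current one; the
#' current period is lightest and drawn topmost, and shades darken
#' monotonically with age.
#'
#' @inheritParams render_panel2_frame
#' @return Invisibly, the number of bubbles drawn.
#' @export
render_panel3_frame <- function(series, period, file = NULL, width = 900, height = 600) {
  stopifnot(inherits(series, "bubble_series"))
  if (!period %in% series$periods) stop("unknown period: ", period, call. = FALSE)
  if (!is.null(file)) {
    grDevices::png(file, width = width, height = height)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  op <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(op), add = TRUE)
  ng <- length(series$groups)
  nc <- ceiling(sqrt(ng))
  nr <- ceiling(ng / nc)
  graphics::par(mfrow = c(nr, nc), oma = c(2.5, 2.5, 2.2, 0.5))
  idx <- match(period, series$periods)
  shown <- series$periods[seq_len(idx)]
  drawn <- 0L
  for (g in series$groups) {
    graphics::par(mar = c(2, 2, 2, 0.8))
    graphics::plot(NA,
      xlim = c(0, 1), ylim = c(0, 1), las = 1,
      xlab = "", ylab = "", cex.axis = 0.8
    )
    graphics::title(main = g, cex.main = 1)
    pts <- series$points[series$points$group == g &
      series$points$period %in% shown, , drop = FALSE]
    if (nrow(pts) > 0) {
      age <- idx - match(pts$period, series$periods) # 0 = current period
      shades <- trail_shades(series$colors[g], idx)
      ord <- order(age, decreasing = TRUE) # oldest first, current on top
      for (i in ord) {
        draw_bubble(pts$p2[i], pts$p1[i],
          bubble_radius(pts$n[i], series$max_n),
          col = shades[age[i] + 1]
        )
      }
      drawn <- drawn + nrow(pts)
    }
  }
  graphics::mtext(series$var2label, side = 1, outer = TRUE, line = 1, cex = 0.85)
  graphics::mtext(series$var1label, side = 2, outer = TRUE, line = 1, cex = 0.85)
  graphics::mtext(paste("Through", period), side = 3, outer = TRUE, line = 0.5, adj = 0)
  invisible(drawn)
}

#' Render every bubble frame to PNG files
#'
#' @param series A `bubble_series`.
#' @param out_dir Output directory; frames are named `panel2_0001.png` /
#'   `panel3_0001.png`, ..., one per period in chronological order.
#' @param class Which panel to render, `"panel2"` (bubble + mosaic) or
#'   `"panel3"` (trails).
#' @param width,height Canvas size in pixels.
#' @return Character vector of file paths in frame order.
#' @export
render_bubble_frames <- function(series, out_dir, class = c("panel2", "panel3"),
                                 width = 800, height = 800) {
  class <- match.arg(class)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- file.path(out_dir, sprintf("%s_%04d.png", class, seq_along(series$periods)))
  for (i in seq_along(series$periods)) {
    if (class == "panel2") {
      render_panel2_frame(series, series$periods[i], file = files[i], width = width, height = height)
    } else {
      render_panel3_frame(series, series$periods[i], file = files[i], width = width, height = height)
    }
  }
  files
}
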