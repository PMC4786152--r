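# Statistical primitives behind the plot classes: product-limit survival,
# local polynomial smoothing, kernel densities, grouped proportion tables.

#' Kaplan-Meier product-limit estimate
#'
#' Computes the product-limit survival function S(t) = prod_{t_i <= t}
#' (1 - d_i / n_i) over distinct event times, with the standard convention
#' that at a tied event/censoring time the event precedes the censoring in
#' the risk-set accounting. The cumulative event probability plotted in the
#' event pane is `1 - S(t)`. The heavy lifting is delegated to
#' [survival::survfit()], which implements exactly this estimator.
#'
#' @param times Follow-up days, all `>= 0` and `<= horizon`.
#' @param events Logical event flags.
#' @param horizon Largest day the curve must cover (defaults to
#'   `max(times)`).
#' @return Object of class `survival_curve`: `time` (strictly increasing
#'   event days), `surv` (S at each event day), `n_risk` (risk-set size just
#'   before each event day), `horizon`, `n`. S(0) = 1 implicitly; the curve
#'   is a right-continuous step function.
#' @examples
#' km <- km_estimate(c(1, 2, 3), c(TRUE, TRUE, TRUE))
#' km$surv # 2/3, 1/3, 0
#' @export
km_estimate <- function(times, events, horizon = max(times)) {
  if (length(times) == 0) stop("km_estimate: empty input", call. = FALSE)
  stopifnot(length(times) == length(events))
  if (anyNA(times) || anyNA(events)) stop("km_estimate: missing values", call. = FALSE)
  if (any(times < 0)) stop("km_estimate: negative follow-up time", call. = FALSE)
  if (any(times > horizon)) stop("km_estimate: time beyond horizon", call. = FALSE)
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1)
  keep <- fit$n.event > 0
  structure(
    list(
      time = fit$time[keep], surv = fit$surv[keep],
      n_risk = fit$n.risk[keep], horizon = horizon, n = length(times)
    ),
    class = "survival_curve"
  )
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf(
    "<survival_curve: n = %d, %d event time(s), S(horizon) = %.4f>\n",
    x$n, length(x$time), if (length(x$surv)) min(x$surv) else 1
  ))
  invisible(x)
}

#' Evaluate a survival curve at arbitrary times
#'
#' @param curve A `survival_curve`.
#' @param t Numeric vector of days.
#' @return S(t), right-continuous (S(0) = 1 before the first event).
#' @export
km_survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "survival_curve"))
  vapply(t, function(tt) {
    i <- sum(curve$time <= tt)
    if (i == 0) 1 else curve$surv[i]
  }, numeric(1))
}

#' Locally weighted polynomial regression on a fixed grid
#'
#' For each grid point g, fits a weighted least-squares polynomial of the
#' given degree over the `ceiling(span * n)` nearest x-neighbors of g, with
#' tricube weights `w = (1 - (d / d_max)^3)^3` (d = |x - g|, d_max = the
#' neighborhood radius), and returns the fitted polynomial value at g. The
#' curve is fit once over the whole span and then revealed frame by frame,
#' so the smooth never changes between animation frames.
#'
#' @param x,y Observations (missing pairs dropped).
#' @param span Neighborhood fraction in (0, 1], default 0.75.
#' @param degree Local polynomial degree, 1 or 2 (default 1; degree 1 is
#'   robust at the sparse right edge of follow-up).
#' @param grid Evaluation grid (default: 100 equally spaced points over the
#'   range of `x`).
#' @return Object of class `smoothed_curve`: `grid`, `fitted`, `span`,
#'   `degree`.
#' @export
loess_fit <- function(x, y, span = 0.75, degree = 1,
                      grid = seq(min(x), max(x), length.out = 100)) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  if (!degree %in% c(1, 2)) stop("degree must be 1 or 2", call. = FALSE)
  if (span <= 0 || span > 1) stop("span must be in (0, 1]", call. = FALSE)
  n <- length(x)
  if (length(unique(x)) < degree + 2) {
    stop("loess_fit: need at least degree + 2 distinct x values", call. = FALSE)
  }
  q <- ceiling(span * n)
  if (q < degree + 1) {
    stop("loess_fit: span * n too small for the requested degree", call. = FALSE)
  }
  fitted <- vapply(grid, function(g) {
    d <- abs(x - g)
    dmax <- sort(d, partial = q)[q]
    if (dmax == 0) {
      # neighborhood collapsed onto duplicated x values: average them
      return(mean(y[d == 0]))
    }
    w <- pmax(0, 1 - (d / dmax)^3)^3
    use <- w > 0
    xc <- x[use] - g
    X <- outer(xc, 0:degree, `^`)
    fit <- stats::lm.wfit(X, y[use], w[use])
    unname(fit$coefficients[1])
  }, numeric(1))
  if (anyNA(fitted)) stop("loess_fit: singular local fit on the grid", call. = FALSE)
  structure(
    list(grid = grid, fitted = fitted, span = span, degree = degree),
    class = "smoothed_curve"
  )
}

#' Gaussian kernel density on a caller-supplied grid
#'
#' Bandwidth is Silverman's rule of thumb,
#' `0.9 * min(sd, IQR / 1.34) * n^(-1/5)` (via [stats::bw.nrd0()]), and the
#' density is the exact Gaussian kernel sum evaluated at each grid point.
#'
#' @param values Numeric sample with at least 2 distinct values.
#' @param grid Evaluation grid (default: 128 points spanning the data plus
#'   three bandwidths either side).
#' @return Object of class `density_curve`: `grid`, `density`, `bandwidth`.
#' @export
kde <- function(values, grid = NULL) {
  values <- values[!is.na(values)]
  if (length(unique(values)) < 2) {
    stop("kde: need at least 2 distinct values", call. = FALSE)
  }
  bw <- stats::bw.nrd0(values)
  if (is.null(grid)) {
    grid <- seq(min(values) - 3 * bw, max(values) + 3 * bw, length.out = 128)
  }
  dens <- vapply(grid, function(g) mean(stats::dnorm(g, mean = values, sd = bw)),
    numeric(1)
  )
  structure(
    list(grid = grid, density = dens, bandwidth = bw),
    class = "density_curve"
  )
}

#' Grouped two-indicator proportion table for bubble plots
#'
#' One point per (group, period): the joint 2x2 cell counts of the two
#' indicators, the marginal proportions `p1` and `p2`, and the denominator
#' `n`. Rows where either indicator is missing are excluded from that cell's
#' denominator, so proportions refer to observed data only. Points with
#' `n < minnum` are suppressed (too few subjects for a meaningful bubble).
#'
#' @param var1,var2 Logical indicator vectors (three-valued).
#' @param groups,periods Parallel classifier and period-label vectors.
#' @param minnum Minimum denominator for a point to be emitted (default 10).
#' @return Data frame of class `bubble_points` with columns `group`,
#'   `period`, `n`, `p1`, `p2`, `n11`, `n10`, `n01`, `n00` (cell `nij` =
#'   count with var1 == i, var2 == j).
#' @export
bubble_stats <- function(var1, var2, groups, periods, minnum = 10) {
  stopifnot(
    length(var1) == length(var2), length(var1) == length(groups),
    length(var1) == length(periods), minnum >= 0
  )
  keep <- !is.na(var1) & !is.na(var2) & !is.na(groups) & !is.na(periods)
  var1 <- var1[keep]
  var2 <- var2[keep]
  key <- paste(groups[keep], periods[keep], sep = "\r")
  rows <- lapply(unique(key), function(k) {
    sel <- key == k
    n <- sum(sel)
    if (n < minnum) {
      return(NULL)
    }
    v1 <- var1[sel]
    v2 <- var2[sel]
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    data.frame(
      group = parts[1], period = parts[2], n = n,
      p1 = mean(v1), p2 = mean(v2),
      n11 = sum(v1 & v2), n10 = sum(v1 & !v2),
      n01 = sum(!v1 & v2), n00 = sum(!v1 & !v2),
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(
      group = character(), period = character(), n = integer(),
      p1 = numeric(), p2 = numeric(), n11 = integer(), n10 = integer(),
      n01 = integer(), n00 = integer(), stringsAsFactors = FALSE
    )
  }
  out <- out[order(out$period, out$group), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("bubble_points", "data.frame"))
}
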