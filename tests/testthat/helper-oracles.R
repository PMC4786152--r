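# Independent brute-force oracles. These re-derive expected values from first
# principles, via code paths disjoint from the package implementation.

# product-limit survival by explicit risk-set counting; events precede
# censorings at tied times
brute_km <- function(times, events) {
  ts <- sort(unique(times[events]))
  surv <- numeric(length(ts))
  s <- 1
  for (i in seq_along(ts)) {
    t <- ts[i]
    at_risk <- sum(times >= t)
    d <- sum(times == t & events)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  list(time = ts, surv = surv)
}

brute_km_at <- function(bk, t) {
  i <- sum(bk$time <= t)
  if (i == 0) 1 else bk$surv[i]
}

# naive local polynomial regression through lm()/predict(): one plain
# weighted regression per grid point
brute_local_regression <- function(x, y, span, degree, grid) {
  n <- length(x)
  q <- ceiling(span * n)
  vapply(grid, function(g) {
    d <- abs(x - g)
    dmax <- sort(d)[q]
    if (dmax == 0) {
      return(mean(y[d == 0]))
    }
    w <- ifelse(d < dmax, (1 - (d / dmax)^3)^3, 0)
    df <- data.frame(x = x, y = y)
    fml <- if (degree == 1) y ~ x else y ~ x + I(x^2)
    fit <- stats::lm(fml, data = df, weights = w)
    unname(stats::predict(fit, newdata = data.frame(x = g)))
  }, numeric(1))
}

# direct per-cell counting for country-year aggregation
brute_country_year <- function(country, year, indicator) {
  out <- list()
  for (cc in sort(unique(country))) {
    for (yy in sort(unique(year))) {
      sel <- country == cc & year == yy & !is.na(indicator)
      den <- sum(sel)
      if (den == 0) next
      out[[length(out) + 1]] <- data.frame(
        iso3 = cc, year = yy,
        numerator = sum(indicator[sel]), denominator = den,
        proportion = sum(indicator[sel]) / den, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

# perceptual luminance of a color (Rec. 601 weights)
luminance <- function(cols) {
  m <- grDevices::col2rgb(cols)
  as.numeric(0.299 * m[1, ] + 0.587 * m[2, ] + 0.114 * m[3, ])
}
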