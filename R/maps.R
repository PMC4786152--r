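# Plot classes "Map 1-2": per-period choropleths of a country-level
# proportion, as a world context map and a cropped region map. Boundaries
# come from any ISO-3-keyed GeoJSON (CShapes, Natural Earth, ...); the
# projection is plate carree (longitude/latitude drawn as-is with a
# cos(latitude) aspect correction), which is adequate for choropleth reading.

#' Load country boundaries from a GeoJSON file
#'
#' Reads a FeatureCollection of `Polygon`/`MultiPolygon` features and indexes
#' the rings by the ISO-3 code found in the named feature property. Features
#' lacking the property are skipped with a warning.
#'
#' @param path GeoJSON file path.
#' @param code_property Feature property holding the ISO-3 code
#'   (default `"iso_a3"`).
#' @return Object of class `boundary_set`: a named list mapping ISO-3 code to
#'   a list of two-column (longitude, latitude) ring matrices.
#' @export
load_boundaries <- function(path, code_property = "iso_a3") {
  if (!file.exists(path)) stop("boundary file not found: ", path, call. = FALSE)
  gj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("cannot parse GeoJSON: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path, call. = FALSE)
  ring_mat <- function(ring) {
    m <- do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    colnames(m) <- c("lon", "lat")
    m
  }
  out <- list()
  skipped <- 0L
  for (ft in gj$features) {
    code <- ft$properties[[code_property]]
    if (is.null(code) || !nzchar(code)) {
      skipped <- skipped + 1L
      next
    }
    geom <- ft$geometry
    rings <- switch(geom$type,
      Polygon = lapply(geom$coordinates, ring_mat),
      MultiPolygon = unlist(lapply(geom$coordinates, function(poly) {
        lapply(poly, ring_mat)
      }), recursive = FALSE),
      {
        skipped <- skipped + 1L
        next
      }
    )
    out[[code]] <- c(out[[code]], rings)
  }
  if (skipped > 0) {
    warning(skipped, " feature(s) skipped (no '", code_property,
      "' property or unsupported geometry)",
      call. = FALSE
    )
  }
  if (length(out) == 0) stop("no usable features in ", path, call. = FALSE)
  structure(out, class = "boundary_set")
}

#' @export
print.boundary_set <- function(x, ...) {
  cat(sprintf(
    "<boundary_set: %d countr%s (%s)>\n", length(x),
    if (length(x) == 1) "y" else "ies",
    paste(utils::head(names(x), 8), collapse = ", ")
  ))
  invisible(x)
}

#' Build the color binning for a choropleth
#'
#' Values are mapped to consecutive percent bins of the given width covering
#' the observed range, colored with a sequential single-hue red ramp,
#' lightest for the lowest bin. Bins are half-open `[lo, hi)` except the last,
#' which is closed, and labelled `"20-29%"` style. Inputs whose maximum is at
#' most 1 are read as proportions and scaled to percent; `scale =
#' "percent"` forces the percentage reading when an all-small percentage
#' input would otherwise be ambiguous.
#'
#' @param values Proportions in `[0, 1]` or percentages in `[0, 100]`.
#' @param width Bin width in percentage points (default 10).
#' @param scale `"auto"`, `"proportion"` or `"percent"`.
#' @return Object of class `color_binning`: `edges` (percent), `colors`,
#'   `labels`, `scale_factor` (100 for proportion input, 1 for percent).
#' @export
build_binning <- function(values, width = 10, scale = c("auto", "proportion", "percent")) {
  scale <- match.arg(scale)
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("build_binning: no values", call. = FALSE)
  if (any(values < 0)) stop("build_binning: negative values", call. = FALSE)
  as_percent <- switch(scale,
    proportion = TRUE,
    percent = FALSE,
    auto = max(values) <= 1
  )
  if (as_percent && any(values > 1)) {
    stop("build_binning: values above 1 declared as proportions", call. = FALSE)
  }
  if (!as_percent && any(values > 100)) {
    stop("build_binning: percentages above 100", call. = FALSE)
  }
  factor <- if (as_percent) 100 else 1
  pct <- values * factor
  lo <- floor(min(pct) / width) * width
  hi <- ceiling(max(pct) / width) * width
  if (hi == lo) hi <- lo + width
  edges <- seq(lo, hi, by = width)
  nb <- length(edges) - 1
  cols <- grDevices::colorRampPalette(c("#FEE5D9", "#A50F15"))(max(nb, 2))[seq_len(nb)]
  labels <- sprintf("%g\u2013%g%%", edges[-length(edges)], edges[-1] - 1)
  labels[nb] <- sprintf("%g\u2013%g%%", edges[nb], edges[nb + 1])
  structure(
    list(edges = edges, colors = cols, labels = labels, scale_factor = factor),
    class = "color_binning"
  )
}

#' Look up the bin color for a value
#'
#' @param binning A `color_binning`.
#' @param value Value on the same scale as the data the binning was built
#'   from.
#' @return A color, or `NA` when the value falls outside every bin.
#' @export
bin_color <- function(binning, value) {
  stopifnot(inherits(binning, "color_binning"))
  pct <- value * binning$scale_factor
  e <- binning$edges
  vapply(pct, function(p) {
    if (is.na(p) || p < e[1] || p > e[length(e)]) {
      return(NA_character_)
    }
    i <- findInterval(p, e, rightmost.closed = TRUE)
    binning$colors[min(i, length(binning$colors))]
  }, character(1))
}

bbox_of <- function(boundaries, codes) {
  rings <- unlist(boundaries[intersect(codes, names(boundaries))], recursive = FALSE)
  if (length(rings) == 0) {
    return(NULL)
  }
  all <- do.call(rbind, rings)
  list(xlim = range(all[, 1]), ylim = range(all[, 2]))
}

#' Render one choropleth frame
#'
#' World mode draws every boundary polygon; region mode crops the viewport
#' (with a 5 percent margin) to the bounding box of the countries that have
#' data in *any* period, so the viewport is identical in every frame. In
#' both modes a country is filled with its bin color when it has a value for
#' the rendered year and neutral gray otherwise; the two modes therefore show
#' identical fills for shared countries.
#'
#' @param boundaries A `boundary_set`.
#' @param table A `country_year_table` (or data frame with columns `iso3`,
#'   `year`, `proportion`).
#' @param binning A `color_binning` built from all periods' values.
#' @param year Year (period) to render.
#' @param mode `"world"` or `"region"`.
#' @param varlabel Legend title.
#' @param file Output PNG path, or `NULL` for the current device.
#' @param width,height Canvas size in pixels.
#' @return Invisibly, a character vector of ISO-3 codes present in the table
#'   but absent from the boundary set (unmatched codes are reported, never
#'   silently dropped).
#' @export
render_map_frame <- function(boundaries, table, binning, year,
                             mode = c("world", "region"),
                             varlabel = "Proportion", file = NULL,
                             width = 900, height = 500) {
  mode <- match.arg(mode)
  stopifnot(inherits(boundaries, "boundary_set"), inherits(binning, "color_binning"))
  year <- as.character(year)
  if (!year %in% as.character(table$year)) {
    stop("year '", year, "' not present in the country table", call. = FALSE)
  }
  unmatched <- sort(unique(table$iso3[!table$iso3 %in% names(boundaries)]))
  rows <- table[as.character(table$year) == year, , drop = FALSE]
  fills <- stats::setNames(bin_color(binning, rows$proportion), rows$iso3)

  if (!is.null(file)) {
    grDevices::png(file, width = width, height = height)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  op <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(op), add = TRUE)
  box <- if (mode == "region") {
    bbox_of(boundaries, unique(table$iso3))
  } else {
    bbox_of(boundaries, names(boundaries))
  }
  pad <- function(r) r + c(-1, 1) * 0.05 * diff(r)
  graphics::par(mar = c(1, 1, 2.5, 1))
  graphics::plot(NA,
    xlim = pad(box$xlim), ylim = pad(box$ylim), asp = 1,
    axes = FALSE, xlab = "", ylab = ""
  )
  graphics::title(main = paste0(varlabel, " \u2014 ", year), adj = 0, cex.main = 1)
  for (code in names(boundaries)) {
    fill <- if (code %in% names(fills) && !is.na(fills[code])) fills[code] else "#DDDDDD"
    for (ring in boundaries[[code]]) {
      graphics::polygon(ring[, 1], ring[, 2], col = fill, border = "grey40", lwd = 0.6)
    }
  }
  graphics::legend("bottomleft",
    legend = binning$labels, fill = binning$colors,
    bty = "n", cex = 0.8, title = varlabel
  )
  invisible(unmatched)
}

#' Render every choropleth frame to PNG files
#'
#' @param boundaries A `boundary_set`.
#' @param table A `country_year_table`.
#' @param mode `"world"` or `"region"`.
#' @param out_dir Output directory; frames are named `map_0001.png`, ...,
#'   one per distinct year in chronological order.
#' @param varlabel Legend title.
#' @param binning Optional `color_binning`; by default built from the
#'   table's proportions over all periods, width 10.
#' @param width,height Canvas size in pixels.
#' @return List with `files` (paths in frame order), `years`, and
#'   `unmatched` (ISO-3 codes with no boundary polygon).
#' @export
render_map_frames <- function(boundaries, table, mode = c("world", "region"),
                              out_dir, varlabel = "Proportion", binning = NULL,
                              width = 900, height = 500) {
  mode <- match.arg(mode)
  if (is.null(binning)) binning <- build_binning(table$proportion)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  years <- sort(unique(as.character(table$year)))
  files <- file.path(out_dir, sprintf("map_%04d.png", seq_along(years)))
  unmatched <- character()
  for (i in seq_along(years)) {
    unmatched <- render_map_frame(boundaries, table, binning, years[i],
      mode = mode, varlabel = varlabel, file = files[i],
      width = width, height = height
    )
  }
  list(files = files, years = years, unmatched = unmatched)
}
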