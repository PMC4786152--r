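# Run-workflow entry points: load data, parse spec, build frames, write the
# PNG sequence under <out>/scroll_images/ plus an HTML scrubber viewer and a
# run report. A thin command-line wrapper over these functions ships in
# inst/cli/cohortviz.

#' Write the HTML animation viewer
#'
#' Self-contained HTML page referencing the frame images by relative path,
#' with a slider scrubber, keyboard stepping (arrow keys), and play/pause at
#' adjustable speed and direction.
#'
#' @param frame_files Ordered frame paths (each referenced exactly once).
#' @param title Page title.
#' @param out Output HTML path; image paths are written relative to its
#'   directory, so the viewer works from any mount point.
#' @return Invisibly, `out`.
#' @export
write_viewer <- function(frame_files, title, out) {
  if (length(frame_files) == 0) stop("no frames to view", call. = FALSE)
  base <- normalizePath(dirname(out), mustWork = FALSE)
  rel <- vapply(frame_files, function(f) {
    f <- normalizePath(f, mustWork = FALSE)
    if (startsWith(f, paste0(base, "/"))) substring(f, nchar(base) + 2) else f
  }, character(1))
  frames_js <- paste0('"', rel, '"', collapse = ",\n    ")
  html <- sprintf(
    '<!DOCTYPE html>
<html>
<head>
<meta charset="utf-8">
<title>%s</title>
<style>
  body { font-family: sans-serif; margin: 1em; }
  img { max-width: 100%%; border: 1px solid #ccc; }
  .controls { margin: 0.6em 0; }
  input[type=range] { width: 60%%; vertical-align: middle; }
</style>
</head>
<body>
<h2>%s</h2>
<div class="controls">
  <button id="play">Play</button>
  <button id="back">&#9664;</button>
  <button id="fwd">&#9654;</button>
  <input type="range" id="slider" min="0" max="%d" value="0">
  <label>speed <select id="speed">
    <option value="250">slow</option>
    <option value="80" selected>normal</option>
    <option value="25">fast</option>
  </select></label>
  <span id="label"></span>
</div>
<img id="frame" src="%s" alt="frame">
<script>
var frames = [
    %s
];
var i = 0, timer = null;
var img = document.getElementById("frame");
var slider = document.getElementById("slider");
var label = document.getElementById("label");
function show(k) {
  i = (k + frames.length) %% frames.length;
  img.src = frames[i];
  slider.value = i;
  label.textContent = (i + 1) + " / " + frames.length;
}
function tick() { show(i + 1); }
document.getElementById("play").onclick = function () {
  if (timer) { clearInterval(timer); timer = null; this.textContent = "Play"; }
  else {
    timer = setInterval(tick, +document.getElementById("speed").value);
    this.textContent = "Pause";
  }
};
document.getElementById("fwd").onclick = function () { show(i + 1); };
document.getElementById("back").onclick = function () { show(i - 1); };
slider.oninput = function () { show(+this.value); };
document.addEventListener("keydown", function (e) {
  if (e.key === "ArrowRight") show(i + 1);
  if (e.key === "ArrowLeft") show(i - 1);
});
show(0);
</script>
</body>
</html>
',
    title, title, length(rel) - 1, rel[1], frames_js
  )
  writeLines(html, out)
  invisible(out)
}

prepare_output <- function(out_dir, force) {
  img_dir <- file.path(out_dir, "scroll_images")
  if (dir.exists(img_dir) && length(list.files(img_dir)) > 0 && !force) {
    stop("output already present in ", out_dir, " (use force = TRUE to overwrite)",
      call. = FALSE
    )
  }
  if (force && dir.exists(img_dir)) unlink(img_dir, recursive = TRUE)
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  img_dir
}

finish_run <- function(out_dir, report_lines, created) {
  writeLines(report_lines, file.path(out_dir, "run_report.txt"))
  message(paste(report_lines, collapse = "\n"))
  invisible(created)
}

run_stage <- function(out_dir, expr) {
  # remove partial output when any stage fails
  tryCatch(expr, error = function(e) {
    unlink(file.path(out_dir, "scroll_images"), recursive = TRUE)
    stop(conditionMessage(e), call. = FALSE)
  })
}

default_date_cols <- function(tables) {
  known <- list(
    basic = "enrol_d", lab_cd4 = "cd4_d", art = "art_sd",
    follow = "l_alive_d", basic_cd4 = "enrol_d"
  )
  known[intersect(names(known), tables)]
}

load_for_run <- function(data_dir, tables, date_cols = NULL) {
  if (is.null(date_cols)) date_cols <- default_date_cols(tables)
  res <- load_cohort(data_dir, tables, date_cols = date_cols)
  if (nrow(res$report$errors) > 0) {
    print(res$report)
    stop("cohort failed validation (", nrow(res$report$errors), " error(s))",
      call. = FALSE
    )
  }
  res
}

#' Run the longitudinal/event panel end to end
#'
#' Loads the cohort tables named by the spec, builds the frame set, writes
#' the PNG sequence to `<out_dir>/scroll_images/panel_*.png`, the viewer to
#' `<out_dir>/panel1_viewer.html`, and a run report to standard output and
#' `<out_dir>/run_report.txt`.
#'
#' @param data_dir Directory of cohort CSV tables.
#' @param spec_path Panel-1 spec CSV.
#' @param out_dir Output directory.
#' @param frame_step Days per frame (default 1).
#' @param width,height Canvas size in pixels.
#' @param force Overwrite existing output.
#' @param date_cols Optional override of the per-table date-column map.
#' @return Invisibly, a list with `frames` (paths) and `viewer`.
#' @export
run_panel1 <- function(data_dir, spec_path, out_dir, frame_step = 1,
                       width = 800, height = 700, force = FALSE,
                       date_cols = NULL) {
  spec <- parse_spec(spec_path, "panel1")
  tables <- unique(c(
    spec$longtablename, spec$eventtablename,
    spec$grouptablename, spec$starttablename
  ))
  res <- load_for_run(data_dir, tables, date_cols)
  img_dir <- prepare_output(out_dir, force)
  created <- run_stage(out_dir, {
    fs <- build_frames(res$cohort, spec, frame_step = frame_step)
    files <- render_panel1_frames(fs, img_dir, width = width, height = height)
    viewer <- write_viewer(files, "Longitudinal values and event probability",
      file.path(out_dir, "panel1_viewer.html")
    )
    list(frames = files, viewer = viewer, frameset = fs)
  })
  finish_run(out_dir, c(
    sprintf("panel1: %d frames (days 0..%d, step %d)",
      length(created$frames), created$frameset$timelines$maxtime, frame_step
    ),
    sprintf("subjects plotted: %d", nrow(created$frameset$timelines$subjects)),
    sprintf("observations: %d; death markers: %d",
      nrow(created$frameset$timelines$obs), nrow(created$frameset$timelines$markers)
    ),
    sprintf("warnings during load: %d", nrow(res$report$warnings)),
    sprintf("viewer: %s", created$viewer)
  ), created[c("frames", "viewer")])
}

#' Run the bubble panels end to end
#'
#' Renders both bubble classes from one spec: the bubble + mosaic panel
#' (`panel2_*.png`, `panel2_viewer.html`) and the darkening-trail panel
#' (`panel3_*.png`, `panel3_viewer.html`).
#'
#' @inheritParams run_panel1
#' @param spec_path Bubble spec CSV.
#' @return Invisibly, a list with `frames2`, `frames3`, `viewer2`, `viewer3`.
#' @export
run_bubbles <- function(data_dir, spec_path, out_dir,
                        width = 800, height = 800, force = FALSE,
                        date_cols = NULL) {
  spec <- parse_spec(spec_path, "bubble")
  require_spec_fields(spec, "vartable", "bubble")
  res <- load_for_run(data_dir, spec$vartable, date_cols)
  img_dir <- prepare_output(out_dir, force)
  created <- run_stage(out_dir, {
    series <- build_bubble_series(res$cohort, spec)
    f2 <- render_bubble_frames(series, img_dir, "panel2", width = width, height = height)
    f3 <- render_bubble_frames(series, img_dir, "panel3", width = width, height = height)
    v2 <- write_viewer(f2, "Indicator proportions by group",
      file.path(out_dir, "panel2_viewer.html")
    )
    v3 <- write_viewer(f3, "Indicator proportions by group (trails)",
      file.path(out_dir, "panel3_viewer.html")
    )
    list(frames2 = f2, frames3 = f3, viewer2 = v2, viewer3 = v3, series = series)
  })
  finish_run(out_dir, c(
    sprintf("bubbles: %d period frame(s), %d point(s), %d group(s)",
      length(created$series$periods), nrow(created$series$points),
      length(created$series$groups)
    ),
    sprintf("suppressed below minimum count: %d of %d (group, period) cells",
      length(created$series$periods) * length(created$series$groups) -
        nrow(created$series$points),
      length(created$series$periods) * length(created$series$groups)
    ),
    sprintf("viewers: %s, %s", created$viewer2, created$viewer3)
  ), created[c("frames2", "frames3", "viewer2", "viewer3")])
}

#' Run the choropleth maps end to end
#'
#' Renders, per year, a world context frame (`map_*.png`,
#' `map1_viewer.html`) and a cropped region frame (`map_region_*.png` via a
#' `region` subdirectory, `map2_viewer.html`), from one country-year table
#' and one binning, so both maps show identical fills for shared countries.
#'
#' @inheritParams run_panel1
#' @param spec_path Map spec CSV.
#' @param boundaries_path GeoJSON boundary file.
#' @param code_property Feature property holding the ISO-3 code.
#' @return Invisibly, a list with `frames_world`, `frames_region`, viewers,
#'   and `unmatched` codes.
#' @export
run_maps <- function(data_dir, spec_path, boundaries_path, out_dir,
                     width = 900, height = 500, force = FALSE,
                     code_property = "iso_a3") {
  spec <- parse_spec(spec_path, "map")
  require_spec_fields(spec, c("countrytable", "var", "country", "year"), "map")
  tab_path <- file.path(data_dir, paste0(spec$countrytable, ".csv"))
  raw <- read_table(tab_path, spec$countrytable)
  df <- raw$data
  for (col in c(spec$var, spec$country, spec$year)) {
    if (!col %in% names(df)) {
      stop("map spec references unknown column '", col, "' in ", spec$countrytable,
        call. = FALSE
      )
    }
  }
  table <- data.frame(
    iso3 = as.character(df[[spec$country]]),
    year = as.character(df[[spec$year]]),
    proportion = as.numeric(df[[spec$var]]),
    stringsAsFactors = FALSE
  )
  table <- table[!is.na(table$proportion), , drop = FALSE]
  if (nrow(table) == 0) stop("country table has no usable rows", call. = FALSE)
  boundaries <- load_boundaries(boundaries_path, code_property)
  binning <- build_binning(table$proportion, scale = spec$varscale)
  varlabel <- if (is.null(spec$varlabel)) "Proportion" else spec$varlabel
  img_dir <- prepare_output(out_dir, force)
  created <- run_stage(out_dir, {
    world <- render_map_frames(boundaries, table, "world", img_dir,
      varlabel = varlabel, binning = binning, width = width, height = height
    )
    region_dir <- file.path(img_dir, "region")
    region <- render_map_frames(boundaries, table, "region", region_dir,
      varlabel = varlabel, binning = binning, width = width, height = height
    )
    v1 <- write_viewer(world$files, paste("World map:", varlabel),
      file.path(out_dir, "map1_viewer.html")
    )
    v2 <- write_viewer(region$files, paste("Region map:", varlabel),
      file.path(out_dir, "map2_viewer.html")
    )
    list(
      frames_world = world$files, frames_region = region$files,
      viewer1 = v1, viewer2 = v2, unmatched = world$unmatched,
      years = world$years
    )
  })
  finish_run(out_dir, c(
    sprintf("maps: %d year frame(s) x 2 modes, %d countr%s with data",
      length(created$years), length(unique(table$iso3)),
      if (length(unique(table$iso3)) == 1) "y" else "ies"
    ),
    if (length(created$unmatched) > 0) {
      sprintf("unmatched ISO-3 code(s), drawn in no frame: %s",
        paste(created$unmatched, collapse = ", ")
      )
    } else {
      "all ISO-3 codes matched a boundary polygon"
    },
    sprintf("viewers: %s, %s", created$viewer1, created$viewer2)
  ), created)
}
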