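#' Read a single HICDEP-style table
#'
#' Reads one comma-separated table (RFC 4180 quoting, header row, UTF-8 with
#' optional BOM) and returns it untyped: every cell is kept as text, with the
#' empty string and the literal `"NA"` both standing for a missing value.
#' Typing (dates, numbers) happens later in [load_cohort()].
#'
#' @param path Path to a `.csv` file.
#' @param name Table identifier; defaults to the file name without extension.
#' @return An object of class `hicdep_table`: a list with elements `name`,
#'   `columns` (character vector of column names) and `data` (a data frame of
#'   character columns, one per column name).
#' @examples
#' p <- tempfile(fileext = ".csv")
#' writeLines(c("patient,aids_y", "P1,0", "P2,1"), p)
#' tab <- read_table(p, "basic")
#' tab$columns
#' @export
read_table <- function(path, name = sub("\\.[cC][sS][vV]$", "", basename(path))) {
  if (!file.exists(path)) {
    stop("table '", name, "': file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path,
    colClasses = "character", check.names = FALSE,
    na.strings = character(), fileEncoding = "UTF-8-BOM",
    stringsAsFactors = FALSE
  )
  cols <- names(df)
  dup <- unique(cols[duplicated(cols)])
  if (length(dup) > 0) {
    stop("table '", name, "': duplicate column name(s): ",
      paste(dup, collapse = ", "),
      call. = FALSE
    )
  }
  structure(list(name = name, columns = cols, data = df),
    class = "hicdep_table"
  )
}

#' @export
print.hicdep_table <- function(x, ...) {
  cat(sprintf(
    "<hicdep_table '%s': %d rows x %d columns>\n",
    x$name, nrow(x$data), length(x$columns)
  ))
  invisible(x)
}

is_missing_cell <- function(x) {
  is.na(x) | trimws(x) == "" | trimws(x) == "NA"
}

#' Parse ISO-8601 dates strictly
#'
#' Accepts only `YYYY-MM-DD`; empty/whitespace cells and the literal `"NA"` are
#' missing. Any other shape, or an impossible calendar date such as
#' `2011-13-01`, is flagged rather than guessed at: silent coercion of
#' ambiguous date dialects (`15/03/2011`) is a classic source of cohort-data
#' bugs.
#'
#' @param text Character vector of cell values.
#' @return A list with `date` (a `Date` vector, `NA` where missing or invalid)
#'   and `bad` (logical vector marking cells that are neither missing nor a
#'   valid ISO date).
#' @examples
#' parse_date(c("2011-03-15", "", "15/03/2011"))
#' @export
parse_date <- function(text) {
  text <- as.character(text)
  miss <- is_missing_cell(text)
  shaped <- !miss & grepl("^\\s*\\d{4}-\\d{2}-\\d{2}\\s*$", text)
  out <- rep(as.Date(NA), length(text))
  out[shaped] <- as.Date(trimws(text[shaped]), format = "%Y-%m-%d")
  # as.Date() yields NA for impossible dates like 2011-02-30
  bad <- (!miss & !shaped) | (shaped & is.na(out))
  out[bad] <- NA
  list(date = out, bad = bad)
}

type_column <- function(x) {
  # numeric typing for non-date columns; anything else stays character
  x[is_missing_cell(x)] <- NA
  utils::type.convert(x, as.is = TRUE, na.strings = c("", "NA"))
}

#' Load and validate a flat-file HICDEP cohort
#'
#' Reads one CSV per requested table from `dir` (file name = table name +
#' `.csv`), parses the declared date columns under the strict ISO rule of
#' [parse_date()], converts purely numeric columns to numbers, and
#' cross-checks subject identifiers: every identifier in a longitudinal or
#' event table is expected in the `basic`-equivalent table (the first table
#' listed). Unknown extra columns are retained untouched.
#'
#' @param dir Directory containing the table files.
#' @param tables Character vector of table names; the first is the
#'   patient-register table that defines the subject set.
#' @param id_field Subject identifier column, present in every table.
#' @param date_cols Named list mapping table name to its date column names.
#' @return A list with `cohort` (class `cohort_data`: `tables` — named list of
#'   typed data frames, `id_field`, `subjects`) and `report` (class
#'   `cohort_validation`: data frames `errors` and `warnings` with columns
#'   `table`, `column`, `row`, `message`). An empty `errors` table means the
#'   cohort is usable downstream.
#' @examples
#' dir <- system.file("extdata", "democohort", package = "cohortviz")
#' res <- load_cohort(dir,
#'   tables = c("basic", "lab_cd4", "art", "follow"),
#'   date_cols = list(
#'     basic = "enrol_d", lab_cd4 = "cd4_d",
#'     art = "art_sd", follow = "l_alive_d"
#'   )
#' )
#' nrow(res$report$errors)
#' @export
load_cohort <- function(dir, tables, id_field = "patient", date_cols = list()) {
  if (!dir.exists(dir)) stop("cohort directory not found: ", dir, call. = FALSE)
  paths <- file.path(dir, paste0(tables, ".csv"))
  absent <- tables[!file.exists(paths)]
  if (length(absent) > 0) {
    stop("missing table file(s) in ", dir, ": ",
      paste0(absent, ".csv", collapse = ", "),
      call. = FALSE
    )
  }
  errors <- warnings <- list()
  note <- function(store, table, column, row, message) {
    c(store, list(data.frame(
      table = table, column = column, row = row,
      message = message, stringsAsFactors = FALSE
    )))
  }

  typed <- list()
  for (i in seq_along(tables)) {
    tab <- read_table(paths[i], tables[i])
    df <- tab$data
    if (!id_field %in% names(df)) {
      errors <- note(
        errors, tables[i], id_field, NA_integer_,
        sprintf("id field '%s' absent from table", id_field)
      )
    }
    dcols <- intersect(date_cols[[tables[i]]], names(df))
    for (dc in setdiff(date_cols[[tables[i]]], names(df))) {
      errors <- note(
        errors, tables[i], dc, NA_integer_,
        "declared date column absent from table"
      )
    }
    for (dc in dcols) {
      parsed <- parse_date(df[[dc]])
      for (r in which(parsed$bad)) {
        errors <- note(
          errors, tables[i], dc, r,
          sprintf("invalid date '%s' (expected YYYY-MM-DD)", df[[dc]][r])
        )
      }
      df[[dc]] <- parsed$date
    }
    for (cc in setdiff(names(df), dcols)) {
      df[[cc]] <- type_column(df[[cc]])
    }
    typed[[tables[i]]] <- df
  }

  subjects <- character()
  base_name <- tables[1]
  if (id_field %in% names(typed[[base_name]])) {
    ids <- as.character(typed[[base_name]][[id_field]])
    subjects <- unique(ids[!is.na(ids)])
    for (nm in tables[-1]) {
      if (!id_field %in% names(typed[[nm]])) next
      other <- as.character(typed[[nm]][[id_field]])
      stray <- which(!is.na(other) & !other %in% subjects)
      for (r in stray) {
        warnings <- note(
          warnings, nm, id_field, r,
          sprintf("subject '%s' not present in '%s' (row retained)", other[r], base_name)
        )
      }
    }
  }

  empty_report <- data.frame(
    table = character(), column = character(),
    row = integer(), message = character(), stringsAsFactors = FALSE
  )
  report <- structure(
    list(
      errors = if (length(errors)) do.call(rbind, errors) else empty_report,
      warnings = if (length(warnings)) do.call(rbind, warnings) else empty_report
    ),
    class = "cohort_validation"
  )
  cohort <- structure(
    list(tables = typed, id_field = id_field, subjects = subjects),
    class = "cohort_data"
  )
  list(cohort = cohort, report = report)
}

#' @export
print.cohort_data <- function(x, ...) {
  cat(sprintf(
    "<cohort_data: %d subjects, %d tables (%s)>\n",
    length(x$subjects), length(x$tables),
    paste(names(x$tables), collapse = ", ")
  ))
  invisible(x)
}

#' @export
print.cohort_validation <- function(x, ...) {
  cat(sprintf(
    "<cohort_validation: %d error(s), %d warning(s)>\n",
    nrow(x$errors), nrow(x$warnings)
  ))
  if (nrow(x$errors) > 0) print(utils::head(x$errors, 10))
  invisible(x)
}

#' Write a cohort back to comma-separated files
#'
#' Inverse of [load_cohort()]: one CSV per table, dates formatted as
#' `YYYY-MM-DD`, missing values written as empty cells. Re-loading the written
#' directory reproduces the cohort cell-for-cell.
#'
#' @param cohort A `cohort_data` object.
#' @param dir Output directory (created if absent).
#' @param force Overwrite existing table files when `TRUE`.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir, force = FALSE) {
  stopifnot(inherits(cohort, "cohort_data"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(names(cohort$tables), ".csv"))
  if (!force && any(file.exists(paths))) {
    stop("refusing to overwrite existing table files in ", dir,
      " (use force = TRUE)",
      call. = FALSE
    )
  }
  for (i in seq_along(cohort$tables)) {
    df <- cohort$tables[[i]]
    for (cc in names(df)) {
      if (inherits(df[[cc]], "Date")) df[[cc]] <- format(df[[cc]], "%Y-%m-%d")
    }
    utils::write.csv(df, paths[i], row.names = FALSE, na = "")
  }
  invisible(paths)
}
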