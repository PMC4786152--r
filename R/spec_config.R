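# Spec-file parsing and the restricted expression mini-language.
#
# Plot specifications are plain CSV files (columns name,specification[,details])
# the user edits by hand. Subset and indicator definitions inside them are
# written in a closed expression language -- column references, literals,
# comparisons, and/or/not, `in (...)` membership and `missing(col)` -- which is
# parsed to an AST and interpreted. Config files are never executed as code.
# The R-flavoured spellings seen in legacy spec files (`tab$col`, `&`, `|`,
# `!`, `%in%`, `is.na`) are accepted as synonyms and normalized away.

# ---- tokenizer -------------------------------------------------------------

TOKEN_PATTERNS <- list(
  c("WS", "^\\s+"),
  c("NUM", "^[0-9]+\\.?[0-9]*([eE][+-]?[0-9]+)?"),
  c("NUM", "^\\.[0-9]+([eE][+-]?[0-9]+)?"),
  c("STR", "^\"[^\"]*\""),
  c("STR", "^'[^']*'"),
  c("IN", "^%in%"),
  c("ID", "^[A-Za-z_.][A-Za-z0-9_.]*"),
  c("CMP", "^(==|!=|<=|>=)"),
  c("AND", "^&&?"),
  c("OR", "^\\|\\|?"),
  c("NOT", "^!"),
  c("CMP", "^[<>]"),
  c("MINUS", "^-"),
  c("LP", "^\\("),
  c("RP", "^\\)"),
  c("COMMA", "^,"),
  c("DOLLAR", "^\\$")
)

KEYWORDS <- c(
  and = "AND", or = "OR", not = "NOT", `in` = "IN",
  missing = "MISSING", is.na = "MISSING",
  true = "BOOL", false = "BOOL"
)

tokenize_expression <- function(text) {
  tokens <- list()
  pos <- 1L
  rest <- text
  while (nchar(rest) > 0) {
    hit <- NULL
    for (tp in TOKEN_PATTERNS) {
      m <- regmatches(rest, regexpr(tp[2], rest))
      if (length(m) == 1) {
        hit <- list(type = tp[1], value = m, pos = pos)
        break
      }
    }
    if (is.null(hit)) {
      stop(sprintf(
        "syntax error at position %d: unexpected character '%s'",
        pos, substr(rest, 1, 1)
      ), call. = FALSE)
    }
    n <- nchar(hit$value)
    if (hit$type == "ID") {
      kw <- KEYWORDS[tolower(hit$value)]
      if (!is.na(kw)) hit$type <- unname(kw)
    }
    if (hit$type != "WS") tokens[[length(tokens) + 1]] <- hit
    pos <- pos + n
    rest <- substr(rest, n + 1L, nchar(rest))
  }
  tokens[[length(tokens) + 1]] <- list(type = "EOF", value = "", pos = pos)
  tokens
}

# ---- parser (recursive descent; precedence or < and < not < comparison) ----

parse_expression_tokens <- function(tokens) {
  st <- new.env(parent = emptyenv())
  st$tokens <- tokens
  st$i <- 1L
  peek <- function() st$tokens[[st$i]]
  advance <- function() {
    tk <- st$tokens[[st$i]]
    st$i <- st$i + 1L
    tk
  }
  fail <- function(tk, expected) {
    what <- if (tk$type == "EOF") "end of expression" else sprintf("'%s'", tk$value)
    stop(sprintf("syntax error at position %d: unexpected %s (expected %s)",
      tk$pos, what, expected
    ), call. = FALSE)
  }
  expect <- function(type, expected) {
    tk <- peek()
    if (tk$type != type) fail(tk, expected)
    advance()
  }

  parse_operand <- function() {
    tk <- peek()
    if (tk$type == "ID") {
      advance()
      name <- tk$value
      if (peek()$type == "DOLLAR") { # strip `table$col` prefixes
        advance()
        coltk <- expect("ID", "column name after '$'")
        name <- coltk$value
      }
      return(list(kind = "col", name = name))
    }
    if (tk$type == "NUM") {
      advance()
      return(list(kind = "num", value = as.numeric(tk$value)))
    }
    if (tk$type == "MINUS") {
      advance()
      num <- expect("NUM", "a number after '-'")
      return(list(kind = "num", value = -as.numeric(num$value)))
    }
    if (tk$type == "STR") {
      advance()
      return(list(kind = "str", value = substr(tk$value, 2, nchar(tk$value) - 1)))
    }
    if (tk$type == "BOOL") {
      advance()
      return(list(kind = "bool", value = tolower(tk$value) == "true"))
    }
    fail(tk, "a column name or literal")
  }

  parse_literal <- function() {
    node <- parse_operand()
    if (node$kind == "col") {
      stop(sprintf("membership list must contain literals, not column '%s'", node$name),
        call. = FALSE
      )
    }
    node
  }

  parse_primary <- function() {
    tk <- peek()
    if (tk$type == "LP") {
      advance()
      inner <- parse_or()
      expect("RP", "')'")
      return(inner)
    }
    if (tk$type == "MISSING") {
      advance()
      expect("LP", "'(' after missing")
      coltk <- expect("ID", "a column name")
      expect("RP", "')'")
      return(list(kind = "missing", col = coltk$value))
    }
    lhs <- parse_operand()
    tk <- peek()
    if (tk$type == "CMP") {
      advance()
      rhs <- parse_operand()
      return(list(kind = "cmp", op = tk$value, lhs = lhs, rhs = rhs))
    }
    if (tk$type == "IN") {
      advance()
      # tolerate R's c(...) vector notation around the membership list
      if (peek()$type == "ID" && peek()$value == "c") advance()
      expect("LP", "'(' after in")
      values <- list(parse_literal())
      while (peek()$type == "COMMA") {
        advance()
        values[[length(values) + 1]] <- parse_literal()
      }
      expect("RP", "')'")
      return(list(kind = "in", operand = lhs, values = values))
    }
    fail(tk, "a comparison operator or 'in'")
  }

  parse_not <- function() {
    if (peek()$type == "NOT") {
      advance()
      return(list(kind = "not", arg = parse_not()))
    }
    parse_primary()
  }

  parse_and <- function() {
    node <- parse_not()
    while (peek()$type == "AND") {
      advance()
      node <- list(kind = "and", lhs = node, rhs = parse_not())
    }
    node
  }

  parse_or <- function() {
    node <- parse_and()
    while (peek()$type == "OR") {
      advance()
      node <- list(kind = "or", lhs = node, rhs = parse_and())
    }
    node
  }

  node <- parse_or()
  tk <- peek()
  if (tk$type != "EOF") fail(tk, "end of expression")
  node
}

ast_columns <- function(node) {
  switch(node$kind,
    col = node$name,
    missing = node$col,
    cmp = c(ast_columns(node$lhs), ast_columns(node$rhs)),
    `in` = ast_columns(node$operand),
    not = ast_columns(node$arg),
    and = ,
    or = c(ast_columns(node$lhs), ast_columns(node$rhs)),
    character()
  )
}

#' Parse a subset/indicator expression
#'
#' Compiles the restricted expression language used in plot-specification
#' files into a predicate object. Supported constructs: column references
#' (optionally written `table$col`; the prefix is stripped), numeric, string
#' and true/false literals, comparisons (`== != < <= > >=`), `and`/`or`/`not`
#' (or `&`/`|`/`!`), membership `col in (v1, v2)` (or `%in% c(...)`) and
#' `missing(col)` (or `is.na(col)`). Nothing is ever executed as R code;
#' anything outside this grammar is a syntax error with a character position.
#'
#' @param text Expression text, e.g. `"cd4_v > 0 and not missing(cd4_v)"`.
#' @return An object of class `cohort_predicate` with elements `ast`, `text`
#'   and `columns` (the referenced column names).
#' @examples
#' p <- parse_expression("aids_cl_y in (0,1) and not missing(aids_cl_y)")
#' p$columns
#' @export
parse_expression <- function(text) {
  if (!is.character(text) || length(text) != 1 || !nzchar(trimws(text))) {
    stop("expression text must be a single nonempty string", call. = FALSE)
  }
  ast <- parse_expression_tokens(tokenize_expression(text))
  structure(
    list(ast = ast, text = text, columns = unique(ast_columns(ast))),
    class = "cohort_predicate"
  )
}

#' @export
print.cohort_predicate <- function(x, ...) {
  cat("<cohort_predicate> ", deparse_predicate(x), "\n", sep = "")
  invisible(x)
}

deparse_node <- function(node) {
  lit <- function(v) {
    switch(v$kind,
      num = format(v$value, digits = 15),
      str = paste0('"', v$value, '"'),
      bool = if (v$value) "true" else "false",
      col = v$name
    )
  }
  switch(node$kind,
    col = ,
    num = ,
    str = ,
    bool = lit(node),
    missing = paste0("missing(", node$col, ")"),
    cmp = paste(deparse_node(node$lhs), node$op, deparse_node(node$rhs)),
    `in` = paste0(
      deparse_node(node$operand), " in (",
      paste(vapply(node$values, lit, ""), collapse = ", "), ")"
    ),
    not = paste0("not ", deparse_node(node$arg)),
    and = paste0("(", deparse_node(node$lhs), " and ", deparse_node(node$rhs), ")"),
    or = paste0("(", deparse_node(node$lhs), " or ", deparse_node(node$rhs), ")")
  )
}

#' Render a predicate back to canonical expression text
#'
#' The canonical form uses the keyword dialect (`and`, `or`, `not`, `in`,
#' `missing`) and parses back to an identical syntax tree.
#'
#' @param pred A `cohort_predicate`.
#' @return A single string.
#' @export
deparse_predicate <- function(pred) {
  stopifnot(inherits(pred, "cohort_predicate"))
  deparse_node(pred$ast)
}

coerce_literal <- function(value, column) {
  if (inherits(column, "Date") && is.character(value)) {
    d <- parse_date(value)
    if (!d$bad[1]) {
      return(d$date)
    }
  }
  if (is.character(column)) {
    return(as.character(value))
  }
  value
}

eval_node <- function(node, df, n) {
  get_col <- function(name) {
    if (!name %in% names(df)) {
      stop("expression references unknown column '", name, "'", call. = FALSE)
    }
    df[[name]]
  }
  operand <- function(x) if (x$kind == "col") get_col(x$name) else x$value
  switch(node$kind,
    missing = is.na(get_col(node$col)),
    cmp = {
      lhs <- operand(node$lhs)
      rhs <- operand(node$rhs)
      if (node$lhs$kind == "col" && node$rhs$kind != "col") {
        rhs <- coerce_literal(rhs, lhs)
      }
      if (node$rhs$kind == "col" && node$lhs$kind != "col") {
        lhs <- coerce_literal(lhs, rhs)
      }
      out <- switch(node$op,
        "==" = lhs == rhs, "!=" = lhs != rhs,
        "<" = lhs < rhs, "<=" = lhs <= rhs,
        ">" = lhs > rhs, ">=" = lhs >= rhs
      )
      rep_len(out, n)
    },
    `in` = {
      x <- operand(node$operand)
      vals <- lapply(node$values, function(v) v$value)
      if (node$operand$kind == "col") {
        vals <- lapply(vals, function(v) coerce_literal(v, x)[1])
      }
      set <- unlist(vals)
      out <- rep_len(as.character(x) %in% as.character(set), n)
      out[is.na(rep_len(x, n))] <- NA # three-valued: missing in (...) is missing
      out
    },
    not = !eval_node(node$arg, df, n),
    # base R's & and | implement Kleene three-valued logic already
    and = eval_node(node$lhs, df, n) & eval_node(node$rhs, df, n),
    or = eval_node(node$lhs, df, n) | eval_node(node$rhs, df, n),
    stop("expression does not evaluate to a logical value", call. = FALSE)
  )
}

#' Evaluate a predicate over a table
#'
#' Three-valued logic: comparisons with a missing cell yield `NA`,
#' `missing(col)` yields `TRUE`/`FALSE`, and `and`/`or` follow Kleene
#' semantics. Callers that subset treat an `NA` row result as "excluded".
#'
#' @param pred A `cohort_predicate` from [parse_expression()].
#' @param table A data frame (typed table from [load_cohort()]).
#' @return Logical vector, one element per row (possibly `NA`).
#' @examples
#' df <- data.frame(cd4_v = c(50, NA, 0))
#' evaluate_predicate(parse_expression("cd4_v > 0 and not missing(cd4_v)"), df)
#' @export
evaluate_predicate <- function(pred, table) {
  stopifnot(inherits(pred, "cohort_predicate"))
  if (inherits(table, "hicdep_table")) table <- table$data
  absent <- setdiff(pred$columns, names(table))
  if (length(absent) > 0) {
    stop("expression references unknown column(s): ",
      paste(absent, collapse = ", "),
      call. = FALSE
    )
  }
  eval_node(pred$ast, table, nrow(table))
}

# rows kept when subsetting on a predicate: NA counts as FALSE
predicate_keep <- function(pred, table) {
  v <- evaluate_predicate(pred, table)
  !is.na(v) & v
}

# ---- spec-file parsing -----------------------------------------------------

spec_error <- function(name, fmt, ...) {
  stop(sprintf("spec field '%s': %s", name, sprintf(fmt, ...)), call. = FALSE)
}

parse_spec_number <- function(name, text, integer = FALSE, min = -Inf) {
  v <- suppressWarnings(as.numeric(trimws(text)))
  if (is.na(v)) spec_error(name, "'%s' is not a number", text)
  if (integer && v != round(v)) spec_error(name, "'%s' is not an integer", text)
  if (v < min) spec_error(name, "value %s is below the minimum %s", v, min)
  v
}

parse_spec_enum <- function(name, text, choices, aliases = character()) {
  v <- trimws(text)
  if (v %in% names(aliases)) v <- unname(aliases[v])
  if (!v %in% choices) {
    spec_error(
      name, "'%s' is not one of {%s}", text,
      paste(choices, collapse = ", ")
    )
  }
  v
}

# numeric list in either "c(0,25,100)" or "0,25,100" notation
parse_spec_numlist <- function(name, text) {
  body <- trimws(text)
  body <- sub("^c\\s*\\(", "", body)
  body <- sub("\\)\\s*$", "", body)
  parts <- trimws(strsplit(body, ",")[[1]])
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0) spec_error(name, "empty numeric list '%s'", text)
  v <- suppressWarnings(as.numeric(parts))
  if (anyNA(v)) spec_error(name, "non-numeric entry in '%s'", text)
  v
}

parse_spec_pair <- function(name, text) {
  v <- parse_spec_numlist(name, text)
  if (length(v) != 2) spec_error(name, "expected exactly two numbers, got %d", length(v))
  if (v[1] >= v[2]) spec_error(name, "limits must be strictly increasing (%s, %s)", v[1], v[2])
  v
}

# value list that may be non-numeric (group codes)
parse_spec_valuelist <- function(name, text) {
  body <- trimws(text)
  body <- sub("^c\\s*\\(", "", body)
  body <- sub("\\)\\s*$", "", body)
  parts <- trimws(strsplit(body, ",")[[1]])
  parts <- gsub("^['\"]|['\"]$", "", parts)
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0) spec_error(name, "empty value list '%s'", text)
  parts
}

#' Parse a `grouplabels` mapping
#'
#' Accepts the pipe-delimited `value = label` notation used in spec files,
#' e.g. `"0 = No AIDS|1 = AIDS|9 = AIDS unknown"`.
#'
#' @param text Mapping text; empty or all-whitespace means "no mapping"
#'   (callers label groups `"Group "` + value).
#' @return A named character vector (names are group values), or `NULL` when
#'   `text` is empty.
#' @export
parse_group_labels <- function(text) {
  if (is.null(text) || !nzchar(trimws(text))) {
    return(NULL)
  }
  parts <- strsplit(text, "|", fixed = TRUE)[[1]]
  keys <- labels <- character(length(parts))
  for (i in seq_along(parts)) {
    eq <- regexpr("=", parts[i], fixed = TRUE)
    if (eq < 0) spec_error("grouplabels", "entry '%s' lacks '='", parts[i])
    keys[i] <- trimws(substr(parts[i], 1, eq - 1))
    labels[i] <- trimws(substr(parts[i], eq + 1, nchar(parts[i])))
  }
  if (anyDuplicated(keys)) {
    spec_error(
      "grouplabels", "duplicate group value '%s'",
      keys[duplicated(keys)][1]
    )
  }
  stats::setNames(labels, keys)
}

group_label_for <- function(labels, value) {
  value <- as.character(value)
  if (is.null(labels)) {
    return(paste("Group", value))
  }
  out <- unname(labels[value])
  out[is.na(out)] <- paste("Group", value[is.na(out)])
  out
}

# field table per spec kind: parser closures + defaults (NULL = absent)
panel1_fields <- function() {
  txt <- function(name) function(v) v
  prd <- function(name) function(v) parse_expression(v)
  list(
    id = list(parse = txt, default = NULL),
    longtablename = list(parse = txt, default = NULL),
    longvar = list(parse = txt, default = NULL),
    longvardate = list(parse = txt, default = NULL),
    longsubset = list(parse = prd, default = NULL),
    eventtablename = list(parse = txt, default = NULL),
    event = list(parse = txt, default = NULL),
    enddate = list(parse = txt, default = NULL),
    grouptablename = list(parse = txt, default = NULL),
    group = list(parse = txt, default = NULL),
    groupsubset = list(
      parse = function(name) function(v) parse_spec_valuelist(name, v),
      default = NULL
    ),
    starttablename = list(parse = txt, default = NULL),
    startdate = list(parse = txt, default = NULL),
    starttype = list(
      parse = function(name) function(v) parse_spec_enum(name, v, c("first", "last")),
      default = "first"
    ),
    longvartrans = list(
      parse = function(name) function(v) {
        parse_spec_enum(name, v, c("identity", "sqrt", "log", "log10"),
          aliases = c(I = "identity")
        )
      },
      default = "identity"
    ),
    maxtime = list(
      parse = function(name) function(v) parse_spec_number(name, v, integer = TRUE, min = 1),
      default = 730
    ),
    long2eventwindow = list(
      parse = function(name) function(v) parse_spec_number(name, v, integer = TRUE, min = 0),
      default = 360
    ),
    longvarlim = list(parse = function(name) function(v) parse_spec_pair(name, v), default = NULL),
    problim = list(parse = function(name) function(v) parse_spec_pair(name, v), default = NULL),
    longticks = list(parse = function(name) function(v) parse_spec_numlist(name, v), default = NULL),
    longlabel = list(parse = txt, default = "Longitudinal Value"),
    timelabel = list(parse = txt, default = "Days"),
    eventlabel = list(parse = txt, default = "Probability of Death"),
    grouplabels = list(parse = function(name) function(v) parse_group_labels(v), default = NULL)
  )
}

bubble_fields <- function() {
  txt <- function(name) function(v) v
  prd <- function(name) function(v) parse_expression(v)
  list(
    vartable = list(parse = txt, default = NULL),
    var1 = list(parse = prd, default = NULL),
    var2 = list(parse = prd, default = NULL),
    vartablesubset = list(parse = prd, default = NULL),
    eventdate = list(parse = txt, default = NULL),
    eventperiod = list(
      parse = function(name) function(v) parse_spec_enum(name, v, c("month", "quarter", "year")),
      default = "year"
    ),
    group = list(parse = txt, default = NULL),
    var1label1 = list(parse = txt, default = NULL),
    var1label0 = list(parse = txt, default = NULL),
    var2label1 = list(parse = txt, default = NULL),
    var2label0 = list(parse = txt, default = NULL),
    var1label = list(parse = txt, default = NULL),
    var2label = list(parse = txt, default = NULL),
    minnum = list(
      parse = function(name) function(v) parse_spec_number(name, v, integer = TRUE, min = 0),
      default = 10
    )
  )
}

map_fields <- function() {
  txt <- function(name) function(v) v
  list(
    countrytable = list(parse = txt, default = NULL),
    var = list(parse = txt, default = NULL),
    country = list(parse = txt, default = NULL),
    year = list(parse = txt, default = NULL),
    varlabel = list(parse = txt, default = NULL),
    varscale = list(
      parse = function(name) function(v) {
        parse_spec_enum(name, v, c("auto", "proportion", "percent"))
      },
      default = "auto"
    )
  )
}

#' Parse a plot-specification file
#'
#' Reads a CSV with columns `name,specification` (a `details` column, if
#' present, is ignored), binds every recognized name, applies the documented
#' default to every omitted one, and warns about unknown names so that
#' forward-compatible spec files still run. Missing required fields (table and
#' column names) are left absent (`NULL`); they are checked when the plot is
#' built, not at parse time.
#'
#' Defaults applied when a name is omitted: `starttype` `"first"`,
#' `longvartrans` `"identity"`, `maxtime` 730 days, `long2eventwindow` 360
#' days, `longlabel` `"Longitudinal Value"`, `timelabel` `"Days"`,
#' `eventlabel` `"Probability of Death"` (panel 1); `eventperiod` `"year"`,
#' `minnum` 10 (bubbles); `varscale` `"auto"` (maps).
#'
#' @param path Spec CSV path.
#' @param kind One of `"panel1"`, `"bubble"`, `"map"`.
#' @return A list of class `panel1_spec`, `bubble_spec` or `map_spec`.
#' @examples
#' p <- system.file("extdata", "demospecs", "panel1_specs.csv", package = "cohortviz")
#' spec <- parse_spec(p, "panel1")
#' spec$maxtime
#' @export
parse_spec <- function(path, kind = c("panel1", "bubble", "map")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("spec file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path,
    colClasses = "character", check.names = FALSE,
    na.strings = character(), fileEncoding = "UTF-8-BOM"
  )
  if (!all(c("name", "specification") %in% names(df))) {
    stop("spec file must have columns 'name' and 'specification': ", path, call. = FALSE)
  }
  fields <- switch(kind,
    panel1 = panel1_fields(),
    bubble = bubble_fields(),
    map = map_fields()
  )
  spec <- lapply(fields, function(f) f$default)
  seen <- character()
  for (i in seq_len(nrow(df))) {
    nm <- trimws(df$name[i])
    raw <- df$specification[i]
    if (!nzchar(nm)) next
    if (!nm %in% names(fields)) {
      warning("spec file ", basename(path), ": unknown name '", nm, "' ignored",
        call. = FALSE
      )
      next
    }
    if (nm %in% seen) spec_error(nm, "field given more than once")
    seen <- c(seen, nm)
    if (!nzchar(trimws(raw))) next # blank specification keeps the default
    spec[[nm]] <- fields[[nm]]$parse(nm)(raw)
  }
  structure(spec, class = paste0(kind, "_spec"))
}

require_spec_fields <- function(spec, fields, kind) {
  absent <- fields[vapply(spec[fields], is.null, TRUE)]
  if (length(absent) > 0) {
    stop(sprintf(
      "%s spec is missing required field(s): %s",
      kind, paste(absent, collapse = ", ")
    ), call. = FALSE)
  }
}
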