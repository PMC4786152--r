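test_that("parse_expression builds the expected syntax trees", {
  p <- parse_expression("cd4_v_cmp < 200")
  expect_equal(p$ast$kind, "cmp")
  expect_equal(p$ast$op, "<")
  expect_equal(p$ast$lhs, list(kind = "col", name = "cd4_v_cmp"))
  expect_equal(p$ast$rhs, list(kind = "num", value = 200))

  q <- parse_expression("aids_cl_y in (0,1) and not missing(aids_cl_y)")
  expect_equal(q$ast$kind, "and")
  expect_equal(q$ast$lhs$kind, "in")
  expect_equal(q$ast$rhs$kind, "not")
  expect_equal(q$columns, "aids_cl_y")

  # table$col prefixes of legacy spec files are stripped
  r <- parse_expression("basic_cd4$cd4_v_cmp < 200")
  expect_equal(r$ast$lhs$name, "cd4_v_cmp")

  # R-flavoured spellings are synonyms for the keyword dialect
  s1 <- parse_expression("cd4_v > 0 &! is.na(cd4_v)")
  s2 <- parse_expression("cd4_v > 0 and not missing(cd4_v)")
  expect_equal(s1$ast, s2$ast)
  expect_equal(
    parse_expression("x %in% (1, 2)")$ast,
    parse_expression("x in (1, 2)")$ast
  )
})

test_that("malformed or unsafe expressions are rejected, never executed", {
  expect_error(parse_expression("cd4_v <"), "syntax error at position")
  expect_error(parse_expression("cd4_v < 200 extra"), "position 13")
  expect_error(parse_expression(""), "nonempty")
  # function calls other than missing/is.na are not part of the grammar
  expect_error(parse_expression("system('ls') == 1"), "syntax error")
  expect_error(parse_expression("x = 1"), "syntax error")
})

test_that("evaluation uses three-valued logic over typed columns", {
  df <- data.frame(cd4_v = c(50, NA, 0))
  p <- parse_expression("cd4_v > 0 and not missing(cd4_v)")
  expect_equal(evaluate_predicate(p, df), c(TRUE, FALSE, FALSE))

  expect_equal(
    evaluate_predicate(parse_expression("1 == 1"), data.frame(x = 1:3)),
    rep(TRUE, 3)
  )
  expect_equal(
    evaluate_predicate(parse_expression("cd4_v > 0"), df),
    c(TRUE, NA, FALSE)
  )
  expect_equal(
    evaluate_predicate(parse_expression("cd4_v in (0, 50)"), df),
    c(TRUE, NA, TRUE)
  )
  expect_error(
    evaluate_predicate(parse_expression("xyz > 1"), df),
    "unknown column.*xyz"
  )
  # date columns compare against ISO string literals
  dd <- data.frame(d = as.Date(c("2010-06-01", "2012-01-01", NA)))
  expect_equal(
    evaluate_predicate(parse_expression('d < "2011-01-01"'), dd),
    c(TRUE, FALSE, NA)
  )
})

test_that("parse -> deparse -> parse is idempotent", {
  cases <- c(
    "cd4_v_cmp < 200",
    "aids_cl_y in (0,1) and not missing(aids_cl_y)",
    "not (a == 1 or b == 2) and c >= 3.5",
    'site == "lima" or site in ("rio", "bsas")',
    "x != 1 and not missing(y) and z <= 10"
  )
  for (txt in cases) {
    p1 <- parse_expression(txt)
    p2 <- parse_expression(deparse_predicate(p1))
    expect_equal(p2$ast, p1$ast, info = txt)
  }
})

test_that("evaluation agrees with a brute-force row-by-row interpreter", {
  set.seed(42)
  ops <- c("<", "<=", ">", ">=", "==", "!=")
  for (rep in 1:30) {
    n <- sample(3:12, 1)
    df <- data.frame(
      a = sample(c(NA, 0:5), n, replace = TRUE),
      b = sample(c(NA, seq(-2, 2, 0.5)), n, replace = TRUE)
    )
    o1 <- sample(ops, 1)
    o2 <- sample(ops, 1)
    t1 <- sample(0:5, 1)
    t2 <- sample(seq(-2, 2, 0.5), 1)
    conj <- sample(c("and", "or"), 1)
    txt <- sprintf("a %s %d %s not b %s %s", o1, t1, conj, o2, t2)
    got <- evaluate_predicate(parse_expression(txt), df)
    want <- vapply(seq_len(n), function(i) {
      lhs <- do.call(o1, list(df$a[i], t1))
      rhs <- !do.call(o2, list(df$b[i], t2))
      if (conj == "and") lhs & rhs else lhs | rhs
    }, logical(1))
    expect_identical(got, want, info = txt)
  }
})

test_that("omitted spec names take their documented defaults", {
  # empty spec file: every defaulted field at its default, the rest absent
  empty <- write_spec_file(c(dummy = "")[0])
  p1 <- parse_spec(empty, "panel1")
  expect_equal(p1$starttype, "first")
  expect_equal(p1$longvartrans, "identity")
  expect_equal(p1$maxtime, 730)
  expect_equal(p1$long2eventwindow, 360)
  expect_equal(p1$longlabel, "Longitudinal Value")
  expect_equal(p1$timelabel, "Days")
  expect_equal(p1$eventlabel, "Probability of Death")
  for (f in c(
    "id", "longtablename", "longvar", "longvardate", "longsubset",
    "eventtablename", "event", "enddate", "grouptablename", "group",
    "groupsubset", "starttablename", "startdate", "longvarlim", "problim",
    "longticks", "grouplabels"
  )) {
    expect_null(p1[[f]], info = f)
  }
  bb <- parse_spec(empty, "bubble")
  expect_equal(bb$eventperiod, "year")
  expect_equal(bb$minnum, 10)
  for (f in c(
    "vartable", "var1", "var2", "vartablesubset", "eventdate", "group",
    "var1label1", "var1label0", "var2label1", "var2label0",
    "var1label", "var2label"
  )) {
    expect_null(bb[[f]], info = f)
  }
  mp <- parse_spec(empty, "map")
  expect_equal(mp$varscale, "auto")
  for (f in c("countrytable", "var", "country", "year", "varlabel")) {
    expect_null(mp[[f]], info = f)
  }
})

test_that("explicit spec values override defaults and are validated", {
  p <- parse_spec(write_spec_file(c(maxtime = "730")), "panel1")
  expect_equal(p$maxtime, 730)
  p2 <- parse_spec(write_spec_file(c(maxtime = "365", longvartrans = "sqrt")), "panel1")
  expect_equal(p2$maxtime, 365)
  expect_equal(p2$longvartrans, "sqrt")
  expect_error(
    parse_spec(write_spec_file(c(starttype = "middle")), "panel1"),
    "first, last"
  )
  expect_error(
    parse_spec(write_spec_file(c(maxtime = "soon")), "panel1"),
    "not a number"
  )
  expect_error(
    parse_spec(write_spec_file(c(longvarlim = "c(10, 5)")), "panel1"),
    "strictly increasing"
  )
  expect_warning(
    parse_spec(write_spec_file(c(fancy_new_knob = "1")), "panel1"),
    "unknown name"
  )
  # numeric lists accept both notations
  a <- parse_spec(write_spec_file(c(longticks = "c(0,25,100)")), "panel1")
  b <- parse_spec(write_spec_file(c(longticks = "0,25,100")), "panel1")
  expect_equal(a$longticks, c(0, 25, 100))
  expect_equal(b$longticks, a$longticks)
})

test_that("group label mappings parse and reject duplicates", {
  m <- parse_group_labels("0 = No AIDS|1 = AIDS|9 = AIDS unknown")
  expect_equal(m, c(`0` = "No AIDS", `1` = "AIDS", `9` = "AIDS unknown"))
  expect_null(parse_group_labels(""))
  expect_error(parse_group_labels("1 = A|1 = B"), "duplicate")
})
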