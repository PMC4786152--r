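# Regenerates the bundled demo fixture under inst/extdata/.
# Run from the package root:  Rscript tools/make_fixture.R

devtools::load_all(".", quiet = TRUE)

dir <- file.path("inst", "extdata", "democohort")
unlink(dir, recursive = TRUE)

params <- sim_params(n_subjects = 150, seed = 4242)
cohort <- simulate_cohort(params)
write_fixture(cohort, dir, force = TRUE)

# derived tables the bubble and map demos consume (baseline CD4 at
# enrollment, then country-year proportions of baseline CD4 < 200)
basic_cd4 <- add_baseline(cohort,
  table = "basic", longtable = "lab_cd4",
  longvar = "cd4_v", longvardate = "cd4_d", anchor_col = "enrol_d",
  out_col = "cd4_base"
)
out <- basic_cd4
out$enrol_d <- format(out$enrol_d, "%Y-%m-%d")
write.csv(out, file.path(dir, "basic_cd4.csv"), row.names = FALSE, na = "")

cyt <- aggregate_country_year(
  country = basic_cd4$country,
  year = format(basic_cd4$enrol_d, "%Y"),
  indicator = !is.na(basic_cd4$cd4_base) & basic_cd4$cd4_base < 200
)
write.csv(
  data.frame(
    country = cyt$iso3, year = cyt$year, var1_prop = round(cyt$proportion, 4),
    n = cyt$denominator
  ),
  file.path(dir, "basic_cd4_country.csv"),
  row.names = FALSE, na = ""
)

cat("fixture written:", dir, "\n")
print(sapply(list.files(dir, full.names = TRUE), function(f) file.size(f)))
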