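test_that("apparent concentration is CR times plasma concentration", {
  # methyltestosterone: 12.2% of up to 40 ng/mL -> up to 4.88 ng/mL
  a <- apparent_concentration(12.2, NA, 40)
  expect_equal(a$apparent_low, 0)
  expect_equal(a$apparent_high, 4.88)
  # prednisolone: 148% of up to 400 ng/mL -> up to 592 ng/mL
  expect_equal(apparent_concentration(148, NA, 400)$apparent_high, 592)
  expect_equal(unlist(apparent_concentration(0, 1, 2)), c(apparent_low = 0,
                                                          apparent_high = 0))
})

test_that("apparent_high is monotone in CR and in the plasma bound", {
  crs <- c(0.1, 1, 5, 50, 200)
  expect_true(all(diff(apparent_concentration(crs, NA, 10)$apparent_high) > 0))
  his <- c(1, 5, 100, 1000)
  expect_true(all(diff(apparent_concentration(4.6, NA, his)$apparent_high) > 0))
})

test_that("likelihood grading reproduces the flagship fixture grades", {
  cort <- load_fixture_panel("cortisol")
  # prednisolone reaches far beyond the cortisol decision level -> high
  expect_equal(grade_likelihood(592, "pediatric transplant patients", cort$assay),
               "high")
  # corticosterone at its physiological maximum is negligible -> low
  expect_equal(grade_likelihood(4.6 / 100 * 2.0, "18 years and younger", cort$assay),
               "low")
  # no plasma data -> unknown
  expect_equal(grade_likelihood(NA, NA_character_, cort$assay), "unknown")
})

test_that("grading never returns unknown when plasma data exists", {
  for (a in available_assays()) {
    p <- load_fixture_panel(a)
    rep <- interference_report(p$assay, p$records, p$ranges, include_target = TRUE)
    with_data <- !is.na(rep$apparent_high)
    expect_false(any(rep$likelihood[with_data] == "unknown"))
    expect_true(all(rep$likelihood[!with_data] == "unknown"))
  }
})

test_that("interference report covers populations, ranks by worst case, flags unknowns", {
  t5 <- load_fixture_panel("testosterone")
  rep <- interference_report(t5$assay, t5$records, t5$ranges)
  # target excluded by default
  expect_false("testosterone" %in% rep$compound_name)
  # methyltestosterone ranks first among compounds with plasma data
  expect_equal(rep$compound_name[1], "methyltestosterone")
  known <- rep[!is.na(rep$apparent_high), ]
  expect_true(all(diff(known$apparent_high) <= 0))
  # cross-reactive anabolic steroids without human pharmacokinetic data
  expect_setequal(rep$compound_name[is.na(rep$apparent_high)],
                  c("19-norclostebol", "11beta-hydroxytestosterone",
                    "methandrostenolone", "normethandrolone"))
})

test_that("exception populations are graded separately from controls", {
  cort <- load_fixture_panel("cortisol")
  rep <- interference_report(cort$assay, cort$records, cort$ranges)
  deoxy <- rep[rep$compound_name == "21-deoxycortisol", ]
  expect_equal(deoxy$likelihood[deoxy$population == "pediatric controls"], "low")
  expect_equal(deoxy$likelihood[grepl("21-hydroxylase", deoxy$population)], "high")
})

test_that("no non-target compound grades high on the DHEA sulfate assay", {
  p <- load_fixture_panel("dhea_sulfate")
  rep <- interference_report(p$assay, p$records, p$ranges)
  expect_false(any(rep$likelihood == "high"))
  with_target <- interference_report(p$assay, p$records, p$ranges,
                                     include_target = TRUE)
  expect_true(all(with_target$likelihood[with_target$compound_name ==
                                           "dhea sulfate"] == "high"))
})

test_that("an empty plasma table grades every cross-reactive compound unknown", {
  p <- load_fixture_panel("estradiol")
  rep <- interference_report(p$assay, p$records, p$ranges[0, ])
  expect_true(all(rep$likelihood == "unknown"))
  expect_setequal(rep$compound_name, c("estrone", "ethinyl estradiol", "estriol"))
})

test_that("population-sex matching picks the vulnerable reference interval", {
  prog <- load_fixture_panel("progesterone")
  # pregnanolone occurs in women, where progesterone runs to 27 ng/mL -> low
  expect_equal(grade_likelihood(0.153, "women", prog$assay), "low")
  # the same apparent concentration in an unsexed population is judged against
  # the assay decision level (1.4 ng/mL) -> possible
  expect_equal(grade_likelihood(0.153, "adults", prog$assay), "possible")
})

test_that("reports serialize to CSV and JSON with citations intact", {
  p <- load_fixture_panel("testosterone")
  rep <- interference_report(p$assay, p$records, p$ranges)
  csvf <- withr::local_tempfile(fileext = ".csv")
  jsonf <- withr::local_tempfile(fileext = ".json")
  write_interference_report(rep, csv_path = csvf, json_path = jsonf)
  back <- utils::read.csv(csvf, stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(rep))
  j <- jsonlite::read_json(jsonf)
  expect_equal(length(j), nrow(rep))
  expect_equal(j[[1]]$citation, rep$citation[1])
})
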