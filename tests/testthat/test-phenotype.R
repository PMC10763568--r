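map_fixture <- function() suppressWarnings(infer_dosage_map())

test_that("arm assignment follows the refined span boundaries", {
  map <- map_fixture()
  t5 <- load_packaged_cohort("table5")
  t5$arm_class <- NA_character_ # force the computed path
  out <- suppressWarnings(assign_arm(t5, map))
  expect_equal(out$arm[out$case_id == "13"], "p")
  expect_equal(out$arm[out$case_id == "G"], "q")
  inside <- tibble::tibble(
    case_id = "in", karyotype_text = "47,XY,+mar", sex = "male",
    clinical_status = "abnormal", shapes = list(character(0)), mosaic = FALSE,
    clone_counts = "", inheritance = "unknown", groups = list(character(0)),
    interval_chrom = "chr11", interval_start = 50e6, interval_end = 57e6,
    build = "GRCh37", modalities = list(character(0)),
    phenotype_terms = list(character(0)), arm_class = NA_character_,
    source_table = "synthetic"
  )
  expect_equal(assign_arm(inside, map)$arm, "none")
  both <- dplyr::mutate(inside, interval_start = 40e6, interval_end = 70e6)
  expect_equal(assign_arm(both, map)$arm, "both")
})

test_that("curated arm labels override the computed assignment with a note", {
  map <- map_fixture()
  case <- tibble::tibble(
    case_id = "ov", karyotype_text = "47,XY,+mar", sex = "male",
    clinical_status = "abnormal", shapes = list(character(0)), mosaic = FALSE,
    clone_counts = "", inheritance = "unknown", groups = list(character(0)),
    interval_chrom = "chr11", interval_start = 40e6, interval_end = 56e6,
    build = "GRCh37", modalities = list(character(0)),
    phenotype_terms = list(character(0)), arm_class = "q",
    source_table = "synthetic"
  )
  out <- assign_arm(case, map) # computed: p; curated: q
  expect_equal(out$arm, "q")
  expect_match(out$arm_note, "overrides computed 'p'")
})

test_that("cases without an interval get 'none' with a warning unless curated", {
  map <- map_fixture()
  t5 <- load_packaged_cohort("table5")
  t5$arm_class <- NA_character_
  expect_warning(out <- assign_arm(t5, map), "without a resolved interval")
  expect_equal(out$arm[out$case_id == "C"], "none")
})

test_that("the packaged tabulation reproduces every published cell", {
  pm <- suppressWarnings(
    tabulate_phenotypes(load_packaged_cohort("table5"), map_fixture())
  )
  expected <- tibble::tribble(
    ~sign, ~p, ~q,
    "growth retardation", 1L, 1L,
    "blepharophimosis/ptosis", 0L, 1L,
    "strabism", 0L, 1L,
    "cleft palate", 1L, 0L,
    "facial dysmorphism", 3L, 4L,
    "heart defect", 0L, 2L,
    "developmental delay", 5L, 4L,
    "intellectual disability", 1L, 1L,
    "hypotonia", 1L, 1L
  )
  got <- pm[match(expected$sign, pm$sign), ]
  expect_equal(got$p, expected$p, ignore_attr = TRUE)
  expect_equal(got$q, expected$q, ignore_attr = TRUE)
  expect_equal(
    attr(pm, "column_totals"), c(p = 5L, q = 4L)
  )
  # cell counts equal the number of listed contributing cases
  expect_equal(lengths(pm$p_cases), pm$p, ignore_attr = TRUE)
  expect_equal(lengths(pm$q_cases), pm$q, ignore_attr = TRUE)
  expect_setequal(pm$p_cases[pm$sign == "developmental delay"][[1]],
    c("13", "C", "D", "E", "F")
  )
})

test_that("an empty case list yields an all-zero matrix", {
  pm <- tabulate_phenotypes(
    load_packaged_cohort("table5")[0, ], map_fixture()
  )
  expect_true(all(pm$p == 0) && all(pm$q == 0))
  expect_equal(attr(pm, "column_totals"), c(p = 0L, q = 0L))
})

test_that("signs outside the vocabulary are collected under 'other'", {
  t5 <- load_packaged_cohort("table5")[1, ]
  t5$phenotype_terms <- list(c("developmental delay", "polydactyly"))
  expect_warning(
    pm <- suppressWarnings(
      tabulate_phenotypes(t5, map_fixture()),
      classes = "ssmc11_arm_warning"
    ),
    "other"
  )
  expect_equal(pm$p[pm$sign == "other"], 1L, ignore_attr = TRUE)
})

test_that("unspecific facial dysmorphism variants fold into the canonical row", {
  t5 <- load_packaged_cohort("table5")[1, ]
  t5$phenotype_terms <- list("facial dysmorphism (no details given)")
  pm <- suppressWarnings(tabulate_phenotypes(t5, map_fixture()))
  expect_equal(pm$p[pm$sign == "facial dysmorphism"], 1L, ignore_attr = TRUE)
})

test_that("a both-arm case is counted in both columns", {
  map <- map_fixture()
  case <- tibble::tibble(
    case_id = "B1", karyotype_text = "47,XY,+mar", sex = "male",
    clinical_status = "abnormal", shapes = list(character(0)), mosaic = FALSE,
    clone_counts = "", inheritance = "unknown", groups = list(character(0)),
    interval_chrom = "chr11", interval_start = 40e6, interval_end = 70e6,
    build = "GRCh37", modalities = list(character(0)),
    phenotype_terms = list("hypotonia"), arm_class = NA_character_,
    source_table = "synthetic"
  )
  pm <- tabulate_phenotypes(case, map)
  expect_equal(pm$p[pm$sign == "hypotonia"], 1L, ignore_attr = TRUE)
  expect_equal(pm$q[pm$sign == "hypotonia"], 1L, ignore_attr = TRUE)
  expect_equal(attr(pm, "column_totals"), c(p = 1L, q = 1L))
  expect_s3_class(autoplot(pm), "ggplot")
})
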