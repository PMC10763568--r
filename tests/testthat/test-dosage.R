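published_span <- function() genomic_interval("chr11", 48303671, 60473821)

test_that("exactly the five published informative normals survive filtering", {
  cohort <- dplyr::bind_rows(
    load_packaged_cohort("table1"),
    load_packaged_cohort("table2")
  )
  parts <- suppressWarnings(filter_informative(cohort))
  expect_setequal(parts$normals$case_id, c("1", "2", "6", "7", "A"))
  excl <- parts$excluded
  expect_equal(
    excl$reason[excl$case_id == "43"], "McClintock"
  )
  expect_equal(
    excl$reason[excl$case_id %in% c("3", "4")],
    rep("anchor-only-extent", 2)
  )
})

test_that("a cohort of only multiple-sSMC carriers is excluded wholesale", {
  coh <- load_packaged_cohort("table1")
  coh <- coh[vapply(coh$groups, function(g) "multiple-sSMC" %in% g, TRUE), ]
  parts <- suppressWarnings(filter_informative(coh))
  expect_equal(nrow(parts$normals) + nrow(parts$abnormals), 0)
  expect_true(all(parts$excluded$reason == "multiple-sSMC"))
})

test_that("filtering matches an independent predicate over random labelled cases", {
  set.seed(11)
  cfg <- sim_config(seed = 11, n_cases = 200)
  coh <- simulate_cohort(cfg)$cohort
  # scramble labels to exercise every branch
  pool <- c("complex", "discontinuous", "multiple-sSMC", "McClintock", "acquired")
  idx <- sample(200, 60)
  coh$groups[idx] <- lapply(idx, function(i) sample(pool, sample(0:2, 1)))
  parts <- suppressWarnings(filter_informative(coh))

  anchor <- test_anchor()
  verdict <- vapply(seq_len(nrow(coh)), function(i) {
    if (coh$clinical_status[i] == "unknown") return("excluded")
    if (length(intersect(coh$groups[[i]], c(
      pool, "pseudo-McClintock", "UPD-associated"
    ))) > 0) {
      return("excluded")
    }
    if (is.na(coh$interval_start[i])) return("excluded")
    if (coh$interval_start[i] >= anchor$start &&
      coh$interval_end[i] <= anchor$end) {
      return("excluded")
    }
    coh$clinical_status[i]
  }, "")
  expect_equal(nrow(parts$normals), sum(verdict == "normal"))
  expect_equal(nrow(parts$abnormals), sum(verdict == "abnormal"))
  expect_equal(nrow(parts$excluded), sum(verdict == "excluded"))
})

test_that("the five published intervals give the published insensitive span", {
  t3 <- suppressWarnings(filter_informative(load_packaged_cohort("table3")))
  span <- insensitive_span(t3$normals)
  expect_equal(c(span$start, span$end), c(48303671, 60473821))
})

test_that("a single interval is its own span", {
  iv <- genomic_interval("chr11", 50000000, 56000000)
  span <- insensitive_span(iv)
  expect_equal(c(span$start, span$end), c(50000000, 56000000))
})

test_that("disconnected normals reduce to the anchored component with a warning", {
  iv <- genomic_interval("chr11", c(50000000, 70000000), c(56000000, 75000000))
  expect_warning(span <- insensitive_span(iv), "anchored")
  expect_equal(c(span$start, span$end), c(50000000, 56000000))
})

test_that("adding a normal interval never shrinks the span", {
  set.seed(5)
  for (rep in 1:30) {
    base <- random_grid_cohort()$normals
    s0 <- suppressWarnings(insensitive_span(base))
    extra <- block_interval(4500, 6000)
    s1 <- suppressWarnings(insensitive_span(dplyr::bind_rows(base, extra)))
    expect_lte(s1$start, s0$start)
    expect_gte(s1$end, s0$end)
  }
})

test_that("benign refinement reproduces the published refined span", {
  refined <- refine_with_population(published_span(), load_packaged_cohort("evidence"))
  expect_equal(c(refined$start, refined$end), c(47675469, 60516539))
  expect_equal(refined$end - refined$start, 12841070)
})

test_that("refinement without overlapping benign records is the identity", {
  ev <- tibble::tibble(
    record_id = "b1", classification = "benign", chrom = "chr11",
    start = 2e6, end = 3e6, build = "GRCh37", flank_only = FALSE,
    synthetic_interval = TRUE
  )
  out <- refine_with_population(published_span(), ev)
  expect_equal(c(out$start, out$end), c(48303671, 60473821))
})

test_that("chained benign records propagate to a fixed point", {
  span <- genomic_interval("chr11", 50e6, 56e6)
  ev <- tibble::tibble(
    record_id = c("a", "b"), classification = "benign", chrom = "chr11",
    start = c(48e6, 45e6), end = c(51e6, 48.5e6), build = "GRCh37",
    flank_only = FALSE, synthetic_interval = TRUE
  )
  # b overlaps only a, not the original span: transitive closure reaches 45e6
  out <- refine_with_population(span, ev)
  expect_equal(out$start, 45e6)
  # idempotence
  again <- refine_with_population(out, ev)
  expect_equal(c(again$start, again$end), c(out$start, out$end))
})

test_that("benign records on another chromosome are skipped with a warning", {
  ev <- tibble::tibble(
    record_id = "offchrom", classification = "benign", chrom = "chr12",
    start = 48e6, end = 61e6, build = "GRCh37", flank_only = FALSE,
    synthetic_interval = TRUE
  )
  expect_warning(out <- refine_with_population(published_span(), ev), "offchrom")
  expect_equal(out$start, 48303671)
})

test_that("windows reproduce the published widths and coarse bounds", {
  ev <- load_packaged_cohort("evidence")
  span <- published_span()
  refined <- refine_with_population(span, ev)
  t4 <- suppressWarnings(filter_informative(load_packaged_cohort("table4")))
  win <- sensitive_windows(refined, t4$abnormals, ev, unrefined = span)
  expect_equal(c(win$p_window$start, win$p_window$end), c(45048321, 47675469))
  expect_equal(win$p_window$end - win$p_window$start, 2627148)
  expect_equal(c(win$q_window$start, win$q_window$end), c(60516539, 61479322))
  expect_equal(win$q_window$end - win$q_window$start, 962783)
  expect_equal(
    c(win$coarse_p_window$start, win$coarse_p_window$end),
    c(42922228, 48303671)
  )
  expect_equal(
    c(win$coarse_q_window$start, win$coarse_q_window$end),
    c(60473821, 79072352)
  )
})

test_that("an arm without pathogenic evidence gets an open-ended flagged window", {
  ev <- load_packaged_cohort("evidence")
  ev_p_only <- ev[!(ev$classification == "pathogenic" & ev$start > 6e7), ]
  refined <- refine_with_population(published_span(), ev_p_only)
  win <- sensitive_windows(refined, genomic_interval("chr11", 4e7, 5e7), ev_p_only)
  expect_true(is.na(win$q_window$end))
  expect_match(paste(win$flags, collapse = " "), "q_window not narrowable")
})

test_that("adding a pathogenic record never widens a window", {
  ev <- load_packaged_cohort("evidence")
  span <- published_span()
  refined <- refine_with_population(span, ev)
  ab <- genomic_interval("chr11", 4e7, 5e7)
  w0 <- sensitive_windows(refined, ab, ev, unrefined = span)
  extra <- tibble::tibble(
    record_id = "p-extra", classification = "pathogenic", chrom = "chr11",
    start = 46e6, end = 47e6, build = "GRCh37", flank_only = TRUE,
    synthetic_interval = TRUE
  )
  w1 <- sensitive_windows(refined, ab, dplyr::bind_rows(ev, extra),
    unrefined = span
  )
  expect_lte(
    w1$p_window$end - w1$p_window$start,
    w0$p_window$end - w0$p_window$start
  )
})

test_that("span and windows match the per-position oracle on random cohorts", {
  set.seed(23)
  n_checked <- 0
  for (rep in 1:110) {
    rc <- random_grid_cohort()
    span <- suppressWarnings(insensitive_span(rc$normals, rc$anchor))
    refined <- suppressWarnings(refine_with_population(span, rc$evidence))
    win <- sensitive_windows(refined, rc$abnormals, rc$evidence, rc$anchor,
      unrefined = span
    )
    # oracle: anchored covered run over normals + chained benign coverage
    run_n <- oracle_anchored_run(covered_cells(rc$normals), rc$anchor)
    expect_equal(c(span$start, span$end), run_n)
    benign <- rc$evidence[rc$evidence$classification == "benign", ]
    run_r <- oracle_anchored_run(
      covered_cells(dplyr::bind_rows(rc$normals, benign)), rc$anchor
    )
    expect_equal(c(refined$start, refined$end), run_r)
    path <- rc$evidence[rc$evidence$classification == "pathogenic", ]
    fw <- oracle_fine_windows(path, refined$start, refined$end)
    expect_equal(win$p_window$start, fw[["f_p"]])
    expect_equal(win$q_window$end, fw[["f_q"]])
    cw <- oracle_coarse(rc$abnormals, span$start, span$end)
    expect_equal(win$coarse_p_window$start, cw[["c_p"]])
    expect_equal(win$coarse_q_window$end, cw[["c_q"]])
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 100)
})

test_that("the end-to-end map prints and reports the published summary", {
  map <- suppressWarnings(infer_dosage_map())
  g <- glance(map)
  expect_equal(g$refined_length_mb, 12.84)
  expect_equal(g$p_window_mb, 2.63)
  expect_equal(g$q_window_mb, 0.96)

  dir <- withr::local_tempdir()
  paths <- report_dosage_map(map, dir)
  expect_match(
    paste(readLines(paths[["md"]]), collapse = "\n"), "12.84 Mb",
    fixed = TRUE
  )
  bed <- read_bed(paths[["bed"]])
  expect_equal(nrow(bed), 5)
  tsv <- readr::read_tsv(paths[["tsv"]], show_col_types = FALSE)
  expect_true(all(c("insensitive_span", "coarse_p_window") %in% tsv$region))
})

test_that("an open-ended window is reported as not narrowable", {
  map <- suppressWarnings(infer_dosage_map(
    evidence = load_packaged_cohort("evidence")[1:3, ] # drop the q flank
  ))
  dir <- withr::local_tempdir()
  paths <- report_dosage_map(map, dir)
  md <- paste(readLines(paths[["md"]]), collapse = "\n")
  expect_match(md, "11q sensitive-start window: not narrowable")
  expect_equal(nrow(read_bed(paths[["bed"]])), 4)
})

test_that("tidy and autoplot expose the map regions", {
  map <- suppressWarnings(infer_dosage_map())
  td <- tidy(map)
  expect_true(all(c(
    "insensitive_span", "refined_span", "p_window", "q_window",
    "coarse_p_window", "coarse_q_window", "centromere_anchor"
  ) %in% td$region))
  expect_equal(td$width_mb[td$region == "refined_span"], 12.84)
  p <- autoplot(map)
  expect_s3_class(p, "ggplot")
})
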