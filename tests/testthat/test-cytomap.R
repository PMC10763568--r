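test_that("the packaged ideogram tiles chromosome 11 and anchors the centromere", {
  bands <- load_cytobands()
  expect_equal(bands$start[1], 0)
  expect_equal(bands$end[nrow(bands)], 135006516)
  anchor <- centromere_anchor(bands)
  expect_equal(c(anchor$start, anchor$end), c(51600000, 55700000))
})

test_that("band lookup reproduces the published pericentric edges", {
  b <- band_to_interval("q11")
  expect_equal(b$end, 55700000)
  expect_equal(band_to_interval("p11.1")$start, 51600000)
})

test_that("coarse labels resolve to sub-band unions and fine labels to parents", {
  p11 <- band_to_interval("p11") # union of p11.2, p11.12, p11.1
  expect_equal(c(p11$start, p11$end), c(43500000, 53700000))
  expect_equal(band_to_interval("p11.21")$start, 43500000) # -> p11.2
  expect_equal(band_to_interval("p11.11")$start, 51600000) # -> p11.1
  expect_equal(band_to_interval("q1?1")$end, 55700000) # '?' stripped -> q11
})

test_that("unknown bands raise a lookup error listing nearby labels", {
  expect_error(band_to_interval("q99"), "unknown band")
  expect_error(band_to_interval("q99"), "nearest")
})

test_that("point_to_band inverts the band intervals", {
  expect_equal(point_to_band(51600001), "p11.1")
  expect_equal(point_to_band(48303671), "p11.2")
  expect_equal(point_to_band(57352936), "q12.1")
})

test_that("resolved extents reproduce every published informative-normal interval", {
  t3 <- resolve_cohort_extents(load_packaged_cohort("table3"))
  expected <- tibble::tribble(
    ~case_id, ~start, ~end,
    "2", 48303671, 55700000,
    "A", 48303671, 55700000,
    "6", 51600000, 57521103,
    "7", 51600000, 59319390,
    "1", 51095992, 60473821
  )
  got <- t3[match(expected$case_id, t3$case_id), ]
  expect_equal(got$extent_start, expected$start)
  expect_equal(got$extent_end, expected$end)
})

test_that("resolved extents reproduce every published informative-abnormal interval", {
  t4 <- resolve_cohort_extents(load_packaged_cohort("table4"))
  expected <- tibble::tribble(
    ~case_id, ~start, ~end,
    "10", 42922228, 50768675,
    "13", 40233424, 54943424,
    "E", 40231033, 50762504,
    "F", 30000000, 51600000,
    "G", 56243424, 79072352
  )
  got <- t4[match(expected$case_id, t4$case_id), ]
  expect_equal(got$extent_start, expected$start)
  expect_equal(got$extent_end, expected$end)
})

test_that("a single-band span resolves to that band exactly", {
  pk <- parse_karyotype("47,XX,+mar.ish min(11)(:q11→q11:)")
  ext <- resolve_extent(pk)
  expect_equal(c(ext$start, ext$end), c(53700000, 55700000))
})

test_that("adding coordinate-level gain evidence never shrinks the extent", {
  base <- parse_karyotype("47,XY,+mar.ish min(11)(:p11.1→q11:)(D11Z1+)")
  e0 <- resolve_extent(base)
  with_probe <- parse_karyotype(
    "47,XY,+mar.ish min(11)(:p11.1→q11:)(RP11-397M16+,D11Z1+)"
  )
  e1 <- resolve_extent(with_probe)
  expect_lte(e1$start, e0$start)
  expect_gte(e1$end, e0$end)
  with_arr <- parse_karyotype(
    "47,XY,+mar.ish min(11)(:p11.1→q11:)(RP11-397M16+,D11Z1+).arr[hg19] 11q12.1(55,896,790_59,319,390)x3"
  )
  e2 <- resolve_extent(with_arr)
  expect_lte(e2$start, e1$start)
  expect_gte(e2$end, e1$end)
})

test_that("a single '+' probe is not gain evidence on an interstitial dup", {
  # on the marker the same call would extend the extent to the probe span
  dup <- parse_karyotype("46,XX,der(11).ish dup(11)(p11.1q11)(D11Z1++,RP11-77M17+)")
  expect_equal(resolve_extent(dup)$end, 55700000)
  mar <- parse_karyotype("47,XX,+mar.ish min(11)(:p11.1→q11:)(D11Z1+,RP11-77M17+)")
  expect_equal(resolve_extent(mar)$end, 57521103)
})

test_that("negative probes warn about inconsistency but never truncate", {
  pk <- parse_karyotype(
    "47,XY,+mar.ish min(11)(:p11.2→q11:)(RP11-397M16-,D11Z1+).arr[hg19] 11p11.2(44,000,000_55,700,000)x3"
  )
  ext <- resolve_extent(pk)
  expect_equal(ext$start, 44000000) # not truncated at the negative probe
  expect_match(attr(ext, "consistency_warnings"), "RP11-397M16")
})

test_that("unusable or off-chromosome evidence is rejected", {
  expect_error(
    resolve_extent(parse_karyotype("mos 47,XY,+mar[10]/46,XY[5]")),
    "no usable evidence"
  )
  pk <- parse_karyotype("47,XX,+mar.arr[hg19] 12q12(30,000,000_40,000,000)x3")
  expect_error(resolve_extent(pk), "chr12")
})
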