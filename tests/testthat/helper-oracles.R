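# Per-position (10 kb cell) brute-force oracles, independent of the
# interval arithmetic under test, plus block-aligned random cohorts.

GRID <- 1e4
CHR_LEN <- 135006516
N_CELLS <- CHR_LEN %/% GRID

cell_start <- function(cell) (cell - 1) * GRID + 1
cell_end <- function(cell) cell * GRID

# cells covered by any interval in iv (tibble with start/end)
covered_cells <- function(iv, n_cells = N_CELLS) {
  cov <- rep(FALSE, n_cells)
  for (i in seq_len(nrow(iv))) {
    # cell c overlaps [start,end] iff cell_start(c) <= end & cell_end(c) >= start
    lo <- max(1, floor((iv$start[i] - 1) / GRID) + 1)
    hi <- min(n_cells, floor((iv$end[i] - 1) / GRID) + 1)
    cov[lo:hi] <- TRUE
  }
  cov
}

# maximal anchored covered run -> c(start_bp, end_bp) of the run
oracle_anchored_run <- function(cov, anchor) {
  a_lo <- floor(anchor$start / GRID) + 1 # anchor boundary coordinates sit on cell edges
  a_hi <- floor((anchor$end - 1) / GRID) + 1
  stopifnot(all(cov[a_lo:a_hi]))
  lo <- a_lo
  while (lo > 1 && cov[lo - 1]) lo <- lo - 1
  hi <- a_hi
  while (hi < length(cov) && cov[hi + 1]) hi <- hi + 1
  c(cell_start(lo), cell_end(hi))
}

# fine windows by per-cell scan of pathogenic coverage
oracle_fine_windows <- function(path_iv, refined_start, refined_end) {
  cov <- covered_cells(path_iv)
  p_cells <- which(cov & cell_end(seq_along(cov)) < refined_start)
  q_cells <- which(cov & cell_start(seq_along(cov)) > refined_end)
  c(
    f_p = if (length(p_cells) > 0) cell_end(max(p_cells)) else NA_real_,
    f_q = if (length(q_cells) > 0) cell_start(min(q_cells)) else NA_real_
  )
}

# coarse bounds by direct scan over abnormal intervals (sort-based path,
# distinct from the pmax/pmin implementation)
oracle_coarse <- function(ab_iv, span_start, span_end) {
  p <- sort(ab_iv$start[ab_iv$start < span_start], decreasing = TRUE)
  q <- sort(ab_iv$end[ab_iv$end > span_end])
  c(
    c_p = if (length(p) > 0) p[1] else NA_real_,
    c_q = if (length(q) > 0) q[1] else NA_real_
  )
}

# block-aligned interval [GRID*u + 1, GRID*v]
block_interval <- function(lo_cell, hi_cell, n = 1) {
  from <- sample(lo_cell:hi_cell, n, replace = TRUE)
  to <- from + floor(stats::runif(n) * (hi_cell - from + 1))
  tibble::tibble(
    chrom = "chr11", start = cell_start(from), end = cell_end(to),
    build = "GRCh37"
  )
}

test_anchor <- function() genomic_interval("chr11", 51600000, 55700000)

# random cohort of anchored normal intervals (cells), plus optional
# disconnected extras, benign and pathogenic records
random_grid_cohort <- function() {
  anchor <- test_anchor()
  a_lo <- anchor$start / GRID # 5160 (boundary coordinate on cell edge)
  a_hi <- anchor$end / GRID # 5570
  n_norm <- sample(2:8, 1)
  from <- sample((a_lo - 600):a_lo, n_norm, replace = TRUE)
  to <- sample(a_hi:(a_hi + 600), n_norm, replace = TRUE)
  normals <- tibble::tibble(
    chrom = "chr11", start = cell_start(from + 1), end = cell_end(to),
    build = "GRCh37"
  )
  ev <- tibble::tibble(
    record_id = character(), classification = character(),
    chrom = character(), start = numeric(), end = numeric(),
    build = character(), flank_only = logical(), synthetic_interval = logical()
  )
  mkrec <- function(cls, iv) {
    tibble::tibble(
      record_id = paste0(cls, "-", nrow(ev) + seq_len(nrow(iv))),
      classification = cls, chrom = "chr11", start = iv$start, end = iv$end,
      build = "GRCh37", flank_only = cls == "pathogenic",
      synthetic_interval = TRUE
    )
  }
  for (k in seq_len(sample(0:3, 1))) { # benign, near the span edges
    side <- sample(c("p", "q"), 1)
    iv <- if (side == "p") {
      block_interval(a_lo - 800, a_lo + 100)
    } else {
      block_interval(a_hi - 100, a_hi + 800)
    }
    ev <- dplyr::bind_rows(ev, mkrec("benign", iv))
  }
  for (k in seq_len(sample(0:2, 1))) { # pathogenic, further out
    side <- sample(c("p", "q"), 1)
    iv <- if (side == "p") {
      block_interval(a_lo - 1200, a_lo - 300)
    } else {
      block_interval(a_hi + 300, a_hi + 1200)
    }
    ev <- dplyr::bind_rows(ev, mkrec("pathogenic", iv))
  }
  n_ab <- sample(0:4, 1)
  abnormals <- if (n_ab > 0) {
    dplyr::bind_rows(lapply(seq_len(n_ab), function(k) {
      block_interval(a_lo - 1500, a_hi + 1500)
    }))
  } else {
    tibble::tibble(
      chrom = character(), start = numeric(), end = numeric(),
      build = character()
    )
  }
  list(anchor = anchor, normals = normals, evidence = ev, abnormals = abnormals)
}
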