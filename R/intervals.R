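#' Construct a table of genomic intervals
#'
#' Intervals are stored the way coordinates are printed in sSMC case tables:
#' 1-based and inclusive at both ends, on a named chromosome of a named
#' genome build. Conversion to the 0-based half-open BED convention happens
#' only in [write_bed()], so every stored number can be compared verbatim
#' with a published coordinate.
#'
#' @param chrom Chromosome name(s), e.g. `"chr11"`.
#' @param start,end Base positions (bp, 1-based, inclusive).
#' @param build Genome build tag; defaults to `"GRCh37"`.
#' @param label Optional label column.
#'
#' @return A tibble with columns `chrom`, `start`, `end`, `build` (and
#'   `label` if given), one row per interval.
#' @examples
#' genomic_interval("chr11", 48303671, 60473821)
#' @export
genomic_interval <- function(chrom, start, end, build = "GRCh37", label = NULL) {
  out <- tibble::tibble(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    build = as.character(build)
  )
  if (!is.null(label)) out$label <- as.character(label)
  validate_intervals(out)
  out
}

#' Validate an interval table
#'
#' Checks the invariants every interval table must satisfy: columns
#' `chrom`, `start`, `end`, `build` present, `start >= 1`, `end >= start`,
#' and a non-empty build token.
#'
#' @param x A data frame of intervals.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_intervals <- function(x) {
  needed <- c("chrom", "start", "end", "build")
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0) {
    stop("interval table lacks column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(x) > 0) {
    if (any(!is.finite(x$start)) || any(!is.finite(x$end))) {
      stop("interval coordinates must be finite", call. = FALSE)
    }
    if (any(x$start < 1)) stop("interval start must be >= 1", call. = FALSE)
    if (any(x$end < x$start)) stop("interval end must be >= start", call. = FALSE)
    if (any(is.na(x$build) | x$build == "")) {
      stop("interval build must be a non-empty token", call. = FALSE)
    }
  }
  invisible(x)
}

#' @keywords internal
check_single_build <- function(x, what = "intervals") {
  b <- unique(x$build)
  if (length(b) > 1) {
    stop(what, " mix genome builds: ", paste(b, collapse = ", "), call. = FALSE)
  }
  invisible(b)
}

#' Interval width in bp and Mb
#'
#' Widths are reported as `end - start`, the convention used for published
#' span lengths (e.g. a 47,675,469-60,516,539 span is reported as
#' 12,841,070 bp = 12.84 Mb); the +1 inclusive-length convention is not
#' used for reported lengths.
#'
#' @param x An interval table.
#' @return `x` with `width_bp` and `width_mb` columns added.
#' @export
interval_width <- function(x) {
  validate_intervals(x)
  dplyr::mutate(
    x,
    width_bp = .data$end - .data$start,
    width_mb = round((.data$end - .data$start) / 1e6, 2)
  )
}

#' Merge overlapping or abutting intervals
#'
#' Two intervals are considered connected when they overlap or abut
#' (`end + 1 >= start` of the next), so coverage is treated per base:
#' \[10,20\] and \[21,30\] form one covered run.
#'
#' @param x Interval table (single chromosome and build).
#' @return Interval table of disjoint merged runs, ordered by start.
#' @export
merge_intervals <- function(x) {
  validate_intervals(x)
  if (nrow(x) == 0) return(x[0, c("chrom", "start", "end", "build")])
  check_single_build(x)
  if (length(unique(x$chrom)) > 1) {
    stop("merge_intervals expects a single chromosome", call. = FALSE)
  }
  x <- dplyr::arrange(x, .data$start, .data$end)
  run_start <- x$start[1]
  run_end <- x$end[1]
  starts <- ends <- numeric(0)
  for (i in seq_len(nrow(x))[-1]) {
    if (x$start[i] <= run_end + 1) {
      run_end <- max(run_end, x$end[i])
    } else {
      starts <- c(starts, run_start)
      ends <- c(ends, run_end)
      run_start <- x$start[i]
      run_end <- x$end[i]
    }
  }
  genomic_interval(x$chrom[1], c(starts, run_start), c(ends, run_end), x$build[1])
}

#' @keywords internal
intervals_overlap <- function(s1, e1, s2, e2, abut = FALSE) {
  slack <- if (abut) 1 else 0
  s1 <= e2 + slack & s2 <= e1 + slack
}

#' Write intervals as a BED file
#'
#' Emits standard 4-column BED: 0-based half-open, so each line carries
#' `start - 1` and `end` of the stored 1-based inclusive interval. Records
#' are ordered by (chrom, start); a header comment states the build.
#'
#' @param regions Interval table with a `label` column.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  validate_intervals(regions)
  if (nrow(regions) > 0) check_single_build(regions, "BED regions")
  if (!"label" %in% names(regions)) regions$label <- ""
  build <- if (nrow(regions) > 0) unique(regions$build) else "NA"
  lines <- c(sprintf("# build=%s; coordinates are 0-based half-open (BED)", build))
  regions <- dplyr::arrange(regions, .data$chrom, .data$start)
  if (nrow(regions) > 0) {
    lines <- c(lines, sprintf(
      "%s\t%d\t%d\t%s",
      regions$chrom, as.integer(regions$start - 1),
      as.integer(regions$end), regions$label
    ))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file back into a 1-based interval table
#'
#' Inverse of [write_bed()]: BED's `[start0, end0)` becomes the 1-based
#' inclusive `[start0 + 1, end0]`.
#'
#' @param path BED file path.
#' @param build Build tag to attach (BED itself carries none; the header
#'   comment written by [write_bed()] is parsed when present).
#' @return Interval table with a `label` column.
#' @export
read_bed <- function(path, build = "GRCh37") {
  lines <- readLines(path)
  header <- grep("^#", lines, value = TRUE)
  m <- regmatches(header, regexpr("build=[^;]+", header))
  if (length(m) > 0) build <- sub("build=", "", m[[1]])
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(genomic_interval(character(), numeric(), numeric(), character())[0, ])
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  genomic_interval(
    chrom = vapply(parts, `[`, "", 1),
    start = as.numeric(vapply(parts, `[`, "", 2)) + 1,
    end = as.numeric(vapply(parts, `[`, "", 3)),
    build = build,
    label = vapply(parts, function(p) if (length(p) >= 4) p[4] else "", "")
  )
}
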