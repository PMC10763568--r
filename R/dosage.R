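#' Partition a cohort into informative normals, abnormals and exclusions
#'
#' A case is informative for boundary inference iff its clinical status is
#' known (normal or abnormal), its trisomy extent is resolvable on GRCh37,
#' it carries none of the exclusion labels (complex, discontinuous,
#' multiple-sSMC, McClintock, pseudo-McClintock, acquired,
#' UPD-associated), and its extent reaches beyond the centromere anchor on
#' at least one arm (a purely heterochromatic, anchor-only marker carries
#' no euchromatin and cannot bound dosage-sensitive territory). Every
#' excluded case is returned with the first matching exclusion reason.
#'
#' @param cohort Cohort tibble ([read_cohort()] schema).
#' @param registry,bands Probe registry and cytoband map.
#' @param min_mosaic_fraction Minimum marker cell fraction for inclusion;
#'   the default 0 keeps every mosaic case (mosaicism level is treated as
#'   having no major influence on the phenotype).
#' @return A list of tibbles `normals`, `abnormals` (each with
#'   `extent_start`/`extent_end`) and `excluded` (with `reason`).
#' @export
filter_informative <- function(cohort, registry = load_probe_registry(),
                               bands = load_cytobands(),
                               min_mosaic_fraction = 0) {
  stopifnot(nrow(cohort) > 0)
  anchor <- centromere_anchor(bands)
  excl_labels <- c(
    "complex", "discontinuous", "multiple-sSMC", "McClintock",
    "pseudo-McClintock", "acquired", "UPD-associated"
  )
  cohort <- resolve_cohort_extents(cohort, registry, bands)

  reason <- rep(NA_character_, nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    row <- cohort[i, ]
    hit <- intersect(row$groups[[1]], excl_labels)
    if (row$clinical_status == "unknown") {
      reason[i] <- "status-unknown"
    } else if (length(hit) > 0) {
      reason[i] <- hit[1]
    } else if (is.na(row$extent_start)) {
      reason[i] <- "no-resolvable-extent"
    } else if (row$extent_start >= anchor$start && row$extent_end <= anchor$end) {
      reason[i] <- "anchor-only-extent"
    } else if (min_mosaic_fraction > 0) {
      frac <- tryCatch(
        mosaic_fraction(parse_karyotype(row$karyotype_text)),
        error = function(e) NA_real_
      )
      if (!is.na(frac) && frac < min_mosaic_fraction) {
        reason[i] <- "below-mosaic-threshold"
      }
    }
  }
  keep <- is.na(reason)
  list(
    normals = cohort[keep & cohort$clinical_status == "normal", ],
    abnormals = cohort[keep & cohort$clinical_status == "abnormal", ],
    excluded = tibble::tibble(
      case_id = cohort$case_id[!keep],
      reason = reason[!keep]
    )
  )
}

#' Minimal triplo-insensitive span from clinically normal carriers
#'
#' The minimal pericentric region demonstrated to tolerate a third copy is
#' the outer envelope of the trisomic intervals of informative clinically
#' normal carriers: \[min of starts, max of ends\]. The inputs must form
#' one covered run connected to the centromere anchor; if the union does
#' not contiguously cover the envelope, the anchored connected component
#' is returned instead with a gap warning attribute (`attr(x, "gap")`).
#'
#' @param normals Interval table (one row per normal case) or a cohort
#'   tibble carrying `extent_start`/`extent_end`.
#' @param anchor Centromere anchor interval.
#' @return One-row interval table labelled `insensitive_span`.
#' @examples
#' \dontrun{
#' parts <- filter_informative(load_packaged_cohort("table3"))
#' insensitive_span(parts$normals) # 48,303,671-60,473,821
#' }
#' @export
insensitive_span <- function(normals, anchor = centromere_anchor()) {
  iv <- as_extent_intervals(normals)
  if (nrow(iv) == 0) {
    stop("no informative normal intervals; cannot infer a span", call. = FALSE)
  }
  validate_intervals(iv)
  check_single_build(dplyr::bind_rows(iv, anchor[, names(iv)[names(iv) %in% c("chrom", "start", "end", "build")]]))
  runs <- merge_intervals(dplyr::bind_rows(
    iv[, c("chrom", "start", "end", "build")],
    anchor[, c("chrom", "start", "end", "build")]
  ))
  anchored <- runs[
    intervals_overlap(runs$start, runs$end, anchor$start, anchor$end, abut = TRUE),
  ]
  span <- genomic_interval(
    iv$chrom[1], min(iv$start), max(iv$end), iv$build[1],
    label = "insensitive_span"
  )
  gap <- NULL
  if (nrow(runs) > 1 || anchored$start[1] > min(iv$start) ||
    anchored$end[1] < max(iv$end)) {
    span <- genomic_interval(
      iv$chrom[1],
      max(anchored$start[1], min(iv$start)),
      min(anchored$end[1], max(iv$end)),
      iv$build[1],
      label = "insensitive_span"
    )
    gap <- "normal intervals do not contiguously cover their envelope; returning the centromere-anchored component"
    warning(gap, call. = FALSE)
  }
  attr(span, "gap") <- gap
  span
}

#' @keywords internal
as_extent_intervals <- function(x) {
  if (all(c("extent_start", "extent_end") %in% names(x))) {
    keep <- !is.na(x$extent_start)
    return(tibble::tibble(
      chrom = if ("interval_chrom" %in% names(x)) {
        dplyr::coalesce(x$interval_chrom[keep], "chr11")
      } else {
        "chr11"
      },
      start = x$extent_start[keep], end = x$extent_end[keep],
      build = "GRCh37"
    ))
  }
  validate_intervals(x)
  x[!is.na(x$start), c("chrom", "start", "end", "build")]
}

#' Refine a span with benign population copy-number gains
#'
#' Benign gains observed in the population demonstrate tolerated
#' territory: every benign record whose interval overlaps (or abuts) the
#' current span extends it to include the record's outer boundaries, and
#' the rule is iterated to a fixed point so chained records propagate.
#' Pathogenic records never extend a span. Records on another chromosome
#' or build are skipped with a warning. The operation is idempotent.
#'
#' @param span One-row interval table (the unrefined insensitive span).
#' @param evidence Evidence tibble (see [load_packaged_cohort()]).
#' @return The refined span; `attr(x, "extended_by")` lists the record
#'   ids that contributed.
#' @export
refine_with_population <- function(span, evidence) {
  validate_intervals(span)
  stopifnot(nrow(span) == 1)
  benign <- evidence[evidence$classification == "benign", ]
  off <- benign$chrom != span$chrom | benign$build != span$build
  if (any(off)) {
    warning(
      "skipping benign record(s) on another chromosome/build: ",
      paste(benign$record_id[off], collapse = ", ")
    )
    benign <- benign[!off, ]
  }
  cur <- span
  used <- character(0)
  repeat {
    hits <- intervals_overlap(benign$start, benign$end, cur$start, cur$end,
      abut = TRUE
    )
    new_start <- min(cur$start, benign$start[hits])
    new_end <- max(cur$end, benign$end[hits])
    if (new_start == cur$start && new_end == cur$end) break
    used <- union(used, benign$record_id[hits])
    cur$start <- new_start
    cur$end <- new_end
  }
  cur$label <- "refined_span"
  attr(cur, "extended_by") <- used
  attr(cur, "gap") <- attr(span, "gap")
  cur
}

#' Uncertainty windows for the start of triplo-sensitive territory
#'
#' Each arm is modelled as insensitive territory adjacent to the
#' centromere followed by sensitive territory distally, with one unknown
#' changeover point per arm; coordinates covered by a pathogenic report
#' are treated as at or beyond the changeover. The changeover is then
#' bracketed:
#'
#' * fine windows (pathogenic evidence): `p_window` runs from the
#'   pericentric-most p-side coordinate covered by any pathogenic record
#'   to the refined span start; `q_window` symmetrically on q.
#' * coarse windows (in-cohort abnormal cases only): an abnormal case
#'   whose trisomy extends beyond the unrefined span proves a sensitive
#'   locus in the extension, so the changeover lies centromere-ward of
#'   its telomere-ward extreme; the binding (least telomere-ward) such
#'   extreme bounds the window against the unrefined span boundary.
#'
#' An arm without evidence gets an open-ended window (far bound `NA`)
#' and a flag.
#'
#' @param refined Refined insensitive span.
#' @param abnormals Interval table or cohort tibble of informative
#'   abnormal cases.
#' @param evidence Evidence tibble (pathogenic rows are used).
#' @param anchor Centromere anchor.
#' @param unrefined The unrefined insensitive span used for the coarse
#'   windows; defaults to `refined`.
#' @return A list with one-row interval tables `p_window`, `q_window`,
#'   `coarse_p_window`, `coarse_q_window` (open far bounds are `NA`) and
#'   a character vector `flags`.
#' @export
sensitive_windows <- function(refined, abnormals, evidence,
                              anchor = centromere_anchor(),
                              unrefined = refined) {
  if (is.null(refined) || nrow(refined) != 1) {
    stop("a refined span is required", call. = FALSE)
  }
  validate_intervals(refined)
  path <- evidence[evidence$classification == "pathogenic" &
    evidence$chrom == refined$chrom & evidence$build == refined$build, ]
  flags <- character(0)

  # fine windows: clip pathogenic coverage to each side of the refined span
  p_cov <- path[path$start < refined$start, ]
  f_p <- if (nrow(p_cov) > 0) max(pmin(p_cov$end, refined$start - 1)) else NA_real_
  q_cov <- path[path$end > refined$end, ]
  f_q <- if (nrow(q_cov) > 0) min(pmax(q_cov$start, refined$end + 1)) else NA_real_
  if (is.na(f_p)) flags <- c(flags, "p_window not narrowable: no pathogenic evidence on 11p")
  if (is.na(f_q)) flags <- c(flags, "q_window not narrowable: no pathogenic evidence on 11q")

  mk <- function(start, end, label) {
    out <- tibble::tibble(
      chrom = refined$chrom, start = start, end = end,
      build = refined$build, label = label
    )
    if (!anyNA(c(start, end))) validate_intervals(out)
    out
  }
  p_window <- mk(f_p, refined$start, "p_window")
  q_window <- mk(refined$end, f_q, "q_window")

  ab <- as_extent_intervals(abnormals)
  p_ext <- ab[ab$start < unrefined$start, ]
  c_p <- if (nrow(p_ext) > 0) max(p_ext$start) else NA_real_
  q_ext <- ab[ab$end > unrefined$end, ]
  c_q <- if (nrow(q_ext) > 0) min(q_ext$end) else NA_real_
  if (is.na(c_p)) flags <- c(flags, "coarse_p_window not narrowable: no p-extending abnormal case")
  if (is.na(c_q)) flags <- c(flags, "coarse_q_window not narrowable: no q-extending abnormal case")
  coarse_p <- mk(c_p, unrefined$start, "coarse_p_window")
  coarse_q <- mk(unrefined$end, c_q, "coarse_q_window")

  list(
    p_window = p_window, q_window = q_window,
    coarse_p_window = coarse_p, coarse_q_window = coarse_q,
    flags = flags
  )
}

#' End-to-end dosage map inference
#'
#' Runs the full pipeline: informative-case filtering of the normal
#' cohort, minimal insensitive span, benign-population refinement, and
#' sensitive-start windows from abnormal cases plus pathogenic flanks.
#' With all defaults it reproduces the packaged chromosome 11 analysis.
#'
#' @param normals Cohort tibble of candidate normal carriers; default the
#'   packaged `table3`.
#' @param abnormals Cohort tibble of abnormal carriers for the coarse
#'   windows; default the packaged `table4`.
#' @param evidence Evidence tibble; default the packaged fixture.
#' @param registry,bands Probe registry and cytoband map.
#' @param min_mosaic_fraction Passed to [filter_informative()].
#' @return A `dosage_map` object: list with interval tables
#'   `insensitive_span`, `refined_span`, `p_window`, `q_window`,
#'   `coarse_p_window`, `coarse_q_window`, `centromere_anchor`, plus
#'   `flags` and a `decisions` tibble of case-level inclusions and
#'   exclusions.
#' @examples
#' \dontrun{
#' map <- infer_dosage_map()
#' map$refined_span # 47,675,469-60,516,539
#' }
#' @export
infer_dosage_map <- function(normals = load_packaged_cohort("table3"),
                             abnormals = load_packaged_cohort("table4"),
                             evidence = load_packaged_cohort("evidence"),
                             registry = load_probe_registry(),
                             bands = load_cytobands(),
                             min_mosaic_fraction = 0) {
  anchor <- centromere_anchor(bands)
  parts_n <- filter_informative(normals, registry, bands, min_mosaic_fraction)
  parts_a <- filter_informative(abnormals, registry, bands, min_mosaic_fraction)
  span <- insensitive_span(parts_n$normals, anchor)
  refined <- refine_with_population(span, evidence)
  win <- sensitive_windows(refined, parts_a$abnormals, evidence, anchor,
    unrefined = span
  )
  decisions <- dplyr::bind_rows(
    tibble::tibble(
      case_id = parts_n$normals$case_id, role = "normal",
      decision = "included", reason = NA_character_
    ),
    tibble::tibble(
      case_id = parts_a$abnormals$case_id, role = "abnormal",
      decision = "included", reason = NA_character_
    ),
    tibble::tibble(
      case_id = c(parts_n$excluded$case_id, parts_a$excluded$case_id),
      role = "candidate", decision = "excluded",
      reason = c(parts_n$excluded$reason, parts_a$excluded$reason)
    )
  )
  structure(
    list(
      insensitive_span = span,
      refined_span = refined,
      p_window = win$p_window,
      q_window = win$q_window,
      coarse_p_window = win$coarse_p_window,
      coarse_q_window = win$coarse_q_window,
      centromere_anchor = anchor,
      flags = win$flags,
      decisions = decisions
    ),
    class = "dosage_map"
  )
}

#' @keywords internal
dosage_map_regions <- function(map, coarse = FALSE) {
  pieces <- list(
    map$insensitive_span, map$refined_span, map$p_window, map$q_window,
    if (coarse) map$coarse_p_window, if (coarse) map$coarse_q_window,
    map$centromere_anchor
  )
  dplyr::bind_rows(purrr::compact(pieces))
}

#' Tidy a dosage map into one row per region
#'
#' @param x A `dosage_map`.
#' @param ... Unused.
#' @return A tibble with `region`, `chrom`, `start`, `end`, `width_bp`,
#'   `width_mb` (widths as end - start).
#' @export
tidy.dosage_map <- function(x, ...) {
  regions <- dosage_map_regions(x, coarse = TRUE)
  out <- tibble::tibble(
    region = regions$label, chrom = regions$chrom,
    start = regions$start, end = regions$end, build = regions$build
  )
  out$width_bp <- out$end - out$start
  out$width_mb <- round(out$width_bp / 1e6, 2)
  out
}

#' One-row summary of a dosage map
#'
#' @param x A `dosage_map`.
#' @param ... Unused.
#' @return A one-row tibble with the six boundary coordinates and the
#'   headline widths in Mb.
#' @export
glance.dosage_map <- function(x, ...) {
  tibble::tibble(
    insensitive_start = x$insensitive_span$start,
    insensitive_end = x$insensitive_span$end,
    refined_start = x$refined_span$start,
    refined_end = x$refined_span$end,
    refined_length_bp = x$refined_span$end - x$refined_span$start,
    refined_length_mb = round((x$refined_span$end - x$refined_span$start) / 1e6, 2),
    p_window_mb = round((x$p_window$end - x$p_window$start) / 1e6, 2),
    q_window_mb = round((x$q_window$end - x$q_window$start) / 1e6, 2),
    coarse_p_start = x$coarse_p_window$start,
    coarse_q_end = x$coarse_q_window$end,
    n_flags = length(x$flags)
  )
}

#' @export
print.dosage_map <- function(x, ...) {
  fmt <- function(v) {
    ifelse(is.na(v), "open", format(v, big.mark = ",", scientific = FALSE))
  }
  mb <- function(iv) {
    if (anyNA(c(iv$start, iv$end))) "not narrowable" else {
      sprintf("%.2f Mb", (iv$end - iv$start) / 1e6)
    }
  }
  cat("Pericentric dosage map (", x$refined_span$chrom, ", ",
    x$refined_span$build, ")\n",
    sep = ""
  )
  cat(
    "  triplo-insensitive span: ", fmt(x$insensitive_span$start), "-",
    fmt(x$insensitive_span$end), " (", mb(x$insensitive_span), ")\n",
    sep = ""
  )
  cat(
    "  refined span:            ", fmt(x$refined_span$start), "-",
    fmt(x$refined_span$end), " (", mb(x$refined_span), ")\n",
    sep = ""
  )
  cat(
    "  11p sensitive-start window: ", fmt(x$p_window$start), "-",
    fmt(x$p_window$end), " (", mb(x$p_window), ")\n",
    sep = ""
  )
  cat(
    "  11q sensitive-start window: ", fmt(x$q_window$start), "-",
    fmt(x$q_window$end), " (", mb(x$q_window), ")\n",
    sep = ""
  )
  cat(
    "  coarse windows: p ", fmt(x$coarse_p_window$start), "-",
    fmt(x$coarse_p_window$end), "; q ", fmt(x$coarse_q_window$start), "-",
    fmt(x$coarse_q_window$end), "\n",
    sep = ""
  )
  for (f in x$flags) cat("  note:", f, "\n")
  invisible(x)
}

#' Plot a dosage map as labelled interval tracks
#'
#' Draws the insensitive and refined spans (tolerated territory), the
#' per-arm sensitive-start windows, and the centromere anchor as
#' horizontal segments along the chromosome.
#'
#' @param object A `dosage_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dosage_map <- function(object, ...) {
  d <- tidy(object)
  d <- d[!is.na(d$start) & !is.na(d$end), ]
  d$region <- factor(d$region, levels = rev(unique(d$region)))
  d$class <- dplyr::case_when(
    d$region %in% c("insensitive_span", "refined_span") ~ "tolerated",
    grepl("window", d$region) ~ "changeover window",
    TRUE ~ "anchor"
  )
  ggplot2::ggplot(d, ggplot2::aes(
    y = .data$region, yend = .data$region,
    x = .data$start / 1e6, xend = .data$end / 1e6, colour = .data$class
  )) +
    ggplot2::geom_segment(linewidth = 4, lineend = "butt") +
    ggplot2::scale_colour_manual(values = c(
      tolerated = "#1b9e77", `changeover window` = "#d95f02",
      anchor = "grey40"
    )) +
    ggplot2::labs(
      x = "chr11 position (Mb, GRCh37)", y = NULL, colour = NULL,
      title = "Pericentric triplo-sensitivity map"
    ) +
    ggplot2::theme_minimal()
}

#' Write the report files for a dosage map
#'
#' Emits `regions.bed` (five records: insensitive span, refined span, the
#' two fine windows, and the centromere anchor; open-ended windows are
#' skipped), `boundaries.tsv` (all boundary coordinates incl. the coarse
#' windows), and `report.md` (text summary with Mb values rounded to two
#' decimals; an open-ended window is reported as "not narrowable").
#'
#' @param map A `dosage_map`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
report_dosage_map <- function(map, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  regions <- dosage_map_regions(map, coarse = FALSE)
  regions <- regions[!is.na(regions$start) & !is.na(regions$end), ]
  bed <- file.path(dir, "regions.bed")
  write_bed(regions, bed)

  boundaries <- tidy(map)
  tsv <- file.path(dir, "boundaries.tsv")
  readr::write_tsv(boundaries, tsv, progress = FALSE)

  md <- file.path(dir, "report.md")
  g <- glance(map)
  win_txt <- function(iv, nm) {
    if (anyNA(c(iv$start, iv$end))) {
      sprintf("- %s: not narrowable (missing evidence on this arm)", nm)
    } else {
      sprintf(
        "- %s: %s-%s (%.2f Mb)", nm,
        format(iv$start, big.mark = ",", scientific = FALSE),
        format(iv$end, big.mark = ",", scientific = FALSE),
        (iv$end - iv$start) / 1e6
      )
    }
  }
  lines <- c(
    "# Pericentric dosage map, chromosome 11 (GRCh37)",
    "",
    sprintf(
      "- minimal triplo-insensitive span: %s-%s",
      format(g$insensitive_start, big.mark = ",", scientific = FALSE),
      format(g$insensitive_end, big.mark = ",", scientific = FALSE)
    ),
    sprintf(
      "- refined span: %s-%s (%.2f Mb)",
      format(g$refined_start, big.mark = ",", scientific = FALSE),
      format(g$refined_end, big.mark = ",", scientific = FALSE),
      g$refined_length_mb
    ),
    win_txt(map$p_window, "11p sensitive-start window"),
    win_txt(map$q_window, "11q sensitive-start window"),
    win_txt(map$coarse_p_window, "coarse 11p window (in-cohort only)"),
    win_txt(map$coarse_q_window, "coarse 11q window (in-cohort only)"),
    if (length(map$flags) > 0) c("", paste("Note:", map$flags))
  )
  writeLines(unlist(lines), md)
  invisible(c(bed = bed, tsv = tsv, md = md))
}
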