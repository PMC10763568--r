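#' Load the chromosome 11 cytoband map (GRCh37)
#'
#' Reads an ideogram table in the standard cytoBand text format (chrom,
#' start, end, band, stain; 0-based half-open on disk). Band intervals
#' keep the raw boundary numbers — published pericentric coordinates quote
#' these boundaries verbatim (a band running 51,600,000-53,700,000 is
#' cited by both its 51,600,000 start and the neighbouring band's
#' 53,700,000 end) — so shared boundary coordinates are reproduced exactly
#' rather than shifted by one. The p-arm acen band is stored under its
#' coarse label `p11.1`, matching how ish breakpoints such as
#' `:p11.1→q11:` denote the centromeric band in case tables.
#'
#' @param path Cytoband file; defaults to the packaged GRCh37 chr11 table.
#' @return A tibble `chrom`, `start`, `end`, `band`, `stain`, ordered by
#'   position, validated to tile the chromosome without gaps or overlaps.
#' @export
load_cytobands <- function(path = system.file("extdata", "cytoband_chr11_grch37.tsv",
                             package = "ssmc11"
                           )) {
  bands <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "band", "stain"),
    col_types = "cddcc", progress = FALSE
  )
  bands <- dplyr::arrange(bands, .data$chrom, .data$start)
  by_chrom <- split(bands, bands$chrom)
  for (b in by_chrom) {
    if (any(b$end[-nrow(b)] != b$start[-1])) {
      stop("cytoband map has gaps or overlaps on ", b$chrom[1], call. = FALSE)
    }
    if (anyDuplicated(b$band) > 0) {
      stop("duplicate band labels on ", b$chrom[1], call. = FALSE)
    }
  }
  bands
}

#' The centromere anchor: union of the acen bands
#'
#' The pericentric anchor is the union of the two acen (centromeric
#' heterochromatin) bands — p11.1 and q11 on chromosome 11, i.e.
#' 51,600,000-55,700,000 on GRCh37. A case is pericentric iff its
#' demonstrated extent intersects or abuts this anchor; that is required
#' for inclusion in span inference.
#'
#' @param bands A cytoband table from [load_cytobands()].
#' @return A one-row interval table.
#' @export
centromere_anchor <- function(bands = load_cytobands()) {
  acen <- dplyr::filter(bands, .data$stain == "acen")
  if (nrow(acen) == 0) stop("cytoband map carries no acen bands", call. = FALSE)
  genomic_interval(acen$chrom[1], min(acen$start), max(acen$end), "GRCh37",
    label = "centromere_anchor"
  )
}

#' Resolve a cytoband label to its genomic interval
#'
#' Exact labels resolve directly. A coarser label than stored resolves to
#' the union of its stored sub-bands (`p15` -> p15.1..p15.5); a finer
#' label than stored falls back to its parent (`q11.1` -> q11,
#' `p11.21` -> p11.2). Uncertainty marks (`?`) are stripped first.
#'
#' @param band Band label, e.g. `"q11"`, `"p11.12"`.
#' @param bands Cytoband table.
#' @param chrom Chromosome to look on.
#' @return A one-row interval table spanning the band.
#' @examples
#' band_to_interval("q11") # ends at 55,700,000
#' @export
band_to_interval <- function(band, bands = load_cytobands(), chrom = "chr11") {
  label <- clean_band_label(trimws(band))
  b <- dplyr::filter(bands, .data$chrom == !!chrom)
  if (nrow(b) == 0) stop("no cytobands for ", chrom, call. = FALSE)
  lookup <- function(lab) {
    hit <- b[b$band == lab, ]
    if (nrow(hit) == 1) return(hit)
    # coarser than stored: union of sub-bands
    sub <- b[grepl(paste0("^", gsub("\\.", "\\\\.", lab), "(\\.|[0-9])"), b$band), ]
    if (nrow(sub) > 0) return(sub)
    NULL
  }
  hit <- lookup(label)
  tries <- 0
  lab <- label
  while (is.null(hit) && tries < 3) {
    # finer than stored: strip one trailing sub-band digit, then the
    # whole dot-component (p11.11 -> p11.1; q11.1 -> q11)
    lab2 <- if (grepl("\\.[0-9]{2,}$", lab)) {
      sub("[0-9]$", "", lab)
    } else {
      sub("\\.[0-9]+$", "", lab)
    }
    lab2 <- sub("\\.$", "", lab2)
    if (identical(lab2, lab) || !grepl("[0-9]", lab2)) break
    lab <- lab2
    hit <- lookup(lab)
    tries <- tries + 1
  }
  if (is.null(hit)) {
    near <- b$band[order(utils::adist(b$band, label))][1:3]
    stop(
      "unknown band '", band, "' on ", chrom, "; nearest labels: ",
      paste(near, collapse = ", "),
      call. = FALSE
    )
  }
  genomic_interval(chrom, min(hit$start), max(hit$end), "GRCh37", label = label)
}

#' Cytoband containing a position
#'
#' @param pos Base position(s), 1-based.
#' @param bands Cytoband table.
#' @param chrom Chromosome.
#' @return Band label(s).
#' @export
point_to_band <- function(pos, bands = load_cytobands(), chrom = "chr11") {
  b <- dplyr::filter(bands, .data$chrom == !!chrom)
  vapply(pos, function(p) {
    hit <- b$band[b$start < p & p <= b$end]
    if (length(hit) == 0) NA_character_ else hit[1]
  }, "")
}

#' Load the FISH probe registry
#'
#' The packaged registry carries the centromeric probe D11Z1 (operational
#' span: the acen anchor) and the two pericentric BAC clones RP11-397M16
#' (11p11.2) and RP11-77M17 (11q12), with GRCh37 coordinates. Users can
#' append additional probes.
#'
#' @param path Registry TSV; defaults to the packaged file.
#' @param extra Optional tibble of additional probes (`probe`, `chrom`,
#'   `start`, `end`, `build`).
#' @return A tibble, one probe per row.
#' @export
load_probe_registry <- function(path = system.file("extdata", "probes_grch37.tsv",
                                  package = "ssmc11"
                                ),
                                extra = NULL) {
  reg <- readr::read_tsv(path, col_types = "ccddcc", progress = FALSE)
  reg <- reg[, c("probe", "chrom", "start", "end", "build")]
  if (!is.null(extra)) reg <- dplyr::bind_rows(reg, extra)
  reg
}

#' Resolve parsed evidence into the demonstrated trisomy extent
#'
#' Combines array intervals, curated coordinates, FISH probe calls and
#' cytoband spans into one maximal demonstrated trisomic interval,
#' per-arm and precision-aware:
#'
#' * Coordinate-level evidence (GRCh37 array interval, curated interval,
#'   spans of gain-positive probes) supersedes band-level evidence on an
#'   arm whenever it extends beyond the centromere anchor on that side;
#'   the boundary is then the outermost such coordinate.
#' * Otherwise the arm boundary is the outer edge of the band-span
#'   endpoint on that arm, or the anchor edge if no evidence reaches
#'   further.
#'
#' A probe call counts as gain evidence when it is `++`, or `+` on a
#' marker-chromosome ish clause (on an interstitial `dup`/`der` clause a
#' single `+` is the undisturbed normal signal, not a gain). Negative
#' probe calls never truncate the extent; if the resolved extent overlaps
#' a `-` probe's span a consistency warning is attached
#' (`attr(x, "consistency_warnings")`).
#'
#' @param pk A `parsed_karyotype`.
#' @param registry Probe registry tibble.
#' @param bands Cytoband table.
#' @param curated Optional curated interval (one-row table, GRCh37) taken
#'   as coordinate-level evidence (e.g. a table-transcribed aCGH value).
#' @return One-row interval table; attributes `evidence` (per-boundary
#'   provenance) and `consistency_warnings`.
#' @export
resolve_extent <- function(pk, registry = load_probe_registry(),
                           bands = load_cytobands(), curated = NULL) {
  anchor <- centromere_anchor(bands)
  chrom <- anchor$chrom

  coord <- tibble::tibble(
    chrom = character(), start = numeric(), end = numeric(),
    build = character(), source = character()
  )
  ai <- pk$array_interval
  if (!is.null(ai) && isTRUE(ai$canonical)) {
    if (!identical(ai$chrom, chrom)) {
      stop("array evidence on ", ai$chrom, ", expected ", chrom, call. = FALSE)
    }
    coord <- dplyr::bind_rows(coord, tibble::tibble(
      chrom = ai$chrom, start = ai$start, end = ai$end, build = "GRCh37",
      source = "aCGH"
    ))
  }
  if (!is.null(curated) && nrow(curated) == 1 && !is.na(curated$start)) {
    if (!identical(curated$chrom, chrom)) {
      stop("curated interval on ", curated$chrom, ", expected ", chrom,
        call. = FALSE
      )
    }
    coord <- dplyr::bind_rows(coord, tibble::tibble(
      chrom = curated$chrom, start = curated$start, end = curated$end,
      build = curated$build, source = "curated"
    ))
  }
  gain_signs <- if (isTRUE(pk$marker_context)) c("+", "++") else "++"
  gains <- names(pk$probe_calls)[pk$probe_calls %in% gain_signs]
  known <- registry[registry$probe %in% gains, ]
  if (nrow(known) > 0) {
    coord <- dplyr::bind_rows(coord, tibble::tibble(
      chrom = known$chrom, start = known$start, end = known$end,
      build = known$build, source = paste0("probe:", known$probe)
    ))
  }

  band_iv <- function(lab) {
    tryCatch(band_to_interval(lab, bands, chrom), error = function(e) {
      warning("band '", lab, "' not resolvable: ", conditionMessage(e),
        call. = FALSE
      )
      NULL
    })
  }
  p_band <- q_band <- NULL
  p_band_inner_end <- q_band_inner_start <- NULL
  if (!is.null(pk$band_span)) {
    for (lab in unique(pk$band_span)) {
      iv <- band_iv(lab)
      if (is.null(iv)) next
      if (startsWith(clean_band_label(lab), "p")) {
        if (is.null(p_band) || iv$start < p_band$start) p_band <- iv
        if (is.null(p_band_inner_end) || iv$end > p_band_inner_end) {
          p_band_inner_end <- iv$end
        }
      } else {
        if (is.null(q_band) || iv$end > q_band$end) q_band <- iv
        if (is.null(q_band_inner_start) || iv$start < q_band_inner_start) {
          q_band_inner_start <- iv$start
        }
      }
    }
  }

  has_coord <- nrow(coord) > 0
  has_band <- !is.null(p_band) || !is.null(q_band)
  if (!has_coord && !has_band) {
    stop("no usable evidence to resolve a trisomy extent", call. = FALSE)
  }

  # Per-side precision hierarchy: coordinate-level evidence supersedes the
  # band-span endpoint on a side whenever it extends beyond the centromere
  # anchor on that side; otherwise the band's outer edge participates.
  p_superseded <- has_coord && any(coord$start < anchor$start)
  p_cands <- c(
    coord$start,
    if (!p_superseded && !is.null(p_band)) p_band$start
  )
  p_srcs <- c(
    coord$source,
    if (!p_superseded && !is.null(p_band)) paste0("band:", p_band$label)
  )
  if (length(p_cands) == 0) { # q-only band span
    p_cands <- q_band_inner_start
    p_srcs <- paste0("band:", q_band$label)
  }
  p_boundary <- min(p_cands)
  p_source <- p_srcs[which.min(p_cands)]

  q_superseded <- has_coord && any(coord$end > anchor$end)
  q_cands <- c(
    coord$end,
    if (!q_superseded && !is.null(q_band)) q_band$end
  )
  q_srcs <- c(
    coord$source,
    if (!q_superseded && !is.null(q_band)) paste0("band:", q_band$label)
  )
  if (length(q_cands) == 0) { # p-only band span
    q_cands <- p_band_inner_end
    q_srcs <- paste0("band:", p_band$label)
  }
  q_boundary <- max(q_cands)
  q_source <- q_srcs[which.max(q_cands)]

  out <- genomic_interval(chrom, p_boundary, q_boundary, "GRCh37")

  # negative probes validate, never truncate
  neg <- names(pk$probe_calls)[pk$probe_calls == "-"]
  neg_reg <- registry[registry$probe %in% neg, ]
  warnings <- character(0)
  if (nrow(neg_reg) > 0) {
    clash <- intervals_overlap(out$start, out$end, neg_reg$start, neg_reg$end)
    if (any(clash)) {
      warnings <- sprintf(
        "resolved extent overlaps negative probe %s (%s-%s)",
        neg_reg$probe[clash], format(neg_reg$start[clash], big.mark = ","),
        format(neg_reg$end[clash], big.mark = ",")
      )
    }
  }
  attr(out, "evidence") <- tibble::tibble(
    boundary = c("p", "q"),
    coordinate = c(p_boundary, q_boundary),
    source = c(p_source, q_source)
  )
  attr(out, "consistency_warnings") <- warnings
  out
}

#' Resolve trisomy extents for a whole cohort
#'
#' For each case, the curated interval columns (when present, GRCh37) and
#' the parsed karyotype evidence are combined through [resolve_extent()].
#' Cases whose evidence cannot be resolved keep `NA` coordinates and a
#' reason; they are never dropped here.
#'
#' @param cohort Cohort tibble from [read_cohort()].
#' @param registry,bands Probe registry and cytoband map.
#' @return The cohort with `extent_start`, `extent_end`, `extent_source`
#'   and `extent_note` columns added.
#' @export
resolve_cohort_extents <- function(cohort, registry = load_probe_registry(),
                                   bands = load_cytobands()) {
  res <- purrr::map(seq_len(nrow(cohort)), function(i) {
    row <- cohort[i, ]
    curated <- NULL
    if (!is.na(row$interval_start) && !is.na(row$interval_end) &&
      identical(row$build, "GRCh37")) {
      curated <- genomic_interval(
        row$interval_chrom, row$interval_start, row$interval_end, row$build
      )
    }
    # A curated (table-transcribed) coordinate interval is authoritative:
    # the published tables treat the aCGH value as the demonstrated extent.
    if (!is.null(curated)) {
      return(list(start = curated$start, end = curated$end, source = "curated",
        note = NA_character_
      ))
    }
    pk <- tryCatch(parse_karyotype(row$karyotype_text), error = function(e) NULL)
    if (is.null(pk)) {
      return(list(start = NA_real_, end = NA_real_, source = NA_character_,
        note = "karyotype unparseable and no curated interval"
      ))
    }
    ext <- tryCatch(
      suppressWarnings(resolve_extent(pk, registry, bands, curated = curated)),
      error = function(e) NULL
    )
    if (is.null(ext)) {
      return(list(start = NA_real_, end = NA_real_, source = NA_character_,
        note = "no resolvable extent"
      ))
    }
    ev <- attr(ext, "evidence")
    list(
      start = ext$start, end = ext$end,
      source = paste(unique(ev$source), collapse = "+"), note = NA_character_
    )
  })
  cohort$extent_start <- vapply(res, function(r) r$start, 1)
  cohort$extent_end <- vapply(res, function(r) r$end, 1)
  cohort$extent_source <- vapply(res, function(r) r$source, "")
  cohort$extent_note <- vapply(res, function(r) r$note, "")
  cohort
}
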