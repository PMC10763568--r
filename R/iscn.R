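#' @keywords internal
.shape_levels <- c("min", "r", "inv dup", "unknown")

#' @keywords internal
normalise_karyotype_text <- function(text) {
  t <- gsub("->", "→", text, fixed = TRUE)
  t <- gsub("∼", "~", t) # tilde operator variants
  gsub("[ \t]+", " ", trimws(t))
}

#' @keywords internal
band_token_regex <- "(?:11)?[pq][0-9?]+(?:\\.[0-9?]+)?"

#' @keywords internal
clean_band_label <- function(x) {
  x <- sub("^11", "", x)
  gsub("\\?", "", x)
}

# Telomere-ward ordering key for band labels: digits compared positionally,
# so p11.2 > p11.12 > p11.1 (ISCN sub-band numbering counts outward from
# the centromere, digit by digit).
#' @keywords internal
band_key <- function(label) {
  digits <- strsplit(gsub("[^0-9]", "", sub("^[pq]", "", label)), "")[[1]]
  as.integer(digits)
}

#' @keywords internal
band_more_telomeric <- function(a, b) {
  ka <- band_key(a)
  kb <- band_key(b)
  n <- max(length(ka), length(kb))
  ka <- c(ka, rep(-1L, n - length(ka)))
  kb <- c(kb, rep(-1L, n - length(kb)))
  for (i in seq_len(n)) {
    if (ka[i] != kb[i]) return(ka[i] > kb[i])
  }
  FALSE
}

#' @keywords internal
outermost_band <- function(labels) {
  if (length(labels) == 0) return(NA_character_)
  out <- labels[1]
  for (l in labels[-1]) if (band_more_telomeric(l, out)) out <- l
  out
}

#' @keywords internal
innermost_band <- function(labels) {
  if (length(labels) == 0) return(NA_character_)
  out <- labels[1]
  for (l in labels[-1]) if (band_more_telomeric(out, l)) out <- l
  out
}

#' @keywords internal
probe_call_tokens <- function(group) {
  toks <- strsplit(group, ",", fixed = TRUE)[[1]]
  toks <- trimws(toks)
  m <- regexec("^([A-Za-z][A-Za-z0-9._-]*?)(\\+{1,2}|-)$", toks, perl = TRUE)
  out <- lapply(regmatches(toks, m), function(p) {
    if (length(p) == 3) c(name = p[2], sign = p[3]) else NULL
  })
  if (any(vapply(out, is.null, TRUE))) return(NULL) # not a probe group
  out
}

#' @keywords internal
parse_cell_bracket <- function(token) {
  token <- trimws(token)
  if (grepl("^[0-9]+$", token)) {
    return(list(count = as.integer(token), percent = NA_real_))
  }
  m <- regexec("^([0-9]+(?:\\.[0-9]+)?)%$", token)[[1]]
  if (m[1] > 0) {
    val <- as.numeric(sub("%$", "", token))
    return(list(count = NA_integer_, percent = val))
  }
  # "?", "?%", "60%-90%", "majority", ... -> absent
  list(count = NA_integer_, percent = NA_real_)
}

#' @keywords internal
parse_clone_stanza <- function(stanza) {
  stanza <- trimws(stanza)
  m <- regexec("^(mos )?([0-9]+)(?:[-~][0-9]+)?", stanza)[[1]]
  if (m[1] < 0) return(NULL)
  chrom_count <- as.integer(regmatches(stanza, regexec(
    "^(?:mos )?([0-9]+)", stanza
  ))[[1]][2])
  rest <- substring(stanza, m[1] + attr(m, "match.length")[1])
  sex <- NA_character_
  sm <- regexec("^,\\s*(X[XYN]?|Y)\\b", rest)[[1]]
  if (sm[1] > 0) {
    sex <- regmatches(rest, list(sm))[[1]][2]
    rest <- substring(rest, attr(sm, "match.length")[1] + 1)
  }
  cell_count <- NA_integer_
  cell_percent <- NA_real_
  remark <- ""
  bm <- regexec("\\[([^]]*)\\]", rest, perl = TRUE)[[1]]
  if (bm[1] > 0) {
    cell <- parse_cell_bracket(regmatches(rest, list(bm))[[1]][2])
    cell_count <- cell$count
    cell_percent <- cell$percent
    remark <- trimws(substring(rest, bm[1] + attr(bm, "match.length")[1]))
    rest <- substring(rest, 1, bm[1] - 1)
  }
  terms <- trimws(strsplit(rest, ",", fixed = TRUE)[[1]])
  terms <- terms[nzchar(terms)]
  has_marker <- any(grepl("^\\+", terms))
  list(
    chrom_count = chrom_count, sex_token = sex, terms = list(terms),
    cell_count = cell_count, cell_percent = cell_percent,
    has_marker = has_marker, remark = remark
  )
}

#' @keywords internal
extract_shape <- function(chunk) {
  m <- regexpr("inv dup|min|(?<![a-z])r(?=\\s*\\()", chunk, perl = TRUE)
  if (m < 0) return(NA_character_)
  regmatches(chunk, m)
}

#' @keywords internal
parse_ish_section <- function(body) {
  body <- trimws(body)
  chunks <- strsplit(body, "/", fixed = TRUE)[[1]]
  shapes <- character(0)
  shape_counts <- integer(0)
  probe_calls <- character(0)
  bands <- character(0)
  for (chunk in chunks) {
    count <- NA_integer_
    bm <- regexec("\\[([0-9]+)\\]", chunk)[[1]]
    if (bm[1] > 0) count <- as.integer(regmatches(chunk, list(bm))[[1]][2])
    # peel off probe groups (parenthesised lists of name+sign tokens)
    groups <- regmatches(chunk, gregexpr("\\(([^()]*)\\)", chunk))[[1]]
    for (g in groups) {
      toks <- probe_call_tokens(substring(g, 2, nchar(g) - 1))
      if (!is.null(toks)) {
        for (tk in toks) {
          if (!tk[["name"]] %in% names(probe_calls)) {
            probe_calls[tk[["name"]]] <- tk[["sign"]]
          }
        }
        chunk <- sub(g, "", chunk, fixed = TRUE)
      }
    }
    shp <- extract_shape(chunk)
    if (!is.na(shp)) {
      shapes <- c(shapes, shp)
      shape_counts <- c(shape_counts, count)
    }
    bands <- c(bands, unlist(regmatches(
      chunk, gregexpr(band_token_regex, chunk, perl = TRUE)
    )))
  }
  list(
    shapes = shapes, shape_counts = shape_counts,
    probe_calls = probe_calls, bands = clean_band_label(bands)
  )
}

#' Parse an array (aCGH) stanza
#'
#' Reads an `arr[build] locus(start_end)xN` stanza: the build token comes
#' from the brackets (parentheses are tolerated), coordinates are split on
#' `_` or `-` with thousands separators stripped, and the trailing `x<N>`
#' is the copy number. Builds other than hg19/GRCh37 are kept but flagged
#' `canonical = FALSE` (needs conversion); the package performs no
#' liftover.
#'
#' @param text A string containing an `arr[...]` stanza.
#' @return A one-row tibble: `chrom`, `start`, `end`, `build`,
#'   `build_token`, `copy_number`, `canonical`, `locus`.
#' @examples
#' parse_arr("arr[hg19] 11q12.1(55,896,790_59,319,390)x3")
#' @export
parse_arr <- function(text) {
  text <- normalise_karyotype_text(text)
  m <- regexec(
    "arr\\s*[\\[(]([A-Za-z0-9]+)[\\])]\\s*([^()]*?)\\(([^()]*)\\)\\s*x([0-9]+)",
    text,
    perl = TRUE
  )[[1]]
  if (m[1] < 0) stop("no arr[...] stanza found in: ", text, call. = FALSE)
  parts <- regmatches(text, list(m))[[1]]
  build_token <- parts[2]
  locus <- trimws(parts[3])
  coords <- parts[4]
  cn <- as.integer(parts[5])
  pieces <- strsplit(coords, "[_-]")[[1]]
  nums <- suppressWarnings(as.numeric(gsub("[.,]", "", pieces)))
  if (length(nums) != 2 || any(is.na(nums))) {
    stop("malformed arr coordinate pair: '", coords, "'", call. = FALSE)
  }
  canonical <- build_token %in% c("hg19", "GRCh37")
  chrom <- regmatches(locus, regexpr("^[0-9XY]+", locus))
  chrom <- if (length(chrom) == 1) paste0("chr", chrom) else "chr11"
  tibble::tibble(
    chrom = chrom, start = nums[1], end = nums[2],
    build = if (canonical) "GRCh37" else build_token,
    build_token = build_token, copy_number = cn,
    canonical = canonical, locus = locus
  )
}

#' Parse an ISCN-style karyotype string
#'
#' Covers the permissive subset of ISCN nomenclature used in sSMC case
#' tables: mosaic clone lists split on `/` with bracketed cell counts or
#' percentages, `.ish` clauses carrying sSMC shape (`min`, `r`,
#' `inv dup`), band spans and FISH probe calls, `arr[...]` stanzas, and
#' `mat`/`pat`/`dn` inheritance tokens. Anything outside the grammar
#' (tissue histories, `seq[...]` breakpoint notation, free-text comments)
#' is preserved as a remark rather than failing, because published case
#' tables contain free-text rows.
#'
#' @param text Karyotype string (non-empty).
#' @return An object of class `parsed_karyotype`: a list with `clones`
#'   (tibble), `shapes` (tibble of shape + clone cell count), `band_span`
#'   (length-2 character or `NULL`), `probe_calls` (named character of
#'   `+`/`++`/`-`), `array_interval` (tibble or `NULL`), `inheritance`,
#'   `mosaic`, `marker_context` and `remarks`.
#' @examples
#' pk <- parse_karyotype(
#'   "mos 47,XY,+mar[21]/46,XY[32].ish min(11)(:p11.1→q11:)(D11Z1+)"
#' )
#' pk$clones
#' @export
parse_karyotype <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text) ||
    !nzchar(trimws(text))) {
    stop("karyotype text must be a non-empty string", call. = FALSE)
  }
  t <- normalise_karyotype_text(text)
  remarks <- character(0)

  # seq[...] breakpoint notation: preserved verbatim, never modelled
  sq <- regexpr("\\bseq\\s*\\[", t)
  if (sq > 0) {
    remarks <- c(remarks, trimws(substring(t, sq)))
    t <- trimws(substring(t, 1, sq - 1))
  }

  # arr stanza
  array_interval <- NULL
  am <- regexpr("(^|[ .])arr\\s*[\\[(]", t)
  if (am > 0) {
    arr_text <- substring(t, am)
    t <- trimws(sub("[. ]$", "", substring(t, 1, am - 1)))
    array_interval <- tryCatch(parse_arr(arr_text), error = function(e) NULL)
    if (is.null(array_interval)) remarks <- c(remarks, trimws(arr_text))
  }

  # ish clause (possibly ".rev ish")
  ish <- NULL
  im <- regexpr("[. ](rev )?ish ", t)
  if (im > 0) {
    body <- sub("^[. ](rev )?ish ", "", substring(t, im))
    ish <- parse_ish_section(body)
    t <- trimws(substring(t, 1, im - 1))
  }

  # clone section
  clone_stanzas <- strsplit(t, "/", fixed = TRUE)[[1]]
  clones <- purrr::map(clone_stanzas, parse_clone_stanza)
  keep <- !vapply(clones, is.null, TRUE)
  if (!any(keep)) {
    stop(
      "no recognizable clone stanza at offset 1 in: ", text,
      call. = FALSE
    )
  }
  if (any(!keep)) remarks <- c(remarks, trimws(clone_stanzas[!keep]))
  clones <- clones[keep]
  clone_remarks <- vapply(clones, function(cl) cl$remark, "")
  remarks <- c(remarks, clone_remarks[nzchar(clone_remarks)])
  clones_tbl <- tibble::tibble(
    chrom_count = vapply(clones, function(cl) cl$chrom_count, 1L),
    sex_token = vapply(clones, function(cl) cl$sex_token, ""),
    terms = lapply(clones, function(cl) cl$terms[[1]]),
    cell_count = vapply(clones, function(cl) cl$cell_count, 1L),
    cell_percent = vapply(clones, function(cl) cl$cell_percent, 1),
    has_marker = vapply(clones, function(cl) cl$has_marker, TRUE)
  )

  shapes <- if (!is.null(ish)) {
    tibble::tibble(shape = ish$shapes, cell_count = ish$shape_counts)
  } else {
    tibble::tibble(shape = character(), cell_count = integer())
  }
  probe_calls <- if (!is.null(ish)) ish$probe_calls else character(0)
  bands <- if (!is.null(ish)) ish$bands else character(0)

  # marker shape may be written in the clone terms ("+r(11)(...)", "+min(...)")
  # or in free-text marker definitions ("mar2 = min(11)") kept as remarks
  for (src in c(
    unlist(clones_tbl$terms, use.names = FALSE),
    remarks
  )) {
    m <- regexpr(
      paste0(
        "inv dup(?=\\s*\\()|min(?=\\s*\\(\\s*(11|:))|",
        "(?<![a-z])r(?=\\s*\\(\\s*(11|:|[0-9]+\\s*;\\s*11))|",
        "(?<=\\+)(min|r)\\b(?!\\s*\\()"
      ),
      src,
      perl = TRUE
    )
    if (m > 0) {
      shapes <- dplyr::bind_rows(
        shapes,
        tibble::tibble(shape = regmatches(src, m), cell_count = NA_integer_)
      )
      bands <- c(bands, clean_band_label(unlist(regmatches(
        src, gregexpr(band_token_regex, src, perl = TRUE)
      ))))
    }
  }

  p_bands <- unique(bands[startsWith(bands, "p")])
  q_bands <- unique(bands[startsWith(bands, "q")])
  band_span <- NULL
  if (length(p_bands) + length(q_bands) > 0) {
    from <- if (length(p_bands) > 0) outermost_band(p_bands) else innermost_band(q_bands)
    to <- if (length(q_bands) > 0) outermost_band(q_bands) else innermost_band(p_bands)
    band_span <- c(from, to)
  }

  inheritance <- "unknown"
  if (grepl("\\bmat\\b", t)) inheritance <- "maternal"
  if (grepl("\\bpat\\b", t)) inheritance <- "paternal"
  if (grepl("\\bdn\\b", t)) inheritance <- "de novo"

  marker_context <- any(clones_tbl$has_marker)

  # mosaic: a clone without the aberration exists. In sSMC context the
  # aberration is the "+" marker; in interstitial dup/der context it is
  # the structural term itself.
  aberrant <- purrr::map_lgl(clones_tbl$terms, function(tm) {
    any(grepl("^\\+", tm)) ||
      any(grepl("^(dup|der|ins|del|inv|t|r|min)\\s*\\(", tm))
  })
  mosaic <- if (any(clones_tbl$has_marker)) {
    any(!clones_tbl$has_marker)
  } else {
    any(aberrant) && any(!aberrant)
  }

  structure(
    list(
      text = text,
      clones = clones_tbl,
      shapes = shapes,
      band_span = band_span,
      probe_calls = probe_calls,
      array_interval = array_interval,
      inheritance = inheritance,
      mosaic = mosaic,
      marker_context = marker_context,
      remarks = remarks
    ),
    class = "parsed_karyotype"
  )
}

#' @export
print.parsed_karyotype <- function(x, ...) {
  cat("<parsed_karyotype>", x$text, "\n")
  cat("  clones:", nrow(x$clones), "| mosaic:", x$mosaic, "\n")
  if (nrow(x$shapes) > 0) {
    cat("  shapes:", paste(x$shapes$shape, collapse = ", "), "\n")
  }
  if (!is.null(x$band_span)) {
    cat("  band span:", x$band_span[1], "→", x$band_span[2], "\n")
  }
  if (length(x$probe_calls) > 0) {
    cat("  probes:", paste0(names(x$probe_calls), x$probe_calls, collapse = ", "), "\n")
  }
  if (!is.null(x$array_interval)) {
    cat(
      "  arr:", x$array_interval$chrom, x$array_interval$start, "-",
      x$array_interval$end, paste0("[", x$array_interval$build_token, "]"), "\n"
    )
  }
  cat("  inheritance:", x$inheritance, "\n")
  invisible(x)
}

#' Predominant sSMC shape of a parsed karyotype
#'
#' When several clone variants with different shapes are reported, the
#' predominant shape is the shape of the clone with the largest cell
#' count, falling back to the first listed.
#'
#' @param pk A `parsed_karyotype`.
#' @return A single shape string, or `NA` if no shape was reported.
#' @export
predominant_shape <- function(pk) {
  s <- pk$shapes
  if (nrow(s) == 0) return(NA_character_)
  if (all(is.na(s$cell_count))) return(s$shape[1])
  s$cell_count[is.na(s$cell_count)] <- -1L
  s$shape[which.max(s$cell_count)]
}

#' Fraction of counted cells carrying the marker
#'
#' With bracketed clone cell counts, the fraction is (cells in
#' marker-bearing clones) / (total counted cells); with percentages, the
#' sum over marker-bearing clones / 100. A case is mosaic iff a clone
#' without the marker exists, independent of the fraction.
#'
#' @param pk A `parsed_karyotype`.
#' @return A fraction in \[0, 1\], or `NA` when counts are absent or
#'   counts and percentages are mixed inconsistently (with a warning).
#' @examples
#' mosaic_fraction(parse_karyotype("mos 47,XY,+mar[21]/46,XY[32]"))
#' @export
mosaic_fraction <- function(pk) {
  cl <- pk$clones
  if (nrow(cl) == 0) return(NA_real_)
  has_counts <- !is.na(cl$cell_count)
  has_pct <- !is.na(cl$cell_percent)
  if (all(has_counts)) {
    total <- sum(cl$cell_count)
    if (total == 0) return(NA_real_)
    return(sum(cl$cell_count[cl$has_marker]) / total)
  }
  if (all(has_pct)) {
    return(min(1, sum(cl$cell_percent[cl$has_marker]) / 100))
  }
  if (any(has_counts) && any(has_pct)) {
    warning("clone counts and percentages mixed inconsistently; fraction absent")
  }
  NA_real_
}

#' Serialise a parsed karyotype back to text
#'
#' Produces a canonical string whose re-parse yields the same structured
#' fields (clones, shapes, band span, probe calls, array interval,
#' inheritance); formatting variants of the input are not preserved.
#'
#' @param pk A `parsed_karyotype`.
#' @return A karyotype string.
#' @export
emit_karyotype <- function(pk) {
  cl <- pk$clones
  inh_tok <- c(maternal = " mat", paternal = " pat", `de novo` = " dn",
    unknown = ""
  )[[pk$inheritance]]
  clone_txt <- vapply(seq_len(nrow(cl)), function(i) {
    terms <- cl$terms[[i]]
    if (i == 1 && nzchar(inh_tok) && length(terms) > 0 &&
      !any(grepl("\\b(mat|pat|dn)\\b", terms))) {
      terms[1] <- paste0(terms[1], inh_tok)
    }
    cell <- if (!is.na(cl$cell_count[i])) {
      sprintf("[%d]", cl$cell_count[i])
    } else if (!is.na(cl$cell_percent[i])) {
      sprintf("[%s%%]", format(cl$cell_percent[i]))
    } else {
      ""
    }
    paste0(
      paste(c(
        cl$chrom_count[i],
        if (!is.na(cl$sex_token[i])) cl$sex_token[i],
        terms
      ), collapse = ","),
      cell
    )
  }, "")
  out <- paste(clone_txt, collapse = "/")
  if (pk$mosaic || nrow(cl) > 1) out <- paste0("mos ", out)

  ish_shapes <- pk$shapes[!is.na(pk$shapes$shape), , drop = FALSE]
  if (nrow(ish_shapes) > 0 || length(pk$probe_calls) > 0) {
    span_txt <- if (!is.null(pk$band_span)) {
      sprintf("(:%s→%s:)", pk$band_span[1], pk$band_span[2])
    } else {
      ""
    }
    variants <- if (nrow(ish_shapes) > 0) {
      vapply(seq_len(nrow(ish_shapes)), function(i) {
        cnt <- if (!is.na(ish_shapes$cell_count[i])) {
          sprintf("[%d]", ish_shapes$cell_count[i])
        } else {
          ""
        }
        paste0(ish_shapes$shape[i], "(11)", span_txt, cnt)
      }, "")
    } else {
      paste0("mar(11)", span_txt)
    }
    probes <- if (length(pk$probe_calls) > 0) {
      sprintf("(%s)", paste0(names(pk$probe_calls), pk$probe_calls, collapse = ","))
    } else {
      ""
    }
    out <- paste0(out, ".ish ", paste(variants, collapse = "/"), probes)
  }

  if (!is.null(pk$array_interval)) {
    ai <- pk$array_interval
    out <- paste0(out, sprintf(
      ".arr[%s] %s(%s_%s)x%d",
      ai$build_token, ai$locus,
      format(ai$start, big.mark = ",", scientific = FALSE),
      format(ai$end, big.mark = ",", scientific = FALSE),
      ai$copy_number
    ))
  }
  if (length(pk$remarks) > 0) out <- paste(out, paste(pk$remarks, collapse = " "))
  out
}
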