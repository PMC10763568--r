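#' @keywords internal
round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Classify a case into descriptive groups
#'
#' Returns the deterministic label set for one case: its curated
#' formation/feature labels (McClintock, multiple-sSMC, ...) plus labels
#' derived from the curated columns and, where those are silent, from the
#' parsed karyotype: predominant shape (`shape:min` / `shape:r` /
#' `shape:invdup` / `shape:unknown`), mosaic state, inheritance and
#' clinical status. Groups are not mutually exclusive.
#'
#' @param case One-row cohort tibble.
#' @return Character vector of group labels.
#' @export
classify_groups <- function(case) {
  stopifnot(nrow(case) == 1)
  labels <- case$groups[[1]]

  shape <- if (length(case$shapes[[1]]) > 0) case$shapes[[1]][1] else NA_character_
  if (is.na(shape)) {
    pk <- tryCatch(parse_karyotype(case$karyotype_text), error = function(e) NULL)
    if (!is.null(pk)) shape <- predominant_shape(pk)
  }
  shape_label <- switch(ifelse(is.na(shape), "unknown", shape),
    "min" = "shape:min", "r" = "shape:r", "inv dup" = "shape:invdup",
    "shape:unknown"
  )
  inh_label <- switch(case$inheritance,
    maternal = "inheritance:mat", paternal = "inheritance:pat",
    "de novo" = "inheritance:dn", NULL
  )
  c(
    labels,
    shape_label,
    if (isTRUE(case$mosaic)) "mosaic" else "non-mosaic",
    inh_label,
    paste0("clinical:", case$clinical_status)
  )
}

#' Cohort descriptive summary
#'
#' Computes the cohort's clinical classification counts, predominant
#' shape distribution (denominator: cases with a reported shape), sex
#' counts and male/female ratio, formation/feature group counts with
#' percentages of the whole cohort (rounded half-up to one decimal),
#' mosaicism, and inheritance counts. Shape is counted once per case by
#' its predominant shape.
#'
#' @param cohort Cohort tibble.
#' @return A `cohort_summary` object (list of tibbles and scalars); see
#'   [tidy.cohort_summary()] and [glance.cohort_summary()].
#' @examples
#' \dontrun{
#' summarize_cohort(load_packaged_cohort("table1"))
#' }
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(nrow(cohort) > 0)
  n <- nrow(cohort)
  count_of <- function(values, levels) {
    tab <- table(factor(values, levels = levels))
    tibble::tibble(level = names(tab), count = as.integer(tab))
  }
  clinical <- count_of(cohort$clinical_status, c("normal", "abnormal", "unknown"))
  sexes <- count_of(cohort$sex, c("male", "female", "unknown"))

  shape_per_case <- vapply(seq_len(n), function(i) {
    s <- cohort$shapes[[i]]
    if (length(s) > 0) s[1] else NA_character_
  }, "")
  reported <- !is.na(shape_per_case)
  shapes <- count_of(shape_per_case[reported], c("min", "r", "inv dup"))
  shapes$percent <- round_half_up(100 * shapes$count / max(1, sum(reported)))

  group_labels <- purrr::map(seq_len(n), function(i) classify_groups(cohort[i, ]))
  all_labels <- sort(unique(unlist(group_labels)))
  groups <- tibble::tibble(
    group = all_labels,
    count = vapply(all_labels, function(g) {
      sum(vapply(group_labels, function(l) g %in% l, TRUE))
    }, 1L, USE.NAMES = FALSE)
  )
  mcc <- sum(vapply(group_labels, function(l) {
    any(c("McClintock", "pseudo-McClintock") %in% l)
  }, TRUE))
  groups <- dplyr::bind_rows(
    groups,
    tibble::tibble(group = "(pseudo-)McClintock", count = mcc)
  )
  groups$percent <- round_half_up(100 * groups$count / n)
  groups$denominator <- n

  males <- sexes$count[sexes$level == "male"]
  females <- sexes$count[sexes$level == "female"]
  inheritance <- count_of(
    cohort$inheritance, c("maternal", "paternal", "de novo", "unknown")
  )

  structure(
    list(
      n_total = n,
      n_by_clinical = clinical,
      n_by_shape = shapes,
      n_shape_reported = sum(reported),
      sex_counts = sexes,
      male_female_ratio = if (females > 0) round(males / females, 2) else NA_real_,
      group_counts = groups,
      mosaic_count = sum(cohort$mosaic),
      mosaic_fraction = round(sum(cohort$mosaic) / n, 3),
      inheritance_counts = inheritance
    ),
    class = "cohort_summary"
  )
}

#' Tidy a cohort summary into one row per counted level
#'
#' @param x A `cohort_summary`.
#' @param ... Unused.
#' @return A long tibble: `statistic`, `level`, `count`, `percent`,
#'   `denominator`.
#' @export
tidy.cohort_summary <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$n_by_clinical,
      statistic = "clinical_status",
      percent = round_half_up(100 * .data$count / x$n_total),
      denominator = x$n_total
    ),
    dplyr::mutate(x$n_by_shape,
      statistic = "shape",
      denominator = x$n_shape_reported
    ),
    dplyr::mutate(x$sex_counts,
      statistic = "sex",
      percent = round_half_up(100 * .data$count / x$n_total),
      denominator = x$n_total
    ),
    dplyr::mutate(x$inheritance_counts,
      statistic = "inheritance",
      percent = round_half_up(100 * .data$count / x$n_total),
      denominator = x$n_total
    ),
    dplyr::rename(
      dplyr::mutate(x$group_counts, statistic = "group"),
      level = "group"
    )
  )[, c("statistic", "level", "count", "percent", "denominator")]
}

#' One-row cohort summary
#'
#' @param x A `cohort_summary`.
#' @param ... Unused.
#' @return A one-row tibble with the headline counts.
#' @export
glance.cohort_summary <- function(x, ...) {
  cl <- stats::setNames(x$n_by_clinical$count, x$n_by_clinical$level)
  sx <- stats::setNames(x$sex_counts$count, x$sex_counts$level)
  tibble::tibble(
    n_total = x$n_total,
    n_normal = cl[["normal"]], n_abnormal = cl[["abnormal"]],
    n_unknown = cl[["unknown"]],
    n_male = sx[["male"]], n_female = sx[["female"]],
    male_female_ratio = x$male_female_ratio,
    n_shape_reported = x$n_shape_reported,
    mosaic_fraction = x$mosaic_fraction
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary:", x$n_total, "cases\n")
  cl <- x$n_by_clinical
  cat(
    "  clinical:",
    paste(sprintf("%s=%d", cl$level, cl$count), collapse = ", "), "\n"
  )
  sx <- x$sex_counts
  cat(
    "  sex:", paste(sprintf("%s=%d", sx$level, sx$count), collapse = ", "),
    sprintf("(M/F ratio %.2f)", x$male_female_ratio), "\n"
  )
  sh <- x$n_by_shape
  cat(
    "  shape (", x$n_shape_reported, " reported): ",
    paste(sprintf("%s=%d (%.1f%%)", sh$level, sh$count, sh$percent),
      collapse = ", "
    ), "\n",
    sep = ""
  )
  cat(
    "  mosaic:", x$mosaic_count,
    sprintf("(%.1f%%)", 100 * x$mosaic_fraction), "\n"
  )
  invisible(x)
}

#' Bar chart of group memberships
#'
#' The analog of a feature-group overview figure: one bar per group
#' label, heights are case counts; memberships are not exclusive.
#'
#' @param object A `cohort_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_summary <- function(object, ...) {
  d <- object$group_counts
  d$group <- stats::reorder(d$group, d$count)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$count, y = .data$group)) +
    ggplot2::geom_col(fill = "#4477aa") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), hjust = -0.3, size = 3) +
    ggplot2::labs(
      x = "cases", y = NULL,
      title = sprintf("Group memberships across %d cases", object$n_total),
      subtitle = "a case may belong to several groups"
    ) +
    ggplot2::theme_minimal()
}
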