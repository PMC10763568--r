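#' The controlled sign/symptom vocabulary
#'
#' The nine sign labels used for the arm-wise genotype-phenotype
#' tabulation of pericentric chromosome 11 trisomies.
#'
#' @return Character vector of sign labels.
#' @export
phenotype_vocabulary <- function() {
  c(
    "growth retardation", "blepharophimosis/ptosis", "strabism",
    "cleft palate", "facial dysmorphism", "heart defect",
    "developmental delay", "intellectual disability", "hypotonia"
  )
}

#' Assign cases to the arm whose sensitive territory their trisomy enters
#'
#' A case is assigned `p` when its trisomic interval extends telomere-ward
#' beyond the refined insensitive span's p boundary, `q` beyond the q
#' boundary, `both` when both, and `none` when the interval lies wholly
#' inside the span. A curated `arm_class` column overrides the computed
#' value (with a note in the `arm_note` column); cases without a resolved
#' interval get `none` with a warning.
#'
#' @param cases Cohort tibble (curated intervals or resolved extents).
#' @param map A `dosage_map`.
#' @return `cases` with `arm` and `arm_note` columns.
#' @export
assign_arm <- function(cases, map) {
  refined <- map$refined_span
  start <- dplyr::coalesce(
    if ("extent_start" %in% names(cases)) cases$extent_start else NA_real_,
    cases$interval_start
  )
  end <- dplyr::coalesce(
    if ("extent_end" %in% names(cases)) cases$extent_end else NA_real_,
    cases$interval_end
  )
  computed <- dplyr::case_when(
    is.na(start) | is.na(end) ~ NA_character_,
    start < refined$start & end > refined$end ~ "both",
    start < refined$start ~ "p",
    end > refined$end ~ "q",
    TRUE ~ "none"
  )
  if (anyNA(computed)) {
    warning(
      "case(s) without a resolved interval assigned 'none': ",
      paste(cases$case_id[is.na(computed)], collapse = ", ")
    )
  }
  curated <- cases$arm_class
  curated[is.na(curated) | !curated %in% c("p", "q", "both", "none")] <- NA
  arm <- dplyr::coalesce(curated, computed, "none")
  note <- dplyr::if_else(
    !is.na(curated) & !is.na(computed) & curated != computed,
    sprintf("curated arm '%s' overrides computed '%s'", curated, computed),
    NA_character_
  )
  dplyr::mutate(cases, arm = arm, arm_note = note)
}

#' Arm-wise genotype-phenotype tabulation
#'
#' Counts, for each sign of the controlled vocabulary, the clinically
#' abnormal informative cases whose trisomy reaches p-arm vs q-arm
#' sensitive territory. A case may contribute to several sign rows but is
#' counted once in the per-arm column totals; a `both`-arm case would be
#' counted in both columns. Signs outside the vocabulary are collected
#' under "facial dysmorphism" only when flagged as unspecific facial
#' dysmorphism, otherwise under "other" with a warning.
#'
#' @param cases Cohort tibble with `phenotype_terms`.
#' @param map A `dosage_map`.
#' @param vocabulary Sign labels; defaults to [phenotype_vocabulary()].
#' @return A `phenotype_matrix`: tibble with `sign`, `p`, `q` counts and
#'   `p_cases`/`q_cases` id lists; `attr(x, "column_totals")` carries the
#'   distinct case counts per arm.
#' @examples
#' \dontrun{
#' tabulate_phenotypes(load_packaged_cohort("table5"), infer_dosage_map())
#' }
#' @export
tabulate_phenotypes <- function(cases, map, vocabulary = phenotype_vocabulary()) {
  cases <- assign_arm(cases, map)
  cases <- cases[cases$clinical_status == "abnormal", ]

  long <- tidyr::unnest(
    tibble::tibble(
      case_id = cases$case_id, arm = cases$arm,
      sign = cases$phenotype_terms
    ),
    "sign"
  )
  if (nrow(long) > 0) {
    unspecific <- grepl("facial dysmorphism", long$sign, fixed = TRUE)
    long$sign[unspecific] <- "facial dysmorphism"
    unknown <- !long$sign %in% vocabulary
    if (any(unknown)) {
      warning(
        "sign(s) outside the vocabulary counted under 'other': ",
        paste(unique(long$sign[unknown]), collapse = ", ")
      )
      long$sign[unknown] <- "other"
    }
  }
  rows <- c(vocabulary, if (any(long$sign == "other")) "other")

  cell <- function(sign_, arm_) {
    ids <- unique(long$case_id[long$sign == sign_ &
      long$arm %in% c(arm_, "both")])
    ids
  }
  out <- tibble::tibble(
    sign = rows,
    p = vapply(rows, function(s) length(cell(s, "p")), 1L),
    p_cases = lapply(rows, function(s) cell(s, "p")),
    q = vapply(rows, function(s) length(cell(s, "q")), 1L),
    q_cases = lapply(rows, function(s) cell(s, "q"))
  )
  totals <- c(
    p = length(unique(long$case_id[long$arm %in% c("p", "both")])),
    q = length(unique(long$case_id[long$arm %in% c("q", "both")]))
  )
  structure(out, column_totals = totals, class = c("phenotype_matrix", class(out)))
}

#' @export
print.phenotype_matrix <- function(x, ...) {
  cat("Arm-wise sign counts (abnormal informative cases)\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-28s p=%d  q=%d\n", x$sign[i], x$p[i], x$q[i]))
  }
  tot <- attr(x, "column_totals")
  cat(sprintf("  %-28s p=%d  q=%d (distinct cases)\n", "total", tot[["p"]], tot[["q"]]))
  invisible(x)
}

#' Heat-tile plot of the arm-wise phenotype matrix
#'
#' @param object A `phenotype_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phenotype_matrix <- function(object, ...) {
  d <- tidyr::pivot_longer(
    object[, c("sign", "p", "q")],
    cols = c("p", "q"), names_to = "arm", values_to = "count"
  )
  d$sign <- factor(d$sign, levels = rev(object$sign))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$arm, y = .data$sign, fill = .data$count)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3.5) +
    ggplot2::scale_fill_gradient(low = "#f7fbff", high = "#2171b5") +
    ggplot2::labs(
      x = "arm entered by the trisomy", y = NULL, fill = "cases",
      title = "Signs by affected chromosome 11 arm"
    ) +
    ggplot2::theme_minimal()
}
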