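#' @keywords internal
cohort_columns <- c(
  "case_id", "karyotype_text", "sex", "clinical_status", "shapes", "mosaic",
  "clone_counts", "inheritance", "groups", "interval_chrom", "interval_start",
  "interval_end", "build", "modalities", "phenotype_terms", "arm_class",
  "source_table"
)

#' @keywords internal
group_vocabulary <- c(
  "complex", "discontinuous", "McClintock", "pseudo-McClintock",
  "multiple-sSMC", "acquired", "UPD-associated"
)

#' @keywords internal
split_multi <- function(x) {
  lapply(x, function(v) {
    if (is.na(v) || !nzchar(v)) character(0) else trimws(strsplit(v, ";", fixed = TRUE)[[1]])
  })
}

#' @keywords internal
join_multi <- function(x) {
  vapply(x, function(v) paste(v, collapse = ";"), "")
}

#' Read a cohort table
#'
#' Reads the cohort dialect: a UTF-8 TSV (or the equivalent JSON array)
#' with one carrier per row and the documented column schema (see
#' Details). Semicolon-joined columns become list-columns; interval
#' columns become numeric. Unparseable coordinate fields yield an absent
#' trisomy interval with a warning, never a failure.
#'
#' @details Columns: `case_id`, `karyotype_text`, `sex`
#'   (male/female/unknown), `clinical_status` (normal/abnormal/unknown;
#'   normal may include infertility), `shapes` (semicolon-joined,
#'   predominant first), `mosaic` (logical), `clone_counts`,
#'   `inheritance`, `groups` (closed vocabulary: complex, discontinuous,
#'   McClintock, pseudo-McClintock, multiple-sSMC, acquired,
#'   UPD-associated), `interval_chrom`, `interval_start`, `interval_end`,
#'   `build`, `modalities`, `phenotype_terms`, `arm_class`,
#'   `source_table`.
#'
#' @param path File path.
#' @param dialect `"tsv"` or `"json"`.
#' @return A tibble, one row per case, with list-columns `shapes`,
#'   `groups`, `modalities`, `phenotype_terms`.
#' @export
read_cohort <- function(path, dialect = c("tsv", "json")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  if (dialect == "tsv") {
    raw <- readr::read_tsv(path,
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE
    )
  } else {
    raw <- tibble::as_tibble(jsonlite::fromJSON(path))
    raw[] <- lapply(raw, as.character)
  }
  mandatory <- c("case_id", "karyotype_text", "clinical_status")
  for (col in mandatory) {
    if (!col %in% names(raw)) {
      stop("cohort table is missing mandatory column '", col, "'",
        call. = FALSE
      )
    }
  }
  for (col in setdiff(cohort_columns, names(raw))) raw[[col]] <- NA_character_
  raw <- raw[, cohort_columns]

  norm_token <- function(x, allowed, default = "unknown") {
    x <- ifelse(is.na(x) | !nzchar(x), default, x)
    x[x == "unknownown"] <- "unknown"
    bad <- !x %in% allowed
    if (any(bad)) {
      warning(
        "non-canonical value(s) coerced to '", default, "': ",
        paste(unique(x[bad]), collapse = ", ")
      )
      x[bad] <- default
    }
    x
  }
  num_or_na <- function(x, what) {
    out <- suppressWarnings(as.numeric(gsub(",", "", x)))
    bad <- !is.na(x) & nzchar(ifelse(is.na(x), "", x)) & is.na(out)
    if (any(bad)) {
      warning(
        "unparseable ", what, " in row(s) ", paste(which(bad), collapse = ", "),
        "; trisomy interval left absent"
      )
    }
    out
  }

  out <- tibble::tibble(
    case_id = raw$case_id,
    karyotype_text = raw$karyotype_text,
    sex = norm_token(raw$sex, c("male", "female", "unknown")),
    clinical_status = norm_token(raw$clinical_status, c("normal", "abnormal", "unknown")),
    shapes = split_multi(raw$shapes),
    mosaic = !is.na(raw$mosaic) & toupper(raw$mosaic) == "TRUE",
    clone_counts = ifelse(is.na(raw$clone_counts), "", raw$clone_counts),
    inheritance = norm_token(
      raw$inheritance, c("maternal", "paternal", "de novo", "unknown")
    ),
    groups = split_multi(raw$groups),
    interval_chrom = raw$interval_chrom,
    interval_start = num_or_na(raw$interval_start, "interval_start"),
    interval_end = num_or_na(raw$interval_end, "interval_end"),
    build = raw$build,
    modalities = split_multi(raw$modalities),
    phenotype_terms = split_multi(raw$phenotype_terms),
    arm_class = raw$arm_class,
    source_table = raw$source_table
  )
  bad_groups <- setdiff(unique(unlist(out$groups)), group_vocabulary)
  if (length(bad_groups) > 0) {
    stop(
      "group label(s) outside the closed vocabulary: ",
      paste(bad_groups, collapse = ", "),
      call. = FALSE
    )
  }
  has_iv <- !is.na(out$interval_start) & !is.na(out$interval_end)
  if (any(has_iv)) {
    validate_intervals(tibble::tibble(
      chrom = out$interval_chrom[has_iv], start = out$interval_start[has_iv],
      end = out$interval_end[has_iv], build = out$build[has_iv]
    ))
  }
  normal_with_pheno <- out$clinical_status == "normal" &
    lengths(out$phenotype_terms) > 0
  if (any(normal_with_pheno)) {
    stop(
      "clinically normal case(s) carry phenotype terms: ",
      paste(out$case_id[normal_with_pheno], collapse = ", "),
      call. = FALSE
    )
  }
  out
}

#' Write a cohort table
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x))` is the
#' identity field-for-field.
#'
#' @param cohort Cohort tibble.
#' @param path Output path.
#' @param dialect `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, dialect = c("tsv", "json")) {
  dialect <- match.arg(dialect)
  flat <- tibble::tibble(
    case_id = cohort$case_id,
    karyotype_text = cohort$karyotype_text,
    sex = cohort$sex,
    clinical_status = cohort$clinical_status,
    shapes = join_multi(cohort$shapes),
    mosaic = ifelse(cohort$mosaic, "TRUE", "FALSE"),
    clone_counts = cohort$clone_counts,
    inheritance = cohort$inheritance,
    groups = join_multi(cohort$groups),
    interval_chrom = cohort$interval_chrom,
    interval_start = ifelse(
      is.na(cohort$interval_start), "",
      format(cohort$interval_start, scientific = FALSE, trim = TRUE)
    ),
    interval_end = ifelse(
      is.na(cohort$interval_end), "",
      format(cohort$interval_end, scientific = FALSE, trim = TRUE)
    ),
    build = cohort$build,
    modalities = join_multi(cohort$modalities),
    phenotype_terms = join_multi(cohort$phenotype_terms),
    arm_class = cohort$arm_class,
    source_table = cohort$source_table
  )
  if (dialect == "tsv") {
    readr::write_tsv(flat, path, na = "", progress = FALSE)
  } else {
    jsonlite::write_json(flat, path, na = "null", auto_unbox = FALSE)
  }
  invisible(path)
}

#' Load a packaged case table or the evidence fixture
#'
#' The package ships transcriptions of the published case tables:
#' `table1` (57 sSMC(11) carriers), `table2` (8 sSMC-like pericentric
#' duplication cases A-H), `table3` (the 5 informative clinically normal
#' cases whose evidence bounds the triplo-insensitive span), `table4`
#' (the 5 informative clinically abnormal cases bounding the sensitive
#' borders), `table5` (the 9 cases with sign-level clinical data), and
#' `evidence` (population-CNV and pathogenic-report records: two benign
#' gains with outer boundaries 47,675,469 / 60,516,539 and two pathogenic
#' flanks at 45,048,321 / 61,479,322; the benign/pathogenic interval
#' bodies are synthesized around the published boundary coordinates and
#' flagged `synthetic_interval`).
#'
#' @param name One of `"table1"`, `"table2"`, `"table3"`, `"table4"`,
#'   `"table5"`, `"evidence"`.
#' @return A cohort tibble, or for `"evidence"` an evidence tibble
#'   (`record_id`, `classification`, `chrom`, `start`, `end`, `build`,
#'   `flank_only`, `synthetic_interval`).
#' @examples
#' nrow(load_packaged_cohort("table1")) # 57
#' @export
load_packaged_cohort <- function(name) {
  options_ <- c("table1", "table2", "table3", "table4", "table5", "evidence")
  if (length(name) != 1 || !name %in% options_) {
    stop(
      "unknown fixture '", paste(name, collapse = ","), "'; available: ",
      paste(options_, collapse = ", "),
      call. = FALSE
    )
  }
  if (name == "evidence") {
    path <- system.file("extdata", "evidence_grch37.tsv", package = "ssmc11")
    ev <- readr::read_tsv(path, col_types = "cccddcll", progress = FALSE)
    validate_intervals(ev)
    return(ev)
  }
  read_cohort(system.file("extdata", paste0(name, ".tsv"), package = "ssmc11"))
}
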