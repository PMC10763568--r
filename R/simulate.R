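#' Configuration for a synthetic sSMC cohort
#'
#' Defines the generative model: markers arise at the chromosome 11
#' centromere and reach into each arm by an exponentially distributed
#' extent (truncated at the arm ends); a hidden triplo-insensitive span
#' surrounds the anchor and hidden sensitive loci lie strictly outside
#' it; a case covering at least one sensitive locus becomes clinically
#' abnormal with probability `penetrance`; statuses are flipped with
#' probability `misclassification_rate`; a fraction of cases is made
#' uninformative (unknown status or an exclusion label). All stochastic
#' draws flow from one seeded generator, so identical seeds give
#' identical cohorts.
#'
#' @param seed Integer seed.
#' @param n_cases Number of cases.
#' @param anchor Centromere anchor interval (default: chr11 acen bands,
#'   51.6-55.7 Mb, GRCh37).
#' @param true_insensitive Hidden insensitive span; must contain the
#'   anchor (default 47,675,469-60,516,539, mimicking pericentric
#'   chromosome 11).
#' @param sensitive_loci_p,sensitive_loci_q Hidden sensitive locus
#'   positions, strictly below / above the insensitive span.
#' @param extent_scale Exponential scale (bp) of the per-arm reach;
#'   default 5 Mb.
#' @param penetrance P(abnormal | covers a sensitive locus).
#' @param misclassification_rate P(status flipped).
#' @param frac_uninformative Fraction of cases given unknown status or an
#'   exclusion label.
#' @param mosaic_beta Two shape parameters of the Beta distribution of
#'   the marker cell fraction.
#' @param chrom_length Chromosome length (bp).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_cases = 100L,
                       anchor = genomic_interval("chr11", 51600000, 55700000),
                       true_insensitive = genomic_interval("chr11", 47675469, 60516539),
                       sensitive_loci_p = c(45048321, 40000000),
                       sensitive_loci_q = c(61479322, 70000000),
                       extent_scale = 5e6,
                       penetrance = 0.9,
                       misclassification_rate = 0.02,
                       frac_uninformative = 0.39,
                       mosaic_beta = c(2, 2),
                       chrom_length = 135006516) {
  fail <- function(field, why) {
    stop("invalid sim_config field '", field, "': ", why, call. = FALSE)
  }
  if (!is.numeric(seed) || length(seed) != 1) fail("seed", "must be one integer")
  if (!is.numeric(n_cases) || n_cases < 1) fail("n_cases", "must be >= 1")
  validate_intervals(anchor)
  validate_intervals(true_insensitive)
  if (true_insensitive$start > anchor$start || true_insensitive$end < anchor$end) {
    fail("true_insensitive", "must contain the anchor")
  }
  if (any(sensitive_loci_p >= true_insensitive$start)) {
    fail("sensitive_loci_p", "must lie strictly below the insensitive span")
  }
  if (any(sensitive_loci_q <= true_insensitive$end)) {
    fail("sensitive_loci_q", "must lie strictly above the insensitive span")
  }
  for (p in c("penetrance", "misclassification_rate", "frac_uninformative")) {
    v <- get(p)
    if (!is.numeric(v) || v < 0 || v > 1) fail(p, "must be a probability in [0,1]")
  }
  if (extent_scale <= 0) fail("extent_scale", "must be positive")
  structure(
    list(
      seed = as.integer(seed), n_cases = as.integer(n_cases),
      anchor = anchor, true_insensitive = true_insensitive,
      sensitive_loci_p = sort(sensitive_loci_p, decreasing = TRUE),
      sensitive_loci_q = sort(sensitive_loci_q),
      extent_scale = extent_scale, penetrance = penetrance,
      misclassification_rate = misclassification_rate,
      frac_uninformative = frac_uninformative,
      mosaic_beta = mosaic_beta, chrom_length = chrom_length
    ),
    class = "sim_config"
  )
}

#' Generate a synthetic sSMC cohort with known ground truth
#'
#' Each case's trisomic interval starts at the anchor and reaches
#' p_extent / q_extent (exponential, truncated at the chromosome ends)
#' into the arms; status follows the two-zone rule plus penetrance and
#' misclassification; a fraction of cases is rendered uninformative.
#' Cases are emitted in the cohort table schema with syntactically valid
#' karyotype strings, so generated cohorts round-trip through
#' [write_cohort()]/[read_cohort()] and [parse_karyotype()].
#'
#' @param config A `sim_config`.
#' @return A list: `cohort` (cohort tibble), `truth` (per-case latent
#'   flags: `covers_sensitive`, `flipped`, `excluded_reason`, plus the
#'   config echo as an attribute), `evidence` (synthetic population
#'   records derived from the truth: benign gains inside the insensitive
#'   span, one pathogenic record per arm whose pericentric-facing
#'   boundary sits at the innermost sensitive locus).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_cases
  anchor <- config$anchor
  ti <- config$true_insensitive

  p_ext <- pmin(stats::rexp(n, 1 / config$extent_scale), anchor$start - 1)
  q_ext <- pmin(stats::rexp(n, 1 / config$extent_scale),
    config$chrom_length - anchor$end
  )
  start <- round(anchor$start - p_ext)
  end <- round(anchor$end + q_ext)

  covers <- vapply(seq_len(n), function(i) {
    any(config$sensitive_loci_p >= start[i] & config$sensitive_loci_p <= end[i]) ||
      any(config$sensitive_loci_q >= start[i] & config$sensitive_loci_q <= end[i])
  }, TRUE)
  status <- ifelse(
    covers & stats::runif(n) < config$penetrance, "abnormal", "normal"
  )
  flipped <- stats::runif(n) < config$misclassification_rate
  status[flipped] <- ifelse(status[flipped] == "normal", "abnormal", "normal")

  uninformative <- stats::runif(n) < config$frac_uninformative
  excl_pool <- c(
    "complex", "discontinuous", "multiple-sSMC", "McClintock",
    "pseudo-McClintock"
  )
  excluded_reason <- rep(NA_character_, n)
  groups <- vector("list", n)
  for (i in which(uninformative)) {
    if (stats::runif(1) < 0.5) {
      status[i] <- "unknown"
      excluded_reason[i] <- "status-unknown"
    } else {
      g <- sample(excl_pool, 1)
      groups[[i]] <- g
      excluded_reason[i] <- g
    }
  }
  groups[vapply(groups, is.null, TRUE)] <- list(character(0))

  mos_frac <- stats::rbeta(n, config$mosaic_beta[1], config$mosaic_beta[2])
  mosaic <- mos_frac < 0.995
  sexes <- sample(c("male", "female"), n, replace = TRUE)
  sex_tok <- ifelse(sexes == "male", "XY", "XX")
  shape <- sample(c("min", "r"), n, replace = TRUE, prob = c(0.52, 0.48))
  cells <- 30L
  k <- pmax(1L, pmin(cells - 1L, round(mos_frac * cells)))

  bands <- load_cytobands()
  kt <- vapply(seq_len(n), function(i) {
    span <- sprintf(
      "(:%s→%s:)",
      point_to_band(start[i], bands), point_to_band(end[i], bands)
    )
    arr <- sprintf(
      ".arr[hg19] 11(%s_%s)x3",
      format(start[i], big.mark = ",", scientific = FALSE),
      format(end[i], big.mark = ",", scientific = FALSE)
    )
    if (mosaic[i]) {
      sprintf(
        "mos 47,%s,+mar[%d]/46,%s[%d].ish %s(11)%s%s",
        sex_tok[i], k[i], sex_tok[i], cells - k[i], shape[i], span, arr
      )
    } else {
      sprintf(
        "47,%s,+mar[100%%].ish %s(11)%s%s",
        sex_tok[i], shape[i], span, arr
      )
    }
  }, "")

  phenos <- rep(list(character(0)), n)
  cohort <- tibble::tibble(
    case_id = sprintf("S%03d", seq_len(n)),
    karyotype_text = kt,
    sex = sexes,
    clinical_status = status,
    shapes = as.list(shape),
    mosaic = mosaic,
    clone_counts = ifelse(
      mosaic, sprintf("%d;%d", k, cells - k), "100%"
    ),
    inheritance = "unknown",
    groups = groups,
    interval_chrom = anchor$chrom,
    interval_start = start,
    interval_end = end,
    build = "GRCh37",
    modalities = list(c("banding", "ish", "aCGH")),
    phenotype_terms = phenos,
    arm_class = NA_character_,
    source_table = "synthetic"
  )

  truth <- tibble::tibble(
    case_id = cohort$case_id,
    true_start = start, true_end = end,
    covers_sensitive = covers, flipped = flipped,
    excluded_reason = excluded_reason
  )
  attr(truth, "config") <- config

  locus_p <- max(config$sensitive_loci_p)
  locus_q <- min(config$sensitive_loci_q)
  evidence <- tibble::tibble(
    record_id = c("sim-benign-p", "sim-benign-q", "sim-path-p", "sim-path-q"),
    classification = c("benign", "benign", "pathogenic", "pathogenic"),
    chrom = anchor$chrom,
    start = c(
      round(stats::runif(1, ti$start, anchor$start)), anchor$start,
      locus_p - 1e6, locus_q
    ),
    end = c(
      anchor$end, round(stats::runif(1, anchor$end, ti$end)),
      locus_p, locus_q + 1e6
    ),
    build = "GRCh37",
    flank_only = c(FALSE, FALSE, TRUE, TRUE),
    synthetic_interval = TRUE
  )

  list(cohort = cohort, truth = truth, evidence = evidence, config = config)
}

#' Run the inference on a synthetic cohort and score recovery
#'
#' Generates a cohort, runs informative-case filtering, span inference,
#' benign refinement and window computation against the generator's own
#' synthetic population evidence, and scores the result against the
#' hidden truth: whether the inferred insensitive span excludes every
#' sensitive locus, whether each arm's window contains the innermost
#' sensitive locus, the window widths, and any span-contamination events
#' (a normal-labelled case covering a sensitive locus).
#'
#' @param config A `sim_config`.
#' @return A `recovery_report` list: `map` (the inferred `dosage_map`),
#'   one-row `scores` tibble, and `contamination` (case ids).
#' @export
recovery_experiment <- function(config) {
  sim <- simulate_cohort(config)
  parts <- filter_informative(sim$cohort)
  anchor <- config$anchor
  map <- tryCatch(
    {
      span <- insensitive_span(parts$normals, anchor)
      refined <- refine_with_population(span, sim$evidence)
      win <- sensitive_windows(refined, parts$abnormals, sim$evidence, anchor,
        unrefined = span
      )
      list(span = span, refined = refined, win = win)
    },
    error = function(e) NULL
  )
  if (is.null(map)) {
    return(structure(
      list(map = NULL, scores = tibble::tibble(inference_failed = TRUE),
        contamination = character(0)
      ),
      class = "recovery_report"
    ))
  }
  loci <- c(config$sensitive_loci_p, config$sensitive_loci_q)
  locus_p <- max(config$sensitive_loci_p)
  locus_q <- min(config$sensitive_loci_q)
  refined <- map$refined
  win <- map$win
  in_win <- function(w, pos) {
    !anyNA(c(w$start, w$end)) && pos >= w$start && pos <= w$end
  }
  contamination <- sim$cohort$case_id[
    sim$cohort$clinical_status == "normal" & sim$truth$covers_sensitive
  ]
  scores <- tibble::tibble(
    n_cases = config$n_cases,
    n_normals = nrow(parts$normals),
    n_abnormals = nrow(parts$abnormals),
    span_excludes_loci = !any(loci >= refined$start & loci <= refined$end),
    p_window_contains_locus = in_win(win$p_window, locus_p),
    q_window_contains_locus = in_win(win$q_window, locus_q),
    p_window_width = win$p_window$end - win$p_window$start,
    q_window_width = win$q_window$end - win$q_window$start,
    n_contamination = length(contamination)
  )
  structure(
    list(
      map = c(list(insensitive_span = map$span, refined_span = refined), win),
      scores = scores, contamination = contamination
    ),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Synthetic recovery report\n")
  print(x$scores)
  invisible(x)
}
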