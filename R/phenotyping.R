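# Applying a phecode map to patient billing events and assembling
# case/control/excluded cohorts per phecode. An "instance" throughout is a
# distinct (patient, date, code) triple, so same-day duplicate billing never
# inflates counts.

#' Map patient billing events to phecode assignments
#'
#' Every event whose (vocabulary, code) is in the map yields one assignment
#' per mapped phecode; events whose codes are not in the map are tallied into
#' an unmapped report with instance and unique-patient counts. Instances are
#' conserved: mapped + unmapped = total.
#'
#' @param events Tibble with columns `patient_id`, `date` (Date or
#'   ISO-8601 string), `vocabulary`, `code`. Codes are assumed canonical
#'   (see [canonicalize_code()]).
#' @param map A `phecode_map` (or several row-bound maps of different
#'   vocabularies).
#' @return An object of class `mapped_events`: a list with
#'   \describe{
#'     \item{assignments}{tibble `patient_id`, `phecode`, `date` (distinct).}
#'     \item{unmapped}{tibble `vocabulary`, `code`, `n_instances`,
#'       `n_patients`, sorted by `n_patients` descending.}
#'     \item{n_instances, n_instances_mapped}{instance-accounting totals.}
#'   }
#' @export
map_events <- function(events, map) {
  events <- as_tibble(events)
  need <- c("patient_id", "date", "vocabulary", "code")
  missing <- setdiff(need, names(events))
  if (length(missing) > 0) {
    stop(sprintf("events missing column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  bad <- which(!events$vocabulary %in% phemap_vocabularies)
  if (length(bad) > 0) {
    stop(sprintf("unknown vocabulary '%s' in events row %d",
                 events$vocabulary[bad[1]], bad[1]), call. = FALSE)
  }
  events$date <- as.Date(events$date)
  if (anyNA(events$date)) stop("events contain unparseable dates", call. = FALSE)

  instances <- dplyr::distinct(events, .data$patient_id, .data$date,
                               .data$vocabulary, .data$code)
  map_tbl <- as_tibble(map) |>
    dplyr::distinct(.data$source_vocab, .data$source_code, .data$phecode)

  joined <- dplyr::inner_join(
    instances, map_tbl,
    by = c(vocabulary = "source_vocab", code = "source_code"),
    relationship = "many-to-many"
  )
  assignments <- dplyr::distinct(joined, .data$patient_id, .data$phecode,
                                 .data$date)

  mapped_inst <- dplyr::semi_join(
    instances, map_tbl,
    by = c(vocabulary = "source_vocab", code = "source_code")
  )
  unmapped_inst <- dplyr::anti_join(
    instances, map_tbl,
    by = c(vocabulary = "source_vocab", code = "source_code")
  )
  unmapped <- unmapped_inst |>
    dplyr::group_by(.data$vocabulary, .data$code) |>
    dplyr::summarise(n_instances = dplyr::n(),
                     n_patients = dplyr::n_distinct(.data$patient_id),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_patients), .data$code)

  structure(
    list(assignments = assignments,
         unmapped = unmapped,
         n_instances = nrow(instances),
         n_instances_mapped = nrow(mapped_inst)),
    class = "mapped_events"
  )
}

#' @export
print.mapped_events <- function(x, ...) {
  cat("<mapped_events>\n")
  cat(sprintf("  instances: %d total, %d mapped (%.2f%%)\n",
              x$n_instances, x$n_instances_mapped,
              if (x$n_instances > 0) 100 * x$n_instances_mapped / x$n_instances else 0))
  cat(sprintf("  assignments: %d rows, %d patients, %d phecodes\n",
              nrow(x$assignments), dplyr::n_distinct(x$assignments$patient_id),
              dplyr::n_distinct(x$assignments$phecode)))
  cat(sprintf("  unmapped codes: %d\n", nrow(x$unmapped)))
  invisible(x)
}

#' Define a case/control/excluded cohort for one phenotype
#'
#' Cases are patients with at least `min_code_count` distinct dates carrying
#' a phecode equal to or descending from `target_prefix`. Among non-cases,
#' patients carrying any phecode inside an exclusion interval are excluded
#' (the built-in guard against case contamination of controls); everyone
#' else in the population is a control. Case status takes precedence over
#' exclusion, since the exclusion range typically contains the target
#' itself. The three sets always partition the population.
#'
#' @param assignments Assignment tibble (`patient_id`, `phecode`, `date`),
#'   e.g. `map_events(...)$assignments`.
#' @param target_prefix Target phecode family root, e.g. `"250.2"` for
#'   phecodes 250.2 and all its descendants.
#' @param exclusions Exclusion intervals: a tibble with columns `lo`, `hi`,
#'   or a span string like `"249-250.99"`, or `NULL` for none.
#' @param population Character vector of all patient ids in the study
#'   population (must cover the patients in `assignments`).
#' @param min_code_count Minimum distinct event dates to qualify as a case
#'   (default 1).
#' @return An object of class `case_control_cohort` with elements `phecode`,
#'   `cases`, `controls`, `excluded`, `min_code_count`, `exclusions`.
#' @export
define_cases_controls <- function(assignments, target_prefix, exclusions = NULL,
                                  population = NULL, min_code_count = 1) {
  if (min_code_count < 1) stop("min_code_count must be >= 1", call. = FALSE)
  assert_phecode(target_prefix, "target_prefix")
  if (is.character(exclusions)) exclusions <- parse_ranges(exclusions)
  if (is.null(exclusions)) exclusions <- tibble(lo = numeric(), hi = numeric())
  assignments <- as_tibble(assignments)
  population <- population %||% unique(assignments$patient_id)
  extra <- setdiff(unique(assignments$patient_id), population)
  if (length(extra) > 0) {
    stop("assignments contain patients outside the population", call. = FALSE)
  }

  target_hits <- assignments |>
    dplyr::filter(phecode_matches_prefix(.data$phecode, target_prefix)) |>
    dplyr::distinct(.data$patient_id, .data$date) |>
    dplyr::count(.data$patient_id)
  cases <- target_hits$patient_id[target_hits$n >= min_code_count]

  in_exclusion <- function(phecode) {
    if (nrow(exclusions) == 0) return(rep(FALSE, length(phecode)))
    v <- as.numeric(phecode)
    Reduce(`|`, lapply(seq_len(nrow(exclusions)), function(i) {
      v >= exclusions$lo[i] & v <= exclusions$hi[i]
    }))
  }
  excluded <- assignments |>
    dplyr::filter(in_exclusion(.data$phecode)) |>
    dplyr::pull(.data$patient_id) |>
    unique() |>
    setdiff(cases)
  controls <- setdiff(population, c(cases, excluded))

  cohort <- structure(
    list(phecode = target_prefix,
         cases = sort(cases), controls = sort(controls),
         excluded = sort(excluded),
         min_code_count = min_code_count, exclusions = exclusions),
    class = "case_control_cohort"
  )
  # partition + purity invariants, asserted on every build
  stopifnot(
    length(cohort$cases) + length(cohort$controls) + length(cohort$excluded) ==
      length(population),
    !any(duplicated(c(cohort$cases, cohort$controls, cohort$excluded)))
  )
  control_phe <- assignments$phecode[assignments$patient_id %in% cohort$controls]
  stopifnot(!any(in_exclusion(control_phe)))
  cohort
}

#' @export
print.case_control_cohort <- function(x, ...) {
  cat(sprintf("<case_control_cohort> phecode %s.*\n", x$phecode))
  cat(sprintf("  cases %d | controls %d | excluded %d (min_code_count=%d)\n",
              length(x$cases), length(x$controls), length(x$excluded),
              x$min_code_count))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.case_control_cohort <- function(x, ...) {
  tibble(
    patient_id = c(x$cases, x$controls, x$excluded),
    status = rep(c("case", "control", "excluded"),
                 c(length(x$cases), length(x$controls), length(x$excluded)))
  )
}

#' Build one cohort per phecode for a phenome scan
#'
#' For every phecode observed in the assignments (optionally limited to
#' `phecodes`), builds a [define_cases_controls()] cohort using that
#' phecode's exclusion ranges from the definitions table.
#'
#' @param assignments Assignment tibble (`patient_id`, `phecode`, `date`).
#' @param population Character vector of all patient ids.
#' @param phecode_defs Phecode definitions tibble (`phecode`,
#'   `exclusion_ranges`), e.g. `bundle$phecodes`.
#' @param min_code_count Passed to [define_cases_controls()].
#' @param phecodes Optional subset of phecodes to build.
#' @return Named list of `case_control_cohort` objects.
#' @export
build_cohorts <- function(assignments, population, phecode_defs,
                          min_code_count = 1, phecodes = NULL) {
  phecodes <- phecodes %||% sort(unique(assignments$phecode))
  defs <- as_tibble(phecode_defs)
  out <- lapply(phecodes, function(p) {
    row <- dplyr::filter(defs, .data$phecode == p)
    excl <- if (nrow(row) > 0) parse_ranges(row$exclusion_ranges) else NULL
    define_cases_controls(assignments, p, excl, population, min_code_count)
  })
  names(out) <- phecodes
  out
}
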