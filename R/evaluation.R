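# Coverage accounting (how much of the official terminology and of the codes
# actually used in an EHR the map reaches) and two-window phenotype
# reproducibility across the ICD-9-CM -> ICD-10-CM coding transition.

pct2 <- function(n, d) if (d > 0) round(100 * n / d, 2) else 0

#' Phecode coverage summary for one vocabulary
#'
#' Partitions codes by official-list membership, EHR usage, and map coverage
#' (the three binary axes of the coverage diagram), and tallies instance-level
#' coverage, where an instance is a distinct (patient, date, code) triple.
#' Codes used in the EHR but absent from the official list (local or
#' supplementary codes) form their own partition cells. Percentages are
#' rounded to 2 decimals; with no events the instance percentage is reported
#' as 0 with `degenerate = TRUE`.
#'
#' @param map A `phecode_map`.
#' @param official_codes Official code table for the map's vocabulary: a
#'   tibble with a `code` column (a `vocabulary` column, when present, is
#'   filtered to the map's vocabulary).
#' @param events Patient event tibble (`patient_id`, `date`, `vocabulary`,
#'   `code`); must contain only the map's vocabulary.
#' @return An object of class `coverage_summary`.
#' @export
coverage_summary <- function(map, official_codes, events) {
  vocab <- attr(map, "source_vocab") %||% unique(as_tibble(map)$source_vocab)
  if (length(vocab) != 1) stop("map must cover a single vocabulary", call. = FALSE)
  official_codes <- as_tibble(official_codes)
  if ("vocabulary" %in% names(official_codes)) {
    official_codes <- dplyr::filter(official_codes, .data$vocabulary == vocab)
  }
  events <- as_tibble(events)
  if (nrow(events) > 0 && !all(events$vocabulary == vocab)) {
    stop(sprintf("events contain vocabularies other than the map's (%s)", vocab),
         call. = FALSE)
  }

  official <- unique(official_codes$code)
  mapped <- unique(as_tibble(map)$source_code)
  used <- unique(events$code)

  instances <- dplyr::distinct(events, .data$patient_id, .data$date, .data$code)
  inst_mapped <- sum(instances$code %in% mapped)

  universe <- union(official, used)
  partition <- tibble(code = universe) |>
    dplyr::mutate(official = .data$code %in% official,
                  used = .data$code %in% used,
                  mapped = .data$code %in% mapped) |>
    dplyr::count(.data$official, .data$used, .data$mapped, name = "n_codes")

  unmapped_breakdown <- instances |>
    dplyr::filter(!.data$code %in% mapped) |>
    dplyr::group_by(.data$code) |>
    dplyr::summarise(n_instances = dplyr::n(),
                     n_patients = dplyr::n_distinct(.data$patient_id),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_patients), .data$code)

  structure(
    list(
      vocabulary = vocab,
      official_unique = length(official),
      official_unique_mapped = sum(official %in% mapped),
      official_unique_mapped_pct = pct2(sum(official %in% mapped), length(official)),
      used_unique = length(used),
      used_unique_mapped = sum(used %in% mapped),
      used_unique_mapped_pct = pct2(sum(used %in% mapped), length(used)),
      total_patients = dplyr::n_distinct(events$patient_id),
      total_instances = nrow(instances),
      instances_mapped = inst_mapped,
      instances_mapped_pct = pct2(inst_mapped, nrow(instances)),
      partition = partition,
      unmapped_breakdown = unmapped_breakdown,
      degenerate = nrow(instances) == 0
    ),
    class = "coverage_summary"
  )
}

#' @export
print.coverage_summary <- function(x, ...) {
  cat(sprintf("<coverage_summary> %s\n", x$vocabulary))
  cat(sprintf("  official codes: %d, mapped %d (%.2f%%)\n",
              x$official_unique, x$official_unique_mapped,
              x$official_unique_mapped_pct))
  cat(sprintf("  used codes:     %d, mapped %d (%.2f%%)\n",
              x$used_unique, x$used_unique_mapped, x$used_unique_mapped_pct))
  cat(sprintf("  instances:      %d, mapped %d (%.2f%%)%s\n",
              x$total_instances, x$instances_mapped, x$instances_mapped_pct,
              if (x$degenerate) " [no events]" else ""))
  invisible(x)
}

#' Tidy a coverage summary into a one-row tibble
#' @param x A `coverage_summary`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.coverage_summary <- function(x, ...) {
  tibble(
    vocabulary = x$vocabulary,
    official_unique = x$official_unique,
    official_unique_mapped = x$official_unique_mapped,
    official_unique_mapped_pct = x$official_unique_mapped_pct,
    used_unique = x$used_unique,
    used_unique_mapped = x$used_unique_mapped,
    used_unique_mapped_pct = x$used_unique_mapped_pct,
    total_patients = x$total_patients,
    total_instances = x$total_instances,
    instances_mapped = x$instances_mapped,
    instances_mapped_pct = x$instances_mapped_pct
  )
}

#' Construct an observation window
#'
#' @param start,end Inclusive window bounds (Date or ISO-8601 string), or a
#'   single `"start:end"` string as `start`.
#' @return A list with Date elements `start`, `end`.
#' @export
observation_window <- function(start, end = NULL) {
  if (is.null(end) && is.character(start) && grepl(":", start, fixed = TRUE)) {
    parts <- strsplit(start, ":", fixed = TRUE)[[1]]
    start <- parts[1]
    end <- parts[2]
  }
  start <- as.Date(start)
  end <- as.Date(end)
  if (is.na(start) || is.na(end)) stop("unparseable window dates", call. = FALSE)
  if (start > end) stop("window start is after its end", call. = FALSE)
  structure(list(start = start, end = end), class = "observation_window")
}

in_window <- function(dates, w) dates >= w$start & dates <= w$end

windows_overlap <- function(a, b) a$start <= b$end & b$start <= a$end

#' Two-window phenotype reproducibility
#'
#' The analysis cohort contains every patient with at least one ICD-9-CM
#' event (any code) in window 1 and at least one ICD-10-CM event in window
#' 2. For each target phenotype, cases are counted per window with the
#' window's own map and `min_code_count` distinct dates; the reported
#' fraction is the share of window-1 cases who are also window-2 cases.
#'
#' @param events Patient event tibble spanning both eras.
#' @param map9 `phecode_map` for ICD-9-CM (e.g. [icd9_phecode_map()]).
#' @param map10 `phecode_map` for the window-2 vocabulary (ICD-10-CM).
#' @param w1,w2 Disjoint [observation_window()]s (window 1 before window 2).
#' @param targets Tibble with columns `name`, `prefix` (phecode family root
#'   per phenotype, e.g. `"401"` for hypertension = phecodes 401.*).
#' @param min_code_count Distinct-date threshold applied per window
#'   (default 1).
#' @return A tibble with one row per target: `phenotype`, `prefix`,
#'   `n_cases_w1`, `n_cases_both`, `pct_reproduced` (2 decimals).
#' @export
reproducibility <- function(events, map9, map10, w1, w2, targets,
                            min_code_count = 1) {
  if (!inherits(w1, "observation_window")) w1 <- observation_window(w1)
  if (!inherits(w2, "observation_window")) w2 <- observation_window(w2)
  if (windows_overlap(w1, w2)) stop("observation windows overlap", call. = FALSE)
  targets <- as_tibble(targets)
  stopifnot(all(c("name", "prefix") %in% names(targets)))
  assert_phecode(targets$prefix, "target prefix")

  events <- as_tibble(events)
  events$date <- as.Date(events$date)
  vocab2 <- attr(map10, "source_vocab") %||% unique(as_tibble(map10)$source_vocab)

  e1 <- dplyr::filter(events, .data$vocabulary == "ICD9CM",
                      in_window(.data$date, w1))
  e2 <- dplyr::filter(events, .data$vocabulary == vocab2,
                      in_window(.data$date, w2))
  cohort <- intersect(unique(e1$patient_id), unique(e2$patient_id))

  a1 <- map_events(dplyr::filter(e1, .data$patient_id %in% cohort), map9)$assignments
  a2 <- map_events(dplyr::filter(e2, .data$patient_id %in% cohort), map10)$assignments

  cases_for <- function(assignments, prefix) {
    hits <- assignments |>
      dplyr::filter(phecode_matches_prefix(.data$phecode, prefix)) |>
      dplyr::distinct(.data$patient_id, .data$date) |>
      dplyr::count(.data$patient_id)
    hits$patient_id[hits$n >= min_code_count]
  }

  purrr::map2_dfr(targets$name, targets$prefix, function(nm, prefix) {
    c1 <- cases_for(a1, prefix)
    c2 <- cases_for(a2, prefix)
    both <- intersect(c1, c2)
    tibble(phenotype = nm, prefix = prefix,
           n_cases_w1 = length(c1), n_cases_both = length(both),
           pct_reproduced = pct2(length(both), length(c1)))
  })
}

#' Bar chart of a reproducibility table
#'
#' @param repro A tibble from [reproducibility()].
#' @return A ggplot object: percent of window-1 cases reproduced in window 2
#'   per phenotype.
#' @export
plot_reproducibility <- function(repro) {
  ggplot2::ggplot(repro, ggplot2::aes(x = stats::reorder(.data$phenotype,
                                                         -.data$pct_reproduced),
                                      y = .data$pct_reproduced)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of era-1 cases reproduced in era 2") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}
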