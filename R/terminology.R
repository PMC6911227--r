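#' @importFrom rlang .data %||%
#' @importFrom tibble tibble as_tibble
NULL

# Controlled vocabularies and crosswalk resources recognised throughout the
# package. PHECODE is treated as a vocabulary so crosswalk edges can terminate
# at a phecode like any other hop.
phemap_vocabularies <- c(
  "ICD9CM", "ICD10CM", "ICD10", "SNOMED", "CUI", "OHDSI_CONCEPT", "PHECODE"
)

phemap_resources <- c(
  "STRING_MATCH", "GEMS", "UMLS_CUI", "NLM_MAP", "OHDSI_REL", "ICD9_PHECODE_MAP"
)

#' Canonicalize a diagnosis or concept code
#'
#' Trims whitespace, upper-cases, and for ICD vocabularies converts undotted
#' codes ("E119") to the dotted form ("E11.9"). ICD-10 and ICD-10-CM codes
#' take the dot after the third character; ICD-9-CM numeric and V codes after
#' the third, E codes after the fourth. Canonicalization is idempotent.
#'
#' @param raw Character vector of raw codes.
#' @param vocabulary One of `"ICD9CM"`, `"ICD10CM"`, `"ICD10"`, `"SNOMED"`,
#'   `"CUI"`, `"OHDSI_CONCEPT"`, `"PHECODE"`.
#' @return Character vector of canonical codes.
#' @examples
#' canonicalize_code("e11.9", "ICD10CM")
#' canonicalize_code("E119", "ICD10CM")
#' canonicalize_code("2500", "ICD9CM")
#' @export
canonicalize_code <- function(raw, vocabulary) {
  vocabulary <- match.arg(vocabulary, phemap_vocabularies)
  vapply(raw, canonicalize_one, character(1), vocabulary = vocabulary,
         USE.NAMES = FALSE)
}

canonicalize_one <- function(x, vocabulary) {
  if (is.na(x)) stop("code is NA", call. = FALSE)
  x <- toupper(trimws(x))
  if (!nzchar(x)) stop("code is empty", call. = FALSE)
  if (vocabulary %in% c("ICD10", "ICD10CM")) {
    if (!grepl("^[A-Z][0-9]", x)) {
      stop(sprintf("'%s' is not a valid %s code (letter + digit expected)",
                   x, vocabulary), call. = FALSE)
    }
    if (!grepl(".", x, fixed = TRUE) && nchar(x) > 3) {
      x <- paste0(substr(x, 1, 3), ".", substr(x, 4, nchar(x)))
    }
  } else if (vocabulary == "ICD9CM") {
    if (!grepl(".", x, fixed = TRUE)) {
      if (grepl("^E[0-9]", x)) {
        if (nchar(x) > 4) x <- paste0(substr(x, 1, 4), ".", substr(x, 5, nchar(x)))
      } else if (grepl("^[V0-9]", x)) {
        if (nchar(x) > 3) x <- paste0(substr(x, 1, 3), ".", substr(x, 4, nchar(x)))
      } else {
        stop(sprintf("'%s': dot position ambiguous for ICD9CM", x),
             call. = FALSE)
      }
    }
  }
  x
}

#' Validate phecode strings
#'
#' A phecode is a nonnegative decimal string with at most two fractional
#' digits; leading zeros are significant ("008" and "8" denote different
#' lineages).
#'
#' @param x Character vector.
#' @return Logical vector.
#' @export
phecode_valid <- function(x) {
  !is.na(x) & grepl("^[0-9]+(\\.[0-9]{1,2})?$", x)
}

assert_phecode <- function(x, arg = "phecode") {
  bad <- x[!phecode_valid(x)]
  if (length(bad) > 0) {
    stop(sprintf("invalid %s: %s", arg,
                 paste(utils::head(unique(bad), 5), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

#' Strict ancestor relation on the phecode hierarchy
#'
#' The phecode hierarchy is encoded in the id string: `a` is a strict
#' ancestor of `b` when their integer parts are equal and the digit sequence
#' of `b` (decimal point removed, leading zeros preserved) strictly extends
#' that of `a`. So 401 is an ancestor of 401.1, and 250 of both 250.2 and
#' 250.23, while 41 is unrelated to 411. The relation is a strict partial
#' order (irreflexive, antisymmetric, transitive).
#'
#' @param a,b Character vectors of phecodes (recycled).
#' @return Logical vector.
#' @examples
#' is_strict_ancestor("401", "401.1")
#' is_strict_ancestor("250.2", "250.2")
#' is_strict_ancestor("41", "411")
#' @export
is_strict_ancestor <- function(a, b) {
  assert_phecode(a)
  assert_phecode(b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  int_a <- as.numeric(sub("\\..*$", "", a))
  int_b <- as.numeric(sub("\\..*$", "", b))
  dig_a <- gsub(".", "", a, fixed = TRUE)
  dig_b <- gsub(".", "", b, fixed = TRUE)
  int_a == int_b &
    nchar(dig_b) > nchar(dig_a) &
    substr(dig_b, 1, nchar(dig_a)) == dig_a
}

#' Does a phecode fall inside a numeric exclusion interval?
#'
#' Bounds are inclusive on both ends: phecode 249 is inside 249-250.99, as is
#' 250.1; 251 is not.
#'
#' @param phecode Character vector of phecodes.
#' @param lo,hi Numeric interval bounds, `lo <= hi`.
#' @return Logical vector.
#' @export
phecode_in_range <- function(phecode, lo, hi) {
  assert_phecode(phecode)
  if (any(lo > hi)) stop("interval has lo > hi", call. = FALSE)
  v <- as.numeric(phecode)
  v >= lo & v <= hi
}

#' Prefix (family) membership for case definitions
#'
#' `"401.*"`-style case definitions cover the phecode itself plus all of its
#' hierarchy descendants.
#'
#' @param phecode Character vector of phecodes.
#' @param prefix A single target phecode acting as the family root.
#' @return Logical vector.
#' @export
phecode_matches_prefix <- function(phecode, prefix) {
  stopifnot(length(prefix) == 1)
  assert_phecode(prefix, "prefix")
  phecode == prefix | is_strict_ancestor(prefix, phecode)
}

#' Parse "lo-hi" exclusion-range spans
#'
#' Ranges are written as semicolon-joined spans, e.g. `"249-250.99"` or
#' `"001-009.99;112-112.99"`. An empty string yields zero intervals.
#'
#' @param x Character vector of span strings.
#' @return A tibble with numeric columns `lo` and `hi` (one row per span).
#' @export
parse_ranges <- function(x) {
  x <- x[!is.na(x) & nzchar(trimws(x))]
  if (length(x) == 0) return(tibble(lo = numeric(), hi = numeric()))
  spans <- unlist(strsplit(x, ";", fixed = TRUE))
  spans <- trimws(spans)
  spans <- spans[nzchar(spans)]
  m <- regmatches(spans, regexec("^([0-9]+(?:\\.[0-9]+)?)-([0-9]+(?:\\.[0-9]+)?)$", spans))
  bad <- vapply(m, length, integer(1)) != 3
  if (any(bad)) {
    stop(sprintf("malformed interval span: %s",
                 paste(spans[bad], collapse = ", ")), call. = FALSE)
  }
  out <- tibble(
    lo = as.numeric(vapply(m, `[`, character(1), 2)),
    hi = as.numeric(vapply(m, `[`, character(1), 3))
  )
  if (any(out$lo > out$hi)) stop("interval has lo > hi", call. = FALSE)
  out
}

format_ranges <- function(ranges) {
  if (nrow(ranges) == 0) return("")
  paste(sprintf("%s-%s", format(ranges$lo, trim = TRUE, scientific = FALSE),
                format(ranges$hi, trim = TRUE, scientific = FALSE)),
        collapse = ";")
}

#' Assemble a terminology bundle
#'
#' A bundle holds the three tables the mapping engine consumes: per-vocabulary
#' code lists, per-resource crosswalk edges, and phecode definitions with
#' exclusion ranges.
#'
#' @param codes Tibble with columns `vocabulary`, `code`, `description`.
#' @param edges Tibble with columns `resource`, `source_vocab`, `source_code`,
#'   `target_vocab`, `target_code`, `approximate_flag` (0/1, meaningful for
#'   GEMS only).
#' @param phecodes Tibble with columns `phecode`, `description`,
#'   `exclusion_ranges` (semicolon-joined "lo-hi" spans, possibly empty).
#' @param validate Run [validate_bundle()] before returning (default `TRUE`).
#' @return An object of class `terminology_bundle`.
#' @export
new_bundle <- function(codes, edges, phecodes, validate = TRUE) {
  codes <- as_tibble(codes)
  edges <- as_tibble(edges)
  phecodes <- as_tibble(phecodes)
  if (!"approximate_flag" %in% names(edges)) edges$approximate_flag <- 0L
  edges$approximate_flag <- as.integer(edges$approximate_flag)
  bundle <- structure(
    list(codes = codes, edges = edges, phecodes = phecodes),
    class = "terminology_bundle"
  )
  if (validate) bundle <- validate_bundle(bundle)
  bundle
}

#' Validate a terminology bundle
#'
#' Enforces the structural invariants: known vocabularies/resources, no
#' duplicate (source, target, resource) edges, no duplicate phecode
#' definitions, parseable exclusion ranges, and cross-vocabulary edges except
#' for OHDSI internal relationship hops. Edges whose endpoints are absent
#' from the code tables are not an error; they are counted and attached as
#' the `dangling_edges` attribute.
#'
#' @param bundle A `terminology_bundle`.
#' @return The bundle, invisibly augmented with a `dangling_edges` attribute.
#' @export
validate_bundle <- function(bundle) {
  codes <- bundle$codes
  edges <- bundle$edges
  phecodes <- bundle$phecodes

  need <- function(df, cols, what) {
    missing <- setdiff(cols, names(df))
    if (length(missing) > 0) {
      stop(sprintf("%s table missing column(s): %s", what,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  need(codes, c("vocabulary", "code", "description"), "codes")
  need(edges, c("resource", "source_vocab", "source_code",
                "target_vocab", "target_code"), "edges")
  need(phecodes, c("phecode", "description", "exclusion_ranges"), "phecodes")

  bad_vocab <- setdiff(unique(c(codes$vocabulary, edges$source_vocab,
                                edges$target_vocab)), phemap_vocabularies)
  if (length(bad_vocab) > 0) {
    stop(sprintf("unknown vocabulary: %s", paste(bad_vocab, collapse = ", ")),
         call. = FALSE)
  }
  bad_res <- setdiff(unique(edges$resource), phemap_resources)
  if (length(bad_res) > 0) {
    stop(sprintf("unknown resource: %s", paste(bad_res, collapse = ", ")),
         call. = FALSE)
  }

  dup <- edges |>
    dplyr::count(.data$resource, .data$source_vocab, .data$source_code,
                 .data$target_vocab, .data$target_code) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop(sprintf("duplicate edge(s), e.g. %s %s:%s -> %s:%s",
                 dup$resource[1], dup$source_vocab[1], dup$source_code[1],
                 dup$target_vocab[1], dup$target_code[1]), call. = FALSE)
  }

  same_vocab <- edges$source_vocab == edges$target_vocab &
    edges$resource != "OHDSI_REL"
  if (any(same_vocab)) {
    stop("edge connects a vocabulary to itself outside OHDSI_REL",
         call. = FALSE)
  }

  if (anyDuplicated(phecodes$phecode)) {
    stop(sprintf("duplicate phecode definition: %s",
                 phecodes$phecode[duplicated(phecodes$phecode)][1]),
         call. = FALSE)
  }
  assert_phecode(phecodes$phecode)
  # malformed ranges raise here, naming the offending span
  parse_ranges(phecodes$exclusion_ranges)

  known <- dplyr::bind_rows(
    dplyr::select(codes, "vocabulary", "code"),
    tibble(vocabulary = "PHECODE", code = phecodes$phecode)
  )
  endpoint_known <- function(vocab, code) {
    paste(vocab, code) %in% paste(known$vocabulary, known$code)
  }
  dangling <- edges |>
    dplyr::filter(!endpoint_known(.data$source_vocab, .data$source_code) |
                    !endpoint_known(.data$target_vocab, .data$target_code))
  if (nrow(dangling) > 0) {
    message(sprintf("bundle has %d dangling edge(s) (endpoint absent from code tables)",
                    nrow(dangling)))
  }
  attr(bundle, "dangling_edges") <- dangling
  bundle
}

#' @export
print.terminology_bundle <- function(x, ...) {
  cat("<terminology_bundle>\n")
  ct <- dplyr::count(x$codes, .data$vocabulary)
  for (i in seq_len(nrow(ct))) {
    cat(sprintf("  codes %-14s %d\n", ct$vocabulary[i], ct$n[i]))
  }
  et <- dplyr::count(x$edges, .data$resource)
  for (i in seq_len(nrow(et))) {
    cat(sprintf("  edges %-14s %d\n", et$resource[i], et$n[i]))
  }
  cat(sprintf("  phecodes              %d\n", nrow(x$phecodes)))
  dang <- attr(x, "dangling_edges")
  if (!is.null(dang) && nrow(dang) > 0) {
    cat(sprintf("  dangling edges        %d\n", nrow(dang)))
  }
  invisible(x)
}

bundle_edges <- function(bundle, resource) {
  dplyr::filter(bundle$edges, .data$resource == !!resource)
}

bundle_codes <- function(bundle, vocabulary) {
  dplyr::filter(bundle$codes, .data$vocabulary == !!vocabulary)
}

#' Read a terminology bundle from a directory of CSV files
#'
#' Expects `codes_<vocab>.csv` (code, description), `edges_<resource>.csv`
#' (source_vocab, source_code, target_vocab, target_code, approximate_flag)
#' and `phecodes.csv` (phecode, description, exclusion_ranges). Files for
#' vocabularies or resources with no rows may simply be absent. All files
#' are comma-delimited UTF-8 with a header row.
#'
#' @param dir Directory containing the bundle files.
#' @return A validated `terminology_bundle`.
#' @export
load_bundle <- function(dir) {
  if (!dir.exists(dir)) stop(sprintf("bundle directory not found: %s", dir),
                             call. = FALSE)
  read_one <- function(path, required_cols) {
    df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
    missing <- setdiff(required_cols, names(df))
    if (length(missing) > 0) {
      stop(sprintf("%s: missing column(s) %s", basename(path),
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    df
  }

  code_files <- list.files(dir, pattern = "^codes_.*\\.csv$", full.names = TRUE)
  codes <- purrr::map_dfr(code_files, function(p) {
    vocab <- toupper(sub("^codes_(.*)\\.csv$", "\\1", basename(p)))
    df <- read_one(p, c("code", "description"))
    tibble(vocabulary = vocab, code = df$code,
           description = df$description %||% "")
  })
  if (nrow(codes) == 0) {
    codes <- tibble(vocabulary = character(), code = character(),
                    description = character())
  }
  codes$description[is.na(codes$description)] <- ""

  edge_files <- list.files(dir, pattern = "^edges_.*\\.csv$", full.names = TRUE)
  edges <- purrr::map_dfr(edge_files, function(p) {
    resource <- toupper(sub("^edges_(.*)\\.csv$", "\\1", basename(p)))
    df <- read_one(p, c("source_vocab", "source_code", "target_vocab", "target_code"))
    tibble(resource = resource,
           source_vocab = df$source_vocab, source_code = df$source_code,
           target_vocab = df$target_vocab, target_code = df$target_code,
           approximate_flag = as.integer(df$approximate_flag %||% 0L))
  })
  if (nrow(edges) == 0) {
    edges <- tibble(resource = character(), source_vocab = character(),
                    source_code = character(), target_vocab = character(),
                    target_code = character(), approximate_flag = integer())
  }
  edges$approximate_flag[is.na(edges$approximate_flag)] <- 0L

  phe_path <- file.path(dir, "phecodes.csv")
  if (!file.exists(phe_path)) {
    stop(sprintf("phecodes.csv not found in %s", dir), call. = FALSE)
  }
  phecodes <- read_one(phe_path, c("phecode", "description"))
  phecodes$exclusion_ranges <- phecodes$exclusion_ranges %||% ""
  phecodes$exclusion_ranges[is.na(phecodes$exclusion_ranges)] <- ""
  phecodes$description[is.na(phecodes$description)] <- ""
  phecodes <- dplyr::select(phecodes, "phecode", "description", "exclusion_ranges")

  new_bundle(codes, edges, phecodes)
}

#' Write a terminology bundle to a directory of CSV files
#'
#' Inverse of [load_bundle()]: a write/read round trip preserves bundle
#' content exactly. Rows are sorted so output is byte-reproducible.
#'
#' @param bundle A `terminology_bundle`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (vocab in sort(unique(bundle$codes$vocabulary))) {
    df <- bundle_codes(bundle, vocab) |>
      dplyr::arrange(.data$code) |>
      dplyr::select("code", "description")
    readr::write_csv(df, file.path(dir, sprintf("codes_%s.csv", tolower(vocab))))
  }
  for (res in sort(unique(bundle$edges$resource))) {
    df <- bundle_edges(bundle, res) |>
      dplyr::arrange(.data$source_vocab, .data$source_code,
                     .data$target_vocab, .data$target_code) |>
      dplyr::select("source_vocab", "source_code", "target_vocab",
                    "target_code", "approximate_flag")
    readr::write_csv(df, file.path(dir, sprintf("edges_%s.csv", tolower(res))))
  }
  phe <- dplyr::arrange(bundle$phecodes, .data$phecode)
  readr::write_csv(phe, file.path(dir, "phecodes.csv"))
  invisible(dir)
}

#' Exclusion intervals for a phecode definition
#'
#' @param bundle A `terminology_bundle`.
#' @param phecode A single phecode id present in the definitions table.
#' @return Tibble with columns `lo`, `hi` (zero rows when the phecode has no
#'   exclusion ranges).
#' @export
exclusion_intervals <- function(bundle, phecode) {
  row <- dplyr::filter(bundle$phecodes, .data$phecode == !!phecode)
  if (nrow(row) == 0) {
    stop(sprintf("phecode %s not in definitions", phecode), call. = FALSE)
  }
  parse_ranges(row$exclusion_ranges)
}
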