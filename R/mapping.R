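# Figure-of-merit of this package: the ICD -> phecode crosswalk engine.
# Each path walks a chain of crosswalk edges from a source ICD code to a
# phecode, carrying a human-readable provenance string of the form
#   "ICD10CM:E11.9 -[GEMS]-> ICD9CM:250.0 -[ICD9_PHECODE_MAP]-> PHECODE:250.2"
# which can be replayed against the bundle (see verify_map()).

node_str <- function(vocab, code) paste0(vocab, ":", code)

# A "frontier" is a tibble(source_vocab, source_code, node_vocab, node_code,
# provenance) of partial chains. take_hop() extends every chain by one edge
# of the given resource, dropping chains with no outgoing edge.
path_start <- function(codes_tbl) {
  tibble(
    source_vocab = codes_tbl$vocabulary,
    source_code = codes_tbl$code,
    node_vocab = codes_tbl$vocabulary,
    node_code = codes_tbl$code,
    provenance = node_str(codes_tbl$vocabulary, codes_tbl$code)
  )
}

take_hop <- function(frontier, bundle, resource, from_vocab = NULL,
                     to_vocab = NULL) {
  edges <- bundle_edges(bundle, resource)
  if (!is.null(from_vocab)) {
    edges <- dplyr::filter(edges, .data$source_vocab %in% from_vocab)
  }
  if (!is.null(to_vocab)) {
    edges <- dplyr::filter(edges, .data$target_vocab %in% to_vocab)
  }
  frontier |>
    dplyr::inner_join(edges,
                      by = c(node_vocab = "source_vocab", node_code = "source_code"),
                      relationship = "many-to-many") |>
    dplyr::transmute(
      source_vocab = .data$source_vocab,
      source_code = .data$source_code,
      node_vocab = .data$target_vocab,
      node_code = .data$target_code,
      provenance = paste0(.data$provenance, " -[", resource, "]-> ",
                          node_str(.data$target_vocab, .data$target_code))
    ) |>
    dplyr::distinct()
}

finish_records <- function(frontier, bundle, path_label) {
  done <- take_hop(frontier, bundle, "ICD9_PHECODE_MAP",
                   from_vocab = "ICD9CM", to_vocab = "PHECODE")
  tibble(
    source_vocab = done$source_vocab,
    source_code = done$source_code,
    phecode = done$node_code,
    path_label = path_label,
    provenance = done$provenance
  )
}

empty_records <- function() {
  tibble(source_vocab = character(), source_code = character(),
         phecode = character(), path_label = character(),
         provenance = character())
}

#' Path A: direct description matching
#'
#' Maps an ICD code straight to a phecode when their descriptions are equal
#' after lower-casing and whitespace trimming (case-insensitive exact match;
#' no fuzzy matching). Codes with empty descriptions never match.
#'
#' @param bundle A `terminology_bundle`.
#' @param source_vocab `"ICD10CM"` or `"ICD10"`.
#' @return A tibble of mapping records (`source_vocab`, `source_code`,
#'   `phecode`, `path_label`, `provenance`).
#' @export
direct_string_match <- function(bundle, source_vocab = "ICD10CM") {
  source_vocab <- match.arg(source_vocab, c("ICD10CM", "ICD10"))
  norm <- function(x) stringr::str_squish(tolower(x))
  icd <- bundle_codes(bundle, source_vocab) |>
    dplyr::mutate(key = norm(.data$description)) |>
    dplyr::filter(nzchar(.data$key))
  phe <- bundle$phecodes |>
    dplyr::mutate(key = norm(.data$description)) |>
    dplyr::filter(nzchar(.data$key))
  hits <- dplyr::inner_join(icd, phe, by = "key",
                            relationship = "many-to-many")
  if (nrow(hits) == 0) return(empty_records())
  tibble(
    source_vocab = source_vocab,
    source_code = hits$code,
    phecode = hits$phecode,
    path_label = "A_DIRECT_STRING",
    provenance = paste0(node_str(source_vocab, hits$code),
                        " -[STRING_MATCH]-> ", node_str("PHECODE", hits$phecode))
  ) |> dplyr::distinct()
}

#' Path B: GEMS crosswalk (ICD-10-CM only)
#'
#' Follows CMS General Equivalence Mappings from ICD-10-CM to ICD-9-CM and
#' then the ICD-9-CM phecode map. Both equivalent (flag 0) and approximate
#' (flag 1) GEMS rows are used. No GEMS exists for WHO ICD-10, so this path
#' never applies to that vocabulary.
#'
#' @param bundle A `terminology_bundle`.
#' @return A tibble of mapping records with path label `B_GEMS`.
#' @export
gems_path <- function(bundle) {
  frontier <- path_start(bundle_codes(bundle, "ICD10CM"))
  frontier <- take_hop(frontier, bundle, "GEMS",
                       from_vocab = "ICD10CM", to_vocab = "ICD9CM")
  finish_records(frontier, bundle, "B_GEMS")
}

#' Paths C-F: concept-equivalence chains
#'
#' Walks ICD -> CUI -> SNOMED CT -> ICD-9-CM -> phecode, where the
#' SNOMED -> ICD-9-CM leg ("bridge") is one of:
#' \describe{
#'   \item{`NLM_MAP`}{NLM SNOMED-to-ICD-9-CM rule maps (path D). By default
#'     SNOMED codes with more than one NLM target are skipped, keeping only
#'     the one-to-one and many-to-one rows; set
#'     `nlm_exclude_one_to_many = FALSE` to keep all rows.}
#'   \item{`OHDSI_REL`}{OHDSI concept relationships (path E), following
#'     internal concept-id hops up to `max_ohdsi_hops` with cycle detection.}
#'   \item{`UMLS_CUI`}{UMLS CUI equivalences, SNOMED -> CUI -> ICD-9-CM
#'     (path F).}
#' }
#' `bridge = "CUI_DIRECT"` instead takes the short chain
#' ICD -> CUI -> ICD-9-CM without a SNOMED hop (path C).
#'
#' @param bundle A `terminology_bundle`.
#' @param source_vocab `"ICD10CM"` or `"ICD10"`.
#' @param bridge One of `"NLM_MAP"`, `"OHDSI_REL"`, `"UMLS_CUI"`,
#'   `"CUI_DIRECT"`.
#' @param nlm_exclude_one_to_many Drop SNOMED codes with multiple NLM
#'   targets (default `TRUE`).
#' @param max_ohdsi_hops Hop limit for OHDSI internal relationship traversal
#'   (default 5).
#' @return A tibble of mapping records labelled C/D/E/F by bridge.
#' @export
concept_path <- function(bundle, source_vocab = "ICD10CM",
                         bridge = c("NLM_MAP", "OHDSI_REL", "UMLS_CUI", "CUI_DIRECT"),
                         nlm_exclude_one_to_many = TRUE,
                         max_ohdsi_hops = 5) {
  source_vocab <- match.arg(source_vocab, c("ICD10CM", "ICD10"))
  bridge <- match.arg(bridge)

  frontier <- path_start(bundle_codes(bundle, source_vocab))
  frontier <- take_hop(frontier, bundle, "UMLS_CUI",
                       from_vocab = source_vocab, to_vocab = "CUI")

  if (bridge == "CUI_DIRECT") {
    frontier <- take_hop(frontier, bundle, "UMLS_CUI",
                         from_vocab = "CUI", to_vocab = "ICD9CM")
    return(finish_records(frontier, bundle, "C_CUI_ICD9"))
  }

  frontier <- take_hop(frontier, bundle, "UMLS_CUI",
                       from_vocab = "CUI", to_vocab = "SNOMED")

  if (bridge == "NLM_MAP") {
    edges <- bundle_edges(bundle, "NLM_MAP")
    if (nlm_exclude_one_to_many) {
      multi <- edges |>
        dplyr::distinct(.data$source_vocab, .data$source_code, .data$target_code) |>
        dplyr::count(.data$source_vocab, .data$source_code) |>
        dplyr::filter(.data$n > 1)
      frontier <- dplyr::anti_join(
        frontier, multi,
        by = c(node_vocab = "source_vocab", node_code = "source_code")
      )
    }
    frontier <- take_hop(frontier, bundle, "NLM_MAP",
                         from_vocab = "SNOMED", to_vocab = "ICD9CM")
    return(finish_records(frontier, bundle, "D_SNOMED_NLM"))
  }

  if (bridge == "UMLS_CUI") {
    frontier <- take_hop(frontier, bundle, "UMLS_CUI",
                         from_vocab = "SNOMED", to_vocab = "CUI")
    frontier <- take_hop(frontier, bundle, "UMLS_CUI",
                         from_vocab = "CUI", to_vocab = "ICD9CM")
    return(finish_records(frontier, bundle, "F_SNOMED_CUI"))
  }

  # OHDSI: iterate relationship hops until an ICD-9-CM concept is reached;
  # a chain never revisits a node (cycle detection) and stops at the hop cap.
  done <- frontier[0, ]
  for (hop in seq_len(max_ohdsi_hops)) {
    frontier <- take_hop(frontier, bundle, "OHDSI_REL")
    if (nrow(frontier) == 0) break
    revisit <- mapply(function(prov, vocab, code) {
      node <- node_str(vocab, code)
      # node already appears earlier in the chain?
      lengths(regmatches(prov, gregexpr(node, prov, fixed = TRUE))) > 1
    }, frontier$provenance, frontier$node_vocab, frontier$node_code)
    if (any(revisit)) {
      warning("OHDSI relationship cycle detected; cyclic chains dropped",
              call. = FALSE)
      frontier <- frontier[!revisit, ]
    }
    arrived <- frontier$node_vocab == "ICD9CM"
    done <- dplyr::bind_rows(done, frontier[arrived, ])
    frontier <- frontier[!arrived, ]
    if (nrow(frontier) == 0) break
  }
  finish_records(done, bundle, "E_SNOMED_OHDSI")
}

#' Resolve the parent/child phecode conflicts within each source code
#'
#' When a source code maps to both a parent phecode and one of its
#' descendants, only the descendant mappings are kept (granularity is
#' preserved); pruning is transitive, so a grandparent is removed whenever
#' any descendant survives. Phecodes from unrelated families are all
#' retained. The operation is idempotent.
#'
#' @param records A tibble of mapping records.
#' @return The filtered tibble.
#' @export
resolve_hierarchy <- function(records) {
  if (nrow(records) == 0) return(records)
  records |>
    dplyr::group_by(.data$source_vocab, .data$source_code) |>
    dplyr::filter({
      phe <- unique(.data$phecode)
      keep <- !vapply(.data$phecode,
                      function(p) any(is_strict_ancestor(p, phe)),
                      logical(1))
      keep
    }) |>
    dplyr::ungroup()
}

#' Build a full ICD-to-phecode map
#'
#' Runs every applicable path (A + B + C/D/E/F for ICD-10-CM; A + D/E/F for
#' ICD-10, which has no GEMS), takes the union of their records with no path
#' precedence, merges duplicate (source, phecode) pairs by concatenating
#' their path labels and provenance chains, and applies
#' [resolve_hierarchy()]. Output rows are sorted by (source_code, phecode)
#' so map files are byte-reproducible.
#'
#' @param bundle A `terminology_bundle`.
#' @param source_vocab `"ICD10CM"` or `"ICD10"`.
#' @param paths Optional character vector of path letters to run, out of
#'   `c("A","B","C","D","E","F")`; defaults to all applicable to the
#'   vocabulary. Paths B and C are silently dropped for ICD-10.
#' @param nlm_exclude_one_to_many,max_ohdsi_hops Passed to [concept_path()].
#' @return A `phecode_map` tibble (`source_vocab`, `source_code`, `phecode`,
#'   `path_label`, `provenance`) with a `source_vocab` attribute.
#' @export
build_map <- function(bundle, source_vocab = c("ICD10CM", "ICD10"),
                      paths = NULL, nlm_exclude_one_to_many = TRUE,
                      max_ohdsi_hops = 5) {
  source_vocab <- match.arg(source_vocab)
  default_paths <- if (source_vocab == "ICD10CM") {
    c("A", "B", "C", "D", "E", "F")
  } else {
    c("A", "D", "E", "F")
  }
  paths <- paths %||% default_paths
  paths <- intersect(toupper(paths), default_paths)

  pieces <- list()
  if ("A" %in% paths) pieces$A <- direct_string_match(bundle, source_vocab)
  if ("B" %in% paths) pieces$B <- gems_path(bundle)
  if ("C" %in% paths) {
    pieces$C <- concept_path(bundle, source_vocab, "CUI_DIRECT")
  }
  if ("D" %in% paths) {
    pieces$D <- concept_path(bundle, source_vocab, "NLM_MAP",
                             nlm_exclude_one_to_many = nlm_exclude_one_to_many)
  }
  if ("E" %in% paths) {
    pieces$E <- concept_path(bundle, source_vocab, "OHDSI_REL",
                             max_ohdsi_hops = max_ohdsi_hops)
  }
  if ("F" %in% paths) pieces$F <- concept_path(bundle, source_vocab, "UMLS_CUI")

  records <- dplyr::bind_rows(pieces)
  if (nrow(records) == 0) {
    return(new_phecode_map(empty_records(), source_vocab))
  }
  records <- records |>
    dplyr::filter(.data$source_vocab == !!source_vocab) |>
    resolve_hierarchy() |>
    dplyr::group_by(.data$source_vocab, .data$source_code, .data$phecode) |>
    dplyr::summarise(
      path_label = paste(sort(unique(.data$path_label)), collapse = "+"),
      provenance = paste(sort(unique(.data$provenance)), collapse = " | "),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$source_code, .data$phecode, .data$path_label)
  new_phecode_map(records, source_vocab)
}

new_phecode_map <- function(records, source_vocab) {
  records <- as_tibble(records)
  structure(records,
            class = c("phecode_map", class(records)),
            source_vocab = source_vocab)
}

#' The identity ICD-9-CM to phecode map
#'
#' Wraps the bundle's ICD-9-CM phecode-map edges as a `phecode_map` (path
#' label `ICD9_DIRECT`), for use as the gold-standard comparator in the
#' reproducibility and comparative PheWAS analyses. Hierarchy resolution is
#' applied the same way as for the derived maps.
#'
#' @param bundle A `terminology_bundle`.
#' @return A `phecode_map` for vocabulary `"ICD9CM"`.
#' @export
icd9_phecode_map <- function(bundle) {
  edges <- bundle_edges(bundle, "ICD9_PHECODE_MAP")
  records <- tibble(
    source_vocab = "ICD9CM",
    source_code = edges$source_code,
    phecode = edges$target_code,
    path_label = "ICD9_DIRECT",
    provenance = paste0(node_str("ICD9CM", edges$source_code),
                        " -[ICD9_PHECODE_MAP]-> ",
                        node_str("PHECODE", edges$target_code))
  ) |>
    resolve_hierarchy() |>
    dplyr::arrange(.data$source_code, .data$phecode)
  new_phecode_map(records, "ICD9CM")
}

#' Write / read a phecode map as CSV
#'
#' Columns: source_vocab, source_code, phecode, path_label, provenance. A
#' write/read round trip is the identity.
#'
#' @param map A `phecode_map`.
#' @param path Output CSV path.
#' @return `path` (write) or a `phecode_map` (read).
#' @export
write_map <- function(map, path) {
  readr::write_csv(as_tibble(map), path)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  need <- c("source_vocab", "source_code", "phecode", "path_label", "provenance")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop(sprintf("map file missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  vocab <- unique(df$source_vocab)
  new_phecode_map(df, if (length(vocab) == 1) vocab else vocab)
}

#' Replay provenance chains against a bundle
#'
#' Parses each record's provenance string and verifies that every hop exists
#' as a bundle edge (string-match hops are checked against the description
#' tables) and that the chain ends at the record's phecode. Used as a
#' map-integrity audit.
#'
#' @param map A `phecode_map`.
#' @param bundle The `terminology_bundle` the map was built from.
#' @return Logical vector, one element per map row.
#' @export
verify_map <- function(map, bundle) {
  edge_keys <- with(bundle$edges, paste(source_vocab, source_code, resource,
                                        target_vocab, target_code))
  norm <- function(x) stringr::str_squish(tolower(x))
  verify_chain <- function(chain, phecode) {
    # a merged provenance field may hold several chains joined by " | "
    all(vapply(strsplit(chain, " | ", fixed = TRUE)[[1]], function(one) {
      parts <- strsplit(one, " -[", fixed = TRUE)[[1]]
      nodes <- character(length(parts))
      resources <- character(length(parts) - 1)
      nodes[1] <- parts[1]
      for (i in seq_along(parts)[-1]) {
        seg <- strsplit(parts[i], "]-> ", fixed = TRUE)[[1]]
        resources[i - 1] <- seg[1]
        nodes[i] <- seg[2]
      }
      if (!identical(nodes[length(nodes)], node_str("PHECODE", phecode))) {
        return(FALSE)
      }
      for (i in seq_along(resources)) {
        sv <- strsplit(nodes[i], ":", fixed = TRUE)[[1]]
        tv <- strsplit(nodes[i + 1], ":", fixed = TRUE)[[1]]
        src_code <- paste(sv[-1], collapse = ":")
        tgt_code <- paste(tv[-1], collapse = ":")
        if (resources[i] == "STRING_MATCH") {
          d_icd <- bundle$codes$description[bundle$codes$vocabulary == sv[1] &
                                              bundle$codes$code == src_code]
          d_phe <- bundle$phecodes$description[bundle$phecodes$phecode == tgt_code]
          ok <- length(d_icd) > 0 && length(d_phe) > 0 &&
            norm(d_icd[1]) == norm(d_phe[1])
        } else {
          ok <- paste(sv[1], src_code, resources[i], tv[1], tgt_code) %in% edge_keys
        }
        if (!ok) return(FALSE)
      }
      TRUE
    }, logical(1)))
  }
  mapply(verify_chain, map$provenance, map$phecode, USE.NAMES = FALSE)
}
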