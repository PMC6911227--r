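test_that("direct description matching is case-insensitive and exact", {
  rec <- direct_string_match(fb, "ICD10CM")
  hit <- dplyr::filter(rec, source_code == "H52.4")
  expect_equal(hit$phecode, "367.4")  # PRESBYOPIA vs Presbyopia
  expect_equal(hit$path_label, "A_DIRECT_STRING")
  # no other fixture descriptions coincide
  expect_equal(nrow(rec), 1)

  # bundle with no shared descriptions yields the empty set
  b0 <- new_bundle(
    tibble::tibble(vocabulary = "ICD10CM", code = "A00.0", description = "Cholera"),
    fb$edges[0, ],
    tibble::tibble(phecode = "401", description = "Hypertension",
                   exclusion_ranges = "")
  )
  expect_equal(nrow(direct_string_match(b0, "ICD10CM")), 0)
})

test_that("GEMS path chains ICD-10-CM through ICD-9-CM to phecodes", {
  rec <- gems_path(fb)
  expect_equal(dplyr::filter(rec, source_code == "E11.9")$phecode, "250.2")
  # two GEMS targets -> two phecode records
  dual <- dplyr::filter(rec, source_code == "I25.708")
  expect_setequal(dual$phecode, c("411.3", "411.4"))
  # dead-end chain: GEMS target with no phecode-map entry yields nothing
  b <- fb
  b$edges <- dplyr::bind_rows(fb$edges, tibble::tibble(
    resource = "GEMS", source_vocab = "ICD10CM", source_code = "Z00.00",
    target_vocab = "ICD9CM", target_code = "V70.0", approximate_flag = 1L))
  expect_equal(nrow(dplyr::filter(gems_path(b), source_code == "Z00.00")), 0)
})

test_that("GEMS path equals an independent brute-force two-hop join", {
  gems <- dplyr::filter(fb$edges, resource == "GEMS")
  phemap9 <- dplyr::filter(fb$edges, resource == "ICD9_PHECODE_MAP")
  brute <- merge(gems, phemap9, by.x = "target_code", by.y = "source_code")
  brute <- unique(data.frame(source_code = brute$source_code,
                             phecode = brute$target_code.y))
  rec <- gems_path(fb)[, c("source_code", "phecode")]
  expect_setequal(paste(rec$source_code, rec$phecode),
                  paste(brute$source_code, brute$phecode))
})

test_that("concept path follows the five-hop OHDSI chain for L01.00", {
  rec <- concept_path(fb, "ICD10CM", "OHDSI_REL")
  hit <- dplyr::filter(rec, source_code == "L01.00")
  expect_equal(hit$phecode, "686.2")
  expect_equal(hit$path_label, "E_SNOMED_OHDSI")
  expect_match(hit$provenance, "C0021099.*48277006.*140480.*44832600.*684",
               fixed = FALSE)
})

test_that("concept path drops incomplete chains", {
  b <- fb
  # break the CUI -> SNOMED hop
  b$edges <- dplyr::filter(fb$edges, !(resource == "UMLS_CUI" &
                                         source_code == "C0021099" &
                                         target_code == "48277006"))
  expect_equal(nrow(dplyr::filter(concept_path(b, "ICD10CM", "OHDSI_REL"),
                                  source_code == "L01.00")), 0)
})

test_that("OHDSI traversal respects the hop limit and survives cycles", {
  expect_equal(nrow(concept_path(fb, "ICD10CM", "OHDSI_REL",
                                 max_ohdsi_hops = 2)), 0)
  # inject a relationship cycle; the acyclic route must still resolve
  b <- fb
  b$edges <- dplyr::bind_rows(fb$edges, tibble::tibble(
    resource = "OHDSI_REL", source_vocab = "OHDSI_CONCEPT",
    source_code = "140480", target_vocab = "SNOMED",
    target_code = "48277006", approximate_flag = 0L))
  expect_warning(rec <- concept_path(b, "ICD10CM", "OHDSI_REL"), "cycle")
  expect_equal(dplyr::filter(rec, source_code == "L01.00")$phecode, "686.2")
})

test_that("ICD-10 B21.1 reaches both unlinked phecodes via the NLM bridge", {
  rec <- concept_path(fb, "ICD10", "NLM_MAP")
  expect_setequal(dplyr::filter(rec, source_code == "B21.1")$phecode,
                  c("071.1", "202.2"))
})

test_that("one-to-many NLM rows are excluded by default but available", {
  b <- fb
  b$edges <- dplyr::bind_rows(fb$edges, tibble::tibble(
    resource = "NLM_MAP", source_vocab = "SNOMED", source_code = "62479008",
    target_vocab = "ICD9CM", target_code = "200.2", approximate_flag = 0L))
  strict <- concept_path(b, "ICD10", "NLM_MAP")
  # 62479008 now has two NLM targets, so its chains are skipped entirely
  expect_setequal(dplyr::filter(strict, source_code == "B21.1")$phecode, "202.2")
  loose <- concept_path(b, "ICD10", "NLM_MAP", nlm_exclude_one_to_many = FALSE)
  expect_setequal(dplyr::filter(loose, source_code == "B21.1")$phecode,
                  c("071.1", "202.2"))
})

test_that("hierarchy resolution keeps children and unrelated families", {
  rec <- tibble::tibble(
    source_vocab = "ICD10CM",
    source_code = c("I10", "I10", "D57.812", "D57.812", "X", "X", "X"),
    phecode = c("401", "401.1", "282.5", "289.5", "250", "250.2", "250.23"),
    path_label = "B_GEMS", provenance = ""
  )
  out <- resolve_hierarchy(rec)
  expect_equal(dplyr::filter(out, source_code == "I10")$phecode, "401.1")
  expect_setequal(dplyr::filter(out, source_code == "D57.812")$phecode,
                  c("282.5", "289.5"))
  # transitive pruning: grandparent and parent both removed
  expect_equal(dplyr::filter(out, source_code == "X")$phecode, "250.23")
  # idempotent
  expect_equal(resolve_hierarchy(out), out)
})

test_that("hierarchy resolution agrees with a brute-force transitive filter", {
  withr::with_seed(77, {
    for (rep in 1:200) {
      phe <- unique(random_phecodes(sample(2:8, 1)))
      rec <- tibble::tibble(source_vocab = "ICD10CM", source_code = "X",
                            phecode = phe, path_label = "B_GEMS",
                            provenance = "")
      got <- sort(resolve_hierarchy(rec)$phecode)
      expect_equal(got, sort(brute_force_resolve(phe)))
      # minimality: no retained ancestor pair
      grid <- expand.grid(a = got, b = got, stringsAsFactors = FALSE)
      expect_false(any(is_strict_ancestor(grid$a, grid$b)))
    }
  })
})

test_that("build_map reproduces every fixture worked-example resolution", {
  got <- dplyr::bind_rows(tibble::as_tibble(map10cm), tibble::as_tibble(map10)) |>
    dplyr::select(source_vocab, source_code, phecode)
  exp <- fixture_expected_mappings()
  expect_setequal(paste(got$source_vocab, got$source_code, got$phecode),
                  paste(exp$source_vocab, exp$source_code, exp$phecode))
  # decoy codes never map
  expect_false(any(c("Z00.00", "T38.3X6A", "O04.6") %in% map10cm$source_code))
  expect_false("A16.9" %in% map10$source_code)
})

test_that("ICD-10 maps never use the GEMS path", {
  expect_false(any(grepl("B_GEMS", map10$path_label)))
  expect_false(any(grepl("GEMS", map10$provenance)))
})

test_that("duplicate (source, phecode) pairs merge their provenance", {
  hit <- dplyr::filter(map10cm, source_code == "L01.00")
  expect_equal(nrow(hit), 1)
  expect_equal(hit$path_label, "C_CUI_ICD9+E_SNOMED_OHDSI+F_SNOMED_CUI")
  expect_equal(length(strsplit(hit$provenance, " | ", fixed = TRUE)[[1]]), 3)
})

test_that("a bundle with only phecode definitions yields an empty map", {
  b <- new_bundle(fb$codes[0, ], fb$edges[0, ], fb$phecodes)
  expect_equal(nrow(build_map(b, "ICD10CM")), 0)
})

test_that("build_map output is monotone in the edge set over the pruned closure", {
  # adding an edge may refine a parent into its child, but the set of
  # mappings that are retained-or-pruned-by-a-retained-descendant only grows
  closure <- function(map) {
    recs <- tibble::as_tibble(map)
    keys <- character(0)
    for (src in unique(recs$source_code)) {
      kept <- recs$phecode[recs$source_code == src]
      anc <- unique(unlist(lapply(kept, function(k) {
        all_phe <- fb$phecodes$phecode
        all_phe[is_strict_ancestor(all_phe, k)]
      })))
      keys <- c(keys, paste(src, union(kept, anc)))
    }
    keys
  }
  base <- build_map(fb, "ICD10CM", paths = c("A", "B"))
  bigger <- build_map(fb, "ICD10CM")
  expect_true(all(closure(base) %in% closure(bigger)))
})

test_that("every mapping record's provenance chain replays through the bundle", {
  expect_true(all(verify_map(map10cm, fb)))
  expect_true(all(verify_map(map10, fb)))
  expect_true(all(verify_map(map9, fb)))
  # a forged chain fails replay
  forged <- map10cm
  forged$provenance[1] <- "ICD10CM:A08.4 -[GEMS]-> ICD9CM:999.9 -[ICD9_PHECODE_MAP]-> PHECODE:008"
  expect_false(verify_map(forged, fb)[1])
})

test_that("map CSV write/read round trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_map(map10cm, path)
  back <- read_map(path)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(map10cm))
  expect_equal(attr(back, "source_vocab"), "ICD10CM")
  # empty map -> header-only file
  path2 <- withr::local_tempfile(fileext = ".csv")
  empty <- build_map(new_bundle(fb$codes[0, ], fb$edges[0, ], fb$phecodes), "ICD10")
  write_map(empty, path2)
  expect_equal(length(readLines(path2)), 1)
})
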