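# Shared fixtures: the worked-example terminology bundle and its three maps
# are cheap to build, so they are constructed once per test run.
fb <- build_fixture_bundle()
map10cm <- build_map(fb, "ICD10CM")
map10 <- build_map(fb, "ICD10")
map9 <- icd9_phecode_map(fb)

# random valid phecode strings for property tests (mix of bare integers,
# zero-padded ids and 1-2 fractional digits)
random_phecodes <- function(n) {
  ints <- sample(c(sprintf("%03d", sample(0:999, n, replace = TRUE)),
                   as.character(sample(1:999, n, replace = TRUE))), n)
  frac <- sample(c("", sprintf(".%d", 0:9), sprintf(".%02d", 0:99)),
                 n, replace = TRUE)
  paste0(ints, frac)
}

# independent brute-force transitive-ancestor filter: keep p unless some q
# in the set sits strictly below it in the hierarchy, decided by numeric
# digit-by-digit comparison rather than the string rule under test
brute_force_resolve <- function(phecodes) {
  digits_of <- function(x) {
    as.integer(strsplit(gsub(".", "", x, fixed = TRUE), "")[[1]])
  }
  int_part <- function(x) as.numeric(sub("\\..*$", "", x))
  below <- function(p, q) {
    # q strictly below p: same integer part, q's digit vector extends p's
    dp <- digits_of(p)
    dq <- digits_of(q)
    int_part(p) == int_part(q) && length(dq) > length(dp) &&
      all(dq[seq_along(dp)] == dp)
  }
  keep <- vapply(phecodes, function(p) {
    !any(vapply(phecodes, function(q) !identical(p, q) && below(p, q), logical(1)))
  }, logical(1))
  phecodes[keep]
}

# small hand-built assignment table used across phenotyping tests
toy_assignments <- function() {
  tibble::tribble(
    ~patient_id, ~phecode, ~date,
    "p1", "250.2",  as.Date("2016-02-01"),
    "p1", "250.2",  as.Date("2016-03-01"),
    "p2", "250.4",  as.Date("2016-02-10"),
    "p3", "401.1",  as.Date("2016-04-01"),
    "p4", "250.23", as.Date("2016-05-01")
  )
}
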