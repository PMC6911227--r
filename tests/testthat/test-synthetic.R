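test_that("fixture bundle validates and replays its expected mappings", {
  expect_s3_class(fb, "terminology_bundle")
  exp <- fixture_expected_mappings()
  got <- dplyr::bind_rows(tibble::as_tibble(map10cm), tibble::as_tibble(map10))
  expect_setequal(paste(got$source_vocab, got$source_code, got$phecode),
                  paste(exp$source_vocab, exp$source_code, exp$phecode))
  # decoy count is honoured and extra decoys stay unmapped
  b5 <- build_fixture_bundle(n_decoys = 5)
  expect_true(all(c("Z99.1", "Z99.2") %in% b5$codes$code))
  m5 <- build_map(b5, "ICD10CM")
  expect_false(any(grepl("^Z99", m5$source_code)))
})

test_that("simulation is a pure function of its seed", {
  a <- simulate_cohort(cohort_sim_config(n_patients = 300, seed = 17))
  b <- simulate_cohort(cohort_sim_config(n_patients = 300, seed = 17))
  expect_identical(a$events, b$events)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$truth, b$truth)
  c <- simulate_cohort(cohort_sim_config(n_patients = 300, seed = 18))
  expect_false(identical(a$events, c$events))
  # simulation does not disturb the caller's RNG stream
  set.seed(1); before <- runif(3)
  set.seed(1); invisible(simulate_cohort(cohort_sim_config(100, seed = 2)))
  expect_identical(runif(3), before)
})

test_that("config validation rejects impossible study designs", {
  expect_error(cohort_sim_config(100), "seed is mandatory")
  expect_error(cohort_sim_config(100, seed = 1, allele_freq = 0), "allele_freq")
  expect_error(cohort_sim_config(100, seed = 1, female_fraction = 1.2),
               "probabilities")
  bad <- default_phenotypes()
  bad$persistence[1] <- 1.7
  expect_error(cohort_sim_config(100, seed = 1, phenotypes = bad),
               "probabilities")
  expect_error(
    cohort_sim_config(100, seed = 1,
                      w1 = observation_window("2014-01-01", "2016-06-30"),
                      w2 = observation_window("2016-01-01", "2017-06-30")),
    "overlap"
  )
})

test_that("genotypes follow Hardy-Weinberg at the configured frequency", {
  q <- 0.07
  sim <- simulate_cohort(cohort_sim_config(n_patients = 20000, seed = 101))
  n <- nrow(sim$subjects)
  expected <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  for (g in 0:2) {
    p_hat <- mean(sim$subjects$dosage == g)
    se <- sqrt(expected[g + 1] * (1 - expected[g + 1]) / n)
    expect_lt(abs(p_hat - expected[g + 1]), 3 * se + 1e-12)
  }
  # covariate marginals
  expect_lt(abs(mean(sim$subjects$sex == "F") - 0.551), 0.02)
  expect_true(all(sim$subjects$age >= 0))
  expect_lt(abs(mean(sim$subjects$age) -
                  mean(sim$subjects$age[sim$subjects$age >= 0])), 1e-9)
})

test_that("truth table realises prevalence, persistence and incidence", {
  sim <- simulate_cohort(cohort_sim_config(n_patients = 20000, seed = 55))
  tr <- dplyr::filter(sim$truth, phenotype == "hypertension")
  n <- nrow(tr)
  expect_lt(abs(mean(tr$status_w1) - 0.25), 3 * sqrt(0.25 * 0.75 / n))
  persisted <- mean(tr$status_w2[tr$status_w1])
  expect_lt(abs(persisted - 0.75), 0.02)
  incident <- mean(tr$status_w2[!tr$status_w1])
  expect_lt(abs(incident - 0.10), 0.02)
  acute <- dplyr::filter(sim$truth, phenotype == "intestinal_infection")
  expect_lt(mean(acute$status_w2[acute$status_w1]), 0.10)
})

test_that("degenerate persistence bounds behave exactly", {
  ph <- default_phenotypes()
  ph$persistence[ph$name == "hypertension"] <- 1.0
  ph$persistence[ph$name == "hyperlipidemia"] <- 0.0
  sim <- simulate_cohort(cohort_sim_config(n_patients = 2000, seed = 77,
                                           phenotypes = ph))
  htn <- dplyr::filter(sim$truth, phenotype == "hypertension", status_w1)
  expect_true(all(htn$status_w2))
  lip <- dplyr::filter(sim$truth, phenotype == "hyperlipidemia", status_w1)
  expect_false(any(lip$status_w2))
})

test_that("the planted effect raises target prevalence by genotype only", {
  sim <- simulate_cohort(cohort_sim_config(n_patients = 20000, seed = 23,
                                           allele_freq = 0.25))
  tr <- dplyr::left_join(sim$truth, sim$subjects, by = "patient_id")
  target <- dplyr::filter(tr, prefix == "411.4")
  by_g <- dplyr::group_by(target, dosage) |>
    dplyr::summarise(p1 = mean(status_w1), .groups = "drop") |>
    dplyr::arrange(dosage)
  expect_true(all(diff(by_g$p1) > 0))  # monotone in dosage
  # per-allele odds ratio near the planted 1.6
  odds <- by_g$p1 / (1 - by_g$p1)
  expect_lt(abs(odds[2] / odds[1] - 1.6), 0.2)
  # an untargeted phenotype shows no comparable gradient
  null_phen <- dplyr::filter(tr, prefix == "401")
  by_g0 <- dplyr::group_by(null_phen, dosage) |>
    dplyr::summarise(p1 = mean(status_w1), .groups = "drop")
  expect_lt(abs(by_g0$p1[2] - by_g0$p1[1]), 0.03)
})

test_that("every patient has a billing code in each window", {
  sim <- simulate_cohort(cohort_sim_config(n_patients = 500, seed = 31))
  ev <- sim$events
  w1 <- sim$config$w1; w2 <- sim$config$w2
  in_w1 <- unique(ev$patient_id[ev$date >= w1$start & ev$date <= w1$end])
  in_w2 <- unique(ev$patient_id[ev$date >= w2$start & ev$date <= w2$end])
  expect_setequal(in_w1, sim$subjects$patient_id)
  expect_setequal(in_w2, sim$subjects$patient_id)
  # era purity: window 1 events are ICD-9-CM, window 2 ICD-10-CM
  expect_true(all(ev$vocabulary[ev$date <= w1$end] == "ICD9CM"))
  expect_true(all(ev$vocabulary[ev$date >= w2$start] == "ICD10CM"))
  # filler codes never map to a phecode
  expect_false("V70.0" %in% map9$source_code)
  expect_false("Z00.00" %in% map10cm$source_code)
  # diseased patient-windows emit between 1 and 3 dated codes per phenotype
  counts <- dplyr::count(dplyr::filter(ev, code == "I10"), patient_id)
  expect_true(all(counts$n >= 1 & counts$n <= 3))
})

test_that("cohort write round-trips through CSV", {
  sim <- simulate_cohort(cohort_sim_config(n_patients = 50, seed = 3))
  dir <- withr::local_tempdir()
  write_cohort(sim, dir)
  ev <- readr::read_csv(file.path(dir, "events.csv"), show_col_types = FALSE)
  expect_equal(tibble::as_tibble(ev), sim$events)
  tr <- readr::read_csv(file.path(dir, "truth.csv"), show_col_types = FALSE)
  expect_equal(nrow(tr), nrow(sim$truth))
})

test_that("the full pipeline recovers the planted association across seeds", {
  hits <- vapply(1:10, function(s) {
    sim <- simulate_cohort(cohort_sim_config(n_patients = 5000, seed = 1000 + s,
                                             allele_freq = 0.25))
    ev10 <- dplyr::filter(sim$events, vocabulary == "ICD10CM")
    me <- map_events(ev10, map10cm)
    cohorts <- build_cohorts(me$assignments, sim$subjects$patient_id,
                             fb$phecodes)
    run <- run_phewas(cohorts, sim$subjects)
    g <- glance(run)
    isTRUE(g$top_phecode == "411.4" && g$min_p < run$bonferroni_alpha)
  }, logical(1))
  expect_gte(sum(hits), 9)
})
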