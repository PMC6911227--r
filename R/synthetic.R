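# Synthetic terminologies and cohorts. Two generators live here:
#
#  * build_fixture_bundle(): a miniature terminology bundle whose crosswalk
#    chains encode the canonical worked examples of each mapping path
#    (description match, GEMS, multi-hop concept chains, parent/child
#    candidates, dual-family targets), plus decoy codes with no complete
#    chain. All public chain identifiers are the real published ones;
#    intermediate CUI/SNOMED identifiers that are not publicly printed
#    (the HIV-Burkitt chains) are synthetic stand-ins (C90000xx CUIs).
#
#  * simulate_cohort(): a two-era EHR cohort with latent disease states,
#    Hardy-Weinberg genotypes, a planted genotype effect on one target
#    phenotype, and billing events drawn from the fixture codes, so the
#    whole mapping -> phenotyping -> PheWAS workflow can run end to end
#    without licensed terminologies or patient data.

#' Build the fixture terminology bundle
#'
#' Encodes, at minimum: the H52.4/367.4 description match; the E11.9 GEMS
#' chain to phecode 250.2; the L01.00 five-hop concept chain to 686.2
#' (also reachable via the CUI-direct and SNOMED-CUI bridges, exercising
#' provenance merging); I10 with parent+child candidates 401/401.1; the
#' dual-family targets of D57.812 (282.5 + 289.5) and I25.708 (411.3 +
#' 411.4); the ICD-10 (non-CM) B21.1 chains to 071.1 and 202.2; the three
#' depression ICD-9-CM codes 311/296.31/296.2 collapsing to phecode 296.2;
#' and decoy codes with no complete chain.
#'
#' @param n_decoys Number of decoy (non-mapping) ICD-10-CM codes, drawn from
#'   a fixed pool and padded with generated Z99.x codes (default 3).
#' @return A validated `terminology_bundle`.
#' @export
build_fixture_bundle <- function(n_decoys = 3) {
  decoy_pool <- tibble(
    code = c("Z00.00", "T38.3X6A", "O04.6"),
    description = c(
      "Encounter for general adult medical examination without abnormal findings",
      "Underdosing of insulin and oral hypoglycemic [antidiabetic] drugs, initial encounter",
      "Delayed or excessive hemorrhage following (induced) termination of pregnancy"
    )
  )
  if (n_decoys > nrow(decoy_pool)) {
    extra <- tibble(
      code = sprintf("Z99.%d", seq_len(n_decoys - nrow(decoy_pool))),
      description = sprintf("Synthetic decoy code %d", seq_len(n_decoys - nrow(decoy_pool)))
    )
    decoy_pool <- dplyr::bind_rows(decoy_pool, extra)
  }
  decoys <- decoy_pool[seq_len(n_decoys), ]

  icd10cm <- dplyr::bind_rows(tibble(
    code = c("H52.4", "E11.9", "L01.00", "I10", "D57.812", "I25.708",
             "I25.10", "E10.9", "E78.5", "A08.4", "R73.09", "F32.9"),
    description = c(
      "PRESBYOPIA",
      "Type 2 diabetes mellitus without complications",
      "Impetigo, unspecified",
      "Essential (primary) hypertension",
      "Other sickle-cell disorders with splenic sequestration",
      "Atherosclerosis of coronary artery bypass graft(s), unspecified, with other forms of angina pectoris",
      "Atherosclerotic heart disease of native coronary artery without angina pectoris",
      "Type 1 diabetes mellitus without complications",
      "Hyperlipidemia, unspecified",
      "Viral intestinal infection, unspecified",
      "Other abnormal glucose",
      "Major depressive disorder, single episode, unspecified"
    )
  ), decoys)

  icd10 <- tibble(
    code = c("B21.1", "A16.9"),
    description = c(
      "HIV disease resulting in Burkitt lymphoma",
      "Respiratory tuberculosis unspecified, without mention of bacteriological or histological confirmation"
    )
  )

  icd9cm <- tibble(
    code = c("250.0", "250.01", "401.9", "282.69", "414.05", "413.9",
             "414.01", "272.4", "008.8", "790.29", "311", "296.31",
             "296.2", "684", "042", "200.2", "V70.0"),
    description = c(
      "Diabetes mellitus without mention of complication",
      "Diabetes mellitus without mention of complication, type I",
      "Unspecified essential hypertension",
      "Other sickle-cell disease without mention of crisis",
      "Coronary atherosclerosis of unspecified bypass graft",
      "Angina pectoris, unspecified",
      "Coronary atherosclerosis of native coronary artery",
      "Other and unspecified hyperlipidemia",
      "Intestinal infection due to other organism, not elsewhere classified",
      "Other abnormal glucose",
      "Depressive disorder, not elsewhere classified",
      "Major depressive affective disorder, recurrent episode, severe",
      "Major depressive affective disorder, single episode",
      "Impetigo",
      "Human immunodeficiency virus [HIV] disease",
      "Burkitt's tumor or lymphoma of unspecified site",
      "Routine general medical examination at a health care facility"
    )
  )

  cui <- tibble(
    code = c("C0021099", "C9000010", "C9000011"),
    description = c("Impetigo",
                    "Synthetic stand-in: HIV disease",
                    "Synthetic stand-in: Burkitt lymphoma")
  )
  snomed <- tibble(
    code = c("48277006", "62479008", "118617005"),
    description = c("Impetigo", "AIDS", "Burkitt lymphoma")
  )
  ohdsi <- tibble(
    code = c("140480", "44832600"),
    description = c("Impetigo (standard concept)", "Impetigo (ICD9CM concept)")
  )

  codes <- dplyr::bind_rows(
    dplyr::mutate(icd10cm, vocabulary = "ICD10CM"),
    dplyr::mutate(icd10, vocabulary = "ICD10"),
    dplyr::mutate(icd9cm, vocabulary = "ICD9CM"),
    dplyr::mutate(cui, vocabulary = "CUI"),
    dplyr::mutate(snomed, vocabulary = "SNOMED"),
    dplyr::mutate(ohdsi, vocabulary = "OHDSI_CONCEPT")
  ) |> dplyr::select("vocabulary", "code", "description")

  edge <- function(resource, sv, sc, tv, tc, flag = 0L) {
    tibble(resource = resource, source_vocab = sv, source_code = sc,
           target_vocab = tv, target_code = tc, approximate_flag = as.integer(flag))
  }
  edges <- dplyr::bind_rows(
    # GEMS: ICD-10-CM -> ICD-9-CM (both equivalent and approximate rows used)
    edge("GEMS", "ICD10CM", "E11.9", "ICD9CM", "250.0", 0),
    edge("GEMS", "ICD10CM", "I10", "ICD9CM", "401.9", 0),
    edge("GEMS", "ICD10CM", "D57.812", "ICD9CM", "282.69", 1),
    edge("GEMS", "ICD10CM", "I25.708", "ICD9CM", "414.05", 1),
    edge("GEMS", "ICD10CM", "I25.708", "ICD9CM", "413.9", 1),
    edge("GEMS", "ICD10CM", "I25.10", "ICD9CM", "414.01", 0),
    edge("GEMS", "ICD10CM", "E10.9", "ICD9CM", "250.01", 0),
    edge("GEMS", "ICD10CM", "E78.5", "ICD9CM", "272.4", 0),
    edge("GEMS", "ICD10CM", "A08.4", "ICD9CM", "008.8", 1),
    edge("GEMS", "ICD10CM", "R73.09", "ICD9CM", "790.29", 0),
    edge("GEMS", "ICD10CM", "F32.9", "ICD9CM", "311", 0),
    # UMLS CUI equivalences
    edge("UMLS_CUI", "ICD10CM", "L01.00", "CUI", "C0021099"),
    edge("UMLS_CUI", "CUI", "C0021099", "SNOMED", "48277006"),
    edge("UMLS_CUI", "SNOMED", "48277006", "CUI", "C0021099"),
    edge("UMLS_CUI", "CUI", "C0021099", "ICD9CM", "684"),
    edge("UMLS_CUI", "ICD10", "B21.1", "CUI", "C9000010"),
    edge("UMLS_CUI", "ICD10", "B21.1", "CUI", "C9000011"),
    edge("UMLS_CUI", "CUI", "C9000010", "SNOMED", "62479008"),
    edge("UMLS_CUI", "CUI", "C9000011", "SNOMED", "118617005"),
    # OHDSI concept relationships (two internal hops then the ICD-9-CM leg)
    edge("OHDSI_REL", "SNOMED", "48277006", "OHDSI_CONCEPT", "140480"),
    edge("OHDSI_REL", "OHDSI_CONCEPT", "140480", "OHDSI_CONCEPT", "44832600"),
    edge("OHDSI_REL", "OHDSI_CONCEPT", "44832600", "ICD9CM", "684"),
    # NLM SNOMED -> ICD-9-CM rule maps
    edge("NLM_MAP", "SNOMED", "62479008", "ICD9CM", "042"),
    edge("NLM_MAP", "SNOMED", "118617005", "ICD9CM", "200.2"),
    # ICD-9-CM phecode map
    edge("ICD9_PHECODE_MAP", "ICD9CM", "250.0", "PHECODE", "250.2"),
    edge("ICD9_PHECODE_MAP", "ICD9CM", "250.01", "PHECODE", "250.1"),
    edge("ICD9_PHECODE_MAP", "ICD9CM", "401.9", "PHECODE", "401"),
    edge("ICD9_PHECODE_MAP", "ICD9CM", "401.9", "PHECODE", "401.1"),
    edge("ICD9_PHECODE_MAP", "ICD9CM", "282.69", "PHECODE", "282.5"),
    edge("ICD9_PHECODE_MAP", "ICD9CM", "282.69", "PHECODE", "289.5"),
    edge("ICD9_PHECODE_MAP", "ICD9CM", "414.05", "PHECODE", "411.4"),
    edge("ICD9_PHECODE_MAP", "ICD9CM", "413.9", "PHECODE", "411.3"),
    edge("ICD9_PHECODE_MAP", "ICD9CM", "414.01", "PHECODE", "411.4"),
    edge("ICD9_PHECODE_MAP", "ICD9CM", "272.4", "PHECODE", "272.1"),
    edge("ICD9_PHECODE_MAP", "ICD9CM", "008.8", "PHECODE", "008"),
    edge("ICD9_PHECODE_MAP", "ICD9CM", "790.29", "PHECODE", "250.4"),
    edge("ICD9_PHECODE_MAP", "ICD9CM", "311", "PHECODE", "296.2"),
    edge("ICD9_PHECODE_MAP", "ICD9CM", "296.31", "PHECODE", "296.2"),
    edge("ICD9_PHECODE_MAP", "ICD9CM", "296.2", "PHECODE", "296.2"),
    edge("ICD9_PHECODE_MAP", "ICD9CM", "684", "PHECODE", "686.2"),
    edge("ICD9_PHECODE_MAP", "ICD9CM", "042", "PHECODE", "071.1"),
    edge("ICD9_PHECODE_MAP", "ICD9CM", "200.2", "PHECODE", "202.2")
  )

  phecodes <- tibble(
    phecode = c("008", "042", "071.1", "202.2", "249", "250", "250.1",
                "250.2", "250.4", "272", "272.1", "282.5", "289.5", "296.2",
                "367.4", "401", "401.1", "411.3", "411.4", "686.2"),
    description = c(
      "Intestinal infection", "HIV infection", "HIV infection, symptomatic",
      "Non-Hodgkins lymphoma", "Secondary diabetes mellitus",
      "Diabetes mellitus", "Type 1 diabetes", "Type 2 diabetes",
      "Abnormal glucose", "Disorders of lipoid metabolism", "Hyperlipidemia",
      "Sickle cell anemia", "Diseases of spleen", "Depression", "Presbyopia",
      "Hypertension", "Essential hypertension", "Angina pectoris",
      "Coronary atherosclerosis", "Impetigo"
    ),
    exclusion_ranges = c(
      "001-009.99", "070-071.99", "070-071.99", "200-204.99", "249-250.99",
      "249-250.99", "249-250.99", "249-250.99", "249-250.99", "272-272.99",
      "272-272.99", "280-285.99", "", "296-296.99", "", "401-405.99",
      "401-405.99", "410-414.99", "410-414.99", ""
    )
  )

  new_bundle(codes, edges, phecodes)
}

#' Expected resolved mappings for the fixture bundle
#'
#' Hand-enumerated chain resolutions of the fixture, one row per retained
#' (source code, phecode) pair, for use as a replay oracle.
#'
#' @return Tibble with columns `source_vocab`, `source_code`, `phecode`.
#' @export
fixture_expected_mappings <- function() {
  tibble::tribble(
    ~source_vocab, ~source_code, ~phecode,
    "ICD10CM", "H52.4", "367.4",
    "ICD10CM", "E11.9", "250.2",
    "ICD10CM", "L01.00", "686.2",
    "ICD10CM", "I10", "401.1",
    "ICD10CM", "D57.812", "282.5",
    "ICD10CM", "D57.812", "289.5",
    "ICD10CM", "I25.708", "411.3",
    "ICD10CM", "I25.708", "411.4",
    "ICD10CM", "I25.10", "411.4",
    "ICD10CM", "E10.9", "250.1",
    "ICD10CM", "E78.5", "272.1",
    "ICD10CM", "A08.4", "008",
    "ICD10CM", "R73.09", "250.4",
    "ICD10CM", "F32.9", "296.2",
    "ICD10", "B21.1", "071.1",
    "ICD10", "B21.1", "202.2"
  )
}

#' Default phenotype panel for the cohort simulator
#'
#' Chronic phenotypes carry persistence 0.75 (the observed reproduction rate
#' for chronic diseases across the coding transition), the acute intestinal
#' infection 0.05 (under the observed <10%). Each phenotype names the
#' era-appropriate fixture billing codes that express it.
#'
#' @return Tibble with columns `name`, `prefix`, `prevalence_w1`,
#'   `persistence`, `incidence_w2`, `icd9_codes`, `icd10cm_codes`
#'   (list-columns of code vectors).
#' @export
default_phenotypes <- function() {
  tibble(
    name = c("hypertension", "hyperlipidemia", "type_1_diabetes",
             "type_2_diabetes", "intestinal_infection",
             "coronary_atherosclerosis", "depression"),
    prefix = c("401", "272", "250.1", "250.2", "008", "411.4", "296.2"),
    prevalence_w1 = c(0.25, 0.20, 0.015, 0.08, 0.03, 0.10, 0.12),
    persistence = c(0.75, 0.75, 0.75, 0.75, 0.05, 0.75, 0.75),
    incidence_w2 = c(0.10, 0.08, 0.005, 0.02, 0.03, 0.05, 0.05),
    icd9_codes = list("401.9", "272.4", "250.01", "250.0", "008.8",
                      "414.01", c("311", "296.31", "296.2")),
    icd10cm_codes = list("I10", "E78.5", "E10.9", "E11.9", "A08.4",
                         "I25.10", "F32.9")
  )
}

#' Cohort simulation configuration
#'
#' Study conditions default to the published cohort: 18-month windows
#' 2014-01-01..2015-06-30 (ICD-9-CM era) and 2016-01-01..2017-06-30
#' (ICD-10-CM era); 55.10% female; age ~ Normal(45, 25) truncated at 0; a
#' Lipoprotein(a)-style effect allele at frequency 0.07 raising the odds of
#' coronary atherosclerosis (phecode 411.4) by 1.6 per allele.
#'
#' @param n_patients Cohort size.
#' @param seed Mandatory RNG seed; simulation is fully reproducible from it.
#' @param w1,w2 [observation_window()]s for the two eras.
#' @param phenotypes Phenotype panel, see [default_phenotypes()].
#' @param target_phecode,allele_freq,log_or Planted genotype effect: target
#'   phenotype prefix, effect-allele frequency (Hardy-Weinberg), and
#'   per-allele log odds ratio applied to that phenotype's window-1
#'   prevalence and window-2 incidence on the logit scale.
#' @param age_mean,age_sd,female_fraction,race_probs Covariate
#'   distributions; `race_probs` is a named probability vector.
#' @return A validated list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_patients = 2000, seed,
                              w1 = observation_window("2014-01-01", "2015-06-30"),
                              w2 = observation_window("2016-01-01", "2017-06-30"),
                              phenotypes = default_phenotypes(),
                              target_phecode = "411.4",
                              allele_freq = 0.07,
                              log_or = log(1.6),
                              age_mean = 45, age_sd = 25,
                              female_fraction = 0.551,
                              race_probs = c(white = 0.70, black = 0.15,
                                             asian = 0.08, other = 0.07)) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  probs <- c(phenotypes$prevalence_w1, phenotypes$persistence,
             phenotypes$incidence_w2, female_fraction)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (allele_freq <= 0 || allele_freq >= 1) {
    stop("allele_freq must lie in (0, 1)", call. = FALSE)
  }
  if (windows_overlap(w1, w2)) stop("simulation windows overlap", call. = FALSE)
  structure(
    list(n_patients = as.integer(n_patients), seed = as.integer(seed),
         w1 = w1, w2 = w2, phenotypes = phenotypes,
         target_phecode = target_phecode, allele_freq = allele_freq,
         log_or = log_or, age_mean = age_mean, age_sd = age_sd,
         female_fraction = female_fraction,
         race_probs = race_probs / sum(race_probs)),
    class = "cohort_sim_config"
  )
}

rdate <- function(n, w) {
  span <- as.integer(w$end - w$start)
  w$start + sample.int(span + 1L, n, replace = TRUE) - 1L
}

#' Simulate a two-era EHR cohort
#'
#' Per patient: covariates and a Hardy-Weinberg genotype are drawn; each
#' phenotype's latent window-1 status is Bernoulli at its prevalence, with
#' the planted genotype effect added on the logit scale for phenotypes in
#' the target family; window-2 status follows the phenotype's persistence
#' (if a window-1 case) or incidence (otherwise, genotype-adjusted for the
#' target). Every diseased patient-window emits 1-3 dated billing codes in
#' the era-appropriate vocabulary drawn from the phenotype's fixture codes,
#' and every patient emits one filler code per window (ICD-9-CM V70.0 /
#' ICD-10-CM Z00.00, neither of which maps to a phecode) so that everyone
#' meets the any-code-in-each-window cohort criterion. Output is fully
#' reproducible from the config seed.
#'
#' @param config A [cohort_sim_config()].
#' @return A list of class `cohort_sim`: tibbles `events` (`patient_id`,
#'   `date`, `vocabulary`, `code`), `subjects` (`patient_id`, `dosage`,
#'   `age`, `sex`, `race`), `truth` (`patient_id`, `phenotype`, `prefix`,
#'   `status_w1`, `status_w2`), plus the `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  withr::with_seed(config$seed, {
    n <- config$n_patients
    ids <- sprintf("P%06d", seq_len(n))

    dosage <- stats::rbinom(n, 2, config$allele_freq)
    age <- stats::rnorm(n, config$age_mean, config$age_sd)
    while (any(age < 0)) {  # truncate at zero by resampling
      age[age < 0] <- stats::rnorm(sum(age < 0), config$age_mean, config$age_sd)
    }
    sex <- ifelse(stats::runif(n) < config$female_fraction, "F", "M")
    race <- sample(names(config$race_probs), n, replace = TRUE,
                   prob = config$race_probs)
    subjects <- tibble(patient_id = ids, dosage = dosage,
                       age = round(age, 1), sex = sex, race = race)

    phen <- config$phenotypes
    # a phenotype carries the genotype effect when its family contains the
    # target phecode
    targeted <- vapply(phen$prefix, function(pf) {
      phecode_matches_prefix(config$target_phecode, pf)
    }, logical(1))

    truth <- purrr::map_dfr(seq_len(nrow(phen)), function(i) {
      eff <- if (targeted[i]) config$log_or * dosage else 0
      p1 <- stats::plogis(stats::qlogis(phen$prevalence_w1[i]) + eff)
      s1 <- stats::runif(n) < p1
      p2_new <- stats::plogis(stats::qlogis(phen$incidence_w2[i]) + eff)
      s2 <- ifelse(s1, stats::runif(n) < phen$persistence[i],
                   stats::runif(n) < p2_new)
      tibble(patient_id = ids, phenotype = phen$name[i],
             prefix = phen$prefix[i], status_w1 = s1, status_w2 = s2)
    })

    emit <- function(pids, codes, vocab, w) {
      if (length(pids) == 0) {
        return(tibble(patient_id = character(), date = as.Date(character()),
                      vocabulary = character(), code = character()))
      }
      k <- sample(1:3, length(pids), replace = TRUE)
      pid <- rep(pids, k)
      tibble(patient_id = pid,
             date = rdate(length(pid), w),
             vocabulary = vocab,
             code = sample(codes, length(pid), replace = TRUE))
    }

    disease_events <- purrr::map_dfr(seq_len(nrow(phen)), function(i) {
      ti <- dplyr::filter(truth, .data$phenotype == phen$name[i])
      dplyr::bind_rows(
        emit(ti$patient_id[ti$status_w1], phen$icd9_codes[[i]], "ICD9CM", config$w1),
        emit(ti$patient_id[ti$status_w2], phen$icd10cm_codes[[i]], "ICD10CM", config$w2)
      )
    })
    filler_events <- dplyr::bind_rows(
      tibble(patient_id = ids, date = rdate(n, config$w1),
             vocabulary = "ICD9CM", code = "V70.0"),
      tibble(patient_id = ids, date = rdate(n, config$w2),
             vocabulary = "ICD10CM", code = "Z00.00")
    )
    events <- dplyr::bind_rows(disease_events, filler_events) |>
      dplyr::arrange(.data$patient_id, .data$date, .data$vocabulary, .data$code)

    structure(list(events = events, subjects = subjects,
                   truth = dplyr::arrange(truth, .data$phenotype, .data$patient_id),
                   config = config),
              class = "cohort_sim")
  })
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("<cohort_sim> %d patients, %d events, %d phenotypes (seed %d)\n",
              x$config$n_patients, nrow(x$events),
              dplyr::n_distinct(x$truth$phenotype), x$config$seed))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Writes `events.csv`, `subjects.csv` and `truth.csv` under `dir`.
#'
#' @param sim A `cohort_sim`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(sim$events, file.path(dir, "events.csv"))
  readr::write_csv(sim$subjects, file.path(dir, "subjects.csv"))
  readr::write_csv(sim$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}
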