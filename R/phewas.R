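# Per-phecode binary logistic regression of case status on allele dosage
# with covariate adjustment. The model for phecode j is
#   logit P(case) = b0 + b1 * dosage + covariates
# with dosage coded additively (0/1/2 effect alleles). Wald 95% CIs are
# exp(beta +/- 1.96 SE); the phenome-wide threshold is Bonferroni at
# alpha = 0.05 / number of phecodes actually tested.

#' Fit one binary logistic regression
#'
#' Thin wrapper around `stats::glm(family = binomial)` that enforces the
#' preconditions a phenome scan needs: at least one case and one control,
#' no constant non-intercept column (rejected as singular), and explicit
#' flagging of non-convergence and quasi-complete separation rather than
#' silently reporting runaway estimates.
#'
#' @param case_status Logical or 0/1 vector.
#' @param design Data frame of predictors, including the `dosage` column of
#'   interest; factors are handled by `glm`'s usual contrasts.
#' @return A list: `tested` (logical), `reason` (NA when tested),
#'   `coefficients` (tibble `term`, `estimate`, `std_error`, `p_value`),
#'   `converged`, `separation`.
#' @examples
#' d <- data.frame(dosage = rep(c(1, 0, 1, 0), c(20, 80, 10, 90)))
#' y <- rep(c(1, 1, 0, 0), c(20, 80, 10, 90))
#' fit <- fit_logistic(y, d)
#' exp(fit$coefficients$estimate[fit$coefficients$term == "dosage"])  # 2.25
#' @export
fit_logistic <- function(case_status, design) {
  y <- as.integer(case_status)
  stopifnot(all(y %in% c(0L, 1L)), nrow(design) == length(y))
  if (sum(y) == 0 || sum(y) == length(y)) {
    return(list(tested = FALSE,
                reason = if (sum(y) == 0) "no cases" else "no controls",
                coefficients = NULL, converged = NA, separation = NA))
  }
  constant <- vapply(design, function(col) dplyr::n_distinct(col) < 2, logical(1))
  if (any(constant)) {
    stop(sprintf("singular design: constant column(s) %s",
                 paste(names(design)[constant], collapse = ", ")), call. = FALSE)
  }

  separation <- FALSE
  df <- cbind(data.frame(.y = y), design)
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (anyNA(stats::coef(fit))) {
    stop("singular design: aliased coefficients", call. = FALSE)
  }
  # glm's own check misses saturated designs (e.g. a 2x2 table with an empty
  # cell) where IRLS converges with divergent coefficients; fitted
  # probabilities this close to 0/1 mean the MLE does not exist
  if (any(fit$fitted.values < 1e-10 | fit$fitted.values > 1 - 1e-10)) {
    separation <- TRUE
  }
  sm <- summary(fit)$coefficients
  coefs <- tibble(
    term = rownames(sm),
    estimate = unname(sm[, "Estimate"]),
    std_error = unname(sm[, "Std. Error"]),
    p_value = unname(sm[, "Pr(>|z|)"])
  )
  if (separation || !fit$converged) {
    return(list(tested = FALSE,
                reason = if (separation) "separation" else "nonconvergence",
                coefficients = coefs, converged = fit$converged,
                separation = separation))
  }
  list(tested = TRUE, reason = NA_character_, coefficients = coefs,
       converged = TRUE, separation = FALSE)
}

#' Run a PheWAS across per-phecode cohorts
#'
#' For each phecode cohort with at least `min_cases` cases, fits case status
#' on allele dosage adjusted for the requested covariates, with excluded
#' patients dropped from that phecode's regression entirely. Race (and any
#' other factor covariate) is releveled to its largest category as
#' reference. The Bonferroni threshold is computed over tested phecodes
#' only.
#'
#' @param cohorts Named list of `case_control_cohort` objects (see
#'   [build_cohorts()]).
#' @param subjects Tibble with columns `patient_id`, `dosage` (0/1/2) and
#'   the covariate columns.
#' @param min_cases Minimum cases for a phecode to be tested (default 20,
#'   the common phenome-scan convention).
#' @param covariates Covariate column names (default age, sex, race); use
#'   `character(0)` for a crude model.
#' @param alpha Family-wise error target for the Bonferroni threshold
#'   (default 0.05).
#' @param map_id Optional label for the map the cohorts came from.
#' @return An object of class `phewas_run` with elements `results` (one row
#'   per phecode), `map_id`, `n_tested`, `bonferroni_alpha`, `min_cases`.
#' @export
run_phewas <- function(cohorts, subjects, min_cases = 20,
                       covariates = c("age", "sex", "race"),
                       alpha = 0.05, map_id = NULL) {
  if (length(cohorts) == 0) stop("no cohorts supplied", call. = FALSE)
  subjects <- as_tibble(subjects)
  missing <- setdiff(c("patient_id", "dosage", covariates), names(subjects))
  if (length(missing) > 0) {
    stop(sprintf("subjects missing column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  stopifnot(all(subjects$dosage %in% 0:2))
  # factor covariates: largest category as reference
  for (cv in covariates) {
    col <- subjects[[cv]]
    if (is.character(col) || is.factor(col)) {
      tab <- sort(table(col), decreasing = TRUE)
      subjects[[cv]] <- stats::relevel(factor(col), ref = names(tab)[1])
    }
  }

  rows <- purrr::map_dfr(cohorts, function(cohort) {
    ids <- c(cohort$cases, cohort$controls)
    dat <- dplyr::filter(subjects, .data$patient_id %in% ids)
    stopifnot(!any(dat$patient_id %in% cohort$excluded))  # exclusion audit
    y <- dat$patient_id %in% cohort$cases
    n_cases <- sum(y)
    n_controls <- sum(!y)
    base <- tibble(phecode = cohort$phecode, n_cases = n_cases,
                   n_controls = n_controls, beta = NA_real_, se = NA_real_,
                   or_ = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                   p = NA_real_, tested = FALSE, reason = NA_character_)
    if (n_cases < min_cases) {
      base$reason <- sprintf("fewer than %d cases", min_cases)
      return(base)
    }
    if (n_controls == 0) {
      base$reason <- "no controls"
      return(base)
    }
    design <- dat[, c("dosage", covariates), drop = FALSE]
    fit <- tryCatch(fit_logistic(y, design),
                    error = function(e) list(tested = FALSE,
                                             reason = conditionMessage(e),
                                             coefficients = NULL))
    if (!isTRUE(fit$tested)) {
      base$reason <- fit$reason
      return(base)
    }
    co <- dplyr::filter(fit$coefficients, .data$term == "dosage")
    base$beta <- co$estimate
    base$se <- co$std_error
    base$or_ <- exp(co$estimate)
    base$ci_lo <- exp(co$estimate - 1.96 * co$std_error)
    base$ci_hi <- exp(co$estimate + 1.96 * co$std_error)
    base$p <- co$p_value
    base$tested <- TRUE
    base
  })

  n_tested <- sum(rows$tested)
  if (n_tested == 0) {
    warning("no phecode passed the testing thresholds; Bonferroni threshold undefined",
            call. = FALSE)
  }
  structure(
    list(results = rows, map_id = map_id, n_tested = n_tested,
         bonferroni_alpha = if (n_tested > 0) alpha / n_tested else NA_real_,
         min_cases = min_cases, alpha = alpha),
    class = "phewas_run"
  )
}

#' @export
print.phewas_run <- function(x, ...) {
  cat(sprintf("<phewas_run>%s %d phecodes, %d tested, Bonferroni alpha %s\n",
              if (!is.null(x$map_id)) paste0(" [", x$map_id, "]") else "",
              nrow(x$results), x$n_tested,
              format(x$bonferroni_alpha, digits = 3)))
  sig <- dplyr::filter(x$results, .data$tested, .data$p < x$bonferroni_alpha)
  if (nrow(sig) > 0) {
    cat(sprintf("  %d phenome-wide significant hit(s); top: phecode %s (OR %.2f, p %.2e)\n",
                nrow(sig), sig$phecode[which.min(sig$p)],
                sig$or_[which.min(sig$p)], min(sig$p)))
  }
  invisible(x)
}

#' @describeIn run_phewas Per-phecode results as a tibble.
#' @param x A `phewas_run`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.phewas_run <- function(x, ...) x$results

#' @describeIn run_phewas One-row scan summary.
#' @exportS3Method generics::glance
glance.phewas_run <- function(x, ...) {
  tested <- dplyr::filter(x$results, .data$tested)
  sig <- dplyr::filter(tested, .data$p < x$bonferroni_alpha)
  tibble(
    n_phecodes = nrow(x$results),
    n_tested = x$n_tested,
    bonferroni_alpha = x$bonferroni_alpha,
    n_significant = nrow(sig),
    top_phecode = if (nrow(tested) > 0) tested$phecode[which.min(tested$p)] else NA_character_,
    min_p = if (nrow(tested) > 0) min(tested$p) else NA_real_
  )
}

#' Manhattan-style plot of a PheWAS run
#'
#' @param object A `phewas_run`.
#' @param ... Unused.
#' @return A ggplot object: -log10 p per phecode with the Bonferroni line.
#' @exportS3Method ggplot2::autoplot
autoplot.phewas_run <- function(object, ...) {
  df <- dplyr::filter(object$results, .data$tested) |>
    dplyr::mutate(phecode_num = as.numeric(.data$phecode),
                  direction = ifelse(.data$beta >= 0, "risk", "protective"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phecode_num,
                                   y = -log10(.data$p),
                                   shape = .data$direction)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(object$bonferroni_alpha),
                        linetype = "dashed") +
    ggplot2::labs(x = "phecode", y = expression(-log[10](p)),
                  title = object$map_id %||% "PheWAS") +
    ggplot2::theme_minimal()
}

#' Compare two PheWAS runs phecode by phecode
#'
#' Joins the per-phecode estimates of two runs over the same subjects (for
#' example one run per coding-era map) for the phecodes tested in both, and
#' summarises concordance: among phecodes Bonferroni-significant in both
#' runs, the fraction whose effect directions agree.
#'
#' @param run_a,run_b `phewas_run` objects.
#' @return A tibble with per-phecode columns suffixed `_a`/`_b` and a
#'   `concordance` attribute (list: `n_common`, `n_significant_both`,
#'   `sign_agreement`).
#' @export
compare_runs <- function(run_a, run_b) {
  a <- dplyr::filter(run_a$results, .data$tested)
  b <- dplyr::filter(run_b$results, .data$tested)
  common <- dplyr::inner_join(a, b, by = "phecode", suffix = c("_a", "_b"))
  if (nrow(common) == 0) {
    warning("runs share no tested phecodes", call. = FALSE)
    attr(common, "concordance") <- list(n_common = 0L,
                                        n_significant_both = 0L,
                                        sign_agreement = NA_real_)
    return(common)
  }
  sig_both <- common$p_a < run_a$bonferroni_alpha &
    common$p_b < run_b$bonferroni_alpha
  agreement <- if (any(sig_both)) {
    mean(sign(common$beta_a[sig_both]) == sign(common$beta_b[sig_both]))
  } else {
    NA_real_
  }
  attr(common, "concordance") <- list(
    n_common = nrow(common),
    n_significant_both = sum(sig_both),
    sign_agreement = agreement
  )
  common
}
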