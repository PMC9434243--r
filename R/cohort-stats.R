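#' Exposures recognised by the association pipeline
#'
#' `"any_osteophyte"` (maximum grade over the three sites),
#' `"op_all_sites"` (all three sites grade >= 1), the three per-site
#' osteophyte exposures, `"jsn"` and `"rhoa"`.
#' @return Character vector of exposure names.
#' @export
rhoa_exposures <- function() {
  c("any_osteophyte", "acetabular", "superior_femoral", "inferior_femoral",
    "op_all_sites", "jsn", "rhoa")
}

exposure_grade <- function(cohort, exposure) {
  switch(exposure,
    acetabular = cohort$osteophyte_grade_acetabular,
    superior_femoral = cohort$osteophyte_grade_superior,
    inferior_femoral = cohort$osteophyte_grade_inferior,
    jsn = cohort$jsn_grade,
    rhoa = cohort$rhoa_grade,
    any_osteophyte = pmax(cohort$osteophyte_grade_acetabular,
                          cohort$osteophyte_grade_superior,
                          cohort$osteophyte_grade_inferior),
    op_all_sites = as.integer(cohort$osteophyte_grade_acetabular >= 1 &
                              cohort$osteophyte_grade_superior >= 1 &
                              cohort$osteophyte_grade_inferior >= 1),
    abort(sprintf("unknown exposure '%s'", exposure), class = "rhoadx_key_error"))
}

# Shared front half of the logistic/Cox fitters: stratum filter, contrast
# subset (grade k vs grade 0, or grade >= 1 vs 0), complete cases.
prepare_contrast <- function(cohort, exposure, level, stratum, adjust,
                             outcome_cols) {
  stratum <- match.arg(stratum, c("all", "male", "female"))
  exposure <- match.arg(exposure, rhoa_exposures())
  if (stratum != "all") cohort <- dplyr::filter(cohort, .data$sex == stratum)
  g <- exposure_grade(cohort, exposure)
  if (identical(level, "ge1")) {
    keep <- !is.na(g)
    x <- as.integer(g[keep] >= 1)
  } else {
    level <- as.integer(level)
    if (is.na(level) || level < 1L) {
      abort("level must be 'ge1' or a positive grade", class = "rhoadx_domain_error")
    }
    keep <- !is.na(g) & g %in% c(0L, level)
    x <- as.integer(g[keep] == level)
  }
  dat <- cohort[keep, , drop = FALSE]
  dat$.x <- x
  covars <- if (adjust) {
    c("age", "height_cm", "weight_kg", if (stratum == "all") "sex")
  } else {
    character()
  }
  cc <- stats::complete.cases(dat[, c(".x", outcome_cols, covars), drop = FALSE])
  n_dropped <- sum(!cc)
  if (n_dropped > 0) {
    inform(sprintf("complete-case analysis: %d record(s) dropped for missingness",
                   n_dropped))
  }
  list(data = dat[cc, , drop = FALSE], covars = covars, stratum = stratum,
       exposure = exposure, level = if (identical(level, "ge1")) "ge1" else level,
       n_dropped = n_dropped)
}

rhs_formula <- function(covars) {
  paste(c(".x", covars), collapse = " + ")
}

new_rhoa_assoc <- function(fit, ctx, outcome, model_type, n, n_events) {
  est <- coef(fit)[[".x"]]
  se <- sqrt(vcov(fit)[".x", ".x"])
  structure(
    list(fit = fit, exposure = ctx$exposure, level = ctx$level, outcome = outcome,
         model = model_type, stratum = ctx$stratum,
         adjusted = length(ctx$covars) > 0,
         adjustment_set = ctx$covars,
         estimate = exp(est), ci_low = exp(est - qnorm(0.975) * se),
         ci_high = exp(est + qnorm(0.975) * se),
         p_value = 2 * pnorm(abs(est / se), lower.tail = FALSE),
         n = n, n_events = n_events, n_dropped = ctx$n_dropped),
    class = "rhoa_assoc"
  )
}

#' Logistic association between an exposure and a binary outcome
#'
#' Maximum-likelihood logistic regression of the outcome on an exposure
#' indicator, optionally adjusted for age, height, weight and (in the
#' combined stratum) sex. The reference group is grade 0 for that exposure;
#' for a single-grade contrast (`level = k`) records at other grades are
#' excluded. Effects are returned as odds ratios with Wald 95% CIs.
#'
#' @param cohort A graded cohort tibble (see [simulate_cohort()] for the
#'   column contract).
#' @param exposure One of [rhoa_exposures()].
#' @param outcome `"hip_pain"` or `"hes_oa"`.
#' @param level `"ge1"` (grade >= 1 vs grade 0) or a single grade to
#'   contrast against grade 0.
#' @param adjust Adjust for age, height, weight (+ sex when unstratified)?
#' @param stratum `"all"`, `"male"` or `"female"`.
#' @return An object of class `rhoa_assoc`; see [tidy.rhoa_assoc()].
#' @export
fit_exposure_logistic <- function(cohort, exposure, outcome = c("hip_pain", "hes_oa"),
                                  level = "ge1", adjust = TRUE, stratum = "all") {
  outcome <- match.arg(outcome)
  ctx <- prepare_contrast(cohort, exposure, level, stratum, adjust, outcome)
  d <- ctx$data
  y <- d[[outcome]]
  cells <- table(factor(d$.x, levels = 0:1), factor(y, levels = 0:1))
  if (any(cells == 0)) {
    abort(sprintf(
      "non-estimable contrast %s[%s] vs 0 for %s (%s): empty exposure/outcome cell",
      ctx$exposure, ctx$level, outcome, ctx$stratum),
      class = "rhoadx_nonestimable")
  }
  fml <- stats::as.formula(paste(outcome, "~", rhs_formula(ctx$covars)))
  fit <- glm(fml, family = binomial(), data = d)
  new_rhoa_assoc(fit, ctx, outcome, "logistic", n = nrow(d), n_events = sum(y))
}

#' Cox proportional-hazards association with total hip replacement
#'
#' Partial-likelihood Cox model of time from scan to THR (administratively
#' censored) on an exposure indicator, Efron tie handling, Wald 95% CIs on
#' the hazard ratio. Same contrast construction as
#' [fit_exposure_logistic()].
#'
#' @inheritParams fit_exposure_logistic
#' @return An object of class `rhoa_assoc`.
#' @export
fit_exposure_cox <- function(cohort, exposure, level = "ge1", adjust = TRUE,
                             stratum = "all") {
  ctx <- prepare_contrast(cohort, exposure, level, stratum, adjust,
                          c("thr_event", "followup_days"))
  d <- ctx$data
  ev <- tapply(d$thr_event, factor(d$.x, levels = 0:1), sum)
  if (any(is.na(ev)) || any(ev == 0)) {
    abort(sprintf(
      "non-estimable contrast %s[%s] vs 0 for thr (%s): no events in a group",
      ctx$exposure, ctx$level, ctx$stratum),
      class = "rhoadx_nonestimable")
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(followup_days, thr_event) ~", rhs_formula(ctx$covars)))
  fit <- survival::coxph(fml, data = d, ties = "efron")
  new_rhoa_assoc(fit, ctx, "thr", "cox", n = nrow(d), n_events = sum(d$thr_event))
}

#' @export
print.rhoa_assoc <- function(x, ...) {
  cat(sprintf(
    "<rhoa_assoc: %s[%s] vs 0 -> %s (%s, %s, %s)>\n  %s %.3f [%.3f, %.3f], p = %.3g, n = %d (%d events)\n",
    x$exposure, x$level, x$outcome, x$model, x$stratum,
    if (x$adjusted) "adjusted" else "unadjusted",
    if (x$model == "cox") "HR" else "OR",
    x$estimate, x$ci_low, x$ci_high, x$p_value, x$n, x$n_events))
  invisible(x)
}

#' Tidy an association fit
#'
#' @param x A `rhoa_assoc` object.
#' @param ... Unused.
#' @return A one-row tibble: exposure, level, outcome, model, stratum,
#'   adjusted, estimate (OR or HR), ci_low, ci_high, p_value.
#' @export
tidy.rhoa_assoc <- function(x, ...) {
  tibble::tibble(
    exposure = x$exposure, level = as.character(x$level), outcome = x$outcome,
    model = x$model, stratum = x$stratum, adjusted = x$adjusted,
    estimate = x$estimate, ci_low = x$ci_low, ci_high = x$ci_high,
    p_value = x$p_value)
}

#' Model-level summary of an association fit
#'
#' @param x A `rhoa_assoc` object.
#' @param ... Unused.
#' @return A one-row tibble: n, n_events, n_dropped, adjustment_set,
#'   converged.
#' @export
glance.rhoa_assoc <- function(x, ...) {
  conv <- if (inherits(x$fit, "glm")) x$fit$converged else TRUE
  tibble::tibble(
    n = x$n, n_events = x$n_events, n_dropped = x$n_dropped,
    adjustment_set = paste(x$adjustment_set, collapse = "+"),
    converged = conv)
}

#' Sex-interaction test for an exposure-outcome association
#'
#' Adds an exposure-by-sex product term to the adjusted combined-sexes model
#' and reports its Wald p-value. Following common practice for interaction
#' screens, the flag threshold is p < 0.1; when flagged, sex-stratified
#' fits are attached.
#'
#' @inheritParams fit_exposure_logistic
#' @param outcome `"hip_pain"`, `"hes_oa"` (logistic) or `"thr"` (Cox).
#' @param threshold Flag threshold on the interaction p-value.
#' @return List with `p_value`, `flag`, and (when flagged) `stratified`, a
#'   tibble of male/female [tidy.rhoa_assoc()] rows.
#' @export
sex_interaction <- function(cohort, exposure, outcome, level = "ge1",
                            threshold = 0.1) {
  outcome <- match.arg(outcome, c("hip_pain", "hes_oa", "thr"))
  if (length(unique(cohort$sex)) < 2L) {
    abort("sex interaction requires both sexes in the cohort",
          class = "rhoadx_nonestimable")
  }
  outcome_cols <- if (outcome == "thr") c("thr_event", "followup_days") else outcome
  ctx <- prepare_contrast(cohort, exposure, level, "all", TRUE, outcome_cols)
  d <- ctx$data
  d$.female <- as.integer(d$sex == "female")
  rhs <- paste(c(".x", ".x:.female", "age", "height_cm", "weight_kg", ".female"),
               collapse = " + ")
  if (outcome == "thr") {
    fit <- survival::coxph(
      stats::as.formula(paste("survival::Surv(followup_days, thr_event) ~", rhs)),
      data = d, ties = "efron")
  } else {
    fit <- glm(stats::as.formula(paste(outcome, "~", rhs)),
               family = binomial(), data = d)
  }
  term <- grep(":", names(coef(fit)), value = TRUE)[1]
  est <- coef(fit)[[term]]
  se <- sqrt(vcov(fit)[term, term])
  p <- 2 * pnorm(abs(est / se), lower.tail = FALSE)
  flag <- is.finite(p) && p < threshold
  strat <- NULL
  if (flag) {
    fit_one <- function(sx) {
      r <- if (outcome == "thr") {
        fit_exposure_cox(cohort, exposure, level = level, stratum = sx)
      } else {
        fit_exposure_logistic(cohort, exposure, outcome, level = level, stratum = sx)
      }
      tidy(r)
    }
    strat <- dplyr::bind_rows(fit_one("male"), fit_one("female"))
  }
  list(p_value = p, flag = flag, stratified = strat)
}

#' Tabulate cohort prevalences
#'
#' Counts and percentages (1 decimal place, 100 * count / N) of the clinical
#' outcomes, grade >= 1 endophenotypes and the composite rHOA grade
#' distribution, overall and by sex.
#'
#' @param cohort A graded cohort tibble.
#' @param strata Strata to tabulate (subset of `"all"`, `"male"`,
#'   `"female"`).
#' @return A tibble: `measure`, `level`, `stratum`, `count`, `n`, `pct`.
#' @export
tabulate_prevalence <- function(cohort, strata = c("all", "male", "female")) {
  if (nrow(cohort) == 0L) {
    abort("empty cohort", class = "rhoadx_empty_input")
  }
  strata <- match.arg(strata, several.ok = TRUE)
  one <- function(stratum) {
    d <- if (stratum == "all") cohort else dplyr::filter(cohort, .data$sex == stratum)
    n <- nrow(d)
    row <- function(measure, level, count) {
      tibble::tibble(measure = measure, level = level, stratum = stratum,
                     count = as.integer(count), n = n,
                     pct = round(100 * count / n, 1))
    }
    out <- list(
      row("hip_pain", "1", sum(d$hip_pain, na.rm = TRUE)),
      row("hes_oa", "1", sum(d$hes_oa, na.rm = TRUE)),
      row("thr_event", "1", sum(d$thr_event, na.rm = TRUE)))
    for (e in setdiff(rhoa_exposures(), "rhoa")) {
      g <- exposure_grade(d, e)
      if (all(is.na(g))) next
      out[[length(out) + 1L]] <- row(e, "ge1", sum(g >= 1, na.rm = TRUE))
    }
    for (g in 0:4) {
      out[[length(out) + 1L]] <-
        row("rhoa_grade", as.character(g), sum(d$rhoa_grade == g, na.rm = TRUE))
    }
    dplyr::bind_rows(out)
  }
  purrr::map_dfr(strata, one)
}

#' Run the full association analysis
#'
#' Fits every exposure-outcome contrast of the standard analysis: grade >= 1
#' for each of the six endophenotype exposures, single-grade contrasts
#' (1-3 for endophenotypes, 1-4 for the composite grade), each against
#' hip pain and hospital-diagnosed OA (logistic) and THR (Cox), unadjusted
#' and adjusted, in the requested strata. Sex-interaction p-values are
#' attached to the adjusted combined-stratum rows. Non-estimable cells are
#' reported with NA estimates and the reason, never dropped.
#'
#' @param cohort A graded cohort tibble.
#' @param adjusted Logical vector of adjustment settings to run.
#' @param strata Strata to run.
#' @param levels Include single-grade contrasts?
#' @param interactions Compute sex-interaction p-values?
#' @return A tibble of class `rhoa_analysis`: one row per contrast with
#'   estimate, Wald 95% CI, p-value, `interaction_p` and `note` (reason for
#'   any non-estimable cell). Row order is deterministic.
#' @export
run_full_analysis <- function(cohort, adjusted = c(FALSE, TRUE),
                              strata = c("all", "male", "female"),
                              levels = TRUE, interactions = TRUE) {
  endo <- c("any_osteophyte", "acetabular", "superior_femoral",
            "inferior_femoral", "op_all_sites", "jsn")
  grid <- list()
  add <- function(exposure, level) {
    grid[[length(grid) + 1L]] <<- list(exposure = exposure, level = level)
  }
  for (e in endo) add(e, "ge1")
  if (levels) {
    for (e in setdiff(endo, c("any_osteophyte", "op_all_sites"))) {
      for (k in 1:3) add(e, k)
    }
    for (k in 1:4) add("rhoa", k)
  }
  outcomes <- c("hip_pain", "hes_oa", "thr")
  rows <- list()
  for (cell in grid) {
    for (outc in outcomes) {
      int_p <- NA_real_
      if (interactions && "all" %in% strata) {
        # screening term only: convergence chatter is not informative here
        int_p <- tryCatch(
          suppressWarnings(
            sex_interaction(cohort, cell$exposure, outc,
                            level = cell$level)$p_value),
          error = function(e) NA_real_)
      }
      for (adj in adjusted) {
        for (st in strata) {
          wmsg <- character() # fit warnings (e.g. monotone likelihood) -> note
          res <- tryCatch(withCallingHandlers({
            f <- if (outc == "thr") {
              fit_exposure_cox(cohort, cell$exposure, level = cell$level,
                               adjust = adj, stratum = st)
            } else {
              fit_exposure_logistic(cohort, cell$exposure, outc,
                                    level = cell$level, adjust = adj, stratum = st)
            }
            r <- tidy(f)
            r$note <- if (length(wmsg)) {
              paste(unique(wmsg), collapse = "; ")
            } else {
              NA_character_
            }
            r
          }, warning = function(w) {
            wmsg <<- c(wmsg, trimws(conditionMessage(w)))
            invokeRestart("muffleWarning")
          }), error = function(e) {
            tibble::tibble(
              exposure = cell$exposure, level = as.character(cell$level),
              outcome = outc, model = if (outc == "thr") "cox" else "logistic",
              stratum = st, adjusted = adj, estimate = NA_real_,
              ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_,
              note = conditionMessage(e))
          })
          res$interaction_p <- if (adj && st == "all") int_p else NA_real_
          rows[[length(rows) + 1L]] <- res
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("rhoa_analysis", class(out))
  out
}
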