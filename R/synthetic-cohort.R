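#' Specification for a synthetic cohort
#'
#' Describes a population resembling a large DXA-scanned adult cohort:
#' truncated-normal demographics, per-sex endophenotype prevalences, and
#' outcome models whose intercepts (logistic) and baseline hazard (Cox /
#' exponential) are calibrated at simulation time so the requested marginal
#' prevalences are met in expectation given the realised covariates and
#' exposures.
#'
#' Two exposure models are available. `"components"` simulates per-site
#' osteophyte grades and the JSN grade from a shared latent severity
#' (Gaussian copula with correlation `site_correlation`, per-sex probit
#' thresholds with a linear age shift, thresholds solved numerically so the
#' per-sex grade >= 1 prevalences hit their targets); the composite rHOA
#' grade then follows from the configured sum-to-grade map. `"rhoa"` draws
#' the composite grade directly from `rhoa_probs` — used when an analysis
#' needs the composite-grade distribution pinned exactly (per-site grades
#' are not generated in that mode).
#'
#' Effect sizes enter on the log-odds (logistic outcomes) or log-hazard
#' (THR) scale as named vectors; names refer to exposure indicator columns
#' of the simulated cohort: `any_osteophyte`, `acetabular`,
#' `superior_femoral`, `inferior_femoral`, `op_all_sites`, `jsn` (each
#' grade >= 1), or `rhoa_grade1` .. `rhoa_grade4`. All effects default to
#' zero (a null generator).
#'
#' @param n Cohort size.
#' @param seed Integer seed; the cohort is deterministic given the spec.
#' @param sex_fraction_female Probability a participant is female.
#' @param age,height,weight Distribution parameters. `age` is a list
#'   `(mean, sd, min, max)`; `height` and `weight` are per-sex lists of the
#'   same shape.
#' @param exposure_model `"components"` or `"rhoa"` (see Details).
#' @param prevalence Per-sex grade >= 1 prevalence targets for the three
#'   osteophyte sites and JSN (named lists with `male`, `female`).
#' @param grade_conditional Probabilities of grades 1..3 given grade >= 1,
#'   for osteophytes and for JSN.
#' @param site_correlation Latent correlation shared by the four
#'   endophenotype indicators (0..1).
#' @param age_probit_slope Latent-threshold shift per year of age.
#' @param rhoa_probs Probabilities of composite grades 0..4 for the
#'   `"rhoa"` exposure model.
#' @param hip_pain,hes_oa Logistic outcome models: lists with `prevalence`,
#'   `effects` (named log-OR vector), `covariates` (named log-OR per unit
#'   of centred age/height/weight or female sex) and optionally
#'   `sex_specific`, a list with `male`/`female` named effect vectors added
#'   on top of the common `effects`.
#' @param thr Time-to-event model: list with `event_fraction`, `effects`
#'   (named log-HR vector), `covariates`, and administrative censoring
#'   bounds `censor_min_days`, `censor_max_days` (uniform entry staggering).
#' @return An object of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(
    n = 40340, seed = 1L,
    sex_fraction_female = 0.522,
    age = list(mean = 63.7, sd = 7.5, min = 44, max = 82),
    height = list(male = list(mean = 177.2, sd = 6.8, min = 150, max = 204),
                  female = list(mean = 163.6, sd = 6.2, min = 135, max = 198)),
    weight = list(male = list(mean = 83.2, sd = 13, min = 47, max = 171),
                  female = list(mean = 68.2, sd = 12.5, min = 34, max = 169)),
    exposure_model = c("components", "rhoa"),
    prevalence = list(acetabular = list(male = 0.080, female = 0.049),
                      superior_femoral = list(male = 0.051, female = 0.024),
                      inferior_femoral = list(male = 0.042, female = 0.012),
                      jsn = list(male = 0.155, female = 0.075)),
    grade_conditional = list(osteophyte = c(0.55, 0.35, 0.10),
                             jsn = c(0.70, 0.22, 0.08)),
    site_correlation = 0.45,
    age_probit_slope = 0.03,
    rhoa_probs = c(32758, 4565, 2317, 543, 157) / 40340,
    hip_pain = list(prevalence = 0.081, effects = numeric(),
                    covariates = c(age = 0.02, sex_female = 0.5,
                                   height_cm = 0, weight_kg = 0.01)),
    hes_oa = list(prevalence = 0.013, effects = numeric(),
                  covariates = c(age = 0.05, sex_female = 0.3,
                                 height_cm = 0, weight_kg = 0.01)),
    thr = list(event_fraction = 0.006, effects = numeric(),
               covariates = c(age = 0.04, sex_female = 0.1,
                              height_cm = 0, weight_kg = 0.01),
               censor_min_days = 3, censor_max_days = 2437)) {
  exposure_model <- match.arg(exposure_model)
  if (n <= 0) abort("n must be positive", class = "rhoadx_domain_error")
  if (sex_fraction_female <= 0 || sex_fraction_female >= 1) {
    abort("sex_fraction_female must be in (0, 1)", class = "rhoadx_domain_error")
  }
  probs <- unlist(prevalence)
  if (any(probs <= 0 | probs >= 1)) {
    abort("prevalence targets must be in (0, 1)", class = "rhoadx_domain_error")
  }
  if (abs(sum(rhoa_probs) - 1) > 1e-8 || length(rhoa_probs) != 5L) {
    abort("rhoa_probs must be 5 probabilities summing to 1",
          class = "rhoadx_domain_error")
  }
  if (site_correlation < 0 || site_correlation >= 1) {
    abort("site_correlation must be in [0, 1)", class = "rhoadx_domain_error")
  }
  structure(
    list(n = as.integer(n), seed = as.integer(seed),
         sex_fraction_female = sex_fraction_female, age = age, height = height,
         weight = weight, exposure_model = exposure_model,
         prevalence = prevalence, grade_conditional = grade_conditional,
         site_correlation = site_correlation, age_probit_slope = age_probit_slope,
         rhoa_probs = rhoa_probs, hip_pain = hip_pain, hes_oa = hes_oa, thr = thr),
    class = "synthetic_cohort_spec"
  )
}

#' Simulate a graded cohort
#'
#' Draws demographics, endophenotype grades, composite rHOA grade and the
#' three clinical outcomes (hip pain, hospital-diagnosed hip OA, total hip
#' replacement with follow-up) from a [synthetic_cohort_spec()].
#'
#' @param spec A [synthetic_cohort_spec()].
#' @param cfg A [grading_config()] supplying the composite sum-to-grade map.
#' @return A tibble with one row per participant: `id`, `age`, `sex`,
#'   `height_cm`, `weight_kg`, per-site osteophyte grades, `jsn_grade`,
#'   `grade_sum`, `rhoa_grade`, `hip_pain`, `hes_oa`, `thr_event`,
#'   `followup_days`. The spec is attached as attribute `"spec"`.
#' @examples
#' coh <- simulate_cohort(synthetic_cohort_spec(n = 2000, seed = 7))
#' mean(coh$hip_pain)
#' @export
simulate_cohort <- function(spec, cfg = grading_config()) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n
    female <- rbinom(n, 1, spec$sex_fraction_female) == 1
    sex <- ifelse(female, "female", "male")
    age <- rtruncnorm(n, spec$age$mean, spec$age$sd, spec$age$min, spec$age$max)
    height <- numeric(n); weight <- numeric(n)
    for (s in c("male", "female")) {
      i <- sex == s
      height[i] <- rtruncnorm(sum(i), spec$height[[s]]$mean, spec$height[[s]]$sd,
                              spec$height[[s]]$min, spec$height[[s]]$max)
      weight[i] <- rtruncnorm(sum(i), spec$weight[[s]]$mean, spec$weight[[s]]$sd,
                              spec$weight[[s]]$min, spec$weight[[s]]$max)
    }
    coh <- tibble::tibble(
      id = sprintf("S%06d", seq_len(n)), age = age, sex = sex,
      height_cm = height, weight_kg = weight)
    coh <- if (spec$exposure_model == "components") {
      simulate_component_grades(coh, spec, cfg)
    } else {
      simulate_rhoa_grades(coh, spec)
    }
    ind <- exposure_indicators(coh)
    coh$hip_pain <- simulate_logistic_outcome(coh, ind, spec$hip_pain)
    coh$hes_oa <- simulate_logistic_outcome(coh, ind, spec$hes_oa)
    thr <- simulate_thr_outcome(coh, ind, spec$thr)
    coh$thr_event <- thr$event
    coh$followup_days <- thr$followup_days
    attr(coh, "spec") <- spec
    coh
  })
}

rtruncnorm <- function(n, mean, sd, min, max) {
  lo <- pnorm(min, mean, sd); hi <- pnorm(max, mean, sd)
  qnorm(runif(n, lo, hi), mean, sd)
}

# Shared-latent (Gaussian copula) endophenotype presence, then conditional
# grade draws; probit thresholds solved per sex for the target prevalence
# given the realised age distribution.
simulate_component_grades <- function(coh, spec, cfg) {
  n <- nrow(coh)
  rho <- spec$site_correlation
  z <- rnorm(n)
  c_age <- spec$age_probit_slope * (coh$age - spec$age$mean)
  draw_site <- function(targets, cond) {
    u <- sqrt(rho) * z + sqrt(1 - rho) * rnorm(n)
    present <- logical(n)
    for (s in c("male", "female")) {
      i <- coh$sex == s
      f <- function(q) mean(pnorm(q - c_age[i], lower.tail = FALSE)) - targets[[s]]
      q <- uniroot(f, c(-8, 8), tol = 1e-10)$root
      present[i] <- u[i] > q - c_age[i]
    }
    grade <- integer(n)
    grade[present] <- sample.int(3L, sum(present), replace = TRUE, prob = cond)
    grade
  }
  coh$osteophyte_grade_acetabular <-
    draw_site(spec$prevalence$acetabular, spec$grade_conditional$osteophyte)
  coh$osteophyte_grade_superior <-
    draw_site(spec$prevalence$superior_femoral, spec$grade_conditional$osteophyte)
  coh$osteophyte_grade_inferior <-
    draw_site(spec$prevalence$inferior_femoral, spec$grade_conditional$osteophyte)
  coh$jsn_grade <- draw_site(spec$prevalence$jsn, spec$grade_conditional$jsn)
  coh$grade_sum <- coh$osteophyte_grade_acetabular + coh$osteophyte_grade_superior +
    coh$osteophyte_grade_inferior + coh$jsn_grade
  coh$rhoa_grade <- cfg$composite_cuts[coh$grade_sum + 1L]
  coh
}

simulate_rhoa_grades <- function(coh, spec) {
  n <- nrow(coh)
  coh$osteophyte_grade_acetabular <- NA_integer_
  coh$osteophyte_grade_superior <- NA_integer_
  coh$osteophyte_grade_inferior <- NA_integer_
  coh$jsn_grade <- NA_integer_
  coh$grade_sum <- NA_integer_
  coh$rhoa_grade <- sample(0:4, n, replace = TRUE, prob = spec$rhoa_probs)
  coh
}

# 0/1 indicator columns the effect vectors may reference.
exposure_indicators <- function(coh) {
  out <- tibble::tibble(.rows = nrow(coh))
  if (!all(is.na(coh$osteophyte_grade_acetabular))) {
    out$acetabular <- as.integer(coh$osteophyte_grade_acetabular >= 1)
    out$superior_femoral <- as.integer(coh$osteophyte_grade_superior >= 1)
    out$inferior_femoral <- as.integer(coh$osteophyte_grade_inferior >= 1)
    out$any_osteophyte <- as.integer(out$acetabular | out$superior_femoral |
                                       out$inferior_femoral)
    out$op_all_sites <- as.integer(out$acetabular & out$superior_femoral &
                                     out$inferior_femoral)
    out$jsn <- as.integer(coh$jsn_grade >= 1)
  }
  for (g in 1:4) out[[paste0("rhoa_grade", g)]] <- as.integer(coh$rhoa_grade == g)
  out
}

linear_predictor <- function(coh, ind, model) {
  eta <- numeric(nrow(coh))
  eff <- model$effects
  if (length(eff)) {
    missing <- setdiff(names(eff), names(ind))
    if (length(missing)) {
      abort(sprintf("unknown exposure effect name(s): %s (available: %s)",
                    paste(missing, collapse = ", "),
                    paste(names(ind), collapse = ", ")),
            class = "rhoadx_key_error")
    }
    for (nm in names(eff)) eta <- eta + eff[[nm]] * ind[[nm]]
  }
  if (!is.null(model$sex_specific)) {
    for (s in c("male", "female")) {
      eff_s <- model$sex_specific[[s]]
      if (is.null(eff_s)) next
      i <- coh$sex == s
      for (nm in names(eff_s)) {
        if (!nm %in% names(ind)) {
          abort(sprintf("unknown sex-specific effect name '%s'", nm),
                class = "rhoadx_key_error")
        }
        eta[i] <- eta[i] + eff_s[[nm]] * ind[[nm]][i]
      }
    }
  }
  cv <- model$covariates %||% numeric()
  centred <- list(age = coh$age - mean(coh$age),
                  sex_female = as.integer(coh$sex == "female"),
                  height_cm = coh$height_cm - mean(coh$height_cm),
                  weight_kg = coh$weight_kg - mean(coh$weight_kg))
  for (nm in intersect(names(cv), names(centred))) {
    eta <- eta + cv[[nm]] * centred[[nm]]
  }
  eta
}

simulate_logistic_outcome <- function(coh, ind, model) {
  eta <- linear_predictor(coh, ind, model)
  f <- function(b0) mean(plogis(b0 + eta)) - model$prevalence
  if (f(-30) > 0 || f(30) < 0) {
    abort("logistic intercept calibration failed: target prevalence unattainable",
          class = "rhoadx_calibration_error")
  }
  b0 <- uniroot(f, c(-30, 30), tol = 1e-12)$root
  rbinom(nrow(coh), 1, plogis(b0 + eta))
}

simulate_thr_outcome <- function(coh, ind, model) {
  eta <- linear_predictor(coh, ind, model)
  cens <- runif(nrow(coh), model$censor_min_days, model$censor_max_days)
  f <- function(l0) mean(1 - exp(-exp(l0 + eta) * cens)) - model$event_fraction
  if (f(-40) > 0 || f(5) < 0) {
    abort("THR baseline-rate calibration failed: target event fraction unattainable",
          class = "rhoadx_calibration_error")
  }
  l0 <- uniroot(f, c(-40, 5), tol = 1e-12)$root
  t_event <- rexp(nrow(coh), rate = exp(l0 + eta))
  event <- t_event <= cens
  list(event = as.integer(event),
       followup_days = pmax(1L, as.integer(round(pmin(t_event, cens)))))
}
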