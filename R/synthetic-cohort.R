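#' Cohort simulation parameters
#'
#' Bundles everything the cohort generator needs: the cohort size, the
#' fraction (or exact count) of children with severe OSA (obstructive
#' AHI >= 10 events/h), and severity-conditional median/IQR targets for each
#' clinical and home-sleep-apnea-test feature. Continuous features are
#' specified as `c(median, q25, q75)` and drawn from quantile-matched
#' two-piece distributions ([qdist()]); tonsil grade is drawn from a
#' categorical distribution over grades 1-4 whose probabilities reproduce
#' the requested quartiles.
#'
#' @param n_patients cohort size (>= 2).
#' @param prevalence_severe fraction of severe OSA in \[0, 1\].
#' @param mode `"quota"` (exact group sizes, `round(n * prevalence)`) or
#'   `"bernoulli"` (independent severity draws).
#' @param age_range inclusive integer age bounds in years.
#' @param sex_male_frac per-group probability of male sex,
#'   `c(severe, non_severe)`.
#' @param features named list; each element is a list with per-group
#'   `severe` / `non_severe` entries of `c(median, q25, q75)` plus a
#'   `transform` (and optional `lower` / `upper` bounds).
#' @param tonsil_probs list with `severe` and `non_severe` probability
#'   vectors over grades 1:4.
#' @param ahi severity-conditional AHI targets, same shape as `features`
#'   entries; draws are truncated at 10 events/h so labels stay consistent.
#' @return a `cohort_params` object.
#' @seealso [cohort_params_study1()], [cohort_params_study2()],
#'   [generate_cohort()]
#' @export
cohort_params <- function(n_patients,
                          prevalence_severe,
                          mode = c("quota", "bernoulli"),
                          age_range = c(5L, 12L),
                          sex_male_frac = c(severe = 18 / 21, non_severe = 12 / 18),
                          features = default_feature_targets(),
                          tonsil_probs = default_tonsil_probs(),
                          ahi = default_ahi_targets()) {
  mode <- match.arg(mode)
  if (!is.numeric(n_patients) || n_patients < 2) {
    stop("n_patients must be >= 2", call. = FALSE)
  }
  if (prevalence_severe < 0 || prevalence_severe > 1) {
    stop("prevalence_severe must be in [0, 1]", call. = FALSE)
  }
  if (any(sex_male_frac < 0 | sex_male_frac > 1)) {
    stop("sex_male_frac entries must be in [0, 1]", call. = FALSE)
  }
  for (nm in names(features)) {
    for (grp in c("severe", "non_severe")) {
      q <- features[[nm]][[grp]]
      if (!(q[2] <= q[1] && q[1] <= q[3])) {
        stop(sprintf("feature '%s' (%s): need q25 <= median <= q75", nm, grp),
             call. = FALSE)
      }
    }
  }
  for (grp in c("severe", "non_severe")) {
    p <- tonsil_probs[[grp]]
    if (length(p) != 4 || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop("tonsil_probs must be length-4 probability vectors", call. = FALSE)
    }
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      prevalence_severe = prevalence_severe,
      mode = mode,
      age_range = as.integer(age_range),
      sex_male_frac = sex_male_frac,
      features = features,
      tonsil_probs = tonsil_probs,
      ahi = ahi
    ),
    class = "cohort_params"
  )
}

#' Default severity-conditional feature targets (discovery-cohort structure)
#'
#' Median and quartiles per severity group for the features the screening
#' analysis uses. ODI3, SI and the five SSE bands describe the home sleep
#' apnea tests; ANR, OSA-18, BMI z-score and age are clinic measurements.
#' Rate-like features (ODI3, SI) are right-skewed and strictly positive,
#' hence log-normal; SSE is already a dB (log) quantity, so it is modeled
#' normal on the dB scale (reported lower quartiles of 0 dB enter as
#' 0.3 dB), and draws are floored at 0 and capped at 55 dB when a cohort
#' is generated.
#'
#' @return named list of feature target specifications.
#' @export
default_feature_targets <- function() {
  list(
    odi3 = list(
      severe = c(11.5, 7.5, 29.0), non_severe = c(4.7, 3.5, 5.3),
      transform = "lognormal"
    ),
    si = list(
      severe = c(929, 348, 1261), non_severe = c(399, 192, 1101),
      transform = "lognormal"
    ),
    sse_21_200 = list(
      severe = c(44.7, 20.8, 53.5), non_severe = c(35.7, 29.6, 48.7),
      transform = "normal"
    ),
    sse_201_400 = list(
      severe = c(34.4, 15.8, 40.7), non_severe = c(27.9, 13.1, 34.9),
      transform = "normal"
    ),
    sse_401_600 = list(
      severe = c(13.4, 7.7, 41.2), non_severe = c(18.8, 0.3, 33.8),
      transform = "normal"
    ),
    sse_601_800 = list(
      severe = c(15.0, 1.1, 28.2), non_severe = c(14.4, 0.3, 24.2),
      transform = "normal"
    ),
    sse_801_1000 = list(
      severe = c(15.9, 4.8, 29.0), non_severe = c(4.4, 0.3, 14.8),
      transform = "normal"
    ),
    anr = list(
      severe = c(0.84, 0.80, 0.92), non_severe = c(0.72, 0.63, 0.81),
      transform = "logitnormal", lower = 0, upper = 1
    ),
    osa18 = list(
      severe = c(77, 65, 84), non_severe = c(70, 58, 83),
      transform = "logitnormal", lower = 18, upper = 126
    ),
    bmi_z = list(
      severe = c(1.4, 0.8, 2.0), non_severe = c(1.0, -0.2, 1.5),
      transform = "normal"
    ),
    age = list(
      severe = c(9, 6, 10), non_severe = c(9, 7, 12),
      transform = "normal"
    )
  )
}

#' Default tonsil-grade probabilities
#'
#' Chosen so the per-group quartiles match the reported summaries
#' (severe: median 4, IQR 3-4; non-severe: median 3, IQR 2-3).
#'
#' @return list with `severe` and `non_severe` probability vectors.
#' @export
default_tonsil_probs <- function() {
  list(
    severe = c(0.02, 0.08, 0.35, 0.55),
    non_severe = c(0.10, 0.20, 0.55, 0.15)
  )
}

#' Default obstructive AHI / AI targets
#' @return list with AHI and AI target specifications.
#' @export
default_ahi_targets <- function() {
  list(
    ahi = list(
      severe = c(21.6, 16.9, 34.6), non_severe = c(3.0, 1.7, 5.8),
      transform = "lognormal"
    ),
    ai = list(
      severe = c(3.3, 0.9, 6.7), non_severe = c(1.0, 0.5, 2.1),
      transform = "lognormal"
    )
  )
}

#' Discovery-cohort parameters (39 analyzable children, 21 severe)
#' @param n_patients cohort size; default 39.
#' @param ... overrides passed to [cohort_params()].
#' @export
cohort_params_study1 <- function(n_patients = 39, ...) {
  cohort_params(n_patients = n_patients, prevalence_severe = 21 / 39, ...)
}

#' Validation-cohort parameters (100 children, 47 severe)
#'
#' Uses the validation cohort's own anatomical, demographic and oximetry
#' summaries; snore-acoustic features reuse the discovery structure (the
#' validation protocol recorded oximetry only, but the generator still
#' emits acoustic features so the full pipeline can run).
#'
#' @param n_patients cohort size; default 100.
#' @param ... overrides passed to [cohort_params()].
#' @export
cohort_params_study2 <- function(n_patients = 100, ...) {
  feats <- default_feature_targets()
  feats$odi3 <- list(
    severe = c(21.3, 11.3, 40.8), non_severe = c(4.3, 2.3, 7.9),
    transform = "lognormal"
  )
  feats$anr <- list(
    severe = c(0.91, 0.72, 0.94), non_severe = c(0.77, 0.60, 0.90),
    transform = "logitnormal", lower = 0, upper = 1
  )
  feats$bmi_z <- list(
    severe = c(0.8, -0.3, 2.2), non_severe = c(0.2, -0.6, 1.8),
    transform = "normal"
  )
  feats$age <- list(
    severe = c(8, 5, 10), non_severe = c(7, 6, 10),
    transform = "normal"
  )
  tonsil <- list(
    severe = c(0.05, 0.15, 0.50, 0.30),
    non_severe = c(0.05, 0.15, 0.50, 0.30)
  )
  ahi <- list(
    ahi = list(
      severe = c(24.4, 15.9, 44.7), non_severe = c(5.3, 4.0, 8.0),
      transform = "lognormal"
    ),
    ai = list(
      severe = c(5.2, 2.1, 12.4), non_severe = c(1.3, 0.6, 2.7),
      transform = "lognormal"
    )
  )
  cohort_params(
    n_patients = n_patients, prevalence_severe = 47 / 100,
    sex_male_frac = c(severe = 32 / 47, non_severe = 41 / 53),
    features = feats, tonsil_probs = tonsil, ahi = ahi, ...
  )
}

qdist_from_target <- function(target, grp) {
  q <- target[[grp]]
  qdist(q[1], q[2], q[3],
    transform = target$transform,
    lower = target$lower %||% 0, upper = target$upper %||% 1
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic cohort
#'
#' Draws `n_patients` patient records with severity labels and
#' severity-conditional features. In `"quota"` mode exactly
#' `round(n_patients * prevalence_severe)` children are severe (the
#' case-matched design of a discovery cohort); in `"bernoulli"` mode each
#' label is an independent draw. Rate-like features come from quantile-
#' matched two-piece log-normals, bounded ratios/scores from two-piece
#' logit-normals, tonsil grade from a categorical over 1-4, and obstructive
#' AHI is truncated at the 10 events/h severity boundary so
#' `severe == (ahi >= 10)` always holds. Deterministic given `seed`.
#'
#' @param params a [cohort_params()] object.
#' @param seed integer seed.
#' @return a tibble with one row per patient: `patient_id`, `severe`,
#'   demographics, anatomy, questionnaire, polysomnography indices and
#'   home-sleep-apnea-test features.
#' @examples
#' coh <- generate_cohort(cohort_params_study1(), seed = 1)
#' table(coh$severe)
#' @export
generate_cohort <- function(params, seed) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(as.integer(seed))
  n <- params$n_patients

  severe <- if (params$mode == "quota") {
    n_sev <- round(n * params$prevalence_severe)
    sample(rep(c(TRUE, FALSE), c(n_sev, n - n_sev)))
  } else {
    stats::runif(n) < params$prevalence_severe
  }

  grp <- ifelse(severe, "severe", "non_severe")
  draw_feature <- function(target, floor = -Inf, cap = Inf) {
    out <- numeric(n)
    for (g in c("severe", "non_severe")) {
      idx <- which(grp == g)
      if (length(idx)) out[idx] <- qdist_sample(length(idx), qdist_from_target(target, g))
    }
    pmin(pmax(out, floor), cap)
  }
  # SSE is a floored dB measure; the cap keeps the loudest simulated bursts
  # inside 16-bit PCM headroom over the default noise floor
  draw_sse <- function(target) draw_feature(target, floor = 0, cap = 55)

  sex <- ifelse(stats::runif(n) < params$sex_male_frac[ifelse(severe, 1L, 2L)],
                "male", "female")

  age_raw <- draw_feature(params$features$age)
  age <- pmin(pmax(round(age_raw), params$age_range[1]), params$age_range[2])

  tonsil <- integer(n)
  for (g in c("severe", "non_severe")) {
    idx <- which(grp == g)
    if (length(idx)) {
      tonsil[idx] <- sample(1:4, length(idx), replace = TRUE,
                            prob = params$tonsil_probs[[g]])
    }
  }

  ahi <- numeric(n)
  ai <- numeric(n)
  for (g in c("severe", "non_severe")) {
    idx <- which(grp == g)
    if (!length(idx)) next
    d_ahi <- qdist_from_target(params$ahi$ahi, g)
    if (g == "severe") {
      ahi[idx] <- qdist_sample_trunc(length(idx), d_ahi, min = 10)
    } else {
      ahi[idx] <- qdist_sample_trunc(length(idx), d_ahi, max = 10 - 1e-9)
    }
    ai[idx] <- qdist_sample(length(idx), qdist_from_target(params$ahi$ai, g))
  }

  tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(n)),
    severe = severe,
    age = as.integer(age),
    sex = factor(sex, levels = c("female", "male")),
    bmi_z = draw_feature(params$features$bmi_z),
    osa18 = round(draw_feature(params$features$osa18)),
    tonsil = tonsil,
    anr = draw_feature(params$features$anr),
    obstructive_ahi = ahi,
    obstructive_ai = ai,
    odi3 = draw_feature(params$features$odi3),
    si = draw_feature(params$features$si),
    sse_21_200 = draw_sse(params$features$sse_21_200),
    sse_201_400 = draw_sse(params$features$sse_201_400),
    sse_401_600 = draw_sse(params$features$sse_401_600),
    sse_601_800 = draw_sse(params$features$sse_601_800),
    sse_801_1000 = draw_sse(params$features$sse_801_1000)
  )
}
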