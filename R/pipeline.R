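#' Study configuration for the end-to-end pipeline
#'
#' Collects the analysis parameters: the 90-minute oximetry window, the
#' discovery-study cut-offs for dichotomizing each predictor, the severity
#' definition (obstructive AHI >= 10 events/h; OSA itself is obstructive
#' AHI >= 2.0 or obstructive AI >= 1.0), QC thresholds, and the signal-
#' simulation settings used when the pipeline generates its own inputs.
#'
#' @param cohort a [cohort_params()] object.
#' @param seed integer master seed.
#' @param mode `"features"` (use the cohort's feature values directly) or
#'   `"signals"` (simulate per-patient oximetry and audio and measure
#'   ODI3/SI/SSE with the detectors).
#' @param window_min oximetry analysis window (minutes).
#' @param cutoffs named list of dichotomization cut-offs.
#' @param qc list with `oximetry_min_valid_minutes` and
#'   `audio_min_analyzed_minutes`.
#' @param severity_ahi_threshold severe-OSA AHI threshold (events/h).
#' @param osa_ahi_threshold,osa_ai_threshold OSA diagnostic thresholds.
#' @param force_oximetry_qc_fail number of patients whose oximetry is
#'   forced below the QC threshold (exercises exclusion bookkeeping).
#' @param signal_sim list of signal-simulation settings for
#'   `mode = "signals"`: `first_snore_offset_min`, `event_depth`,
#'   `event_duration_s`, `audio_duration_min`, `audio_noise_rms`,
#'   `max_odi3_rate`, `max_snore_rate`.
#' @return a `study_config` object.
#' @export
study_config <- function(cohort = cohort_params_study1(),
                         seed = 1,
                         mode = c("features", "signals"),
                         window_min = 90,
                         cutoffs = list(odi3 = 6.0, anr = 0.78, tonsil = 4L,
                                        sse = 22.0, osa18 = 77),
                         qc = list(oximetry_min_valid_minutes = 75,
                                   audio_min_analyzed_minutes = 300),
                         severity_ahi_threshold = 10.0,
                         osa_ahi_threshold = 2.0,
                         osa_ai_threshold = 1.0,
                         force_oximetry_qc_fail = 0L,
                         signal_sim = list()) {
  mode <- match.arg(mode)
  stopifnot(inherits(cohort, "cohort_params"))
  if (any(unlist(cutoffs) <= 0)) stop("cut-offs must be positive", call. = FALSE)
  sim_defaults <- list(
    first_snore_offset_min = 10, event_depth = 3.5, event_duration_s = 20,
    audio_duration_min = 2.5, audio_noise_rms = 0.02,
    max_odi3_rate = 55, max_snore_rate = 2000
  )
  signal_sim <- utils::modifyList(sim_defaults, signal_sim)
  structure(
    list(cohort = cohort, seed = as.integer(seed), mode = mode,
         window_min = window_min, cutoffs = cutoffs, qc = qc,
         severity_ahi_threshold = severity_ahi_threshold,
         osa_ahi_threshold = osa_ahi_threshold,
         osa_ai_threshold = osa_ai_threshold,
         force_oximetry_qc_fail = as.integer(force_oximetry_qc_fail),
         signal_sim = signal_sim),
    class = "study_config"
  )
}

measure_patient_signals <- function(target, config, patient_seed, force_qc_fail) {
  ss <- config$signal_sim
  # oximetry: plant the patient's ODI3 as the event rate (capped at what a
  # 90-min window can hold with 30-s separations) and measure it back
  rate <- min(target$odi3, ss$max_odi3_rate)
  duration <- if (force_qc_fail) 60 else config$window_min + ss$first_snore_offset_min
  tr <- simulate_spo2_trace(trace_sim_spec(
    duration_min = duration,
    event_rate_per_h = if (force_qc_fail) 0 else rate,
    event_depth = ss$event_depth,
    event_duration_s = ss$event_duration_s,
    first_snore_offset_min = if (force_qc_fail) 0 else ss$first_snore_offset_min,
    seed = patient_seed
  ))
  tr <- clean_trace(tr)
  win <- select_window(tr, first_snore_s = if (force_qc_fail) 0 else ss$first_snore_offset_min * 60,
                       window_min = config$window_min)
  odi <- compute_odi3(win, qc_min_valid_minutes = config$qc$oximetry_min_valid_minutes)

  # audio: plant the patient's SI and SSE-band gains and measure them back
  aud <- simulate_snore_audio(audio_sim_spec(
    duration_min = ss$audio_duration_min,
    noise_rms = ss$audio_noise_rms,
    snore_rate_per_h = min(target$si, ss$max_snore_rate),
    band_gains_db = pmax(0, c(target$sse_21_200, target$sse_201_400,
                              target$sse_401_600, target$sse_601_800,
                              target$sse_801_1000)),
    seed = patient_seed + 1L
  ))
  ac <- analyze_audio(aud, qc_min_minutes = config$qc$audio_min_analyzed_minutes)
  list(odi = odi, acoustic = ac$features)
}

#' Run the screening pipeline end to end
#'
#' Generates a synthetic cohort, obtains per-patient home-sleep-apnea-test
#' features (directly, or by simulating and re-measuring oximetry traces
#' and snore audio), applies the QC exclusion rules (oximetry < 75 valid
#' minutes; audio < 300 analyzed minutes - the latter only in cohorts
#' where audio duration is part of the protocol), dichotomizes predictors
#' at the configured cut-offs, scores the anatomical, home-sleep-apnea-
#' test and combined models, and evaluates each against polysomnography
#' severity. Deterministic given the config seed.
#'
#' In `"signals"` mode the per-patient audio is a short planted-snore
#' recording; its analyzed minutes stand in for the full 6-h protocol, so
#' the audio QC rule is only enforced when `qc$audio_min_analyzed_minutes`
#' is at or below the simulated duration.
#'
#' @param config a [study_config()].
#' @return a `study_report` list: `cohort` (analyzed patients with
#'   measured features and indicators), `excluded` (tibble of exclusions
#'   with reasons), `models` (per-model metrics), `counts`
#'   (enrolled/analyzed/excluded), `config_seed`, `mode`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "study_config"))
  cohort <- generate_cohort(config$cohort, seed = config$seed)
  if (nrow(cohort) == 0) stop("empty cohort", call. = FALSE)
  n <- nrow(cohort)

  if (config$mode == "signals") {
    res <- vector("list", n)
    for (i in seq_len(n)) {
      res[[i]] <- measure_patient_signals(
        cohort[i, ], config,
        patient_seed = config$seed * 10000L + 2L * i,
        force_qc_fail = i <= config$force_oximetry_qc_fail
      )
    }
    cohort$valid_minutes <- vapply(res, function(r) r$odi$valid_minutes, numeric(1))
    cohort$oximetry_qc <- vapply(res, function(r) r$odi$qc_pass, logical(1))
    cohort$odi3_measured <- vapply(res, function(r) r$odi$odi3, numeric(1))
    cohort$si_measured <- vapply(res, function(r) r$acoustic$si, numeric(1))
    sse_m <- t(vapply(res, function(r) r$acoustic$sse_db, numeric(5)))
    cohort$sse_801_1000_measured <- sse_m[, 5]
    cohort$analyzed_minutes <- vapply(res, function(r) r$acoustic$analyzed_minutes, numeric(1))
    audio_qc_applies <- config$qc$audio_min_analyzed_minutes <=
      config$signal_sim$audio_duration_min
    cohort$audio_qc <- if (audio_qc_applies) {
      vapply(res, function(r) r$acoustic$qc_pass, logical(1))
    } else TRUE
  } else {
    cohort$valid_minutes <- config$window_min
    cohort$oximetry_qc <- TRUE
    if (config$force_oximetry_qc_fail > 0) {
      idx <- seq_len(min(config$force_oximetry_qc_fail, n))
      cohort$valid_minutes[idx] <- 60
      cohort$oximetry_qc[idx] <- FALSE
    }
    cohort$odi3_measured <- cohort$odi3
    cohort$si_measured <- cohort$si
    cohort$sse_801_1000_measured <- cohort$sse_801_1000
    cohort$analyzed_minutes <- 360
    cohort$audio_qc <- TRUE
  }

  excluded <- tibble::tibble(
    patient_id = character(0), reason = character(0)
  )
  if (any(!cohort$oximetry_qc)) {
    excluded <- rbind(excluded, tibble::tibble(
      patient_id = cohort$patient_id[!cohort$oximetry_qc],
      reason = sprintf("insufficient pulse oximetry data (< %g valid min)",
                       config$qc$oximetry_min_valid_minutes)
    ))
  }
  if (any(!cohort$audio_qc & cohort$oximetry_qc)) {
    excluded <- rbind(excluded, tibble::tibble(
      patient_id = cohort$patient_id[!cohort$audio_qc & cohort$oximetry_qc],
      reason = sprintf("insufficient snoring sound data (< %g analyzed min)",
                       config$qc$audio_min_analyzed_minutes)
    ))
  }
  analyzed <- cohort[cohort$oximetry_qc & cohort$audio_qc, ]
  if (nrow(analyzed) == 0) stop("all patients excluded by QC", call. = FALSE)

  feat <- analyzed
  feat$odi3 <- feat$odi3_measured
  feat$si <- feat$si_measured
  feat$sse_801_1000 <- feat$sse_801_1000_measured
  feat <- dichotomize_cohort(feat, config$cutoffs)

  models <- lapply(c("anatomical", "hsat", "combined"), function(nm) {
    ms <- model_spec(nm)
    sc <- score_cohort(feat, ms)
    cm <- confusion_from_predictions(sc$predicted_severe, feat$severe)
    m <- confusion_metrics(cm)
    list(
      name = nm,
      threshold = ms$threshold,
      metrics_pct = as.list(metrics_pct(m)),
      auc = auc_rank(sc$score, feat$severe),
      odds_ratio = odds_ratio(cm)$or,
      kappa = cohens_kappa(cm),
      cm = unclass(cm)
    )
  })
  names(models) <- c("anatomical", "hsat", "combined")

  structure(
    list(
      cohort = feat,
      excluded = excluded,
      models = models,
      counts = list(
        enrolled = n,
        analyzed = nrow(analyzed),
        excluded = nrow(excluded)
      ),
      config_seed = config$seed,
      mode = config$mode
    ),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d enrolled, %d analyzed, %d excluded (seed %d, %s mode)\n",
              x$counts$enrolled, x$counts$analyzed, x$counts$excluded,
              x$config_seed, x$mode))
  for (m in x$models) {
    p <- m$metrics_pct
    cat(sprintf("  %-10s sens %g%% spec %g%% ppv %g%% npv %g%% acc %g%% (AUC %.2f)\n",
                m$name, p$sens, p$spec, p$ppv, p$npv, p$acc, m$auc))
  }
  invisible(x)
}

#' Write a study report to disk
#'
#' Emits `features.csv` (analyzed patients), `exclusions.csv` and
#' `report.json` (model metrics, counts, seed) under `dir`.
#'
#' @param report a `study_report` from [run_pipeline()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_features_csv(report$cohort, file.path(dir, "features.csv"))
  utils::write.csv(as.data.frame(report$excluded),
                   file.path(dir, "exclusions.csv"), row.names = FALSE)
  write_metrics_json(
    list(models = report$models, counts = report$counts,
         seed = report$config_seed, mode = report$mode),
    file.path(dir, "report.json")
  )
  invisible(dir)
}
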