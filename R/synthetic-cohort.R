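# Synthetic cohort generator
#
# Emulates the design of a combination-ICI melanoma trial cohort profiled on
# an autoantigen microarray: 60 patients, 120 antigens x {IgG, IgM} x
# {baseline, week6}, ~15% missing week-6 draws, internal positive-control
# spots, organ-specific adverse events with CTCAE grades and attributions,
# ANA/RF/anti-CCP serology, total immunoglobulins and PFS/OS follow-up.
# Group differences in antibody score can be planted so that downstream
# statistics are testable by parameter recovery.

#' Organ categories of the immune-related adverse events of interest
#'
#' The nine organ systems tracked by the pipeline: hepatic, gastrointestinal
#' (diarrhea/colitis), dermatologic, arthritis/arthralgia, myocarditis,
#' myositis/myalgia, sicca, thyroid and non-thyroid endocrinopathy.
#'
#' @return Character vector of nine organ labels.
#' @export
irae_organs <- function() {
  c("hepatic", "gastrointestinal", "dermatologic", "arthritis_arthralgia",
    "myocarditis", "myositis_myalgia", "sicca", "thyroid",
    "nonthyroid_endocrine")
}

#' Recognised event-attribution levels
#' @return Character vector, strongest attribution first.
#' @export
attribution_levels <- function() {
  c("definite", "probable", "possible", "unlikely", "unrelated")
}

# per-patient probability of >= 1 event in each organ category; chosen so a
# typical cohort has a median of ~3 distinct organ events, a small no-event
# minority, and rare myocarditis
default_event_rates <- function() {
  c(hepatic = 0.45, gastrointestinal = 0.60, dermatologic = 0.65,
    arthritis_arthralgia = 0.40, myocarditis = 0.05,
    myositis_myalgia = 0.30, sicca = 0.25, thyroid = 0.45,
    nonthyroid_endocrine = 0.20)
}

# median onset (weeks) per organ; dermatologic/myocarditis early, joints and
# non-thyroid endocrinopathies late
default_onset_medians <- function() {
  c(hepatic = 5.3, gastrointestinal = 6.3, dermatologic = 2.4,
    arthritis_arthralgia = 11.5, myocarditis = 2.4,
    myositis_myalgia = 8.0, sicca = 9.0, thyroid = 7.0,
    nonthyroid_endocrine = 11.7)
}

#' Describe a planted group difference in antibody score
#'
#' A planted effect shifts the antibody score (ABS, log2 units) of a set of
#' antigens for one patient group at one timepoint and isotype, additively on
#' the ABS scale.  Effects are injected before the scores are back-transformed
#' into NFI/SNR spot signals, so recovering the shift exercises the full
#' scoring and testing path.
#'
#' @param antigens Character or integer vector of panel antigens to shift.
#' @param effect Shift in ABS units applied to the target group (signed).
#' @param grouping One of `"organ"`, `"timing"`, `"severity"`, `"patients"`.
#' @param value For `grouping = "organ"`, the organ label.
#' @param patients For `grouping = "patients"`, explicit patient ids (the
#'   target group).
#' @param timepoint `"baseline"` or `"week6"`.
#' @param isotype `"IgG"` or `"IgM"`.
#' @return An object of class `planted_effect`.
#' @export
planted_effect <- function(antigens, effect,
                           grouping = c("organ", "timing", "severity",
                                        "patients"),
                           value = NULL, patients = NULL,
                           timepoint = "baseline", isotype = "IgG") {
  grouping <- match.arg(grouping)
  if (!is.finite(effect)) stop_field("planted_effects", "effect_size must be finite")
  if (grouping == "organ" && is.null(value))
    stop_field("planted_effects", "organ grouping requires 'value'")
  if (grouping == "patients" && is.null(patients))
    stop_field("planted_effects", "patients grouping requires 'patients'")
  structure(list(antigens = antigens, effect = effect, grouping = grouping,
                 value = value, patients = patients,
                 timepoint = match.arg(timepoint, c("baseline", "week6")),
                 isotype = match.arg(isotype, c("IgG", "IgM"))),
            class = "planted_effect")
}

#' Configuration of a synthetic autoantibody cohort
#'
#' Defaults emulate the study conditions: 60 patients, a 120-antigen panel
#' read in IgG and IgM at baseline and week 6, 15% of patients missing the
#' week-6 draw, eight internal positive-control spots per slide, and
#' marginal clinical structure (sex, stage, melanoma type, event rates and
#' onsets, serology positivity) matching the trial cohort.
#'
#' @param n_patients Number of patients (>= 2).
#' @param n_antigens Panel size.
#' @param n_control_spots Internal positive-control spots per slide.
#' @param isotypes Isotypes profiled.
#' @param week6_missing_fraction Fraction of patients without a week-6 draw.
#' @param organ_categories Organ labels for adverse events.
#' @param planted_effects List of [planted_effect()] objects.
#' @param seed Integer seed; one global seed fans out to per-component
#'   substreams so each table can be regenerated independently.
#' @param event_rates Named per-organ probability of an event per patient.
#' @param onset_medians Named per-organ median onset in weeks.
#' @param onset_log_sd Log-scale SD of the lognormal onset distributions.
#' @param grade_probs Probabilities of CTCAE grades 1..5 per event.
#' @param attribution_probs Named probabilities over attribution levels.
#' @param snr_quiet_fraction Fraction of panel antigens that rarely rise
#'   above background (SNR mostly < 3); these occupy the tail of the panel.
#' @param abs_mean,abs_antigen_sd,abs_patient_sd,abs_noise_sd Location and
#'   variance components of the baseline antibody score (log2 scale):
#'   antigen-specific means, a shared per-patient offset, and spot noise.
#' @param sample_scale_sd,sample_shift_sd SD of the per-sample affine
#'   distortion (slope around 1, intercept around 0) applied to every spot
#'   of a slide; this is what control-based normalization must remove.
#' @param control_abs,control_noise_sd Mean score and replicate noise of the
#'   internal positive-control spots.
#' @param fc_noise_sd Baseline-to-week-6 drift SD common to all patients.
#' @param fc_sd_per_event Additional week-6 drift SD per distinct-organ
#'   definite/probable event, coupling fold-change magnitude to irAE burden.
#' @param ana_rate,rf_pos_rate,ccp_pos_rate Baseline positivity rates.
#' @param ana_persist,ana_gain Week-6 transition probabilities for ANA.
#' @param sex_female_igg_ratio Multiplicative IgG excess in women.
#' @param pfs_median_months,os_median_months Medians of the exponential
#'   PFS/OS generators before censoring at last follow-up.
#' @param followup_months Median follow-up used for censoring.
#' @return An object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_patients = 60,
                          n_antigens = 120,
                          n_control_spots = 8,
                          isotypes = c("IgG", "IgM"),
                          week6_missing_fraction = 0.15,
                          organ_categories = irae_organs(),
                          planted_effects = list(),
                          seed = 1L,
                          event_rates = default_event_rates(),
                          onset_medians = default_onset_medians(),
                          onset_log_sd = 0.6,
                          grade_probs = c(0.45, 0.33, 0.15, 0.05, 0.02),
                          attribution_probs = c(definite = 0.50, probable = 0.30,
                                                possible = 0.10, unlikely = 0.05,
                                                unrelated = 0.05),
                          snr_quiet_fraction = 0.10,
                          abs_mean = 6, abs_antigen_sd = 1.2,
                          abs_patient_sd = 0.5, abs_noise_sd = 0.8,
                          sample_scale_sd = 0.05, sample_shift_sd = 0.15,
                          control_abs = 12, control_noise_sd = 0.05,
                          fc_noise_sd = 0.3, fc_sd_per_event = 0.1,
                          ana_rate = 14 / 60, rf_pos_rate = 4 / 60,
                          ccp_pos_rate = 0.01,
                          ana_persist = 0.75, ana_gain = 0.07,
                          sex_female_igg_ratio = 1.15,
                          pfs_median_months = 10, os_median_months = 25,
                          followup_months = 25) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_antigens = as.integer(n_antigens),
              n_control_spots = as.integer(n_control_spots),
              isotypes = isotypes,
              timepoints = c("baseline", "week6"),
              week6_missing_fraction = week6_missing_fraction,
              organ_categories = organ_categories,
              planted_effects = planted_effects,
              seed = as.integer(seed),
              event_rates = event_rates,
              onset_medians = onset_medians,
              onset_log_sd = onset_log_sd,
              grade_probs = grade_probs,
              attribution_probs = attribution_probs,
              snr_quiet_fraction = snr_quiet_fraction,
              abs_mean = abs_mean, abs_antigen_sd = abs_antigen_sd,
              abs_patient_sd = abs_patient_sd, abs_noise_sd = abs_noise_sd,
              sample_scale_sd = sample_scale_sd,
              sample_shift_sd = sample_shift_sd,
              control_abs = control_abs, control_noise_sd = control_noise_sd,
              fc_noise_sd = fc_noise_sd, fc_sd_per_event = fc_sd_per_event,
              ana_rate = ana_rate, rf_pos_rate = rf_pos_rate,
              ccp_pos_rate = ccp_pos_rate,
              ana_persist = ana_persist, ana_gain = ana_gain,
              sex_female_igg_ratio = sex_female_igg_ratio,
              pfs_median_months = pfs_median_months,
              os_median_months = os_median_months,
              followup_months = followup_months)
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (is.na(cfg$n_patients) || cfg$n_patients < 2)
    stop_field("n_patients", "must be an integer >= 2")
  if (cfg$n_antigens < 1) stop_field("n_antigens", "must be >= 1")
  if (cfg$n_control_spots < 2)
    stop_field("n_control_spots", "need >= 2 control spots for normalization")
  for (f in c("week6_missing_fraction", "snr_quiet_fraction")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || is.na(v) || v < 0 || v > 1)
      stop_field(f, "must be a proportion in [0, 1]")
  }
  if (!all(cfg$isotypes %in% c("IgG", "IgM")) || !length(cfg$isotypes))
    stop_field("isotypes", "must be a nonempty subset of {IgG, IgM}")
  if (!length(cfg$organ_categories) || anyDuplicated(cfg$organ_categories))
    stop_field("organ_categories", "must be nonempty, no duplicates")
  if (!all(cfg$organ_categories %in% names(cfg$event_rates)))
    stop_field("event_rates", "must name every organ category")
  if (!all(cfg$organ_categories %in% names(cfg$onset_medians)))
    stop_field("onset_medians", "must name every organ category")
  if (any(cfg$event_rates < 0 | cfg$event_rates > 1))
    stop_field("event_rates", "must be probabilities in [0, 1]")
  if (any(cfg$onset_medians <= 0)) stop_field("onset_medians", "must be > 0")
  if (length(cfg$grade_probs) != 5 || any(cfg$grade_probs < 0) ||
      abs(sum(cfg$grade_probs) - 1) > 1e-8)
    stop_field("grade_probs", "must be 5 probabilities summing to 1")
  if (!setequal(names(cfg$attribution_probs), attribution_levels()) ||
      abs(sum(cfg$attribution_probs) - 1) > 1e-8)
    stop_field("attribution_probs",
               "must cover the five attribution levels and sum to 1")
  for (f in c("abs_antigen_sd", "abs_patient_sd", "abs_noise_sd",
              "sample_scale_sd", "sample_shift_sd", "control_noise_sd",
              "fc_noise_sd", "fc_sd_per_event", "onset_log_sd")) {
    if (!is.numeric(cfg[[f]]) || is.na(cfg[[f]]) || cfg[[f]] < 0)
      stop_field(f, "must be a nonnegative number")
  }
  for (f in c("ana_rate", "rf_pos_rate", "ccp_pos_rate", "ana_persist",
              "ana_gain")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop_field(f, "must be in [0, 1]")
  }
  if (!is.list(cfg$planted_effects) ||
      (length(cfg$planted_effects) &&
       !all(vapply(cfg$planted_effects, inherits, TRUE, "planted_effect"))))
    stop_field("planted_effects", "must be a list of planted_effect objects")
  invisible(cfg)
}

patient_ids <- function(n) sprintf("P%03d", seq_len(n))
antigen_ids <- function(n) sprintf("AG%03d", seq_len(n))

#' Generate adverse events for a patient set
#'
#' Events are drawn independently per patient and organ category with the
#' configured per-organ rates; onset weeks follow organ-specific lognormal
#' distributions whose medians default to the early/late pattern seen in
#' ICI cohorts (dermatologic and myocarditis around 2.4 weeks, joints and
#' non-thyroid endocrinopathies around 11.5-11.7 weeks).  Grades 1-5 and
#' attribution levels are sampled from the configured probabilities.
#'
#' @param config A [cohort_config()].
#' @param ids Patient identifiers.
#' @return Data frame with columns `patient_id`, `organ`, `grade`,
#'   `onset_week`, `attribution`.
#' @export
generate_events <- function(config, ids = patient_ids(config$n_patients)) {
  validate_cohort_config(config)
  with_seed(substream_seed(config$seed, 2L), {
    organs <- config$organ_categories
    rows <- vector("list", length(ids) * length(organs))
    k <- 0L
    for (pid in ids) {
      for (org in organs) {
        if (runif(1) < config$event_rates[[org]]) {
          k <- k + 1L
          rows[[k]] <- data.frame(
            patient_id = pid, organ = org,
            grade = sample.int(5L, 1L, prob = config$grade_probs),
            onset_week = round(rlnorm(1, log(config$onset_medians[[org]]),
                                      config$onset_log_sd), 1),
            attribution = sample(names(config$attribution_probs), 1L,
                                 prob = config$attribution_probs),
            stringsAsFactors = FALSE)
        }
      }
    }
    if (k == 0L)
      return(data.frame(patient_id = character(), organ = character(),
                        grade = integer(), onset_week = numeric(),
                        attribution = character(), stringsAsFactors = FALSE))
    ev <- do.call(rbind, rows[seq_len(k)])
    rownames(ev) <- NULL
    ev
  })
}

# patients x 1 count of distinct organs with definite/probable events
distinct_organ_counts <- function(events, ids,
                                  organs = irae_organs()) {
  counts <- setNames(integer(length(ids)), ids)
  if (nrow(events)) {
    qual <- events[events$attribution %in% c("definite", "probable") &
                     events$organ %in% organs, , drop = FALSE]
    if (nrow(qual)) {
      tab <- tapply(qual$organ, qual$patient_id,
                    function(x) length(unique(x)))
      counts[names(tab)] <- as.integer(tab)
    }
  }
  counts
}

# resolve a planted effect to the set of target patient ids
planted_target_patients <- function(pe, events, ids) {
  if (pe$grouping == "patients") return(intersect(pe$patients, ids))
  spec <- switch(pe$grouping,
                 organ = grouping_spec("organ", organ = pe$value),
                 timing = grouping_spec("timing"),
                 severity = grouping_spec("severity"))
  ga <- assign_groups(events, ids, spec)
  ga$patient_id[ga$group == "A"]
}

generate_signals <- function(config, events, ids, week6_missing) {
  n <- length(ids)
  a <- config$n_antigens
  ags <- antigen_ids(a)
  ctrls <- sprintf("CTRL%02d", seq_len(config$n_control_spots))
  counts <- distinct_organ_counts(events, ids, config$organ_categories)
  n_quiet <- floor(config$snr_quiet_fraction * a)
  quiet <- if (n_quiet > 0) tail(seq_len(a), n_quiet) else integer()

  with_seed(substream_seed(config$seed, 4L), {
    out <- vector("list", length(config$isotypes) * 2L)
    k <- 0L
    for (iso in config$isotypes) {
      mu_a <- rnorm(a, config$abs_mean, config$abs_antigen_sd)
      p_off <- rnorm(n, 0, config$abs_patient_sd)
      base <- outer(p_off, mu_a, "+") +
        matrix(rnorm(n * a, 0, config$abs_noise_sd), n, a)
      drift_sd <- config$fc_noise_sd + config$fc_sd_per_event * counts
      wk6 <- base + matrix(rnorm(n * a, 0, drift_sd), n, a)
      dimnames(base) <- dimnames(wk6) <- list(ids, ags)

      for (pe in config$planted_effects) {
        if (pe$isotype != iso) next
        target <- planted_target_patients(pe, events, ids)
        cols <- if (is.character(pe$antigens)) pe$antigens else ags[pe$antigens]
        if (pe$timepoint == "baseline") {
          base[target, cols] <- base[target, cols] + pe$effect
          # baseline shifts persist into week 6 so fold changes stay null
          wk6[target, cols] <- wk6[target, cols] + pe$effect
        } else {
          wk6[target, cols] <- wk6[target, cols] + pe$effect
        }
      }

      ctrl_profile <- rnorm(config$n_control_spots, config$control_abs, 0.5)
      for (tp in c("baseline", "week6")) {
        abs_mat <- if (tp == "baseline") base else wk6
        keep <- if (tp == "week6") setdiff(ids, week6_missing) else ids
        slope <- rnorm(n, 1, config$sample_scale_sd)
        shift <- rnorm(n, 0, config$sample_shift_sd)
        ctrl_mat <- matrix(rep(ctrl_profile, each = n), n,
                           config$n_control_spots,
                           dimnames = list(ids, ctrls)) +
          matrix(rnorm(n * config$n_control_spots, 0,
                       config$control_noise_sd), n)
        snr_ag <- matrix(rlnorm(n * a, log(8), 0.6), n, a)
        if (length(quiet))
          snr_ag[, quiet] <- matrix(rlnorm(n * length(quiet), log(1.2), 0.5),
                                    n, length(quiet))
        snr_ctrl <- matrix(rlnorm(n * config$n_control_spots, log(50), 0.3),
                           n, config$n_control_spots)
        # per-sample affine distortion on the log2 score scale, shared by
        # antigen and control spots; normalization must undo it
        ab_d <- shift + slope * abs_mat
        ct_d <- shift + slope * ctrl_mat
        nfi_ag <- pmax(2^ab_d - 1, 0) / snr_ag
        nfi_ctrl <- pmax(2^ct_d - 1, 0) / snr_ctrl
        keep_idx <- match(keep, ids)
        k <- k + 1L
        out[[k]] <- rbind(
          data.frame(patient_id = rep(keep, times = a),
                     timepoint = tp, isotype = iso,
                     antigen = rep(ags, each = length(keep)),
                     is_control = FALSE,
                     nfi = as.vector(nfi_ag[keep_idx, , drop = FALSE]),
                     snr = as.vector(snr_ag[keep_idx, , drop = FALSE]),
                     stringsAsFactors = FALSE),
          data.frame(patient_id = rep(keep, times = config$n_control_spots),
                     timepoint = tp, isotype = iso,
                     antigen = rep(ctrls, each = length(keep)),
                     is_control = TRUE,
                     nfi = as.vector(nfi_ctrl[keep_idx, , drop = FALSE]),
                     snr = as.vector(snr_ctrl[keep_idx, , drop = FALSE]),
                     stringsAsFactors = FALSE))
      }
    }
    sig <- do.call(rbind, out[seq_len(k)])
    rownames(sig) <- NULL
    sig$nfi <- round(sig$nfi, 4)
    sig$snr <- round(sig$snr, 4)
    sig
  })
}

generate_clinical <- function(config, ids) {
  with_seed(substream_seed(config$seed, 1L), {
    n <- length(ids)
    data.frame(
      patient_id = ids,
      age = pmin(pmax(round(rnorm(n, 63, 11)), 25), 90),
      sex = sample(c("male", "female"), n, replace = TRUE,
                   prob = c(0.63, 0.37)),
      stage = sample(c("III", "IV"), n, replace = TRUE, prob = c(0.15, 0.85)),
      melanoma_type = sample(c("cutaneous", "uveal", "acral", "mucosal",
                               "unknown"), n, replace = TRUE,
                             prob = c(0.617, 0.017, 0.017, 0.266, 0.083)),
      ici_cycles = pmax(1, round(rlnorm(n, log(5.5), 0.8))),
      followup_months = round(pmin(pmax(rnorm(n, config$followup_months, 3),
                                        6), 36), 1),
      stringsAsFactors = FALSE)
  })
}

generate_serology <- function(config, ids, week6_missing) {
  with_seed(substream_seed(config$seed, 5L), {
    n <- length(ids)
    ana_b <- runif(n) < config$ana_rate
    rf_pos <- runif(n) < config$rf_pos_rate
    rf_b <- ifelse(rf_pos, rlnorm(n, log(40), 0.5), rlnorm(n, log(3), 0.5))
    ccp_pos <- runif(n) < config$ccp_pos_rate
    ccp_b <- ifelse(ccp_pos, rlnorm(n, log(60), 0.5), rlnorm(n, log(3), 0.5))
    ana_w <- ifelse(ana_b, runif(n) < config$ana_persist,
                    runif(n) < config$ana_gain)
    rf_w <- rf_b * exp(rnorm(n, 0, 0.35))
    ccp_w <- ccp_b * exp(rnorm(n, 0, 0.35))
    base <- data.frame(patient_id = ids, timepoint = "baseline",
                       ana_positive = ana_b, rf_iu_ml = round(rf_b, 2),
                       ccp_u_ml = round(ccp_b, 2), stringsAsFactors = FALSE)
    keep <- !(ids %in% week6_missing)
    wk6 <- data.frame(patient_id = ids[keep], timepoint = "week6",
                      ana_positive = ana_w[keep],
                      rf_iu_ml = round(rf_w[keep], 2),
                      ccp_u_ml = round(ccp_w[keep], 2),
                      stringsAsFactors = FALSE)
    out <- rbind(base, wk6)
    rownames(out) <- NULL
    out
  })
}

generate_ig <- function(config, clinical) {
  with_seed(substream_seed(config$seed, 6L), {
    n <- nrow(clinical)
    igg <- exp(rnorm(n, log(1050), 0.25)) *
      ifelse(clinical$sex == "female", config$sex_female_igg_ratio, 1)
    igm <- exp(rnorm(n, log(100), 0.4))
    data.frame(patient_id = clinical$patient_id,
               igg_mg_dl = round(igg, 1), igm_mg_dl = round(igm, 1),
               stringsAsFactors = FALSE)
  })
}

generate_survival <- function(config, clinical) {
  with_seed(substream_seed(config$seed, 7L), {
    n <- nrow(clinical)
    fu <- clinical$followup_months
    pfs_raw <- rexp(n, log(2) / config$pfs_median_months)
    os_raw <- pmax(rexp(n, log(2) / config$os_median_months), pfs_raw)
    data.frame(patient_id = clinical$patient_id, stage = clinical$stage,
               pfs_months = round(pmin(pfs_raw, fu), 2),
               pfs_event = as.integer(pfs_raw <= fu),
               os_months = round(pmin(os_raw, fu), 2),
               os_event = as.integer(os_raw <= fu),
               stringsAsFactors = FALSE)
  })
}

#' Generate a complete synthetic study
#'
#' Draws every table of a synthetic cohort: spot-level antigen signals
#' (NFI/SNR, including internal positive-control spots and per-sample affine
#' distortions), clinical covariates, adverse events, serology, total
#' immunoglobulins and survival.  Baseline antibody scores are normal on the
#' log2 (ABS) scale with antigen-specific means, a per-patient offset and spot
#' noise (so NFI is lognormal-like); planted effects are added on the ABS
#' scale before back-transformation into NFI and SNR.  Week-6 draws are
#' missing completely at random for `round(week6_missing_fraction *
#' n_patients)` patients; their week-6 signal and serology rows are absent.
#'
#' @param config A [cohort_config()].
#' @return An object of class `synthetic_study`: a list with elements
#'   `signals`, `clinical`, `events`, `serology`, `ig`, `survival`,
#'   `week6_missing` (patient ids) and `config`.
#' @examples
#' study <- generate_cohort(cohort_config(n_patients = 10, n_antigens = 20))
#' head(study$signals)
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  ids <- patient_ids(config$n_patients)
  clinical <- generate_clinical(config, ids)
  events <- generate_events(config, ids)
  week6_missing <- with_seed(substream_seed(config$seed, 3L), {
    n_miss <- round(config$week6_missing_fraction * config$n_patients)
    sort(sample(ids, n_miss))
  })
  signals <- generate_signals(config, events, ids, week6_missing)
  serology <- generate_serology(config, ids, week6_missing)
  ig <- generate_ig(config, clinical)
  surv <- generate_survival(config, clinical)
  structure(list(signals = signals, clinical = clinical, events = events,
                 serology = serology, ig = ig, survival = surv,
                 week6_missing = week6_missing, config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d patients, %d antigens, %d signal rows\n",
              x$config$n_patients, x$config$n_antigens, nrow(x$signals)))
  cat(sprintf("  events: %d; week-6 draws missing for %d patients; seed %d\n",
              nrow(x$events), length(x$week6_missing), x$config$seed))
  invisible(x)
}

fmt_num <- function(x) {
  if (is.numeric(x)) sprintf("%.17g", x) else as.character(x)
}

write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop(sprintf("failed to write '%s'", path), call. = FALSE)
  invisible(path)
}

#' Write a synthetic study to TSV fixtures
#'
#' Emits `signals.tsv`, `clinical.tsv`, `events.tsv`, `serology.tsv`,
#' `ig.tsv` and `survival.tsv` plus a `manifest.json` carrying the seed, a
#' hash of the configuration and row counts.  Numeric columns are written
#' with 17 significant digits so a write/load round trip is exact.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths.
#' @export
write_fixtures <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) stop(sprintf("cannot create directory '%s'", dir))
  tabs <- c("signals", "clinical", "events", "serology", "ig", "survival")
  paths <- setNames(file.path(dir, paste0(tabs, ".tsv")), tabs)
  for (t in tabs) write_tsv(study[[t]], paths[[t]])
  manifest <- list(seed = study$config$seed,
                   config_hash = fnv1a_hash(deparse_config(unclass(study$config))),
                   n_patients = study$config$n_patients,
                   n_antigens = study$config$n_antigens,
                   rows = lapply(setNames(tabs, tabs),
                                 function(t) nrow(study[[t]])))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, manifest = file.path(dir, "manifest.json")))
}
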