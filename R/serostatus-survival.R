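# ANA/RF/anti-CCP serostatus classification, seroconversion accounting,
# serogroup comparisons, and Kaplan-Meier / log-rank time-to-event analyses.

#' Classify seropositivity per timepoint
#'
#' Thresholds are strict inequalities: RF positive when RF > 14 IU/mL,
#' anti-CCP positive when CCP > 20 U/mL; ANA is ingested as the binary
#' immunofluorescence report.  A patient is "any positive" at a timepoint
#' when ANA, RF or CCP is positive.  Overall ("any timepoint") positivity is
#' baseline or week-6 positivity; a missing week-6 draw leaves the week-6
#' status unknown and the patient out of week-6 denominators.
#'
#' @param serology Long serology data frame (`patient_id`, `timepoint`,
#'   `ana_positive`, `rf_iu_ml`, `ccp_u_ml`).
#' @param rf_cut,ccp_cut Positivity thresholds (exclusive).
#' @return Data frame, one row per patient: `patient_id`, `baseline_positive`,
#'   `week6_positive` (NA when no week-6 draw), `any_positive`, plus the
#'   per-component flags `ana_baseline`, `rf_baseline`, `ccp_baseline`.
#' @export
classify_serostatus <- function(serology, rf_cut = 14, ccp_cut = 20) {
  assert_columns(serology, c("patient_id", "timepoint", "ana_positive",
                             "rf_iu_ml", "ccp_u_ml"), "serology")
  if (any(serology$rf_iu_ml < 0, na.rm = TRUE) ||
      any(serology$ccp_u_ml < 0, na.rm = TRUE))
    stop("negative RF/CCP titer in serology table", call. = FALSE)
  serology$any <- serology$ana_positive | serology$rf_iu_ml > rf_cut |
    serology$ccp_u_ml > ccp_cut
  base <- serology[serology$timepoint == "baseline", ]
  wk6 <- serology[serology$timepoint == "week6", ]
  ids <- base$patient_id
  w_idx <- match(ids, wk6$patient_id)
  out <- data.frame(
    patient_id = ids,
    baseline_positive = base$any,
    week6_positive = wk6$any[w_idx],
    stringsAsFactors = FALSE)
  out$any_positive <- out$baseline_positive |
    (!is.na(out$week6_positive) & out$week6_positive)
  out$ana_baseline <- base$ana_positive
  out$rf_baseline <- base$rf_iu_ml > rf_cut
  out$ccp_baseline <- base$ccp_u_ml > ccp_cut
  out
}

#' Seroconversion accounting between baseline and week 6
#'
#' Counts baseline-positive patients, patients who seroconvert to positive
#' (gained) or to negative (lost) among those with both draws, week-6
#' positives, and any-timepoint positives, and asserts the bookkeeping
#' identities `week6 = baseline(paired) + gained - lost` and
#' `any = baseline + gained`.
#'
#' @param status Output of [classify_serostatus()].
#' @return List of counts: `baseline_positive`, `baseline_positive_paired`,
#'   `gained`, `lost`, `week6_positive`, `any_positive`, `n_paired`.
#' @export
seroconversion_accounting <- function(status) {
  assert_columns(status, c("patient_id", "baseline_positive",
                           "week6_positive", "any_positive"), "status")
  paired <- !is.na(status$week6_positive)
  baseline_pos <- sum(status$baseline_positive)
  baseline_pos_paired <- sum(status$baseline_positive[paired])
  gained <- sum(paired & !status$baseline_positive & status$week6_positive)
  lost <- sum(paired & status$baseline_positive & !status$week6_positive)
  week6_pos <- sum(status$week6_positive[paired])
  any_pos <- sum(status$any_positive)
  if (week6_pos != baseline_pos_paired + gained - lost)
    stop("seroconversion identity violated: week6 != baseline + gained - lost",
         call. = FALSE)
  if (any_pos != baseline_pos + gained)
    stop("seroconversion identity violated: any != baseline + gained",
         call. = FALSE)
  list(baseline_positive = baseline_pos,
       baseline_positive_paired = baseline_pos_paired,
       gained = gained, lost = lost, week6_positive = week6_pos,
       any_positive = any_pos, n_paired = sum(paired))
}

# Fisher when any expected cell count < 5, else chi-squared
categorical_test <- function(tab) {
  if (any(dim(tab) < 2)) return(NA_real_)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    fisher.test(tab)$p.value
  } else {
    suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
  }
}

#' Compare baseline-seropositive and seronegative patients
#'
#' Per characteristic: continuous traits (age, irAE count) via Wilcoxon
#' rank-sum; categorical traits (sex, severity class, timing class, each
#' organ) via Fisher's exact test, switching to the chi-squared test when
#' every expected cell count is at least 5.
#'
#' @param clinical Clinical data frame.
#' @param events Events data frame.
#' @param status Output of [classify_serostatus()].
#' @param organs Organ categories tested.
#' @return Data frame `characteristic`, `test`, `p`, `n_positive`,
#'   `n_negative`; tests are skipped (`p = NA`) when a stratum is empty.
#' @export
compare_serogroups <- function(clinical, events, status,
                               organs = irae_organs()) {
  pos <- status$patient_id[status$baseline_positive]
  neg <- status$patient_id[!status$baseline_positive]
  rows <- list()
  add <- function(name, test, p) {
    rows[[length(rows) + 1L]] <<- data.frame(
      characteristic = name, test = test, p = p,
      n_positive = length(pos), n_negative = length(neg),
      stringsAsFactors = FALSE)
  }
  if (!length(pos) || !length(neg)) {
    add("all", "skipped", NA_real_)
    return(do.call(rbind, rows))
  }
  grp <- factor(ifelse(clinical$patient_id %in% pos, "positive", "negative"))
  identical_groups <- function(x) length(unique(x)) == 1L
  # continuous traits
  counts <- distinct_organ_counts(events, clinical$patient_id, organs)
  for (trait in list(list("age", clinical$age),
                     list("n_irae", as.numeric(counts)))) {
    x <- trait[[2]]
    p <- if (identical_groups(x)) 1 else
      suppressWarnings(wilcox.test(x[grp == "positive"],
                                   x[grp == "negative"])$p.value)
    add(trait[[1]], "wilcoxon", p)
  }
  # categorical traits
  qual <- qualifying_events(events, organs)
  mx <- tapply(qual$grade, qual$patient_id, max)
  sev <- ifelse(is.na(mx[clinical$patient_id]), "none",
                ifelse(mx[clinical$patient_id] >= 3, "severe", "mild"))
  first <- tapply(qual$onset_week, qual$patient_id, min)
  timing <- ifelse(is.na(first[clinical$patient_id]), "none",
                   ifelse(first[clinical$patient_id] < 6, "early", "late"))
  cats <- list(sex = clinical$sex, severity = sev, timing = timing)
  for (nm in names(cats)) {
    tab <- table(cats[[nm]], grp)
    p <- if (nrow(tab) < 2) 1 else categorical_test(tab)
    add(nm, "fisher_or_chisq", p)
  }
  for (org in organs) {
    hit <- clinical$patient_id %in% unique(qual$patient_id[qual$organ == org])
    tab <- table(factor(hit, c(FALSE, TRUE)), grp)
    p <- if (identical_groups(hit)) 1 else categorical_test(tab)
    add(org, "fisher_or_chisq", p)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimator of the survival function, with the median defined
#' as the earliest time at which the estimate drops to 0.5 or below
#' (undefined when the curve never reaches 0.5).
#'
#' @param time Follow-up times (>= 0).
#' @param event Event indicator (1 = event, 0 = censored).
#' @return List: `curve` (data frame `time`, `n_risk`, `n_event`,
#'   `survival`), `median`, `n`, `fit` (the underlying
#'   [survival::survfit()] object).
#' @export
km_estimate <- function(time, event) {
  if (any(time < 0)) stop("negative follow-up times", call. = FALSE)
  if (!length(time)) stop("need at least one subject", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  curve <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, survival = fit$surv)
  med <- curve$time[curve$survival <= 0.5][1]
  list(curve = curve, median = med, n = length(time), fit = fit)
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank chi-square comparing the survival experience of
#' two groups, two-sided.  Undefined (flagged) when neither group has any
#' event.
#'
#' @param time_a,event_a Times and event flags for group A.
#' @param time_b,event_b Times and event flags for group B.
#' @return List: `chisq`, `p`, `defined`.
#' @export
logrank <- function(time_a, event_a, time_b, event_b) {
  if (!length(time_a) || !length(time_b))
    stop("both groups must be nonempty", call. = FALSE)
  if (sum(event_a) + sum(event_b) == 0)
    return(list(chisq = NA_real_, p = NA_real_, defined = FALSE))
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  group <- rep(c("A", "B"), c(length(time_a), length(time_b)))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(chisq = sd_$chisq, p = pchisq(sd_$chisq, df = 1, lower.tail = FALSE),
       defined = TRUE)
}

#' Build a time-to-event table for one endpoint
#'
#' * `first_irae` — time (weeks) to the first definite/probable event of an
#'   organ of interest; event-free patients are censored at last follow-up.
#' * `first_severe_irae` — same, restricted to grade 3-5 events.
#' * `pfs` / `os` — months, restricted to stage IV patients, taken from the
#'   survival table.
#'
#' @param events Events data frame.
#' @param clinical Clinical data frame (needs `followup_months` for
#'   censoring of the irAE endpoints and `stage` for PFS/OS restriction).
#' @param survival_tab Survival data frame (`pfs_months`, `pfs_event`,
#'   `os_months`, `os_event`) — required for `pfs`/`os`.
#' @param endpoint One of `"first_irae"`, `"first_severe_irae"`, `"pfs"`,
#'   `"os"`.
#' @param organs Organ categories of interest.
#' @return Data frame `patient_id`, `time`, `event` (1/0), `endpoint`;
#'   time unit is weeks for irAE endpoints, months for PFS/OS.
#' @export
build_time_to_event <- function(events, clinical, survival_tab = NULL,
                                endpoint = c("first_irae",
                                             "first_severe_irae",
                                             "pfs", "os"),
                                organs = irae_organs()) {
  endpoint <- match.arg(endpoint)
  if (endpoint %in% c("pfs", "os")) {
    if (is.null(survival_tab))
      stop("PFS/OS endpoints require the survival table", call. = FALSE)
    sub <- merge(survival_tab,
                 clinical[, c("patient_id", "stage")], by = "patient_id",
                 suffixes = c("", ".clin"))
    sub <- sub[sub$stage == "IV", , drop = FALSE]
    col <- if (endpoint == "pfs") c("pfs_months", "pfs_event")
           else c("os_months", "os_event")
    out <- data.frame(patient_id = sub$patient_id, time = sub[[col[1]]],
                      event = sub[[col[2]]], endpoint = endpoint,
                      stringsAsFactors = FALSE)
    return(out)
  }
  qual <- qualifying_events(events, organs)
  if (endpoint == "first_severe_irae")
    qual <- qual[qual$grade >= 3, , drop = FALSE]
  first <- tapply(qual$onset_week, qual$patient_id, min)
  fu_weeks <- clinical$followup_months * (52 / 12)
  idx <- match(clinical$patient_id, names(first))
  has <- !is.na(idx)
  out <- data.frame(patient_id = clinical$patient_id,
                    time = ifelse(has, first[idx], fu_weeks),
                    event = as.integer(has), endpoint = endpoint,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
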