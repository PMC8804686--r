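# Cohort characteristics table and the centralized n (%) arithmetic.

#' Percentage with half-up rounding
#'
#' Central helper for every printed "n (%)" value: `100 * n / d`, rounded
#' half-up (not banker's rounding) to the requested number of decimals.
#'
#' @param numerator,denominator Counts with `0 <= numerator <= denominator`,
#'   `denominator > 0`.
#' @param decimals Decimal places (default 1).
#' @return Numeric percentage.
#' @examples
#' proportion(28, 60)  # 46.7
#' proportion(38, 60, 0)  # 63
#' @export
proportion <- function(numerator, denominator, decimals = 1) {
  if (any(denominator <= 0)) stop("denominator must be > 0", call. = FALSE)
  if (any(numerator < 0) || any(numerator > denominator))
    stop("numerator must lie in [0, denominator]", call. = FALSE)
  round_half_up(100 * numerator / denominator, decimals)
}

med_iqr <- function(x) {
  q <- quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
  sprintf("%g (%g, %g)", q[2], q[1], q[3])
}

#' Cohort characteristics summary
#'
#' Builds the standard characteristics table: medians with IQR for age,
#' ICI cycles and distinct-irAE count; n (%) rows for sex, stage, melanoma
#' type, maximum-grade category (none / mild grade 1-2 / severe grade 3-5),
#' timing of the first event (< 6 vs >= 6 weeks, among all patients) and of
#' the first severe event (among severe patients), and baseline / week-6 /
#' any-timepoint seropositivity.  Percentages are computed with
#' [proportion()] on the stated denominators.
#'
#' @param clinical Clinical data frame.
#' @param events Events data frame.
#' @param status Output of [classify_serostatus()] (optional; adds the
#'   serology rows).
#' @param organs Organ categories of interest.
#' @return Data frame `characteristic`, `value`, `n`, `percent` (NA for
#'   median rows, where `value` carries "median (IQR)").
#' @export
summarize_cohort <- function(clinical, events, status = NULL,
                             organs = irae_organs()) {
  n <- nrow(clinical)
  if (!n) stop("empty cohort", call. = FALSE)
  qual <- qualifying_events(events, organs)
  counts <- distinct_organ_counts(events, clinical$patient_id, organs)
  rows <- list()
  add <- function(characteristic, value, count = NA_integer_,
                  percent = NA_real_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      characteristic = characteristic, value = value,
      n = count, percent = percent, stringsAsFactors = FALSE)
  }
  add("age_median_iqr", med_iqr(clinical$age))
  add("sex_male", "n_pct", sum(clinical$sex == "male"),
      proportion(sum(clinical$sex == "male"), n, 0))
  for (st in c("III", "IV")) {
    k <- sum(clinical$stage == st)
    add(paste0("stage_", st), "n_pct", k, proportion(k, n, 0))
  }
  for (mt in unique(clinical$melanoma_type)) {
    k <- sum(clinical$melanoma_type == mt)
    add(paste0("melanoma_", mt), "n_pct", k, proportion(k, n, 1))
  }
  add("ici_cycles_median_iqr", med_iqr(clinical$ici_cycles))
  add("n_irae_median_iqr", med_iqr(counts))
  mx <- tapply(qual$grade, qual$patient_id, max)
  sev <- ifelse(is.na(mx[clinical$patient_id]), "none",
                ifelse(mx[clinical$patient_id] >= 3, "severe", "mild"))
  for (cat_ in c("none", "mild", "severe")) {
    k <- sum(sev == cat_)
    add(paste0("max_grade_", cat_), "n_pct", k, proportion(k, n, 1))
  }
  first <- tapply(qual$onset_week, qual$patient_id, min)
  ft <- first[clinical$patient_id]
  add("first_irae_lt6w", "n_pct", sum(!is.na(ft) & ft < 6),
      proportion(sum(!is.na(ft) & ft < 6), n, 0))
  add("first_irae_ge6w", "n_pct", sum(!is.na(ft) & ft >= 6),
      proportion(sum(!is.na(ft) & ft >= 6), n, 0))
  sev_qual <- qual[qual$grade >= 3, , drop = FALSE]
  if (nrow(sev_qual)) {
    fs <- tapply(sev_qual$onset_week, sev_qual$patient_id, min)
    d <- length(fs)
    add("first_severe_lt6w", "n_pct", sum(fs < 6), proportion(sum(fs < 6), d, 0))
    add("first_severe_ge6w", "n_pct", sum(fs >= 6),
        proportion(sum(fs >= 6), d, 0))
  }
  if (!is.null(status)) {
    nb <- nrow(status)
    nw <- sum(!is.na(status$week6_positive))
    add("seropositive_baseline", "n_pct", sum(status$baseline_positive),
        proportion(sum(status$baseline_positive), nb, 0))
    if (nw > 0)
      add("seropositive_week6", "n_pct",
          sum(status$week6_positive, na.rm = TRUE),
          proportion(sum(status$week6_positive, na.rm = TRUE), nw, 0))
    add("seropositive_any", "n_pct", sum(status$any_positive),
        proportion(sum(status$any_positive), nb, 0))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
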