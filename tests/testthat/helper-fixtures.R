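# shared fixture builders (all data constructed in code)

# wrap a plain matrix as an abs_matrix object
make_abs_matrix <- function(values, controls = NULL, isotype = "IgG",
                            timepoint = "baseline", normalized = FALSE) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("P%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("AG%03d", seq_len(ncol(values)))
  if (!is.null(controls) && is.null(rownames(controls)))
    dimnames(controls) <- list(rownames(values),
                               sprintf("CTRL%02d", seq_len(ncol(controls))))
  structure(list(values = values,
                 mask = matrix(TRUE, nrow(values), ncol(values),
                               dimnames = dimnames(values)),
                 controls = controls, isotype = isotype,
                 timepoint = timepoint, normalized = normalized),
            class = "abs_matrix")
}

make_cluster_result <- function(patient_id, label) {
  structure(list(assignments = data.frame(patient_id = patient_id,
                                          cluster = as.integer(factor(label)),
                                          label = label,
                                          stringsAsFactors = FALSE),
                 means = NULL, hclust = NULL, k = length(unique(label)),
                 linkage = "complete"),
            class = "cluster_result")
}

event_row <- function(patient_id, organ = "gastrointestinal", grade = 2,
                      onset_week = 3, attribution = "definite") {
  data.frame(patient_id = patient_id, organ = organ, grade = grade,
             onset_week = onset_week, attribution = attribution,
             stringsAsFactors = FALSE)
}

no_events <- function() {
  data.frame(patient_id = character(), organ = character(),
             grade = integer(), onset_week = numeric(),
             attribution = character(), stringsAsFactors = FALSE)
}

# events table reproducing the marginal structure of the trial cohort:
# 60 patients; first irAE < 6 weeks for 38, >= 6 weeks for 17, none for 5;
# 28 patients with a severe (grade 3-5) event, of whom 6 have their first
# severe event before 6 weeks and 22 at or after 6 weeks
table1_events <- function() {
  ids <- sprintf("P%03d", 1:60)
  rows <- list()
  for (i in 1:38) rows[[length(rows) + 1L]] <-
    event_row(ids[i], "dermatologic", grade = 2, onset_week = 3)
  for (i in 39:55) rows[[length(rows) + 1L]] <-
    event_row(ids[i], "hepatic", grade = 2, onset_week = 10)
  severe_ids <- ids[c(1:20, 39:46)]          # 28 severe patients
  early_severe <- severe_ids[1:6]
  for (p in severe_ids) rows[[length(rows) + 1L]] <-
    event_row(p, "gastrointestinal", grade = 3,
              onset_week = if (p %in% early_severe) 3 else 9)
  do.call(rbind, rows)
}

table1_clinical <- function() {
  ids <- sprintf("P%03d", 1:60)
  data.frame(patient_id = ids, age = 63,
             sex = rep(c("male", "female"), c(38, 22)),
             stage = rep(c("IV", "III"), c(51, 9)),
             melanoma_type = "cutaneous", ici_cycles = 5,
             followup_months = 25, stringsAsFactors = FALSE)
}

# serology with 17 baseline positives (all drawn at week 6), 7 who gain
# positivity and 5 who lose it
table1_serology <- function() {
  ids <- sprintf("P%03d", 1:60)
  base_pos <- ids[1:17]
  wk6_pos <- c(ids[6:17], ids[18:24])  # 17 - 5 lost + 7 gained = 19
  rbind(
    data.frame(patient_id = ids, timepoint = "baseline",
               ana_positive = ids %in% base_pos, rf_iu_ml = 3, ccp_u_ml = 3,
               stringsAsFactors = FALSE),
    data.frame(patient_id = ids, timepoint = "week6",
               ana_positive = ids %in% wk6_pos, rf_iu_ml = 3, ccp_u_ml = 3,
               stringsAsFactors = FALSE))
}

# small default study cached per test run
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_cohort(cohort_config(n_patients = 24,
                                              n_antigens = 30, seed = 42))
    cache
  }
})
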