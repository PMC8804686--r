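sero_row <- function(id, tp, ana = FALSE, rf = 3, ccp = 3) {
  data.frame(patient_id = id, timepoint = tp, ana_positive = ana,
             rf_iu_ml = rf, ccp_u_ml = ccp, stringsAsFactors = FALSE)
}

test_that("seropositivity thresholds are strict inequalities", {
  pan <- rbind(sero_row("P001", "baseline", rf = 14.0),
               sero_row("P002", "baseline", rf = 14.01),
               sero_row("P003", "baseline", ccp = 20.5),
               sero_row("P004", "baseline", ccp = 20.0))
  st <- classify_serostatus(pan)
  expect_identical(st$baseline_positive, c(FALSE, TRUE, TRUE, FALSE))
  expect_identical(st$rf_baseline, c(FALSE, TRUE, FALSE, FALSE))
  expect_identical(st$ccp_baseline, c(FALSE, FALSE, TRUE, FALSE))
  expect_error(classify_serostatus(
    sero_row("P001", "baseline", rf = -1)), "negative")
})

test_that("week-6-only positivity is overall-positive, baseline-negative", {
  pan <- rbind(sero_row("P001", "baseline"),
               sero_row("P001", "week6", ana = TRUE),
               sero_row("P002", "baseline"))
  st <- classify_serostatus(pan)
  p1 <- st[st$patient_id == "P001", ]
  expect_false(p1$baseline_positive)
  expect_true(p1$week6_positive)
  expect_true(p1$any_positive)
  # P002 has no week-6 draw: unknown, excluded from week-6 accounting
  expect_true(is.na(st$week6_positive[st$patient_id == "P002"]))
})

test_that("raising a titer never flips a positive to negative", {
  set.seed(31)
  for (i in 1:25) {
    pan <- sero_row(sprintf("P%03d", 1:8), "baseline",
                    ana = runif(8) < 0.3, rf = runif(8, 0, 30),
                    ccp = runif(8, 0, 40))
    before <- classify_serostatus(pan)$baseline_positive
    pan$rf_iu_ml <- pan$rf_iu_ml + runif(8, 0, 20)
    pan$ccp_u_ml <- pan$ccp_u_ml + runif(8, 0, 20)
    after <- classify_serostatus(pan)$baseline_positive
    expect_true(all(after >= before))
  }
})

test_that("seroconversion flow reproduces the bookkeeping identities", {
  acc <- seroconversion_accounting(classify_serostatus(table1_serology()))
  expect_identical(acc$baseline_positive, 17L)
  expect_identical(acc$gained, 7L)
  expect_identical(acc$lost, 5L)
  expect_identical(acc$week6_positive, 19L)   # 17 + 7 - 5
  expect_identical(acc$any_positive, 24L)     # 17 + 7

  # no conversions: week6 equals baseline
  pan <- rbind(sero_row(c("P001", "P002"), "baseline", ana = c(TRUE, FALSE)),
               sero_row(c("P001", "P002"), "week6", ana = c(TRUE, FALSE)))
  acc0 <- seroconversion_accounting(classify_serostatus(pan))
  expect_identical(acc0$week6_positive, acc0$baseline_positive)
})

test_that("serogroup comparison returns p = 1 for identical strata", {
  cl <- table1_clinical()
  cl$age <- 60; cl$sex <- "male"
  status <- classify_serostatus(table1_serology())
  tab <- compare_serogroups(cl, no_events(), status)
  expect_true(all(tab$p == 1, na.rm = TRUE))
})

test_that("organ-specific serogroup tests match the exact-enumeration oracle", {
  cl <- table1_clinical()
  status <- classify_serostatus(table1_serology())   # 17 positive at baseline
  ids <- cl$patient_id
  # thyroid events in 10 seronegative patients only -> table [[0,17],[10,33]]
  ev <- do.call(rbind, lapply(ids[18:27], event_row, organ = "thyroid"))
  tab <- compare_serogroups(cl, ev, status)
  p_pkg <- tab$p[tab$characteristic == "thyroid"]
  probs <- dhyper(0:10, 10, 50, 17)   # events in the positive group
  p_oracle <- sum(probs[probs <= probs[1] * (1 + 1e-7)])
  expect_equal(p_pkg, p_oracle)
  # empty stratum: tests are skipped, not errored
  status_all_neg <- status
  status_all_neg$baseline_positive <- FALSE
  skipped <- compare_serogroups(cl, ev, status_all_neg)
  expect_true(all(is.na(skipped$p)))
})

test_that("KM estimator matches the closed form without censoring", {
  time <- c(5, 1, 3, 2, 4)
  km <- km_estimate(time, rep(1, 5))
  expect_equal(km$curve$survival, seq(0.8, 0, by = -0.2))
  expect_equal(km$curve$time, 1:5)
  expect_identical(km$median, 3)   # earliest time with S <= 0.5

  all_cens <- km_estimate(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(all_cens$curve$survival == 1))
  expect_true(is.na(all_cens$median))
  expect_error(km_estimate(-1, 1), "negative")
})

test_that("log-rank is symmetric, zero for identical groups", {
  t1 <- c(1, 3, 5, 7); e1 <- c(1, 1, 0, 1)
  same <- logrank(t1, e1, t1, e1)
  expect_equal(same$chisq, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)
  t2 <- c(2, 4, 6, 9); e2 <- c(1, 0, 1, 1)
  ab <- logrank(t1, e1, t2, e2)
  ba <- logrank(t2, e2, t1, e1)
  expect_equal(ab$chisq, ba$chisq)
  expect_gte(ab$chisq, 0)
  none <- logrank(t1, c(0, 0, 0, 0), t2, c(0, 0, 0, 0))
  expect_false(none$defined)
})

test_that("time-to-event tables follow the endpoint rules", {
  cl <- table1_clinical()[1:3, ]
  ev <- rbind(event_row("P001", "hepatic", grade = 2, onset_week = 3),
              event_row("P001", "thyroid", grade = 2, onset_week = 10),
              event_row("P002", "dermatologic", grade = 2, onset_week = 4))
  tt <- build_time_to_event(ev, cl, endpoint = "first_irae")
  expect_equal(tt$time[tt$patient_id == "P001"], 3)
  expect_identical(tt$event[tt$patient_id == "P001"], 1L)
  # P003 has no event: censored at last follow-up (25 months in weeks)
  expect_identical(tt$event[tt$patient_id == "P003"], 0L)
  expect_equal(tt$time[tt$patient_id == "P003"], 25 * 52 / 12)

  sev <- build_time_to_event(ev, cl, endpoint = "first_severe_irae")
  expect_identical(sum(sev$event), 0L)   # only grade-2 events

  surv <- data.frame(patient_id = cl$patient_id, stage = cl$stage,
                     pfs_months = c(5, 8, 12), pfs_event = c(1, 0, 1),
                     os_months = c(10, 20, 25), os_event = c(1, 0, 0),
                     stringsAsFactors = FALSE)
  pfs <- build_time_to_event(ev, cl, surv, endpoint = "pfs")
  expect_true(all(pfs$patient_id %in%
                    cl$patient_id[cl$stage == "IV"]))
  expect_error(build_time_to_event(ev, cl, endpoint = "pfs"),
               "survival table")
})

test_that("severe-endpoint event count matches the cohort marginals", {
  tt <- build_time_to_event(table1_events(), table1_clinical(),
                            endpoint = "first_severe_irae")
  expect_identical(sum(tt$event), 28L)
  early <- sum(tt$time[tt$event == 1] < 6)
  expect_identical(early, 6L)
})
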