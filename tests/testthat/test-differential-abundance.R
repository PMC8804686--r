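test_that("organ, timing and severity groupings follow the event rules", {
  ev <- table1_events()
  ids <- sprintf("P%03d", 1:60)

  timing <- assign_groups(ev, ids, grouping_spec("timing"))
  expect_identical(sum(timing$group == "A"), 38L)
  expect_identical(sum(timing$group == "B"), 17L)
  expect_identical(sum(timing$group == "excluded"), 5L)

  sev <- assign_groups(ev, ids, grouping_spec("severity"))
  expect_identical(sum(sev$group == "A"), 28L)
  expect_identical(sum(sev$group == "B"), 27L)

  org <- assign_groups(ev, ids, grouping_spec("organ", organ = "hepatic"))
  expect_identical(sum(org$group == "A"), 17L)
  expect_identical(sum(org$group == "B"), 43L)
})

test_that("grouping matches an independent recount on generated events", {
  st <- small_study()
  ids <- st$clinical$patient_id
  sev <- assign_groups(st$events, ids, grouping_spec("severity"))
  # brute-force recount straight off the events table
  qual <- st$events[st$events$attribution %in% c("definite", "probable"), ]
  expected <- vapply(ids, function(p) {
    g <- qual$grade[qual$patient_id == p]
    if (!length(g)) "excluded" else if (max(g) >= 3) "A" else "B"
  }, character(1))
  expect_identical(sev$group, unname(expected))
})

test_that("attribution filter keeps only definite/probable events", {
  ev <- rbind(event_row("P001", "hepatic", attribution = "possible"),
              event_row("P002", "hepatic", attribution = "definite"))
  ga <- assign_groups(ev, c("P001", "P002", "P003"),
                      grouping_spec("organ", organ = "hepatic"))
  expect_identical(ga$group, c("B", "A", "B"))
})

test_that("a one-group cohort is flagged degenerate", {
  ev <- do.call(rbind, lapply(sprintf("P%03d", 1:6), event_row))
  ga <- assign_groups(ev, sprintf("P%03d", 1:6),
                      grouping_spec("organ", organ = "gastrointestinal"))
  expect_true(attr(ga, "degenerate"))
  expect_error(assign_groups(ev, "P001", list(type = "bogus")), "unknown")
})

test_that("Mann-Whitney comparison handles exact and degenerate cases", {
  same <- compare_antigen(c(1, 2, 3), c(1, 2, 3))
  expect_identical(same$log2fc, 0)
  expect_equal(same$p_raw, 1)
  expect_identical(compare_antigen(c(2, 2), c(2, 2)),
                   list(log2fc = 0, p_raw = 1))
  # complete separation at 3 vs 3: exact two-sided p = 2 / choose(6, 3)
  sep <- compare_antigen(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$p_raw, 0.1)
  expect_equal(sep$log2fc, -3)
  expect_error(compare_antigen(numeric(), 1), "at least one")
})

test_that("Mann-Whitney p is invariant under monotone transforms and
           label swap negates the fold change", {
  set.seed(33)
  for (i in 1:20) {
    a <- rnorm(7 + i %% 5); b <- rnorm(9, 0.5)
    r <- compare_antigen(a, b)
    r_mono <- compare_antigen(exp(a), exp(b))
    expect_equal(r_mono$p_raw, r$p_raw)
    r_swap <- compare_antigen(b, a)
    expect_equal(r_swap$p_raw, r$p_raw)
    expect_equal(r_swap$log2fc, -r$log2fc)
  }
})

test_that("run_de adjusts with Benjamini-Hochberg within the family", {
  st <- small_study()
  m <- build_abs_matrix(st$signals, "IgG", "baseline")
  ga <- assign_groups(st$events, st$clinical$patient_id,
                      grouping_spec("severity"))
  de <- run_de(m, ga)
  expect_s3_class(de, "de_result")
  expect_identical(nrow(de), ncol(m$values))
  expect_equal(de$p_adj, p.adjust(de$p_raw, "BH"))
  expect_true(all(de$p_adj >= de$p_raw))
  expect_true(all(de$p_adj <= 1))
  # adjusted p is monotone in raw p
  ord <- order(de$p_raw)
  expect_true(all(diff(de$p_adj[ord]) >= -1e-12))
  # significance at a stricter alpha is a subset
  de01 <- run_de(m, ga, alpha = 0.01)
  expect_true(all(de01$antigen[de01$significant] %in%
                    de$antigen[de$significant]))
})

test_that("degenerate groupings return an empty result with a warning", {
  st <- small_study()
  m <- build_abs_matrix(st$signals, "IgG", "baseline")
  ga <- data.frame(patient_id = st$clinical$patient_id, group = "A",
                   stringsAsFactors = FALSE)
  expect_warning(de <- run_de(m, ga), "degenerate")
  expect_identical(nrow(de), 0L)
})

test_that("volcano sides follow the sign convention", {
  de <- structure(
    data.frame(antigen = c("AG001", "AG002", "AG003"),
               isotype = "IgG", timepoint = "baseline", n_A = 10, n_B = 10,
               log2fc = c(-2, 1.5, 0.2), p_raw = c(0.001, 0.2, 0.9),
               p_adj = c(0.01, 0.4, 0.9),
               significant = c(TRUE, FALSE, FALSE),
               stringsAsFactors = FALSE),
    class = c("de_result", "data.frame"))
  v <- volcano_table(de)
  expect_identical(v$side, c("non_event", "event", "event"))
  expect_identical(attr(v, "n_left"), 1L)
  expect_identical(attr(v, "n_right"), 0L)

  de_null <- de
  de_null$p_raw <- c(0.5, 0.6, 0.7); de_null$significant <- FALSE
  v0 <- volcano_table(de_null)
  expect_identical(attr(v0, "n_left") + attr(v0, "n_right"), 0L)
  expect_error(volcano_table(de[0, ]), "no differential")
})

test_that("planted negative shifts land on the left volcano side", {
  target <- sprintf("P%03d", 1:30)
  pe <- planted_effect(sprintf("AG%03d", 1:4), effect = -1.6,
                       grouping = "patients", patients = target)
  st <- generate_cohort(cohort_config(n_patients = 60, n_antigens = 40,
                                      isotypes = "IgG",
                                      planted_effects = list(pe), seed = 14))
  m <- normalize_rlm(build_abs_matrix(st$signals, "IgG", "baseline"))
  ga <- data.frame(patient_id = st$clinical$patient_id,
                   group = ifelse(st$clinical$patient_id %in% target,
                                  "A", "B"), stringsAsFactors = FALSE)
  v <- volcano_table(run_de(m, ga))
  sig_planted <- v[v$antigen %in% sprintf("AG%03d", 1:4) & v$significant_adj, ]
  expect_gt(nrow(sig_planted), 0)
  expect_true(all(sig_planted$side == "non_event"))
})
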