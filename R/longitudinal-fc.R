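# Baseline -> week-6 fold changes, the supervised event-ordered heatmap
# layout, and the association between fold-change magnitude and the number
# of distinct organ-specific events.

#' Per-patient antibody fold changes between timepoints
#'
#' Cellwise `ABS(week6) - ABS(baseline)` (a log2 fold change, since ABS is
#' already log2).  Only patients present in both matrices appear; excluded
#' patients are listed in the attached report.
#'
#' @param baseline,week6 `abs_matrix` objects sharing an antigen axis.
#' @return Object of class `fc_matrix`: list with `values` (patients x
#'   antigens FC matrix), `summary` (per patient: `mean_abs_fc`, `mean_fc`),
#'   `isotype`, and attribute `excluded` (patients lacking a week-6 draw).
#' @export
fold_changes <- function(baseline, week6) {
  stopifnot(inherits(baseline, "abs_matrix"), inherits(week6, "abs_matrix"))
  if (!identical(colnames(baseline$values), colnames(week6$values)))
    stop("matrices must share the antigen axis", call. = FALSE)
  common <- intersect(rownames(baseline$values), rownames(week6$values))
  if (!length(common))
    stop("no patients with both baseline and week-6 draws", call. = FALSE)
  excluded <- setdiff(rownames(baseline$values), common)
  fc <- week6$values[common, , drop = FALSE] -
    baseline$values[common, , drop = FALSE]
  summary <- data.frame(patient_id = common,
                        mean_abs_fc = rowMeans(abs(fc)),
                        mean_fc = rowMeans(fc), stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  structure(list(values = fc, summary = summary, isotype = baseline$isotype),
            class = "fc_matrix", excluded = excluded)
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf("<fc_matrix> %s: %d patients x %d antigens (%d excluded)\n",
              x$isotype, nrow(x$values), ncol(x$values),
              length(attr(x, "excluded"))))
  invisible(x)
}

#' Association between fold-change magnitude and irAE multiplicity
#'
#' Spearman correlation between each patient's mean absolute fold change
#' (over the supplied antigen set) and the number of distinct organ
#' categories with definite/probable events, plus a Kruskal-Wallis test
#' across the count strata.
#'
#' @param fc An `fc_matrix`.
#' @param events Events data frame.
#' @param organs Organ categories counted.
#' @return List: `n`, `rho`, `p_spearman`, `p_kruskal`, `per_patient`
#'   (data frame with `mean_abs_fc` and `n_organs`), `degenerate` flag
#'   (constant counts or constant fold changes make the correlation
#'   undefined).
#' @export
fc_vs_irae_count <- function(fc, events, organs = irae_organs()) {
  stopifnot(inherits(fc, "fc_matrix"))
  pp <- fc$summary
  if (nrow(pp) < 3) stop("need at least 3 patients", call. = FALSE)
  counts <- distinct_organ_counts(events, pp$patient_id, organs)
  pp$n_organs <- as.integer(counts[pp$patient_id])
  degenerate <- length(unique(pp$n_organs)) < 2 ||
    length(unique(pp$mean_abs_fc)) < 2
  if (degenerate) {
    return(list(n = nrow(pp), rho = NA_real_, p_spearman = NA_real_,
                p_kruskal = NA_real_, per_patient = pp, degenerate = TRUE))
  }
  ct <- suppressWarnings(cor.test(pp$mean_abs_fc, pp$n_organs,
                                  method = "spearman"))
  kw <- kruskal.test(pp$mean_abs_fc, factor(pp$n_organs))
  list(n = nrow(pp), rho = unname(ct$estimate), p_spearman = ct$p.value,
       p_kruskal = kw$p.value, per_patient = pp, degenerate = FALSE)
}

#' Supervised patient ordering for the event-annotated heatmap
#'
#' Orders patients for the supervised fold-change heatmap: event patients
#' first, sorted by descending number of distinct organ events and then by
#' descending mean absolute fold change; patients with no qualifying event
#' come last (stable within ties, preserving input order).  Also returns the
#' binary organ x patient indicator block for the annotation strip.
#'
#' @param fc An `fc_matrix`.
#' @param events Events data frame.
#' @param organs Organ categories shown.
#' @return List: `order` (patient ids in display order), `indicators`
#'   (organs x patients 0/1 matrix), `per_patient` sort-key table.
#' @export
supervised_order <- function(fc, events, organs = irae_organs()) {
  stopifnot(inherits(fc, "fc_matrix"))
  pp <- fc$summary
  counts <- distinct_organ_counts(events, pp$patient_id, organs)
  pp$n_organs <- as.integer(counts[pp$patient_id])
  pp$has_event <- pp$n_organs > 0
  # mean |FC| breaks ties among event patients only; the no-event block
  # keeps its input order (stable sort)
  ord <- order(-pp$has_event, -pp$n_organs,
               ifelse(pp$has_event, -pp$mean_abs_fc, 0))
  ids <- pp$patient_id[ord]
  qual <- qualifying_events(events, organs)
  ind <- matrix(0L, length(organs), length(ids),
                dimnames = list(organs, ids))
  for (org in organs) {
    hit <- unique(qual$patient_id[qual$organ == org])
    ind[org, ids %in% hit] <- 1L
  }
  list(order = ids, indicators = ind, per_patient = pp[ord, ])
}
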