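# Per-antigen group comparisons: Mann-Whitney tests, Benjamini-Hochberg
# adjustment, fold changes on the log2 antibody-score scale, and volcano
# bookkeeping.

#' Specify a patient grouping for differential abundance
#'
#' Three grouping families are supported, all derived from events attributed
#' definitely or probably to the checkpoint inhibitor:
#' * `"organ"` — patients with at least one qualifying event of the given
#'   organ (group A) versus all other patients (group B);
#' * `"timing"` — first qualifying event before 6 weeks (A) versus at or
#'   after 6 weeks (B); patients with no qualifying event are excluded;
#' * `"severity"` — maximum grade 3-5 ("severe", A) versus 1-2 (B);
#'   no-event patients are excluded.
#'
#' @param type `"organ"`, `"timing"` or `"severity"`.
#' @param organ Organ label (required for `type = "organ"`).
#' @param timing_cut Week threshold for the timing dichotomy (default 6).
#' @return An object of class `grouping_spec`.
#' @export
grouping_spec <- function(type = c("organ", "timing", "severity"),
                          organ = NULL, timing_cut = 6) {
  type <- match.arg(type)
  if (type == "organ" && is.null(organ))
    stop("organ grouping requires an organ label", call. = FALSE)
  structure(list(type = type, organ = organ, timing_cut = timing_cut),
            class = "grouping_spec")
}

qualifying_events <- function(events, organs = irae_organs()) {
  events[events$attribution %in% c("definite", "probable") &
           events$organ %in% organs, , drop = FALSE]
}

#' Assign patients to comparison groups
#'
#' @param events Events data frame (`patient_id`, `organ`, `grade`,
#'   `onset_week`, `attribution`).
#' @param ids All patient ids in the cohort.
#' @param spec A [grouping_spec()].
#' @param organs Organ categories counted as events of interest.
#' @return Data frame `patient_id`, `group` (`"A"`, `"B"` or `"excluded"`),
#'   with an attribute `degenerate` set when either group is empty.
#' @export
assign_groups <- function(events, ids, spec, organs = irae_organs()) {
  if (!inherits(spec, "grouping_spec"))
    stop("unknown grouping spec", call. = FALSE)
  qual <- qualifying_events(events, organs)
  group <- rep("excluded", length(ids))
  if (spec$type == "organ") {
    hit <- unique(qual$patient_id[qual$organ == spec$organ])
    group <- ifelse(ids %in% hit, "A", "B")
  } else if (spec$type == "timing") {
    first <- tapply(qual$onset_week, qual$patient_id, min)
    idx <- match(ids, names(first))
    group[!is.na(idx) & first[idx] < spec$timing_cut] <- "A"
    group[!is.na(idx) & first[idx] >= spec$timing_cut] <- "B"
  } else {
    mx <- tapply(qual$grade, qual$patient_id, max)
    idx <- match(ids, names(mx))
    group[!is.na(idx) & mx[idx] >= 3] <- "A"
    group[!is.na(idx) & mx[idx] <= 2] <- "B"
  }
  out <- data.frame(patient_id = ids, group = group, stringsAsFactors = FALSE)
  attr(out, "degenerate") <- !all(c("A", "B") %in% group)
  out
}

#' Compare one antigen's scores between two groups
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test: exact when the pooled
#' size is <= 20 with no ties, otherwise the tie-corrected normal
#' approximation with continuity correction.  The fold change is the
#' difference of group means on the ABS scale (already log2), with the sign
#' convention positive = higher in group A (the event group).
#'
#' @param a,b Numeric ABS values for groups A and B.
#' @return List with `log2fc` and `p_raw`.
#' @export
compare_antigen <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (!length(a) || !length(b))
    stop("both groups need at least one observation", call. = FALSE)
  if (length(unique(c(a, b))) == 1L)
    return(list(log2fc = 0, p_raw = 1))
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= 20) && !ties
  p <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = TRUE)$p.value)
  list(log2fc = mean(a) - mean(b), p_raw = min(p, 1))
}

#' Differential antibody abundance across an ABS matrix
#'
#' Runs [compare_antigen()] per antigen between the two groups of a
#' [grouping_spec()] assignment and applies Benjamini-Hochberg adjustment
#' across the retained antigens of this one (isotype, timepoint, grouping)
#' family.  Significance for downstream antigen sets uses the adjusted p
#' value.
#'
#' @param m An `abs_matrix` (normalized and antigen-filtered).
#' @param groups Output of [assign_groups()].
#' @param alpha Significance level on the adjusted p value (default 0.05).
#' @return Data frame of class `de_result`: `antigen`, `isotype`,
#'   `timepoint`, `n_A`, `n_B`, `log2fc`, `p_raw`, `p_adj`, `significant`.
#'   Degenerate groupings return an empty result with a warning.
#' @export
run_de <- function(m, groups, alpha = 0.05) {
  stopifnot(inherits(m, "abs_matrix"))
  empty <- data.frame(antigen = character(), isotype = character(),
                      timepoint = character(), n_A = integer(),
                      n_B = integer(), log2fc = numeric(),
                      p_raw = numeric(), p_adj = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
  ids_a <- groups$patient_id[groups$group == "A"]
  ids_b <- groups$patient_id[groups$group == "B"]
  ids_a <- intersect(ids_a, rownames(m$values))
  ids_b <- intersect(ids_b, rownames(m$values))
  if (!length(ids_a) || !length(ids_b)) {
    warning("degenerate grouping: one group is empty; returning no results",
            call. = FALSE)
    return(structure(empty, class = c("de_result", "data.frame")))
  }
  ags <- colnames(m$values)
  res <- lapply(ags, function(ag) {
    cmp <- compare_antigen(m$values[ids_a, ag], m$values[ids_b, ag])
    data.frame(antigen = ag, isotype = m$isotype, timepoint = m$timepoint,
               n_A = length(ids_a), n_B = length(ids_b),
               log2fc = cmp$log2fc, p_raw = cmp$p_raw,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- p.adjust(out$p_raw, method = "BH")
  out$significant <- out$p_adj < alpha
  structure(out, class = c("de_result", "data.frame"))
}

#' Volcano table from differential-abundance results
#'
#' Plot-ready table of log2 fold change against -log10 raw p, with the
#' standard sign convention: antigens on the left (negative log2 FC) are
#' higher in the non-event group, antigens on the right higher in the event
#' group.  The raw-p significance line sits at `p_line` (default 0.05, the
#' dotted horizontal of a volcano plot); corner counts of raw-significant
#' antigens per side are attached as attributes.
#'
#' @param de A `de_result` data frame.
#' @param p_line Raw p value of the significance line.
#' @return Data frame `antigen`, `log2fc`, `neg_log10_p`, `significant_raw`,
#'   `significant_adj`, `side`; attributes `n_left` / `n_right` hold the
#'   corner counts (raw p below the line on each side).
#' @export
volcano_table <- function(de, p_line = 0.05) {
  if (!nrow(de)) stop("no differential-abundance results", call. = FALSE)
  side <- ifelse(de$log2fc < 0, "non_event", ifelse(de$log2fc > 0, "event",
                                                    "none"))
  out <- data.frame(antigen = de$antigen, log2fc = de$log2fc,
                    neg_log10_p = -log10(pmax(de$p_raw, .Machine$double.xmin)),
                    significant_raw = de$p_raw < p_line,
                    significant_adj = de$significant,
                    side = side, stringsAsFactors = FALSE)
  attr(out, "n_left") <- sum(out$significant_raw & side == "non_event")
  attr(out, "n_right") <- sum(out$significant_raw & side == "event")
  out
}

#' Union of significant antigens over the organ-specific comparisons
#'
#' Convenience wrapper: runs [run_de()] for each organ grouping at one
#' isotype/timepoint and returns the union of antigens significant after
#' adjustment — the antigen set the patient clustering stage consumes.
#'
#' @param m An `abs_matrix`.
#' @param events Events data frame.
#' @param ids Cohort patient ids.
#' @param organs Organ categories to iterate over.
#' @param alpha Adjusted-p significance level.
#' @param fallback_n When no antigen reaches significance, fall back to the
#'   `fallback_n` antigens with the smallest raw p over all comparisons (so
#'   clustering still has a substrate); set to 0 to disable.
#' @return Character vector of antigen labels.
#' @export
de_antigen_union <- function(m, events, ids, organs = irae_organs(),
                             alpha = 0.05, fallback_n = 20) {
  sig <- character()
  best <- list()
  for (org in organs) {
    ga <- assign_groups(events, ids, grouping_spec("organ", organ = org),
                        organs)
    if (attr(ga, "degenerate")) next
    de <- suppressWarnings(run_de(m, ga, alpha))
    if (!nrow(de)) next
    sig <- union(sig, de$antigen[de$significant])
    best[[org]] <- de[, c("antigen", "p_raw")]
  }
  if (!length(sig) && fallback_n > 0 && length(best)) {
    all_p <- do.call(rbind, best)
    ord <- all_p[order(all_p$p_raw), ]
    sig <- unique(ord$antigen)[seq_len(min(fallback_n,
                                           length(unique(ord$antigen))))]
  }
  sig
}
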