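# Total-immunoglobulin quartile analyses and the Ig-normalization
# sensitivity check on the microarray differential-abundance results.

#' Assign total-Ig quartiles
#'
#' Quartile cut points use the linear-interpolation sample quantile
#' (R's default, type 7).  Values at or below the first cut point fall in
#' Q1, and so on; tied values land in the same quartile (ties cannot be
#' split), so a degenerate all-equal input collapses into Q1 and is
#' flagged.
#'
#' @param levels Positive numeric vector of total Ig (mg/dL), named by or
#'   aligned with patient ids.
#' @param ids Patient identifiers (defaults to names of `levels`).
#' @return Data frame `patient_id`, `level`, `quartile` (factor Q1-Q4);
#'   attribute `degenerate` set when the cut points collapse.
#' @export
assign_quartiles <- function(levels, ids = names(levels)) {
  if (length(levels) < 4)
    stop("need at least 4 patients for quartiles", call. = FALSE)
  if (any(!is.finite(levels)) || any(levels <= 0))
    stop("Ig levels must be positive and finite", call. = FALSE)
  if (is.null(ids)) ids <- patient_ids(length(levels))
  cuts <- quantile(levels, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  q <- 1L + (levels > cuts[1]) + (levels > cuts[2]) + (levels > cuts[3])
  degenerate <- length(unique(cuts)) < 3
  out <- data.frame(patient_id = ids, level = levels,
                    quartile = factor(paste0("Q", q),
                                      levels = paste0("Q", 1:4)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "degenerate") <- degenerate
  if (degenerate)
    warning("degenerate Ig levels: quartile cut points collapse",
            call. = FALSE)
  out
}

#' Associations between Ig quartiles and clinical traits
#'
#' Fisher's exact test of quartile membership against categorical traits
#' (irAE timing class, melanoma type, stage, maximum severity class),
#' Wilcoxon rank-sum for sex against the Ig level itself, and a log-rank
#' test of highest versus lowest quartile for PFS and OS (stage IV only).
#'
#' @param quartiles Output of [assign_quartiles()].
#' @param clinical Clinical data frame.
#' @param events Events data frame.
#' @param survival_tab Survival data frame (optional; enables PFS/OS rows).
#' @param organs Organ categories of interest.
#' @return Data frame `characteristic`, `test`, `p`.
#' @export
quartile_associations <- function(quartiles, clinical, events,
                                  survival_tab = NULL,
                                  organs = irae_organs()) {
  qmap <- setNames(as.character(quartiles$quartile), quartiles$patient_id)
  cl <- clinical[clinical$patient_id %in% names(qmap), , drop = FALSE]
  qf <- factor(qmap[cl$patient_id], levels = paste0("Q", 1:4))
  if (any(table(qf) == 0))
    warning("empty quartile; affected tests may be skipped", call. = FALSE)
  qual <- qualifying_events(events, organs)
  first <- tapply(qual$onset_week, qual$patient_id, min)
  timing <- ifelse(is.na(first[cl$patient_id]), "none",
                   ifelse(first[cl$patient_id] < 6, "early", "late"))
  mx <- tapply(qual$grade, qual$patient_id, max)
  sev <- ifelse(is.na(mx[cl$patient_id]), "none",
                ifelse(mx[cl$patient_id] >= 3, "severe", "mild"))
  rows <- list()
  add <- function(name, test, p) {
    rows[[length(rows) + 1L]] <<- data.frame(characteristic = name,
                                             test = test, p = p,
                                             stringsAsFactors = FALSE)
  }
  for (nm in c("timing", "melanoma_type", "stage", "severity")) {
    x <- switch(nm, timing = timing, severity = sev, cl[[nm]])
    tab <- table(droplevels(qf), x)
    p <- if (nrow(tab) < 2 || ncol(tab) < 2) NA_real_ else
      fisher.test(tab, simulate.p.value = nrow(tab) * ncol(tab) > 16,
                  B = 10000)$p.value
    add(nm, "fisher", p)
  }
  lev <- quartiles$level[match(cl$patient_id, quartiles$patient_id)]
  p_sex <- if (length(unique(cl$sex)) < 2) NA_real_ else
    suppressWarnings(wilcox.test(lev[cl$sex == "female"],
                                 lev[cl$sex == "male"])$p.value)
  add("sex_vs_level", "wilcoxon", p_sex)
  if (!is.null(survival_tab)) {
    for (ep in c("pfs", "os")) {
      tt <- build_time_to_event(events, cl, survival_tab, endpoint = ep,
                                organs = organs)
      hi <- tt[qmap[tt$patient_id] == "Q4", , drop = FALSE]
      lo <- tt[qmap[tt$patient_id] == "Q1", , drop = FALSE]
      if (nrow(hi) && nrow(lo)) {
        lr <- logrank(hi$time, hi$event, lo$time, lo$event)
        add(paste0(ep, "_q4_vs_q1"), "logrank", lr$p)
      } else add(paste0(ep, "_q4_vs_q1"), "logrank", NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sensitivity of differential abundance to total-Ig normalization
#'
#' Re-scores each patient's antigen signals after dividing the linear-scale
#' signal by that patient's total Ig of the matching isotype (scaled by the
#' cohort median so the overall scale is preserved), reruns the
#' differential-abundance comparison, and reports how concordant the two
#' runs are: the fraction of antigens whose fold change keeps its sign and
#' the Spearman rank correlation of the fold changes.
#'
#' @param m An `abs_matrix` (log2 ABS scale).
#' @param ig Ig data frame (`patient_id`, `igg_mg_dl`, `igm_mg_dl`).
#' @param groups Output of [assign_groups()].
#' @param alpha Significance level for both runs.
#' @return List: `concordance` (sign agreement of log2fc),
#'   `rank_correlation` (Spearman rho of log2fc), `de_raw`, `de_normalized`.
#' @export
ig_normalized_sensitivity <- function(m, ig, groups, alpha = 0.05) {
  stopifnot(inherits(m, "abs_matrix"))
  col <- if (m$isotype == "IgG") "igg_mg_dl" else "igm_mg_dl"
  lev <- setNames(ig[[col]], ig$patient_id)[rownames(m$values)]
  if (any(is.na(lev)))
    stop("Ig levels missing for some patients in the matrix", call. = FALSE)
  if (any(lev <= 0)) stop("zero or negative total Ig level", call. = FALSE)
  de_raw <- run_de(m, groups, alpha)
  m_norm <- m
  scale <- lev / median(lev)
  lin <- pmax(2^m$values - 1, 0) / scale  # divide linear signal by relative Ig
  m_norm$values <- log2(lin + 1)
  de_norm <- run_de(m_norm, groups, alpha)
  stopifnot(identical(de_raw$antigen, de_norm$antigen))
  nonzero <- de_raw$log2fc != 0 | de_norm$log2fc != 0
  concordance <- if (any(nonzero))
    mean(sign(de_raw$log2fc[nonzero]) == sign(de_norm$log2fc[nonzero]))
  else 1
  rho <- if (nrow(de_raw) > 2)
    suppressWarnings(cor(de_raw$log2fc, de_norm$log2fc, method = "spearman"))
  else NA_real_
  list(concordance = concordance, rank_correlation = rho,
       de_raw = de_raw, de_normalized = de_norm)
}
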