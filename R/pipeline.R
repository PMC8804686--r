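# End-to-end orchestration: simulate -> process -> differential abundance ->
# clustering -> longitudinal fold changes -> serostatus/survival -> Ig ->
# cohort summary, with every table written to an artifact directory.

#' Default analysis settings for [run_pipeline()]
#' @param alpha Adjusted-p significance level for antigen sets.
#' @param linkage Clustering linkage.
#' @param k Number of patient clusters.
#' @return Named list of analysis knobs.
#' @export
analysis_config <- function(alpha = 0.05, linkage = "complete", k = 4) {
  list(alpha = alpha, linkage = linkage, k = k)
}

read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cohort_args <- cfg$cohort %||% list()
  analysis_args <- cfg$analysis %||% list()
  list(cohort = do.call(cohort_config, cohort_args),
       analysis = do.call(analysis_config, analysis_args))
}

#' Run the full analysis pipeline
#'
#' Generates (or loads) a cohort, processes the signals into filtered and
#' normalized antibody-score matrices, runs the organ/timing/severity
#' differential-abundance comparisons at baseline, clusters patients on the
#' baseline IgG DE antigen set, computes baseline-to-week-6 fold changes and
#' their association with irAE multiplicity, classifies serostatus with
#' seroconversion accounting, runs the Kaplan-Meier / log-rank endpoints,
#' the Ig quartile and sensitivity analyses, and writes the cohort summary
#' plus a provenance manifest (seed, config hash, package version).
#'
#' @param config Either a [cohort_config()], or a path to a YAML file with
#'   `cohort:` and `analysis:` sections.
#' @param outdir Artifact directory (created if needed); `NULL` skips
#'   writing and returns results only.
#' @param analysis An [analysis_config()] (ignored when `config` is a YAML
#'   path that carries its own).
#' @param study Optionally, an existing `synthetic_study` (or a list of the
#'   same tables loaded from disk) to analyse instead of generating one.
#' @return Invisibly, a list with every stage's results: `study`,
#'   `filter_reports`, `matrices`, `de`, `de_antigens`, `clusters`,
#'   `enrichment`, `fc`, `fc_association`, `serostatus`, `seroconversion`,
#'   `serogroup_comparison`, `km`, `ig_quartiles`, `ig_sensitivity`,
#'   `summary`, `manifest`.
#' @export
run_pipeline <- function(config = cohort_config(), outdir = NULL,
                         analysis = analysis_config(), study = NULL) {
  if (is.character(config)) {
    parsed <- read_pipeline_config(config)
    config <- parsed$cohort
    analysis <- parsed$analysis
  }
  if (is.null(study)) study <- generate_cohort(config)
  ids <- study$clinical$patient_id
  organs <- config$organ_categories

  # --- signal processing -------------------------------------------------
  filter_reports <- list()
  matrices <- list()
  for (iso in config$isotypes) {
    flt <- filter_antigens(study$signals, isotype = iso)
    filter_reports[[iso]] <- flt$report
    for (tp in c("baseline", "week6")) {
      m <- build_abs_matrix(study$signals, isotype = iso, timepoint = tp)
      m <- normalize_rlm(m)
      matrices[[paste(iso, tp, sep = "_")]] <-
        subset_antigens(m, flt$retained)
    }
  }

  # --- differential abundance at baseline --------------------------------
  groupings <- c(lapply(organs, function(o) grouping_spec("organ", organ = o)),
                 list(grouping_spec("timing"), grouping_spec("severity")))
  names(groupings) <- c(organs, "timing", "severity")
  de <- list()
  for (iso in config$isotypes) {
    m <- matrices[[paste0(iso, "_baseline")]]
    for (g in names(groupings)) {
      ga <- assign_groups(study$events, ids, groupings[[g]], organs)
      de[[paste(iso, g, sep = "_")]] <-
        suppressWarnings(run_de(m, ga, analysis$alpha))
    }
  }
  de_antigens <- de_antigen_union(matrices[["IgG_baseline"]], study$events,
                                  ids, organs, analysis$alpha)

  # --- clustering on DE antigens -----------------------------------------
  clusters <- NULL
  enrichment <- NULL
  if (length(de_antigens) >= 1 &&
      nrow(matrices[["IgG_baseline"]]$values) >= analysis$k) {
    clusters <- cluster_patients(
      subset_antigens(matrices[["IgG_baseline"]], de_antigens),
      k = analysis$k, method = analysis$linkage)
    enrichment <- cluster_enrichment(clusters, study$events, organs)
  }

  # --- longitudinal fold changes -----------------------------------------
  fc <- list()
  fc_association <- list()
  sup_order <- list()
  for (iso in config$isotypes) {
    f <- fold_changes(matrices[[paste0(iso, "_baseline")]],
                      matrices[[paste0(iso, "_week6")]])
    fc[[iso]] <- f
    fc_association[[iso]] <- fc_vs_irae_count(f, study$events, organs)
    sup_order[[iso]] <- supervised_order(f, study$events, organs)
  }

  # --- serostatus and time-to-event --------------------------------------
  serostatus <- classify_serostatus(study$serology)
  seroconversion <- seroconversion_accounting(serostatus)
  serogroup_comparison <- compare_serogroups(study$clinical, study$events,
                                             serostatus, organs)
  km <- list()
  pos_ids <- serostatus$patient_id[serostatus$baseline_positive]
  for (ep in c("first_irae", "first_severe_irae", "pfs", "os")) {
    tt <- build_time_to_event(study$events, study$clinical, study$survival,
                              endpoint = ep, organs = organs)
    strat <- ifelse(tt$patient_id %in% pos_ids, "seropositive",
                    "seronegative")
    est <- km_estimate(tt$time, tt$event)
    lr <- if (all(c("seropositive", "seronegative") %in% strat)) {
      logrank(tt$time[strat == "seropositive"],
              tt$event[strat == "seropositive"],
              tt$time[strat == "seronegative"],
              tt$event[strat == "seronegative"])
    } else list(chisq = NA_real_, p = NA_real_, defined = FALSE)
    km[[ep]] <- list(table = cbind(tt, stratum = strat), estimate = est,
                     logrank = lr)
  }

  # --- immunoglobulins ---------------------------------------------------
  igg_q <- assign_quartiles(setNames(study$ig$igg_mg_dl,
                                     study$ig$patient_id))
  igm_q <- assign_quartiles(setNames(study$ig$igm_mg_dl,
                                     study$ig$patient_id))
  ig_quartiles <- list(
    IgG = igg_q, IgM = igm_q,
    associations_IgG = quartile_associations(igg_q, study$clinical,
                                             study$events, study$survival,
                                             organs))
  sero_groups <- assign_groups(study$events, ids, grouping_spec("severity"),
                               organs)
  ig_sensitivity <- tryCatch(
    ig_normalized_sensitivity(matrices[["IgG_baseline"]], study$ig,
                              sero_groups, analysis$alpha),
    warning = function(w) NULL, error = function(e) NULL)

  summary_tab <- summarize_cohort(study$clinical, study$events, serostatus,
                                  organs)
  manifest <- list(seed = config$seed,
                   config_hash = fnv1a_hash(deparse_config(unclass(config))),
                   package_version = as.character(utils::packageVersion("iraeab")),
                   n_patients = config$n_patients,
                   n_antigens = config$n_antigens,
                   alpha = analysis$alpha,
                   n_de_antigens = length(de_antigens))

  result <- list(study = study, filter_reports = filter_reports,
                 matrices = matrices, de = de, de_antigens = de_antigens,
                 clusters = clusters, enrichment = enrichment, fc = fc,
                 fc_association = fc_association,
                 supervised_order = sup_order,
                 serostatus = serostatus, seroconversion = seroconversion,
                 serogroup_comparison = serogroup_comparison, km = km,
                 ig_quartiles = ig_quartiles,
                 ig_sensitivity = ig_sensitivity,
                 summary = summary_tab, manifest = manifest)
  if (!is.null(outdir)) write_pipeline_outputs(result, outdir)
  invisible(result)
}

write_pipeline_outputs <- function(result, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  write_fixtures(result$study, file.path(outdir, "cohort"))
  for (iso in names(result$filter_reports))
    write_tsv(result$filter_reports[[iso]],
              file.path(outdir, sprintf("filter_report_%s.tsv", iso)))
  for (nm in names(result$matrices)) {
    m <- result$matrices[[nm]]
    df <- data.frame(patient_id = rownames(m$values), m$values,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv(df, file.path(outdir, sprintf("abs_matrix_%s.tsv", nm)))
    rep_ <- attr(m, "normalization_report")
    if (!is.null(rep_))
      write_tsv(rep_, file.path(outdir,
                                sprintf("normalization_report_%s.tsv", nm)))
  }
  for (nm in names(result$de)) {
    write_tsv(result$de[[nm]], file.path(outdir, sprintf("de_%s.tsv", nm)))
    if (nrow(result$de[[nm]]))
      write_tsv(volcano_table(result$de[[nm]]),
                file.path(outdir, sprintf("volcano_%s.tsv", nm)))
  }
  if (!is.null(result$enrichment))
    write_tsv(result$enrichment, file.path(outdir, "enrichment.tsv"))
  for (ep in names(result$km)) {
    est <- result$km[[ep]]$estimate
    write_tsv(est$curve, file.path(outdir, sprintf("km_%s.tsv", ep)))
  }
  write_tsv(result$serogroup_comparison,
            file.path(outdir, "serogroup_comparison.tsv"))
  write_tsv(result$summary, file.path(outdir, "cohort_summary.tsv"))
  jsonlite::write_json(result$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}
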