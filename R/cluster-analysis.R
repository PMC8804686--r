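# Hierarchical patient clustering on differentially expressed antigens and
# per-cluster event enrichment.

cluster_label_levels <- function() c("high", "moderate", "slightly_low", "low")

#' Cluster patients into four intensity subgroups
#'
#' Hierarchical clustering (`hclust`) of patients on their antibody-score
#' rows restricted to the differentially expressed antigen set: Euclidean
#' distance, complete linkage, tree cut at `k`.  Clusters are labelled
#' `high`, `moderate`, `slightly_low`, `low` by descending mean ABS over the
#' clustering antigens.
#'
#' @param m An `abs_matrix`, typically already restricted with
#'   [subset_antigens()] to the DE antigen set.
#' @param k Number of subgroups (default 4).
#' @param method Linkage (default `"complete"`; `"average"` and `"ward.D2"`
#'   available for sensitivity runs).
#' @return Object of class `cluster_result`: list with `assignments`
#'   (data frame `patient_id`, `cluster`, `label`), `means` (per-cluster
#'   mean ABS, descending), `hclust` (the dendrogram object), `k`,
#'   `linkage`.
#' @export
cluster_patients <- function(m, k = 4, method = "complete") {
  stopifnot(inherits(m, "abs_matrix"))
  x <- m$values
  if (nrow(x) < k)
    stop(sprintf("need at least %d patients to form %d clusters", k, k),
         call. = FALSE)
  if (!ncol(x)) stop("no antigens to cluster on", call. = FALSE)
  hc <- hclust(dist(x, method = "euclidean"), method = method)
  cl <- cutree(hc, k = k)
  cl_means <- tapply(rowMeans(x), cl, mean)
  ord <- order(-cl_means)  # descending mean ABS; ties broken by cluster id
  labels <- setNames(cluster_label_levels()[seq_len(k)][order(ord)],
                     names(cl_means))
  if (k != 4)
    labels <- setNames(paste0("rank", order(order(-cl_means))),
                       names(cl_means))
  assignments <- data.frame(patient_id = rownames(x),
                            cluster = as.integer(cl),
                            label = labels[as.character(cl)],
                            stringsAsFactors = FALSE)
  rownames(assignments) <- NULL
  structure(list(assignments = assignments,
                 means = sort(cl_means, decreasing = TRUE),
                 hclust = hc, k = k, linkage = method),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> k = %d (%s linkage)\n", x$k, x$linkage))
  print(table(x$assignments$label))
  invisible(x)
}

#' Event enrichment per cluster
#'
#' For every (cluster, organ) pair, tests whether patients in the cluster
#' experience a definite/probable event of that organ more or less often
#' than the rest of the cohort: two-sided Fisher's exact test on the 2x2
#' table (in-cluster event / no-event vs out-of-cluster event / no-event),
#' direction from the odds ratio, highlighted when p < 0.05.
#'
#' @param clusters A `cluster_result`.
#' @param events Events data frame.
#' @param organs Organ categories to test.
#' @param alpha Highlight threshold.
#' @return Data frame: `label`, `organ`, `n_cluster`, `n_events_cluster`,
#'   `fraction`, `p`, `direction` (`more_common` / `less_common` / `none`),
#'   `highlight`.  Empty clusters yield rows with `p = NA`.
#' @export
cluster_enrichment <- function(clusters, events, organs = irae_organs(),
                               alpha = 0.05) {
  stopifnot(inherits(clusters, "cluster_result"))
  asg <- clusters$assignments
  qual <- qualifying_events(events, organs)
  rows <- list()
  for (lab in unique(asg$label)) {
    in_ids <- asg$patient_id[asg$label == lab]
    out_ids <- asg$patient_id[asg$label != lab]
    for (org in organs) {
      hit <- unique(qual$patient_id[qual$organ == org])
      a <- sum(in_ids %in% hit); b <- length(in_ids) - a
      c_ <- sum(out_ids %in% hit); d <- length(out_ids) - c_
      if (length(in_ids) == 0 || length(out_ids) == 0) {
        p <- NA_real_; dir <- "none"
      } else {
        ft <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                          alternative = "two.sided")
        p <- ft$p.value
        in_rate <- a / length(in_ids); out_rate <- c_ / length(out_ids)
        dir <- if (in_rate > out_rate) "more_common"
               else if (in_rate < out_rate) "less_common" else "none"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        label = lab, organ = org, n_cluster = length(in_ids),
        n_events_cluster = a,
        fraction = if (length(in_ids)) a / length(in_ids) else NA_real_,
        p = p, direction = dir,
        highlight = !is.na(p) && p < alpha && dir != "none",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
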