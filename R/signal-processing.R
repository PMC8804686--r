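# Spot-level signal processing: antibody scores, true-signal masking,
# low-signal antigen filtering and control-based robust normalization.

#' Antibody score from net fluorescence intensity and signal-to-noise ratio
#'
#' `ABS = log2(NFI * SNR + 1)`, the quantitative per-spot readout of antibody
#' binding.  Monotone nondecreasing in each argument and zero whenever either
#' argument is zero.  Negative NFI values (possible after upstream background
#' subtraction) are clamped to zero with a warning; non-finite inputs are an
#' error.
#'
#' @param nfi Net fluorescence intensity (vectorised, >= 0 after clamping).
#' @param snr Signal-to-noise ratio (>= 0).
#' @return Numeric vector of antibody scores (log2 units, >= 0).
#' @examples
#' compute_abs(31, 33)  # 31*33 + 1 = 1024, so exactly 10
#' @export
compute_abs <- function(nfi, snr) {
  if (any(!is.finite(nfi)) || any(!is.finite(snr))) {
    bad <- which(!is.finite(nfi) | !is.finite(snr))
    stop(sprintf("non-finite NFI/SNR at record(s): %s",
                 paste(head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  if (any(snr < 0))
    stop("negative SNR encountered; SNR must be >= 0", call. = FALSE)
  if (any(nfi < 0)) {
    warning(sprintf("%d negative NFI value(s) clamped to 0", sum(nfi < 0)),
            call. = FALSE)
    nfi <- pmax(nfi, 0)
  }
  log2(nfi * snr + 1)
}

#' True-signal mask
#'
#' Spots with SNR >= 3 are considered true signal above background noise.
#'
#' @param snr Numeric vector (or a signals data frame with an `snr` column).
#' @return Logical vector, `TRUE` where the spot is true signal.
#' @export
true_signal_mask <- function(snr) {
  if (is.data.frame(snr)) snr <- snr$snr
  snr >= 3
}

#' Filter antigens with weak signal across the cohort
#'
#' An antigen is removed when SNR < 3 in more than 90% of all samples, where
#' a sample is one (patient, timepoint) draw and both timepoints within an
#' isotype are pooled.  The boundary is strict: exactly 90% below threshold
#' retains the antigen.
#'
#' @param signals Signals data frame (`patient_id`, `timepoint`, `isotype`,
#'   `antigen`, `is_control`, `nfi`, `snr`); control spots are ignored.
#' @param isotype Isotype to filter within.
#' @param max_low_fraction Removal threshold on the fraction of samples with
#'   SNR < 3 (default 0.90, strict inequality).
#' @return List with `retained` (character vector of antigen labels) and
#'   `report` (per-antigen data frame: `antigen`, `n_samples`, `n_low`,
#'   `frac_low`, `retained`).
#' @export
filter_antigens <- function(signals, isotype = "IgG",
                            max_low_fraction = 0.90) {
  assert_columns(signals, c("patient_id", "timepoint", "isotype", "antigen",
                            "is_control", "snr"), "signals")
  sub <- signals[signals$isotype == isotype & !signals$is_control, ,
                 drop = FALSE]
  if (!nrow(sub)) stop("empty antigen panel after subsetting", call. = FALSE)
  low <- tapply(sub$snr < 3, sub$antigen, sum)
  tot <- tapply(sub$snr, sub$antigen, length)
  ags <- sort(names(tot))
  frac <- as.numeric(low[ags]) / as.numeric(tot[ags])
  keep <- !(frac > max_low_fraction)
  report <- data.frame(antigen = ags, n_samples = as.integer(tot[ags]),
                       n_low = as.integer(low[ags]), frac_low = frac,
                       retained = keep, stringsAsFactors = FALSE)
  rownames(report) <- NULL
  list(retained = ags[keep], report = report)
}

#' Build an antibody-score matrix for one isotype and timepoint
#'
#' Pivots the long signals table into a patients x antigens matrix of ABS
#' values, with a validity mask (SNR >= 3) and the control-spot score matrix
#' alongside for normalization.
#'
#' @param signals Signals data frame.
#' @param isotype,timepoint Slice to extract.
#' @return An object of class `abs_matrix`: list with `values` (patients x
#'   antigens ABS matrix), `mask` (logical, same shape), `controls`
#'   (patients x control-spot ABS matrix), `isotype`, `timepoint`,
#'   `normalized` flag.
#' @export
build_abs_matrix <- function(signals, isotype = "IgG",
                             timepoint = "baseline") {
  assert_columns(signals, c("patient_id", "timepoint", "isotype", "antigen",
                            "is_control", "nfi", "snr"), "signals")
  sub <- signals[signals$isotype == isotype & signals$timepoint == timepoint, ,
                 drop = FALSE]
  if (!nrow(sub))
    stop(sprintf("no signals for isotype '%s' at '%s'", isotype, timepoint),
         call. = FALSE)
  if (anyDuplicated(sub[c("patient_id", "antigen")]))
    stop("duplicate (patient, antigen) records in signal slice", call. = FALSE)
  sub$abs <- compute_abs(sub$nfi, sub$snr)
  ag <- sub[!sub$is_control, , drop = FALSE]
  ct <- sub[sub$is_control, , drop = FALSE]
  pts <- sort(unique(ag$patient_id))
  ags <- sort(unique(ag$antigen))
  pivot <- function(df, cols, value) {
    m <- matrix(NA_real_, length(pts), length(cols),
                dimnames = list(pts, cols))
    m[cbind(match(df$patient_id, pts), match(df$antigen, cols))] <- df[[value]]
    m
  }
  values <- pivot(ag, ags, "abs")
  mask <- pivot(ag, ags, "snr") >= 3
  controls <- if (nrow(ct)) pivot(ct, sort(unique(ct$antigen)), "abs") else NULL
  structure(list(values = values, mask = mask, controls = controls,
                 isotype = isotype, timepoint = timepoint,
                 normalized = FALSE),
            class = "abs_matrix")
}

#' @export
print.abs_matrix <- function(x, ...) {
  cat(sprintf("<abs_matrix> %s %s: %d patients x %d antigens (%s)\n",
              x$isotype, x$timepoint, nrow(x$values), ncol(x$values),
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' Restrict an ABS matrix to a set of antigens
#' @param m An `abs_matrix`.
#' @param antigens Antigen labels to keep.
#' @return The restricted `abs_matrix`.
#' @export
subset_antigens <- function(m, antigens) {
  stopifnot(inherits(m, "abs_matrix"))
  keep <- intersect(colnames(m$values), antigens)
  m$values <- m$values[, keep, drop = FALSE]
  m$mask <- m$mask[, keep, drop = FALSE]
  m
}

# robust affine fit of y on x (Huber, c = 1.345); returns c(intercept, slope)
robust_affine <- function(x, y, maxit = 50, acc = 1e-8) {
  if (sd(x) < 1e-12 || sd(y) < 1e-12) return(NULL)
  fit <- tryCatch(
    suppressWarnings(MASS::rlm(y ~ x, psi = MASS::psi.huber, k = 1.345,
                               maxit = maxit, acc = acc)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- coef(fit)
  if (!all(is.finite(cf)) || abs(cf[2]) < 1e-8) return(NULL)
  cf
}

#' Normalize an ABS matrix against internal positive controls
#'
#' Each sample's control-spot scores are regressed on the across-sample
#' median control profile with a robust linear model (Huber M-estimation,
#' tuning constant 1.345, at most 50 iterations, tolerance 1e-8, intercept
#' included); the sample's antigen scores are then mapped through the
#' inverse of the fitted affine transform, removing per-slide scale and
#' offset drift.  Samples whose controls are degenerate (zero variance or a
#' failed fit) fall back to median-ratio scaling and are flagged.
#'
#' @param m An `abs_matrix` with a `controls` component (>= 2 control spots).
#' @param reference Optional reference control profile (defaults to the
#'   per-spot median over samples of `m$controls`).
#' @return The normalized `abs_matrix`; the per-sample fit is attached as
#'   `attr(, "normalization_report")` (`patient_id`, `slope`, `intercept`,
#'   `method`).
#' @export
normalize_rlm <- function(m, reference = NULL) {
  stopifnot(inherits(m, "abs_matrix"))
  if (is.null(m$controls) || ncol(m$controls) < 2)
    stop("normalization requires >= 2 internal control spots per sample",
         call. = FALSE)
  ref <- reference %||% apply(m$controls, 2, median, na.rm = TRUE)
  pts <- rownames(m$values)
  report <- data.frame(patient_id = pts, slope = NA_real_,
                       intercept = NA_real_, method = "rlm",
                       stringsAsFactors = FALSE)
  for (i in seq_along(pts)) {
    y <- m$controls[pts[i], ]
    cf <- robust_affine(ref, y)
    if (is.null(cf)) {
      ratio <- median(ref) / median(y)
      if (!is.finite(ratio)) ratio <- 1
      m$values[pts[i], ] <- m$values[pts[i], ] * ratio
      m$controls[pts[i], ] <- m$controls[pts[i], ] * ratio
      report$slope[i] <- 1 / ratio
      report$intercept[i] <- 0
      report$method[i] <- "median_ratio"
    } else {
      m$values[pts[i], ] <- (m$values[pts[i], ] - cf[1]) / cf[2]
      m$controls[pts[i], ] <- (m$controls[pts[i], ] - cf[1]) / cf[2]
      report$slope[i] <- cf[2]
      report$intercept[i] <- cf[1]
    }
  }
  m$values <- pmax(m$values, 0)
  m$normalized <- TRUE
  attr(m, "normalization_report") <- report
  m
}

#' Load a spot-level signals table
#'
#' Reads a tab-delimited signals file (columns `patient_id`, `timepoint`,
#' `isotype`, `antigen`, `is_control`, `nfi`, `snr`) with schema validation.
#' Negative NFI values are clamped to zero with a warning; malformed rows
#' raise an error naming the line.
#'
#' @param path Path to a TSV written by [write_fixtures()] or equivalent.
#' @return Signals data frame.
#' @export
load_signals <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path),
                               call. = FALSE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  assert_columns(df, c("patient_id", "timepoint", "isotype", "antigen",
                       "is_control", "nfi", "snr"), path)
  for (col in c("nfi", "snr")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop(sprintf("malformed %s at line %d of '%s'", col, bad[1] + 1L, path),
           call. = FALSE)
    df[[col]] <- v
  }
  if (any(is.na(df$nfi) | is.na(df$snr)))
    stop(sprintf("missing NFI/SNR values in '%s'", path), call. = FALSE)
  if (!is.logical(df$is_control)) df$is_control <- as.logical(df$is_control)
  if (any(df$nfi < 0)) {
    warning(sprintf("%d negative NFI value(s) clamped to 0 in '%s'",
                    sum(df$nfi < 0), path), call. = FALSE)
    df$nfi <- pmax(df$nfi, 0)
  }
  if (any(df$snr < 0))
    stop(sprintf("negative SNR in '%s'", path), call. = FALSE)
  df
}

#' Parse a GenePix-results-style tab-delimited file
#'
#' Minimal reader for the quantification tables exported by array scanners:
#' an optional header block of quoted `"key=value"` lines, then a
#' column-titled table.  Spot names are taken from the `Name` (or `ID`)
#' column; rows whose name matches `control_pattern` are flagged as internal
#' positive controls.  NFI is read from an `F532 Median - B532` style column
#' when present, otherwise from a column named `NFI`; SNR from `SNR 532` or
#' `SNR`.
#'
#' @param path Path to the GPR-like file.
#' @param patient_id,timepoint,isotype Sample annotations to attach (a GPR
#'   file holds one sample).
#' @param control_pattern Regular expression identifying control spots.
#' @return Signals data frame in the standard schema.
#' @export
load_gpr <- function(path, patient_id, timepoint = "baseline",
                     isotype = "IgG", control_pattern = "^(CTRL|Control)") {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path),
                               call. = FALSE)
  lines <- readLines(path)
  is_header <- grepl("^\"[^\t]*=[^\t]*\"\\s*$", lines) |
    grepl("^(ATF|[0-9]+\\s+[0-9]+)\\s*$", lines)
  start <- which(!is_header)[1]
  if (is.na(start)) stop(sprintf("no data table found in '%s'", path),
                         call. = FALSE)
  tab <- read.delim(text = paste(lines[start:length(lines)], collapse = "\n"),
                    check.names = FALSE, stringsAsFactors = FALSE)
  name_col <- intersect(c("Name", "ID"), names(tab))[1]
  nfi_col <- intersect(c("F532 Median - B532", "NFI"), names(tab))[1]
  snr_col <- intersect(c("SNR 532", "SNR"), names(tab))[1]
  if (is.na(name_col) || is.na(nfi_col) || is.na(snr_col))
    stop(sprintf("unrecognized GPR header in '%s'", path), call. = FALSE)
  nfi <- as.numeric(tab[[nfi_col]])
  if (any(nfi < 0, na.rm = TRUE)) {
    warning(sprintf("%d negative NFI value(s) clamped to 0 in '%s'",
                    sum(nfi < 0, na.rm = TRUE), path), call. = FALSE)
    nfi <- pmax(nfi, 0)
  }
  data.frame(patient_id = patient_id, timepoint = timepoint, isotype = isotype,
             antigen = as.character(tab[[name_col]]),
             is_control = grepl(control_pattern, tab[[name_col]]),
             nfi = nfi, snr = as.numeric(tab[[snr_col]]),
             stringsAsFactors = FALSE)
}
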