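test_that("antibody score follows log2(NFI x SNR + 1)", {
  expect_identical(compute_abs(0, 5), 0)
  expect_identical(compute_abs(7, 0), 0)
  expect_identical(compute_abs(31, 33), 10)   # 31*33 + 1 = 2^10
  expect_equal(compute_abs(1000, 4), log2(4001))
  expect_warning(out <- compute_abs(c(-2, 4), c(1, 1)), "clamped")
  expect_identical(out[1], 0)
  expect_error(compute_abs(NA, 1), "non-finite")
  expect_error(compute_abs(Inf, 1), "non-finite")
  expect_error(compute_abs(1, -0.5), "negative SNR")
})

test_that("antibody score is monotone in each argument", {
  set.seed(1)
  n <- 1000
  nfi <- runif(n, 0, 5000); snr <- runif(n, 0, 50)
  eps <- runif(n, 0, 10)
  base <- compute_abs(nfi, snr)
  expect_true(all(compute_abs(nfi + eps, snr) >= base))
  expect_true(all(compute_abs(nfi, snr + eps) >= base))
})

test_that("true-signal mask uses SNR >= 3 with a sharp boundary", {
  expect_true(true_signal_mask(3.0))
  expect_false(true_signal_mask(2.999))
  expect_identical(true_signal_mask(c(0, 0, 0)), c(FALSE, FALSE, FALSE))
})

# 100 samples (50 patients x 2 timepoints) and 3 antigens with a chosen
# number of low-SNR samples each
filter_fixture <- function(n_low = c(A1 = 91, A2 = 90, A3 = 0)) {
  ids <- rep(sprintf("P%03d", 1:50), 2)
  tp <- rep(c("baseline", "week6"), each = 50)
  do.call(rbind, lapply(names(n_low), function(ag) {
    snr <- c(rep(1, n_low[[ag]]), rep(10, 100 - n_low[[ag]]))
    data.frame(patient_id = ids, timepoint = tp, isotype = "IgG",
               antigen = ag, is_control = FALSE, nfi = 100, snr = snr,
               stringsAsFactors = FALSE)
  }))
}

test_that("antigen filter removes only antigens low in > 90% of samples", {
  flt <- filter_antigens(filter_fixture())
  expect_setequal(flt$retained, c("A2", "A3"))      # 90/100 is retained
  expect_false("A1" %in% flt$retained)              # 91/100 is removed
  expect_equal(flt$report$frac_low[flt$report$antigen == "A2"], 0.90)
  expect_error(filter_antigens(filter_fixture()[0, ]), "empty")
})

test_that("antigen filter ignores sample order and full duplication", {
  fx <- filter_fixture()
  shuffled <- fx[sample(nrow(fx)), ]
  doubled <- rbind(fx, fx)
  expect_setequal(filter_antigens(shuffled)$retained,
                  filter_antigens(fx)$retained)
  expect_setequal(filter_antigens(doubled)$retained,
                  filter_antigens(fx)$retained)
})

test_that("abs matrix pivot preserves values and flags", {
  st <- small_study()
  m <- build_abs_matrix(st$signals, "IgM", "baseline")
  sig <- st$signals[st$signals$isotype == "IgM" &
                      st$signals$timepoint == "baseline" &
                      !st$signals$is_control, ]
  i <- sample(nrow(sig), 20)
  expect_equal(m$values[cbind(sig$patient_id[i], sig$antigen[i])],
               compute_abs(sig$nfi[i], sig$snr[i]))
  expect_identical(m$mask[cbind(sig$patient_id[i], sig$antigen[i])],
                   sig$snr[i] >= 3)
  expect_identical(dim(m$controls), c(24L, 8L))
})

test_that("normalization inverts a planted affine distortion exactly", {
  ctrl_profile <- c(10, 11, 12, 13, 11.5, 12.5)
  truth <- matrix(seq(2, 9, length.out = 10), 5, 10, byrow = TRUE)
  controls <- matrix(ctrl_profile, 5, 6, byrow = TRUE)
  # sample 5 is distorted by y = 1.5 x + 0.3 on every spot
  values <- truth
  values[5, ] <- 1.5 * truth[5, ] + 0.3
  controls[5, ] <- 1.5 * ctrl_profile + 0.3
  m <- normalize_rlm(make_abs_matrix(values, controls))
  expect_equal(m$values[5, ], truth[5, ], tolerance = 1e-6,
               ignore_attr = TRUE)
  rep_ <- attr(m, "normalization_report")
  expect_equal(rep_$slope[5], 1.5, tolerance = 1e-6)
  expect_equal(rep_$intercept[5], 0.3, tolerance = 1e-6)
  # undistorted samples map through the identity
  expect_equal(rep_$slope[1:4], rep(1, 4), tolerance = 1e-6)
  expect_equal(m$values[1:4, ], truth[1:4, ], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("normalization reduces between-sample control variance", {
  st <- generate_cohort(cohort_config(n_patients = 30, n_antigens = 20,
                                      sample_scale_sd = 0.1,
                                      sample_shift_sd = 0.4, seed = 8))
  m <- build_abs_matrix(st$signals, "IgG", "baseline")
  before <- sum(apply(m$controls, 2, var))
  mn <- normalize_rlm(m)
  after <- sum(apply(mn$controls, 2, var))
  expect_lt(after, before)
})

test_that("normalization is idempotent against a fixed reference", {
  ctrl_profile <- c(9, 10, 11, 12)
  set.seed(21)
  values <- matrix(rnorm(60, 6), 6, 10)
  controls <- matrix(ctrl_profile, 6, 4, byrow = TRUE) *
    rnorm(6, 1, 0.05) + rnorm(6, 0, 0.2)
  m1 <- normalize_rlm(make_abs_matrix(values, controls))
  ref <- apply(m1$controls, 2, median)
  m2 <- normalize_rlm(m1, reference = ref)
  rep2 <- attr(m2, "normalization_report")
  expect_equal(rep2$slope, rep(1, 6), tolerance = 1e-4)
  expect_equal(rep2$intercept, rep(0, 6), tolerance = 1e-4)
})

test_that("degenerate controls fall back to median-ratio scaling", {
  values <- matrix(5, 3, 4)
  controls <- matrix(8, 3, 3)   # zero variance in the profile
  controls[2, ] <- 16
  expect_silent(m <- normalize_rlm(make_abs_matrix(values, controls)))
  rep_ <- attr(m, "normalization_report")
  expect_true(all(rep_$method == "median_ratio"))
  expect_equal(m$controls[2, ], c(8, 8, 8), ignore_attr = TRUE)
})

test_that("signals loader validates schema and clamps negative NFI", {
  dir <- withr::local_tempdir()
  df <- data.frame(patient_id = "P001", timepoint = "baseline",
                   isotype = "IgG", antigen = c("AG001", "AG002"),
                   is_control = FALSE, nfi = c(-5, 10), snr = c(2, 4),
                   stringsAsFactors = FALSE)
  path <- file.path(dir, "sig.tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(out <- load_signals(path), "clamped")
  expect_identical(out$nfi, c(0, 10))
  expect_identical(nrow(out), length(readLines(path)) - 1L)

  bad <- df; bad$nfi <- c("oops", "10")
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_signals(path), "line 2")
  expect_error(load_signals(file.path(dir, "absent.tsv")), "not found")
})

test_that("GPR-like quantification tables are parsed", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "sample.gpr")
  writeLines(c('"Type=GenePix Results 3"',
               '"DateTime=2021/03/01 12:00:00"',
               paste("Block", "Name", "F532 Median - B532", "SNR 532",
                     sep = "\t"),
               paste(1, "AG001", 250, 5.2, sep = "\t"),
               paste(1, "AG002", -4, 1.1, sep = "\t"),
               paste(1, "CTRL01", 9000, 40, sep = "\t")), path)
  expect_warning(sig <- load_gpr(path, patient_id = "P001"), "clamped")
  expect_identical(sig$antigen, c("AG001", "AG002", "CTRL01"))
  expect_identical(sig$is_control, c(FALSE, FALSE, TRUE))
  expect_identical(sig$nfi, c(250, 0, 9000))
})
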