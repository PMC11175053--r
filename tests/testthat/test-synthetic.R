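test_that("generate_window is deterministic and honours degenerate motifs", {
  motif <- behavior_motif(1L, amplitude = c(1, 1, 0.5, 0.5), frequency = 2,
                          harmonics = 2L, noise_sd = 0.1,
                          offset = seq(0.1, 1.2, length.out = 12))
  w1 <- generate_window(motif, seed = 5)
  w2 <- generate_window(motif, seed = 5)
  expect_identical(w1$values[[1]], w2$values[[1]])
  expect_identical(w1$label, motif$class_id)
  expect_equal(dim(w1$values[[1]]), c(100L, 12L))

  silent <- behavior_motif(0L, amplitude = rep(0, 4), frequency = 1,
                           noise_sd = 0, offset = seq_len(12) / 10)
  w <- generate_window(silent, seed = 1)$values[[1]]
  expect_equal(w, matrix(rep(seq_len(12) / 10, each = 100), 100, 12,
                         dimnames = list(NULL, cmpl_channels())))
})

test_that("generated windows carry the motif's fundamental frequency", {
  # DFT oracle: with no noise the dominant non-DC bin must sit at 2 Hz +/- one bin
  motif <- behavior_motif(2L, amplitude = c(1, 1, 1, 1), frequency = 2,
                          harmonics = 3L, noise_sd = 0)
  w <- generate_window(motif, seed = 9)$values[[1]]
  freqs <- (0:99) * 50 / 100
  for (ch in 1:12) {
    spec <- Mod(stats::fft(w[, ch] - mean(w[, ch])))[2:50]
    dominant <- freqs[2:50][which.max(spec)]
    expect_lte(abs(dominant - 2), 0.5 + 1e-9)
  }
})

test_that("inactive windows have the stated noise level and low activity", {
  const <- generate_inactive_window(noise_sd = 0, seed = 1)$values[[1]]
  expect_true(all(const == matrix(rep(inactive_offset(), each = 100), 100, 12)))
  expect_identical(generate_inactive_window(seed = 2)$label, inactive_class())

  # sample-variance oracle, averaged over channels for stability
  w <- generate_inactive_window(noise_sd = 0.1, seed = 3)$values[[1]]
  v <- mean(apply(w, 2L, stats::var))
  expect_lt(abs(v - 0.01) / 0.01, 0.2)

  # Monte-Carlo: mean per-channel MAD below every active class, 50 seeds
  motifs <- default_motifs()
  mad_of <- function(vals) mean(apply(vals, 2L, function(x) mean(abs(x - mean(x)))))
  inact <- vapply(1:50, function(s) {
    mad_of(generate_inactive_window(seed = s)$values[[1]])
  }, numeric(1))
  for (m in motifs) {
    act <- vapply(1:50, function(s) {
      mad_of(generate_window(m, seed = 1000 + s)$values[[1]])
    }, numeric(1))
    expect_lt(mean(inact), mean(act))
  }
})

test_that("make_dataset composes pools as specified", {
  spec <- stream_spec(n_labeled_per_class = 10L, n_unlabeled = 60L,
                      inactive_fraction = 0.25, missing_rate = 0, seed = 7L)
  ds <- make_dataset(spec)
  expect_equal(nrow(ds$labeled), 50L)
  expect_equal(as.integer(table(ds$labeled$label)), rep(10L, 5))
  expect_equal(nrow(ds$unlabeled), 60L)
  expect_equal(sum(ds$inactive_mask), 15L)
  expect_true(all(is.na(ds$unlabeled$label)))
  # 80/20 split: the test pool is a quarter of the labeled pool, stratified
  n_test_pc <- max(1L, as.integer(round(0.25 * 10)))
  expect_equal(nrow(ds$test), 5L * n_test_pc)
  expect_equal(as.integer(table(ds$test$label)), rep(n_test_pc, 5))
  # truth aligns with the mask and hides nothing from evaluation
  expect_identical(ds$unlabeled_truth$is_inactive, ds$inactive_mask)
  expect_true(all(is.na(ds$unlabeled_truth$true_label[ds$inactive_mask])))
  expect_true(all(!is.na(ds$unlabeled_truth$true_label[!ds$inactive_mask])))

  none <- make_dataset(stream_spec(n_labeled_per_class = 5L, n_unlabeled = 20L,
                                   inactive_fraction = 0, seed = 1L))
  expect_false(any(none$inactive_mask))
})

test_that("make_dataset is deterministic and validates fractions", {
  a <- make_dataset(stream_spec(n_labeled_per_class = 5L, n_unlabeled = 20L, seed = 42L))
  b <- make_dataset(stream_spec(n_labeled_per_class = 5L, n_unlabeled = 20L, seed = 42L))
  expect_identical(a$labeled$values, b$labeled$values)
  expect_identical(a$unlabeled$values, b$unlabeled$values)
  expect_identical(a$inactive_mask, b$inactive_mask)
  expect_error(stream_spec(inactive_fraction = 1.2), "inactive_fraction")
  expect_error(stream_spec(missing_rate = -0.1), "missing_rate")
})

test_that("missing values hit about the configured share of unlabeled windows", {
  # counting oracle: whole-window Bernoulli(0.05) over 20 seeds
  frac <- vapply(1:20, function(s) {
    ds <- make_dataset(stream_spec(n_labeled_per_class = 2L, n_unlabeled = 100L,
                                   missing_rate = 0.05, seed = s))
    mean(ds$unlabeled$has_missing)
  }, numeric(1))
  expect_lt(abs(mean(frac) - 0.05), 0.015)
  ds <- make_dataset(stream_spec(n_labeled_per_class = 2L, n_unlabeled = 50L,
                                 missing_rate = 1, seed = 3))
  expect_true(all(vapply(ds$unlabeled$values, anyNA, logical(1))))
})

test_that("the synthetic task is learnable by a 1-nearest-neighbour classifier", {
  skip_if_not_installed("class")
  ds <- make_dataset(stream_spec(seed = 77L))
  train <- windows_matrix(ds$labeled)
  # stratified 50-window hold-out: 10 per class
  hold_idx <- sort(unlist(lapply(0:4, function(c) which(ds$test$label == c)[1:10])))
  hold <- windows_matrix(ds$test)[hold_idx, ]
  pred <- class::knn1(train, hold, factor(ds$labeled$label))
  acc <- mean(as.integer(as.character(pred)) == ds$test$label[hold_idx])
  expect_gt(acc, 0.9)
})

test_that("CSV round trip preserves values, labels and missingness", {
  ds <- tiny_dataset(seed = 5L, n_labeled = 3L, n_unlabeled = 8L,
                     missing_rate = 0.5)
  mixed <- dplyr::bind_rows(ds$labeled[1:4, ], ds$unlabeled)
  f <- withr::local_tempfile(fileext = ".csv")
  write_windows_csv(mixed, f)
  back <- read_windows_csv(f)
  expect_equal(nrow(back), nrow(mixed))
  expect_identical(back$label, mixed$label)
  expect_identical(back$has_missing, mixed$has_missing)
  for (i in seq_len(nrow(mixed))) {
    expect_equal(back$values[[i]], mixed$values[[i]], tolerance = 1e-12)
  }
})

test_that("CSV reader rejects malformed files with a line number", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(paste(c("timestamp", cmpl_channels()[1:10], "label"), collapse = ","),
               paste(rep("0", 12), collapse = ",")), f)
  expect_error(read_windows_csv(f), "14 columns")

  w <- generate_inactive_window(seed = 1)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_windows_csv(w, f2)
  lines <- readLines(f2)
  lines[5] <- paste0(lines[5], ",999")  # extra field on data line 4
  writeLines(lines, f2)
  expect_error(read_windows_csv(f2), "line")
})

test_that("empty CSV cells mark the window as containing missing values", {
  w <- generate_inactive_window(seed = 4)
  w$values[[1]][10, 3] <- NA_real_
  w$has_missing <- TRUE
  f <- withr::local_tempfile(fileext = ".csv")
  write_windows_csv(w, f)
  expect_true(grepl(",,", readLines(f)[11]))
  back <- read_windows_csv(f)
  expect_true(back$has_missing[1])
  expect_true(is.na(back$values[[1]][10, 3]))
})

test_that("write_dataset emits pools and a manifest", {
  ds <- tiny_dataset(seed = 9L, n_labeled = 2L, n_unlabeled = 6L)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(all(file.exists(file.path(dir, c("labeled.csv", "unlabeled.csv",
                                               "test.csv", "manifest.json")))))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  expect_equal(man$n_unlabeled, 6L)
  expect_equal(length(man$inactive_mask), 6L)
})
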