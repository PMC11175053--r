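#' Specification of a synthetic sensor stream
#'
#' Describes the sampling setup and dataset composition emulated by the
#' generator: 12-channel streams at `sample_rate` Hz cut into
#' `window_len`-sample windows (2 s by default), a labeled pool balanced over
#' the five behavior classes, an unlabeled pool contaminated with inactive
#' windows at `inactive_fraction`, and transmission-loss missing values hitting
#' a `missing_rate` share of the unlabeled windows as contiguous gaps.
#'
#' @param sample_rate Sampling rate in Hz (default 50).
#' @param window_len Window length in samples (default `2 * sample_rate`,
#'   a 2-second action time frame).
#' @param n_labeled_per_class Labeled training windows per class.
#' @param n_unlabeled Size of the unlabeled pool.
#' @param inactive_fraction Proportion of the unlabeled pool that is inactive
#'   (class-less low-activity) data, in `[0, 1]`.
#' @param missing_rate Proportion of unlabeled windows containing at least one
#'   missing-value gap, in `[0, 1]`.
#' @param test_fraction Size of the held-out test pool relative to the labeled
#'   pool; the default 0.25 yields the standard 80/20 labeled/test split.
#' @param seed Integer seed controlling the whole dataset draw.
#' @return An object of class `stream_spec`.
#' @export
stream_spec <- function(sample_rate = 50, window_len = 2 * sample_rate,
                        n_labeled_per_class = 80L, n_unlabeled = 460L,
                        inactive_fraction = 0.3, missing_rate = 0.02,
                        test_fraction = 0.25, seed = 1L) {
  sample_rate <- check_number(sample_rate, "sample_rate", lower = 1)
  window_len <- as.integer(check_number(window_len, "window_len", lower = 2))
  n_labeled_per_class <- as.integer(check_number(n_labeled_per_class, "n_labeled_per_class", lower = 1))
  n_unlabeled <- as.integer(check_number(n_unlabeled, "n_unlabeled", lower = 0))
  inactive_fraction <- check_number(inactive_fraction, "inactive_fraction", lower = 0, upper = 1)
  missing_rate <- check_number(missing_rate, "missing_rate", lower = 0, upper = 1)
  test_fraction <- check_number(test_fraction, "test_fraction", lower = 0, upper = 1)
  structure(
    list(
      sample_rate = sample_rate, window_len = window_len,
      n_labeled_per_class = n_labeled_per_class, n_unlabeled = n_unlabeled,
      inactive_fraction = inactive_fraction, missing_rate = missing_rate,
      test_fraction = test_fraction, seed = as.integer(seed)
    ),
    class = "stream_spec"
  )
}

#' Generate one labeled sensor window from a motif
#'
#' Each channel is the motif's baseline offset plus a stack of harmonics at
#' the motif's fundamental frequency (harmonic k weighted 1/k, random phase
#' per channel and harmonic) scaled by the channel's sensor-group amplitude,
#' plus white Gaussian noise. Deterministic given `(motif, seed)`.
#'
#' @param motif A [behavior_motif()].
#' @param seed Integer seed; `NULL` uses (and advances) the current RNG stream.
#' @param window_len,sample_rate Window geometry; defaults give 100 samples
#'   at 50 Hz.
#' @return One-row window-set tibble (see package overview) whose `values`
#'   entry is a `window_len` x 12 matrix with [cmpl_channels()] columns.
#' @export
generate_window <- function(motif, seed = NULL, window_len = 100L, sample_rate = 50) {
  if (!inherits(motif, "behavior_motif")) stopf("`motif` must be a `behavior_motif`.")
  values <- with_seed_(seed, motif_signal(motif, window_len, sample_rate))
  new_window_set(list(values), label = motif$class_id, is_inactive = FALSE)
}

motif_signal <- function(motif, window_len, sample_rate) {
  tt <- (seq_len(window_len) - 1L) / sample_rate
  # per-window random effects: action intensity, posture shift, cadence
  amp_scale <- if (motif$amp_jitter > 0) exp(stats::rnorm(1L, 0, motif$amp_jitter)) else 1
  offset <- if (!is.null(motif$modes)) {
    motif$modes[[sample.int(length(motif$modes), 1L)]]
  } else {
    motif$offset
  }
  if (motif$offset_jitter > 0) {
    offset <- offset + stats::rnorm(12L, 0, motif$offset_jitter)
  }
  freq <- motif$frequency *
    (if (motif$freq_jitter > 0) exp(stats::rnorm(1L, 0, motif$freq_jitter)) else 1)
  amp_per_channel <- amp_scale * rep(motif$amplitude, each = 3L)
  values <- matrix(rep(offset, each = window_len), window_len, 12L)
  if (any(amp_per_channel > 0)) {
    phases <- matrix(stats::runif(12L * motif$harmonics, 0, 2 * pi), motif$harmonics, 12L)
    for (k in seq_len(motif$harmonics)) {
      # outer(time, channel): one sinusoid per channel at harmonic k
      values <- values + sweep(
        sin(outer(2 * pi * k * freq * tt, phases[k, ], `+`)),
        2L, amp_per_channel / k, `*`
      )
    }
  }
  if (motif$noise_sd > 0) {
    values <- values + matrix(stats::rnorm(window_len * 12L, 0, motif$noise_sd), window_len, 12L)
  }
  colnames(values) <- cmpl_channels()
  values
}

#' Generate one inactive (class-less) window
#'
#' Inactive windows model idle segments that belong to no behavior class:
#' small-amplitude white noise around a static resting offset, with per-channel
#' variance well below every active class. They carry the reserved label 5.
#'
#' @param noise_sd Noise standard deviation in normalized units (>= 0).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param offset Length-12 static offset (default: a resting posture).
#' @param window_len Window length in samples.
#' @param offset_jitter Sd of a per-window perturbation of the resting
#'   offset (0 disables; the dataset generator uses a small value so idle
#'   episodes differ slightly in pose).
#' @return One-row window-set tibble with `label = 5` and `is_inactive = TRUE`.
#' @export
generate_inactive_window <- function(noise_sd = 0.02, seed = NULL,
                                     offset = inactive_offset(), window_len = 100L,
                                     offset_jitter = 0) {
  noise_sd <- check_number(noise_sd, "noise_sd", lower = 0)
  offset_jitter <- check_number(offset_jitter, "offset_jitter", lower = 0)
  if (length(offset) != 12L) stopf("`offset` must have 12 values.")
  values <- with_seed_(seed, {
    off <- as.numeric(offset)
    if (offset_jitter > 0) off <- off + stats::rnorm(12L, 0, offset_jitter)
    v <- matrix(rep(off, each = window_len), window_len, 12L)
    if (noise_sd > 0) v <- v + matrix(stats::rnorm(window_len * 12L, 0, noise_sd), window_len, 12L)
    v
  })
  colnames(values) <- cmpl_channels()
  new_window_set(list(values), label = inactive_class(), is_inactive = TRUE)
}

#' @rdname generate_inactive_window
#' @export
inactive_offset <- function() {
  # device idle off the animal (e.g. collar removed and set down flat):
  # no rotation rates, gravity on -z instead of any worn orientation,
  # an arbitrary resting heading, attitude unlike any behavior posture
  c(0, 0, 0, 0, 0, -1.0, 0.8, -0.5, -0.3, -1.0, -0.5, 0.8)
}

#' Generate a labeled/unlabeled/test dataset
#'
#' Draws a class-balanced labeled pool and a stratified held-out test pool
#' (80/20 by default via `spec$test_fraction`), plus an unlabeled pool in
#' which a fixed `inactive_fraction` share of windows is inactive and the
#' rest are drawn uniformly over the five classes with their labels hidden.
#' Missing values are injected into unlabeled windows as contiguous gaps
#' (geometric lengths, mean 5 samples) mimicking Bluetooth transmission loss.
#' The ground-truth identity of unlabeled windows is returned separately for
#' evaluation only and must never be fed to training.
#'
#' @param spec A [stream_spec()].
#' @param motifs List of 5 [behavior_motif()]s, one per class in order 0..4.
#' @return A list with elements `labeled`, `unlabeled`, `test` (window-set
#'   tibbles; `unlabeled` has `label = NA` and no truth columns),
#'   `inactive_mask` (logical, ground truth for the unlabeled pool),
#'   `unlabeled_truth` (tibble with `window_id`, `true_label`, `is_inactive`),
#'   and `manifest` (counts, seed and spec echo).
#' @export
make_dataset <- function(spec = stream_spec(), motifs = default_motifs()) {
  if (!inherits(spec, "stream_spec")) stopf("`spec` must be a `stream_spec`.")
  if (length(motifs) != 5L) stopf("`motifs` must list 5 motifs, one per class.")
  ids <- vapply(motifs, function(m) m$class_id, integer(1))
  if (!identical(sort(unname(ids)), 0:4)) stopf("`motifs` must cover class ids 0..4 exactly once.")
  motifs <- motifs[order(ids)]

  with_seed_(spec$seed, {
    gen_class <- function(class_id, n) {
      lapply(seq_len(n), function(i) {
        motif_signal(motifs[[class_id + 1L]], spec$window_len, spec$sample_rate)
      })
    }

    n_test_per_class <- max(1L, as.integer(round(spec$test_fraction * spec$n_labeled_per_class)))
    lab_values <- list(); lab_labels <- integer()
    test_values <- list(); test_labels <- integer()
    for (cls in 0:4) {
      lab_values <- c(lab_values, gen_class(cls, spec$n_labeled_per_class))
      lab_labels <- c(lab_labels, rep.int(cls, spec$n_labeled_per_class))
      test_values <- c(test_values, gen_class(cls, n_test_per_class))
      test_labels <- c(test_labels, rep.int(cls, n_test_per_class))
    }

    n_inactive <- as.integer(round(spec$inactive_fraction * spec$n_unlabeled))
    inactive_mask <- rep(FALSE, spec$n_unlabeled)
    if (spec$n_unlabeled > 0L && n_inactive > 0L) {
      inactive_mask[sample.int(spec$n_unlabeled, n_inactive)] <- TRUE
    }
    true_label <- rep(NA_integer_, spec$n_unlabeled)
    unl_values <- vector("list", spec$n_unlabeled)
    for (i in seq_len(spec$n_unlabeled)) {
      if (inactive_mask[i]) {
        unl_values[[i]] <- generate_inactive_window(window_len = spec$window_len,
                                                    offset_jitter = 0.1)$values[[1L]]
      } else {
        cls <- sample(0:4, 1L)
        true_label[i] <- cls
        unl_values[[i]] <- motif_signal(motifs[[cls + 1L]], spec$window_len, spec$sample_rate)
      }
    }

    # transmission-loss gaps: whole-window Bernoulli(missing_rate), gap length
    # geometric with mean 5 samples, one random channel run per hit window
    if (spec$missing_rate > 0 && spec$n_unlabeled > 0L) {
      hit <- stats::runif(spec$n_unlabeled) < spec$missing_rate
      for (i in which(hit)) {
        len <- min(spec$window_len, stats::rgeom(1L, prob = 1 / 5) + 1L)
        start <- sample.int(spec$window_len - len + 1L, 1L)
        unl_values[[i]][start:(start + len - 1L), ] <- NA_real_
      }
    }

    labeled <- new_window_set(lab_values, label = lab_labels)
    test <- new_window_set(test_values, label = test_labels)
    unlabeled <- new_window_set(unl_values, label = NA_integer_)

    manifest <- list(
      seed = spec$seed,
      spec = unclass(spec),
      n_labeled = nrow(labeled),
      n_test = nrow(test),
      n_unlabeled = nrow(unlabeled),
      n_inactive = sum(inactive_mask),
      labeled_per_class = as.list(table(factor(lab_labels, levels = 0:4)))
    )

    list(
      labeled = labeled,
      unlabeled = unlabeled,
      test = test,
      inactive_mask = inactive_mask,
      unlabeled_truth = tibble::tibble(
        window_id = unlabeled$window_id,
        true_label = true_label,
        is_inactive = inactive_mask
      ),
      manifest = manifest
    )
  })
}

#' Write and read window sets as CSV
#'
#' The CSV dialect has 14 columns in fixed order: `timestamp`, the 12
#' channels of [cmpl_channels()], and `label`. Each window occupies
#' `window_len` consecutive rows; `label` is the behavior code, the string
#' `"inactive"`, or empty for unlabeled windows; missing sensor values are
#' empty fields. The round trip `write_windows_csv()` then
#' `read_windows_csv()` is lossless for values, labels and missingness.
#'
#' @param data A window-set tibble.
#' @param file Path to a CSV file.
#' @param sample_rate Sampling rate used to emit timestamps (seconds).
#' @return `write_windows_csv()` returns `file` invisibly;
#'   `read_windows_csv()` returns a window-set tibble.
#' @export
write_windows_csv <- function(data, file, sample_rate = 50) {
  check_window_set(data)
  rows <- purrr::map2(data$values, data$label, function(v, lab) {
    df <- as.data.frame(v)
    names(df) <- cmpl_channels()
    lab_chr <- if (is.na(lab)) "" else if (lab == inactive_class()) "inactive" else as.character(lab)
    df$label <- lab_chr
    df
  })
  out <- dplyr::bind_rows(rows)
  out <- tibble::add_column(out,
    timestamp = (seq_len(nrow(out)) - 1L) / sample_rate,
    .before = 1L
  )
  readr::write_csv(out, file, na = "")
  invisible(file)
}

#' @param window_len Number of rows per window when reading back.
#' @rdname write_windows_csv
#' @export
read_windows_csv <- function(file, window_len = 100L) {
  header <- strsplit(readr::read_lines(file, n_max = 1L), ",")[[1L]]
  expected <- c("timestamp", cmpl_channels(), "label")
  if (length(header) != 14L) {
    stopf("line 1: expected 14 columns (timestamp, 12 channels, label), got %d.", length(header))
  }
  if (!identical(header, expected)) {
    stopf("line 1: unexpected column names; expected %s.", paste(expected, collapse = ", "))
  }
  # parse problems are re-raised as errors below, with a line number
  raw <- suppressWarnings(readr::read_csv(
    file,
    col_types = readr::cols(
      timestamp = readr::col_double(),
      label = readr::col_character(),
      .default = readr::col_double()
    ),
    na = "", progress = FALSE
  ))
  probs <- readr::problems(raw)
  if (nrow(probs) > 0L) {
    stopf("malformed CSV at line %d: %s", probs$row[1L] + 1L, probs$expected[1L])
  }
  n <- nrow(raw)
  if (n == 0L) return(new_window_set(list()))
  if (n %% window_len != 0L) {
    stopf("%d data rows is not a multiple of window_len = %d.", n, window_len)
  }
  k <- n %/% window_len
  vals <- as.matrix(raw[, cmpl_channels()])
  values <- lapply(seq_len(k), function(i) {
    v <- vals[((i - 1L) * window_len + 1L):(i * window_len), , drop = FALSE]
    colnames(v) <- cmpl_channels()
    v
  })
  lab_chr <- raw$label[seq(1L, n, by = window_len)]
  label <- ifelse(
    is.na(lab_chr), NA_integer_,
    ifelse(lab_chr == "inactive", inactive_class(), suppressWarnings(as.integer(lab_chr)))
  )
  new_window_set(values, label = label, is_inactive = !is.na(label) & label == inactive_class())
}

#' Write a generated dataset (CSV pools + JSON manifest) to a directory
#'
#' @param dataset A list as returned by [make_dataset()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_windows_csv(dataset$labeled, file.path(dir, "labeled.csv"))
  write_windows_csv(dataset$unlabeled, file.path(dir, "unlabeled.csv"))
  write_windows_csv(dataset$test, file.path(dir, "test.csv"))
  manifest <- dataset$manifest
  manifest$inactive_mask <- dataset$inactive_mask
  manifest$unlabeled_true_label <- dataset$unlabeled_truth$true_label
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(dir)
}
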