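#' Drop windows containing missing values
#'
#' Wireless transmission loss produces runs of missing samples; windows
#' containing any missing value are deleted outright (never interpolated),
#' keeping the labeled pool trustworthy. Order is preserved and the number of
#' dropped windows is reported via `message()`.
#'
#' @param data A window-set tibble.
#' @param quiet Suppress the drop-count message.
#' @return The windows with `has_missing == FALSE`.
#' @export
drop_missing_windows <- function(data, quiet = FALSE) {
  check_window_set(data)
  dropped <- sum(data$has_missing)
  if (!quiet && dropped > 0L) {
    message(sprintf("dropped %d window(s) containing missing values", dropped))
  }
  dplyr::filter(data, !.data$has_missing)
}

#' Per-channel z-score normalization
#'
#' `fit_normalizer()` computes per-channel mean and standard deviation over
#' all time steps of all windows in the (training) pool; `apply_normalizer()`
#' centers and scales every window so that, on the fitting pool, each channel
#' has mean 0 and standard deviation 1. Standard deviations use the
#' population convention (divide by n); zero-variance channels are clamped to
#' `eps` and reported. Statistics fitted on training data must be reused
#' unchanged on validation/test data.
#'
#' @param data A window-set tibble without missing values.
#' @param eps Lower clamp for degenerate channel standard deviations.
#' @return `fit_normalizer()`: an object of class `normalization_stats` with
#'   `mean` and `sd` (12-vectors). `apply_normalizer()`: the transformed
#'   window set.
#' @export
fit_normalizer <- function(data, eps = 1e-8) {
  check_window_set(data)
  if (nrow(data) == 0L) stopf("cannot fit a normalizer on an empty window set.")
  if (any(data$has_missing)) stopf("normalizer input must not contain missing values.")
  all_rows <- do.call(rbind, data$values)
  mu <- colMeans(all_rows)
  sd_ <- sqrt(colMeans(sweep(all_rows, 2L, mu)^2))
  degenerate <- sd_ < eps
  if (any(degenerate)) {
    message(sprintf(
      "clamped %d zero-variance channel(s) to eps = %g: %s",
      sum(degenerate), eps, paste(cmpl_channels()[degenerate], collapse = ", ")
    ))
    sd_[degenerate] <- eps
  }
  structure(
    list(mean = stats::setNames(mu, cmpl_channels()),
         sd = stats::setNames(sd_, cmpl_channels()),
         degenerate = degenerate),
    class = "normalization_stats"
  )
}

#' @param stats A fitted `normalization_stats`.
#' @param invert Apply the inverse transform (de-normalize).
#' @rdname fit_normalizer
#' @export
apply_normalizer <- function(data, stats, invert = FALSE) {
  check_window_set(data)
  if (!inherits(stats, "normalization_stats")) stopf("`stats` must come from fit_normalizer().")
  data$values <- lapply(data$values, function(v) {
    if (invert) {
      sweep(sweep(v, 2L, stats$sd, `*`), 2L, stats$mean, `+`)
    } else {
      sweep(sweep(v, 2L, stats$mean), 2L, stats$sd, `/`)
    }
  })
  data
}

#' Write normalization statistics as JSON
#'
#' @param stats A `normalization_stats` object.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_normalizer <- function(stats, file) {
  jsonlite::write_json(
    list(mean = as.list(stats$mean), sd = as.list(stats$sd)),
    file, auto_unbox = TRUE, digits = NA
  )
  invisible(file)
}

#' Reshape a window between the 2D and 4D layouts
#'
#' `reshape_4d()` maps a time x 12 window to the time x sensor x axis array
#' used by the 4D input layout: `out[t, s, a] = in[t, 3*(s-1) + a]`, with
#' sensors ordered (gyro, acc, mag, rot) and axes (x, y, z) — i.e. row t
#' `[g1 g2 g3 a1 a2 a3 m1 m2 m3 r1 r2 r3]` becomes
#' `[[g1 g2 g3], [a1 a2 a3], [m1 m2 m3], [r1 r2 r3]]`. The map is a bijection;
#' `flatten_4d()` is its exact inverse.
#'
#' @param window A time x 12 numeric matrix.
#' @return `reshape_4d()`: a time x 4 x 3 array; `flatten_4d()`: the matrix.
#' @export
reshape_4d <- function(window) {
  check_window(window, "window")
  tl <- nrow(window)
  out <- array(NA_real_, dim = c(tl, 4L, 3L),
               dimnames = list(NULL, cmpl_sensors(), c("x", "y", "z")))
  for (s in 1:4) out[, s, ] <- window[, (3L * (s - 1L) + 1L):(3L * s)]
  out
}

#' @param window4d A time x 4 x 3 array from `reshape_4d()`.
#' @rdname reshape_4d
#' @export
flatten_4d <- function(window4d) {
  if (!is.array(window4d) || length(dim(window4d)) != 3L ||
      !identical(dim(window4d)[2:3], c(4L, 3L))) {
    stopf("`window4d` must be a time x 4 x 3 array.")
  }
  tl <- dim(window4d)[1L]
  out <- matrix(NA_real_, tl, 12L, dimnames = list(NULL, cmpl_channels()))
  for (s in 1:4) out[, (3L * (s - 1L) + 1L):(3L * s)] <- window4d[, s, ]
  out
}

#' Slice a continuous stream into fixed-length windows
#'
#' Windows start at offsets `0, stride, 2*stride, ...`; a trailing partial
#' window is discarded. The default stride equals the window length
#' (non-overlapping windows).
#'
#' @param stream A samples x 12 numeric matrix (or data frame with the
#'   channel columns of [cmpl_channels()]).
#' @param window_len Window length in samples.
#' @param stride Offset between consecutive windows (default `window_len`).
#' @param label Optional label applied to every resulting window.
#' @return A window-set tibble (possibly empty, with a message, when the
#'   stream is shorter than one window).
#' @export
slice_windows <- function(stream, window_len = 100L, stride = window_len, label = NA_integer_) {
  if (is.data.frame(stream)) stream <- as.matrix(stream[, cmpl_channels()])
  check_window(stream, "stream")
  window_len <- as.integer(window_len)
  stride <- as.integer(stride)
  if (stride < 1L) stopf("`stride` must be >= 1.")
  n <- nrow(stream)
  if (n < window_len) {
    message(sprintf("stream of %d samples is shorter than window_len = %d; no windows.", n, window_len))
    return(new_window_set(list()))
  }
  starts <- seq.int(1L, n - window_len + 1L, by = stride)
  values <- lapply(starts, function(s) {
    v <- stream[s:(s + window_len - 1L), , drop = FALSE]
    colnames(v) <- cmpl_channels()
    v
  })
  new_window_set(values, label = label)
}
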