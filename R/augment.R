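#' Augmentation configuration
#'
#' Weak augmentation introduces minor, label-preserving changes (random sign
#' flip, Gaussian jittering) and is applied to the 2D time x channel layout.
#' Strong augmentation applies structure-altering transformations (axis
#' dimension shuffle, temporal inversion) on the 4D time x sensor x axis
#' layout, in the fixed order dimension shuffle then time inverse so the
#' consistency target stays stable.
#'
#' @param jitter_sd Standard deviation of weak Gaussian jitter, in normalized
#'   units (>= 0).
#' @param flip_probability Probability of the weak sign flip, in `[0, 1]`.
#' @param strong_ops Non-empty subset of
#'   `c("dimension_shuffle", "time_inverse")`, applied in that order.
#' @param per_sensor_shuffle Draw an independent axis permutation per sensor
#'   instead of one shared spatial permutation per window.
#' @return An object of class `augmentation_config`.
#' @export
augmentation_config <- function(jitter_sd = 0.05, flip_probability = 0.5,
                                strong_ops = c("dimension_shuffle", "time_inverse"),
                                per_sensor_shuffle = FALSE) {
  jitter_sd <- check_number(jitter_sd, "jitter_sd", lower = 0)
  flip_probability <- check_number(flip_probability, "flip_probability", lower = 0, upper = 1)
  strong_ops <- match.arg(strong_ops, c("dimension_shuffle", "time_inverse"),
                          several.ok = TRUE)
  if (length(strong_ops) == 0L) stopf("`strong_ops` must not be empty.")
  structure(
    list(jitter_sd = jitter_sd, flip_probability = flip_probability,
         strong_ops = strong_ops, per_sensor_shuffle = isTRUE(per_sensor_shuffle)),
    class = "augmentation_config"
  )
}

#' Elementary window augmentations
#'
#' `flip_window()` negates every channel value (mirrored motion) and is an
#' involution. `jitter_window()` adds i.i.d. Gaussian noise.
#' `time_inverse()` reverses temporal order (works on the 2D matrix and the
#' 4D array layouts) and is an involution. `dimension_shuffle()` applies one
#' random permutation of the three axis positions — the same permutation
#' across all time steps and (by default) all sensors — and requires the 4D
#' layout.
#'
#' @param window A time x 12 matrix (2D ops) .
#' @param sd Jitter standard deviation (>= 0).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A transformed window of the same shape.
#' @export
flip_window <- function(window) {
  check_window(window, "window")
  -window
}

#' @rdname flip_window
#' @export
jitter_window <- function(window, sd, seed = NULL) {
  check_window(window, "window")
  sd <- check_number(sd, "sd", lower = 0)
  if (sd == 0) return(window)
  with_seed_(seed, window + matrix(stats::rnorm(length(window), 0, sd), nrow(window)))
}

#' @rdname flip_window
#' @export
time_inverse <- function(window) {
  if (is.matrix(window)) {
    window[rev(seq_len(nrow(window))), , drop = FALSE]
  } else if (is.array(window) && length(dim(window)) == 3L) {
    window[rev(seq_len(dim(window)[1L])), , , drop = FALSE]
  } else {
    stopf("`window` must be a 2D matrix or 3D array.")
  }
}

#' @param window4d A time x 4 x 3 array (see [reshape_4d()]).
#' @param perm Optional explicit permutation of `1:3` (or a 4 x 3 matrix of
#'   per-sensor permutations when `per_sensor = TRUE`); drawn at random when
#'   `NULL`.
#' @param per_sensor Independent permutation per sensor group.
#' @rdname flip_window
#' @export
dimension_shuffle <- function(window4d, seed = NULL, perm = NULL, per_sensor = FALSE) {
  if (!is.array(window4d) || length(dim(window4d)) != 3L ||
      !identical(dim(window4d)[2:3], c(4L, 3L))) {
    stopf("dimension_shuffle() requires the 4D time x 4 x 3 layout; see reshape_4d().")
  }
  if (is.null(perm)) {
    perm <- with_seed_(seed, {
      if (per_sensor) t(vapply(1:4, function(s) sample.int(3L), integer(3))) else sample.int(3L)
    })
  }
  out <- window4d
  if (is.matrix(perm)) {
    for (s in 1:4) out[, s, ] <- window4d[, s, perm[s, ]]
  } else {
    out[] <- window4d[, , perm]
  }
  out
}

#' Weak and strong augmentation
#'
#' `weak_augment()` applies the sign flip with `cfg$flip_probability` and then
#' Gaussian jitter with `cfg$jitter_sd` to a 2D window. `strong_augment()`
#' applies the configured strong operations (dimension shuffle, then time
#' inverse) to a 4D window. Both are deterministic given `seed`.
#'
#' @param window A time x 12 matrix.
#' @param window4d A time x 4 x 3 array.
#' @param cfg An [augmentation_config()].
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A transformed window of the same shape as the input.
#' @export
weak_augment <- function(window, cfg = augmentation_config(), seed = NULL) {
  check_window(window, "window")
  with_seed_(seed, {
    if (stats::runif(1L) < cfg$flip_probability) window <- flip_window(window)
    jitter_window(window, cfg$jitter_sd)
  })
}

#' @rdname weak_augment
#' @export
strong_augment <- function(window4d, cfg = augmentation_config(), seed = NULL) {
  if (length(cfg$strong_ops) == 0L) stopf("`strong_ops` must not be empty.")
  with_seed_(seed, {
    if ("dimension_shuffle" %in% cfg$strong_ops) {
      window4d <- dimension_shuffle(window4d, per_sensor = cfg$per_sensor_shuffle)
    }
    if ("time_inverse" %in% cfg$strong_ops) {
      window4d <- time_inverse(window4d)
    }
    window4d
  })
}

# ---- deterministic batch kernels on flattened n x (T*12) matrices ----------
# Flattening is column-major per window (as.vector of the T x 12 matrix):
# channel c occupies columns ((c-1)*T + 1):(c*T).

# column permutation realizing time inversion on the flattened layout
time_inverse_perm <- function(window_len) {
  as.vector(vapply(1:12, function(c) (c - 1L) * window_len + rev(seq_len(window_len)),
                   integer(window_len)))
}

batch_time_inverse <- function(X, window_len) {
  X[, time_inverse_perm(window_len), drop = FALSE]
}

# perms: n x 3 integer matrix, one shared axis permutation per window
batch_axis_shuffle <- function(X, perms, window_len) {
  stopifnot(nrow(perms) == nrow(X))
  key <- perms %*% c(100L, 10L, 1L)
  out <- X
  for (k in unique(key)) {
    rows <- which(key == k)
    perm <- perms[rows[1L], ]
    new_channel <- as.vector(vapply(1:4, function(s) 3L * (s - 1L) + perm, integer(3)))
    cols <- as.vector(vapply(new_channel, function(c) (c - 1L) * window_len + seq_len(window_len),
                             integer(window_len)))
    out[rows, ] <- X[rows, cols, drop = FALSE]
  }
  out
}

batch_flip <- function(X, flips) {
  X[flips, ] <- -X[flips, , drop = FALSE]
  X
}
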