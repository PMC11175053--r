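#' Channel and sensor naming conventions
#'
#' A sensor window is a numeric matrix with one row per time step and one
#' column per channel. The fixed channel order is gyroscope (x, y, z),
#' accelerometer (x, y, z), magnetometer (x, y, z), rotation
#' (roll, pitch, yaw); the same order is used in the CSV dialect and in the
#' time x sensor x axis 4D layout.
#'
#' @return `cmpl_channels()` returns the 12 channel names in canonical order;
#'   `cmpl_sensors()` the 4 sensor group names.
#' @export
cmpl_channels <- function() {
  c(
    "gyro_x", "gyro_y", "gyro_z",
    "acc_x", "acc_y", "acc_z",
    "mag_x", "mag_y", "mag_z",
    "rot_roll", "rot_pitch", "rot_yaw"
  )
}

#' @rdname cmpl_channels
#' @export
cmpl_sensors <- function() c("gyro", "acc", "mag", "rot")

#' Behavior class labels
#'
#' Five behavior classes, coded 0 to 4, plus the reserved inactive (noise)
#' class coded 5. Inactive windows belong to no behavior class; the cleaning
#' stage of the training loop relabels detected inactive windows to class 5.
#'
#' @return Named integer vector mapping class names to codes.
#' @export
behavior_classes <- function() {
  c(stand = 0L, walk = 1L, sit = 2L, lying = 3L, eat = 4L)
}

#' @rdname behavior_classes
#' @export
inactive_class <- function() 5L

# Run code with a temporary RNG seed, restoring the caller's RNG state.
# When seed is NULL the current stream is used (and advanced).
with_seed_ <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stopf <- function(...) rlang::abort(sprintf(...), call = NULL)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stopf("`%s` must be a single finite number in [%s, %s].", name, lower, upper)
  }
  as.numeric(x)
}

check_window <- function(values, name = "values") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("`%s` must be a numeric matrix (time x channel).", name)
  }
  if (ncol(values) != 12L) {
    stopf("`%s` must have 12 channel columns, got %d.", name, ncol(values))
  }
  invisible(values)
}

# Build the standard window-set tibble. `values` is a list of time x 12
# matrices; `label` uses NA for unlabeled windows and 5 for inactive ones.
new_window_set <- function(values, label = NA_integer_, is_inactive = FALSE) {
  n <- length(values)
  tibble::tibble(
    window_id = seq_len(n),
    label = vctrs_recycle_int(label, n),
    is_inactive = rep_len(as.logical(is_inactive), n),
    has_missing = vapply(values, anyNA, logical(1)),
    values = values
  )
}

vctrs_recycle_int <- function(x, n) {
  x <- as.integer(x)
  if (length(x) == 1L) rep.int(x, n) else {
    if (length(x) != n) stopf("label length %d does not match %d windows.", length(x), n)
    x
  }
}

check_window_set <- function(data, name = "data") {
  if (!is.data.frame(data) || !all(c("values", "has_missing") %in% names(data))) {
    stopf("`%s` must be a window-set tibble with `values` and `has_missing` columns.", name)
  }
  invisible(data)
}

# Flatten a window set into an n x (T*12) matrix (column-major per window:
# channel blocks of T consecutive time steps). The canonical model input.
windows_matrix <- function(data) {
  check_window_set(data)
  if (nrow(data) == 0L) return(matrix(numeric(), 0L, 0L))
  t(vapply(data$values, as.vector, numeric(length(data$values[[1]]))))
}
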