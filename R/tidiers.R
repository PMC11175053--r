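#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cleaned-MPL fit
#'
#' `tidy()` returns the periodic evaluation history (one row per logged
#' evaluation step); `glance()` a one-row summary of the final state.
#'
#' @param x A `cmpl_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cmpl_fit <- function(x, ...) x$eval_history

#' @rdname tidy.cmpl_fit
#' @export
glance.cmpl_fit <- function(x, ...) {
  last <- utils::tail(x$eval_history, 1L)
  out <- tibble::tibble(
    total_steps = x$config$total_steps,
    batch_size = x$config$batch_size,
    uda_enabled = x$config$uda_enabled,
    cleaning_enabled = x$config$cleaning_enabled,
    final_threshold = x$state$threshold,
    final_beta = x$state$beta
  )
  if (nrow(last) > 0L) out <- dplyr::bind_cols(out, last[, setdiff(names(last), "step")])
  out
}

#' @rdname tidy.cmpl_fit
#' @export
tidy.cmpl_supervised_fit <- function(x, ...) x$eval_history

#' @rdname tidy.cmpl_fit
#' @export
glance.cmpl_supervised_fit <- function(x, ...) {
  last <- utils::tail(x$eval_history, 1L)
  out <- tibble::tibble(total_steps = x$config$total_steps,
                        batch_size = x$config$batch_size)
  if (nrow(last) > 0L) out <- dplyr::bind_cols(out, last[, setdiff(names(last), "step")])
  out
}

#' Tidy classification metrics
#'
#' Per-class precision, recall, F1 and support as rows; `glance()` the
#' scalar summary.
#'
#' @param x A `cmpl_metrics` object from [compute_metrics()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cmpl_metrics <- function(x, ...) x$by_class

#' @rdname tidy.cmpl_metrics
#' @export
glance.cmpl_metrics <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, macro_f1 = x$macro_f1,
                 macro_recall = x$macro_recall, test_loss = x$test_loss)
}

#' Plot training loss trajectories
#'
#' Per-step curves of the loss breakdown (MPL, consistency, UDA, distance,
#' student) with the periodic test accuracy overlaid on a free facet.
#'
#' @param object A `cmpl_fit`.
#' @param smooth Window (steps) of the running mean applied to the per-step
#'   losses for display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cmpl_fit <- function(object, smooth = 25L, ...) {
  hist <- object$history
  roll <- function(v) {
    if (smooth <= 1L) return(v)
    stats::filter(v, rep(1 / smooth, smooth), sides = 1L)
  }
  long <- hist |>
    dplyr::transmute(
      step = .data$step,
      `L_MPL` = roll(.data$l_mpl), `L_cons` = roll(.data$l_cons),
      `L_UDA` = roll(.data$l_uda), `L_dis` = roll(.data$l_dis),
      student = roll(.data$student_loss)
    ) |>
    tidyr::pivot_longer(-"step", names_to = "component", values_to = "loss") |>
    dplyr::filter(is.finite(.data$loss))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$loss,
                                     color = .data$component)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::guides(color = "none") +
    ggplot2::labs(x = "training step", y = "loss",
                  title = "Cleaned meta pseudo labels loss breakdown") +
    ggplot2::theme_minimal()
}

#' Plot a row-normalized confusion matrix
#'
#' @param metrics A `cmpl_metrics` object.
#' @return A ggplot tile plot (rows = actual, columns = predicted).
#' @export
plot_confusion <- function(metrics) {
  if (!inherits(metrics, "cmpl_metrics")) stopf("`metrics` must be a `cmpl_metrics`.")
  df <- as.data.frame(as.table(metrics$confusion))
  names(df) <- c("actual", "predicted", "proportion")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$actual,
                                   fill = .data$proportion)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$proportion)),
                       size = 3) +
    ggplot2::scale_y_discrete(limits = rev(rownames(metrics$confusion))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue", limits = c(0, 1)) +
    ggplot2::labs(x = "predicted", y = "actual") +
    ggplot2::theme_minimal()
}

#' Plot the benchmark grid
#'
#' Mean test accuracy per method and label ratio over seeds, with per-seed
#' points.
#'
#' @param grid A tibble from [run_benchmark()].
#' @return A ggplot object.
#' @export
plot_benchmark <- function(grid) {
  ok <- dplyr::filter(grid, .data$status == "ok")
  summ <- ok |>
    dplyr::group_by(.data$method, .data$label_ratio) |>
    dplyr::summarise(accuracy = mean(.data$accuracy), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$label_ratio, y = .data$accuracy,
                                     color = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = ok, alpha = 0.4) +
    ggplot2::labs(x = "labeled data ratio", y = "test accuracy (%)") +
    ggplot2::theme_minimal()
}
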