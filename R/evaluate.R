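#' Classification metrics over the five behavior classes
#'
#' Accuracy, macro (unweighted) F1 and recall, and the row-normalized 5 x 5
#' confusion matrix (rows = actual labels, columns = predicted labels, the
#' diagonal holding each class's correct-classification proportion).
#' Predictions of the inactive class (5) are counted as plain errors against
#' behavior labels: they lower accuracy and the affected confusion row then
#' sums to less than 1 (each row sums to exactly 1 whenever none of its
#' predictions were inactive). Classes absent from `labels` are excluded
#' from the macro averages; a class never predicted contributes precision 0
#' to its F1.
#'
#' @param predictions Integer predictions in 0..5.
#' @param labels True labels in 0..4.
#' @param loss Optional scalar test loss carried through.
#' @return An object of class `cmpl_metrics`: `accuracy`, `macro_f1`,
#'   `macro_recall` (all in percent), `test_loss`, `confusion` (5 x 5),
#'   `support` and the per-class table `by_class`.
#' @export
compute_metrics <- function(predictions, labels, loss = NA_real_) {
  if (length(predictions) != length(labels)) {
    stopf("predictions (%d) and labels (%d) must align.", length(predictions), length(labels))
  }
  if (length(labels) == 0L) stopf("cannot compute metrics on empty input.")
  if (any(!labels %in% 0:4)) stopf("labels must lie in 0..4.")
  predictions <- as.integer(predictions)
  labels <- as.integer(labels)

  acc <- 100 * mean(predictions == labels)
  cls <- 0:4
  support <- vapply(cls, function(c) sum(labels == c), integer(1))
  prec <- rec <- f1 <- numeric(5)
  for (i in seq_along(cls)) {
    c <- cls[i]
    tp <- sum(predictions == c & labels == c)
    npred <- sum(predictions == c)
    prec[i] <- if (npred > 0) tp / npred else 0
    rec[i] <- if (support[i] > 0) tp / support[i] else NA_real_
    f1[i] <- if (support[i] > 0 && (prec[i] + rec[i]) > 0) {
      2 * prec[i] * rec[i] / (prec[i] + rec[i])
    } else if (support[i] > 0) 0 else NA_real_
  }
  present <- support > 0
  confusion <- matrix(0, 5L, 5L, dimnames = list(
    actual = names(behavior_classes()), predicted = names(behavior_classes())
  ))
  for (i in seq_along(cls)) {
    if (support[i] == 0L) next
    for (j in seq_along(cls)) {
      confusion[i, j] <- sum(labels == cls[i] & predictions == cls[j]) / support[i]
    }
  }
  structure(
    list(
      accuracy = acc,
      macro_f1 = 100 * mean(f1[present]),
      macro_recall = 100 * mean(rec[present]),
      test_loss = loss,
      confusion = confusion,
      support = stats::setNames(support, names(behavior_classes())),
      by_class = tibble::tibble(
        class = names(behavior_classes()), class_id = cls,
        precision = prec, recall = rec, f1 = f1, support = support
      )
    ),
    class = "cmpl_metrics"
  )
}

#' @export
print.cmpl_metrics <- function(x, ...) {
  cat(sprintf("<cmpl_metrics> accuracy %.2f%%, macro F1 %.2f%%, macro recall %.2f%%",
              x$accuracy, x$macro_f1, x$macro_recall))
  if (is.finite(x$test_loss)) cat(sprintf(", test loss %.3f", x$test_loss))
  cat("\n")
  print(round(x$confusion, 3))
  invisible(x)
}

#' Precision and recall of inactive-window detection
#'
#' @param flagged Logical vector of detector flags.
#' @param truth Logical ground-truth inactive mask.
#' @return A one-row tibble with `precision`, `recall`, `f1`, `n_flagged`
#'   and `n_inactive`.
#' @export
noise_detection_metrics <- function(flagged, truth) {
  if (length(flagged) != length(truth)) stopf("flags and truth must align.")
  tp <- sum(flagged & truth)
  prec <- if (sum(flagged) > 0) tp / sum(flagged) else NA_real_
  rec <- if (sum(truth) > 0) tp / sum(truth) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0) 2 * prec * rec / (prec + rec) else NA_real_
  tibble::tibble(precision = prec, recall = rec, f1 = f1,
                 n_flagged = sum(flagged), n_inactive = sum(truth))
}

#' Accuracy of cleaned pseudo labels over training
#'
#' Extracts the per-evaluation-interval accuracy of the teacher's cleaned
#' pseudo labels on the whole unlabeled pool against the synthetic ground
#' truth (active windows must get their true class; inactive windows count
#' as correct when flagged by the detector). Requires a fit trained with
#' `unlabeled_truth`.
#'
#' @param fit A `cmpl_fit`.
#' @return A tibble with `step` and `pseudo_label_accuracy` (percent).
#' @export
pseudo_label_accuracy_curve <- function(fit) {
  if (!inherits(fit, "cmpl_fit")) stopf("`fit` must be a `cmpl_fit`.")
  if (!isTRUE(fit$has_truth) || !"pseudo_label_accuracy" %in% names(fit$eval_history)) {
    stopf("fit was trained without unlabeled ground truth; no curve available.")
  }
  fit$eval_history[, c("step", "pseudo_label_accuracy")]
}

#' Desk-scale ablation/benchmark grid
#'
#' Runs the standard label-ratio ablation design at desk scale. For every
#' (method, label ratio, seed) cell: a stratified subsample of the labeled
#' pool at the ratio is kept labeled, and either the remaining labeled
#' windows with hidden labels form the unlabeled pool (`protocol =
#' "relabel"`, no contamination) or they are pooled with the genuinely
#' unlabeled, inactive-contaminated windows (`protocol = "contaminated"`).
#' The method trains and is evaluated on the held-out test pool. Failed
#' cells are recorded and the grid continues.
#'
#' @param dataset A dataset from [make_dataset()] (raw; preprocessing is
#'   applied internally with the normalizer fitted on the labeled pool).
#' @param methods Subset of `c("supervised", "mpl", "mpl_uda", "cleaned")`.
#' @param label_ratios Fractions of the labeled pool kept labeled.
#' @param seeds Integer seeds, one run per seed per cell.
#' @param config Base [train_config()]; each cell overrides `seed` and the
#'   ablation flags.
#' @param backbone A [backbone_config()].
#' @param protocol `"contaminated"` (remainder pooled with the contaminated
#'   unlabeled windows) or `"relabel"` (remainder only, no contamination).
#' @return A tibble with one row per cell: method, label_ratio, seed,
#'   status, accuracy, macro_f1, test_loss and (for cleaned cells) noise
#'   detection precision/recall.
#' @export
run_benchmark <- function(dataset,
                          methods = c("supervised", "mpl_uda", "cleaned"),
                          label_ratios = 0.2, seeds = 1:3,
                          config = desk_config(),
                          backbone = backbone_config(),
                          protocol = c("contaminated", "relabel")) {
  protocol <- match.arg(protocol)
  methods <- match.arg(methods, c("supervised", "mpl", "mpl_uda", "cleaned"),
                       several.ok = TRUE)
  prep <- preprocess_dataset(dataset)
  rows <- list()
  for (ratio in label_ratios) {
    for (seed in seeds) {
      split <- with_seed_(seed + 90000L, split_labeled_pool(prep, ratio, protocol))
      for (method in methods) {
        cell <- tibble::tibble(method = method, label_ratio = ratio, seed = seed,
                               status = "ok", accuracy = NA_real_,
                               macro_f1 = NA_real_, test_loss = NA_real_,
                               noise_precision = NA_real_, noise_recall = NA_real_)
        res <- tryCatch({
          cfg <- config
          cfg$seed <- as.integer(seed)
          if (method == "supervised") {
            fit <- supervised_train(split$labeled, cfg, backbone, test = prep$test)
          } else {
            cfg$uda_enabled <- method %in% c("mpl_uda", "cleaned")
            cfg$cleaning_enabled <- method == "cleaned"
            fit <- cmpl_train(split$labeled, split$unlabeled, cfg, backbone,
                              test = prep$test, unlabeled_truth = split$truth)
          }
          last <- utils::tail(fit$eval_history, 1L)
          cell$accuracy <- last$accuracy
          cell$macro_f1 <- last$macro_f1
          cell$test_loss <- last$test_loss
          if (method == "cleaned" && "noise_precision" %in% names(last)) {
            cell$noise_precision <- last$noise_precision
            cell$noise_recall <- last$noise_recall
          }
          cell
        }, error = function(e) {
          cell$status <- paste("failed:", conditionMessage(e))
          cell
        })
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  dplyr::bind_rows(rows)
}

# stratified subsample of the labeled pool; remainder becomes unlabeled
split_labeled_pool <- function(prep, ratio, protocol) {
  keep <- integer(0)
  for (c in 0:4) {
    idx <- which(prep$labeled$label == c)
    n_keep <- max(1L, round(ratio * length(idx)))
    keep <- c(keep, sample(idx, n_keep))
  }
  keep <- sort(keep)
  rest <- setdiff(seq_len(nrow(prep$labeled)), keep)
  labeled <- prep$labeled[keep, ]
  hidden <- prep$labeled[rest, ]
  hidden_truth <- tibble::tibble(
    window_id = hidden$window_id,
    true_label = hidden$label,
    is_inactive = FALSE
  )
  hidden$label <- NA_integer_
  hidden$is_inactive <- FALSE
  if (protocol == "relabel") {
    unlabeled <- hidden
    truth <- hidden_truth
  } else {
    unlabeled <- dplyr::bind_rows(hidden, prep$unlabeled)
    truth <- dplyr::bind_rows(hidden_truth, prep$unlabeled_truth)
  }
  list(labeled = labeled, unlabeled = unlabeled, truth = truth)
}
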