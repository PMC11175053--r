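#' Training configuration for the cleaned meta pseudo labels loop
#'
#' Full-scale defaults are batch size 50 over 50,000 steps;
#' [desk_config()] returns the desk-scale preset used throughout the tests
#' and benchmarks (batch 16, 2,000 steps, evaluation every 100 steps), which
#' finishes in seconds on one CPU with the `"small"` backbone.
#'
#' @param batch_size Windows per labeled and per unlabeled sub-batch.
#' @param total_steps Number of training steps.
#' @param student_lr,teacher_lr SGD learning rates (eta_S, eta_T).
#' @param ema_alpha EMA rate alpha for the threshold statistics, in `(0, 1]`.
#' @param centroid_lr Centroid step size in `(0, 1]`.
#' @param beta_start,beta_end Linear ramp of the threshold coefficient beta.
#' @param clip_norm Global L2 gradient-norm clip applied to every teacher,
#'   student and supervised SGD step (`Inf` disables).
#' @param dis_weight Weight of the distance loss in the teacher objective
#'   (center-loss convention; the raw squared distance has much higher
#'   curvature than the cross-entropy terms and diverges unweighted under
#'   plain SGD).
#' @param noise_mode `"relabel"` (flagged windows become class 5 targets) or
#'   `"exclude"` (flagged windows drop out of the student loss).
#' @param uda_enabled Include the weak/strong consistency loss.
#' @param cleaning_enabled Run the embedding-distance cleaning (centroid,
#'   threshold, distance loss, relabeling).
#' @param warmup_frac Fraction of steps during which cleaning is inert (no
#'   window is flagged) while the embedding space forms.
#' @param pseudo_view View of the unlabeled batch the teacher pseudo-labels
#'   (and the student trains on): `"weak"` (default; the process feeds the
#'   augmented unlabeled data to both models, and pairing the student's
#'   inputs with the view the labels came from keeps targets consistent
#'   under non-label-preserving transforms such as the sign flip) or
#'   `"raw"`.
#' @param eval_every Evaluation interval in steps.
#' @param seed Seed for the entire run (batching, augmentation, init).
#' @param augment An [augmentation_config()].
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 50L, total_steps = 50000L,
                         student_lr = 0.05, teacher_lr = 0.05,
                         ema_alpha = 0.05, centroid_lr = 0.1,
                         beta_start = 0.5, beta_end = 3.0, dis_weight = 0.05,
                         clip_norm = 10,
                         noise_mode = c("relabel", "exclude"),
                         uda_enabled = TRUE, cleaning_enabled = TRUE,
                         warmup_frac = 0.1,
                         pseudo_view = c("weak", "raw"),
                         eval_every = 1000L, seed = 1L,
                         augment = augmentation_config()) {
  noise_mode <- match.arg(noise_mode)
  pseudo_view <- match.arg(pseudo_view)
  if (student_lr <= 0 || teacher_lr <= 0) stopf("learning rates must be > 0.")
  ema_alpha <- check_number(ema_alpha, "ema_alpha", lower = 1e-12, upper = 1)
  if (beta_start < 0 || beta_end < beta_start) {
    stopf("need beta_end >= beta_start >= 0.")
  }
  warmup_frac <- check_number(warmup_frac, "warmup_frac", lower = 0, upper = 1)
  structure(
    list(batch_size = as.integer(batch_size), total_steps = as.integer(total_steps),
         student_lr = student_lr, teacher_lr = teacher_lr,
         ema_alpha = ema_alpha, centroid_lr = centroid_lr,
         beta_start = beta_start, beta_end = beta_end, dis_weight = dis_weight,
         clip_norm = clip_norm,
         noise_mode = noise_mode, uda_enabled = isTRUE(uda_enabled),
         cleaning_enabled = isTRUE(cleaning_enabled),
         warmup_frac = warmup_frac, pseudo_view = pseudo_view,
         eval_every = as.integer(eval_every), seed = as.integer(seed),
         augment = augment),
    class = "train_config"
  )
}

#' @param ... Overrides passed on to [train_config()].
#' @rdname train_config
#' @export
desk_config <- function(...) {
  args <- list(...)
  defaults <- list(batch_size = 16L, total_steps = 2000L, eval_every = 100L)
  do.call(train_config, utils::modifyList(defaults, args))
}

#' Assemble one training batch
#'
#' Draws equally sized labeled and unlabeled sub-batches (with replacement)
#' and produces the weak view (random sign flip, then jitter, on the 2D
#' layout) and the strong view (axis dimension shuffle, then time inverse,
#' on the 4D layout) of the unlabeled sub-batch. Deterministic given the RNG
#' state (or `seed`).
#'
#' @param labeled,unlabeled Window-set tibbles (or flattened matrices; pass
#'   labels via `labels` when `labeled` is a matrix).
#' @param cfg A [train_config()].
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @param labels 0-based labels when `labeled` is a matrix.
#' @return A list with `x_l`, `y_l`, `x_u`, `x_weak`, `x_strong` (matrices),
#'   and the drawn `idx_l`, `idx_u`.
#' @export
assemble_batch <- function(labeled, unlabeled, cfg = train_config(), seed = NULL,
                           labels = NULL) {
  if (is.data.frame(labeled)) {
    labels <- labeled$label
    labeled <- windows_matrix(labeled)
  }
  if (is.data.frame(unlabeled)) unlabeled <- windows_matrix(unlabeled)
  if (nrow(labeled) == 0L || nrow(unlabeled) == 0L) stopf("pools must be non-empty.")
  with_seed_(seed, assemble_batch_(labeled, labels, unlabeled, cfg))
}

# internal fast path; consumes the current RNG stream
assemble_batch_ <- function(x_labeled, y_labeled, x_unlabeled, cfg) {
  bs <- cfg$batch_size
  window_len <- ncol(x_labeled) %/% 12L
  idx_l <- sample.int(nrow(x_labeled), bs, replace = TRUE)
  idx_u <- sample.int(nrow(x_unlabeled), bs, replace = TRUE)
  x_u <- x_unlabeled[idx_u, , drop = FALSE]

  aug <- cfg$augment
  flips <- stats::runif(bs) < aug$flip_probability
  x_weak <- batch_flip(x_u, flips)
  if (aug$jitter_sd > 0) {
    x_weak <- x_weak + matrix(stats::rnorm(length(x_weak), 0, aug$jitter_sd),
                              nrow(x_weak), ncol(x_weak))
  }

  x_strong <- x_u
  if ("dimension_shuffle" %in% aug$strong_ops) {
    if (aug$per_sensor_shuffle) {
      perms4 <- lapply(seq_len(bs), function(i) {
        t(vapply(1:4, function(s) sample.int(3L), integer(3)))
      })
      x_strong <- t(vapply(seq_len(bs), function(i) {
        w4 <- reshape_4d(matrix(x_strong[i, ], window_len, 12L))
        as.vector(flatten_4d(dimension_shuffle(w4, perm = perms4[[i]])))
      }, numeric(ncol(x_strong))))
    } else {
      perms <- t(vapply(seq_len(bs), function(i) sample.int(3L), integer(3)))
      x_strong <- batch_axis_shuffle(x_strong, perms, window_len)
    }
  }
  if ("time_inverse" %in% aug$strong_ops) {
    x_strong <- batch_time_inverse(x_strong, window_len)
  }

  list(
    x_l = x_labeled[idx_l, , drop = FALSE],
    y_l = y_labeled[idx_l],
    x_u = x_u, x_weak = x_weak, x_strong = x_strong,
    idx_l = idx_l, idx_u = idx_u
  )
}

#' Preprocess a generated dataset for training
#'
#' Applies the standard pipeline: drop unlabeled windows containing missing
#' values (keeping the ground-truth records aligned), fit the z-score
#' normalizer on the labeled training pool only, and apply it unchanged to
#' every pool.
#'
#' @param dataset A list as returned by [make_dataset()].
#' @param quiet Suppress drop-count messages.
#' @return The dataset list with normalized pools, aligned
#'   `inactive_mask`/`unlabeled_truth`, and the fitted `stats` attached.
#' @export
preprocess_dataset <- function(dataset, quiet = TRUE) {
  keep <- !dataset$unlabeled$has_missing
  dataset$unlabeled <- drop_missing_windows(dataset$unlabeled, quiet = quiet)
  dataset$inactive_mask <- dataset$inactive_mask[keep]
  dataset$unlabeled_truth <- dataset$unlabeled_truth[keep, ]
  dataset$labeled <- drop_missing_windows(dataset$labeled, quiet = quiet)
  dataset$test <- drop_missing_windows(dataset$test, quiet = quiet)
  stats <- fit_normalizer(dataset$labeled)
  dataset$labeled <- apply_normalizer(dataset$labeled, stats)
  dataset$unlabeled <- apply_normalizer(dataset$unlabeled, stats)
  dataset$test <- apply_normalizer(dataset$test, stats)
  dataset$stats <- stats
  dataset
}

#' Cleaned meta pseudo labels training
#'
#' Runs the full teacher-student loop for `config$total_steps` steps. Each
#' step: assemble a batch with weak/strong views; teacher pseudo-labels the
#' unlabeled windows; distance scores against the embedding centroid flag
#' windows beyond the threshold as inactive (after a warm-up), which are
#' relabeled to class 5 or excluded; the student takes one SGD step on the
#' cleaned pseudo labels; the feedback signal h (labeled-loss improvement of
#' the student) weights the teacher's MPL loss; the teacher takes one SGD
#' step on `L_MPL + L_UDA + L_dis`; finally the centroid and the threshold
#' statistics are updated. Fully reproducible given `config$seed`.
#'
#' @param labeled,unlabeled Preprocessed window-set tibbles (no missing
#'   values; see [preprocess_dataset()]). `unlabeled` labels are ignored.
#' @param config A [train_config()].
#' @param backbone A [backbone_config()] shared by teacher and student.
#' @param test Optional test window-set for periodic evaluation.
#' @param unlabeled_truth Optional ground truth for the unlabeled pool (a
#'   tibble with `true_label` and `is_inactive`, as from [make_dataset()]);
#'   used for evaluation-only diagnostics (pseudo-label accuracy, noise
#'   detection precision/recall), never by the training updates.
#' @return An object of class `cmpl_fit` with the trained `student` and
#'   `teacher`, the final embedding `state`, the per-step loss `history`,
#'   and the periodic `eval_history`.
#' @export
cmpl_train <- function(labeled, unlabeled, config = desk_config(),
                       backbone = backbone_config(), test = NULL,
                       unlabeled_truth = NULL) {
  check_window_set(labeled, "labeled")
  check_window_set(unlabeled, "unlabeled")
  if (nrow(labeled) == 0L || nrow(unlabeled) == 0L) stopf("pools must be non-empty.")
  if (any(labeled$has_missing) || any(unlabeled$has_missing)) {
    stopf("pools must not contain missing values; see preprocess_dataset().")
  }
  x_l_pool <- windows_matrix(labeled)
  y_l_pool <- labeled$label
  x_u_pool <- windows_matrix(unlabeled)
  x_test <- if (!is.null(test)) windows_matrix(test)
  y_test <- if (!is.null(test)) test$label
  backbone$input_dim <- ncol(x_l_pool)

  set.seed(config$seed)
  teacher <- build_model(backbone, seed = NULL)
  student <- build_model(backbone, seed = NULL)
  state <- embedding_state(beta = config$beta_start)
  warmup_steps <- as.integer(ceiling(config$warmup_frac * config$total_steps))

  ts <- config$total_steps
  hist <- list(
    step = seq_len(ts), student_loss = numeric(ts), h = numeric(ts),
    l_mpl = numeric(ts), l_cons = numeric(ts), l_uda = numeric(ts),
    l_dis = numeric(ts), teacher_total = numeric(ts), beta = numeric(ts),
    mu = rep(NA_real_, ts), sigma = rep(NA_real_, ts),
    threshold = rep(NA_real_, ts), n_flagged = integer(ts)
  )
  evals <- list()

  for (t in seq_len(ts)) {
    beta_t <- beta_schedule(config, t)
    batch <- assemble_batch_(x_l_pool, y_l_pool, x_u_pool, config)

    fw_l <- model_forward(teacher, batch$x_l, keep_cache = TRUE)
    fw_weak <- model_forward(teacher, batch$x_weak, keep_cache = TRUE)
    if (config$pseudo_view == "raw") {
      pseudo_fw <- model_forward(teacher, batch$x_u, keep_cache = TRUE)
      x_student <- batch$x_u
    } else {
      pseudo_fw <- fw_weak
      x_student <- batch$x_weak
    }
    plb <- pseudo_label(teacher, x_student, forward = pseudo_fw)

    cleaning_live <- config$cleaning_enabled && !is.null(state$centroid)
    if (cleaning_live) {
      feats_u <- model_forward(teacher, batch$x_u)$features
      plb$scores <- distance_scores(teacher, batch$x_u, state, features = feats_u)
      if (t > warmup_steps) {
        plb <- clean_pseudo_labels(plb, state, noise_mode = config$noise_mode)
      }
    }

    stu <- student_step(student, x_student, plb$labels, config$student_lr,
                        weights = plb$weights, clip_norm = config$clip_norm)
    h <- if (stu$skipped) 0 else compute_h(student, stu$model, batch$x_l, batch$y_l)
    student <- stu$model

    mpl <- mpl_loss(h, teacher, batch$x_weak, plb$labels,
                    weights = plb$weights, forward = pseudo_fw)
    grads <- model_backward(teacher, pseudo_fw$cache, d_logits = mpl$d_logits)

    cons_val <- 0
    if (config$uda_enabled) {
      fw_strong <- model_forward(teacher, batch$x_strong, keep_cache = TRUE)
      cons <- consistency_loss(teacher, batch$x_weak, batch$x_strong,
                               forward_weak = fw_weak, forward_strong = fw_strong)
      cons_val <- cons$loss
      grads <- add_grads(grads, model_backward(teacher, fw_strong$cache,
                                               d_logits = cons$d_logits))
    }
    sup <- uda_loss(teacher, batch$x_l, batch$y_l, l_cons = cons_val, forward = fw_l)

    dis_val <- 0
    d_feat_l <- NULL
    if (config$cleaning_enabled) {
      if (is.null(state$centroid)) {
        state <- update_centroid(state, fw_l$features, config$centroid_lr)
      }
      dis <- distance_loss(teacher, batch$x_l, state, forward = fw_l,
                           weight = config$dis_weight)
      dis_val <- dis$loss
      d_feat_l <- dis$d_features
    }
    grads <- add_grads(grads, model_backward(teacher, fw_l$cache,
                                             d_logits = sup$d_logits,
                                             d_features = d_feat_l))

    breakdown <- list(l_mpl = mpl$loss, l_uda = sup$loss, l_dis = dis_val,
                      student_loss = stu$loss)
    teacher <- teacher_step(teacher, grads, config$teacher_lr,
                            breakdown = breakdown, clip_norm = config$clip_norm)

    if (config$cleaning_enabled) {
      state <- update_centroid(state, fw_l$features, config$centroid_lr)
      scores_l <- distance_scores(teacher, batch$x_l, state, features = fw_l$features)
      state <- update_threshold(state, scores_l, config$ema_alpha, beta_t)
    }

    hist$student_loss[t] <- stu$loss
    hist$h[t] <- h
    hist$l_mpl[t] <- mpl$loss
    hist$l_cons[t] <- cons_val
    hist$l_uda[t] <- sup$loss
    hist$l_dis[t] <- dis_val
    hist$teacher_total[t] <- mpl$loss + sup$loss + dis_val
    hist$beta[t] <- beta_t
    hist$n_flagged[t] <- sum(plb$noise_mask)
    if (config$cleaning_enabled && !is.null(state$mu)) {
      hist$mu[t] <- state$mu
      hist$sigma[t] <- state$sigma
      hist$threshold[t] <- state$threshold
    }

    if (t %% config$eval_every == 0L || t == ts) {
      evals[[length(evals) + 1L]] <- eval_snapshot(
        t, teacher, student, state, config,
        x_test, y_test, x_u_pool, unlabeled_truth,
        cleaning_live = config$cleaning_enabled && t > warmup_steps
      )
    }
  }

  structure(
    list(
      student = student, teacher = teacher, state = state,
      config = config, backbone = backbone,
      history = tibble::as_tibble(hist),
      eval_history = dplyr::bind_rows(evals),
      has_truth = !is.null(unlabeled_truth)
    ),
    class = "cmpl_fit"
  )
}

# evaluation-only snapshot; consumes no RNG
eval_snapshot <- function(step, teacher, student, state, config,
                          x_test, y_test, x_u_pool, truth, cleaning_live) {
  row <- tibble::tibble(step = step)
  if (!is.null(x_test)) {
    fw <- model_forward(student, x_test)
    pred <- max.col(fw$probabilities, ties.method = "first") - 1L
    m <- compute_metrics(pred, y_test,
                         loss = ce_loss(fw$probabilities, onehot(y_test)))
    row$test_loss <- m$test_loss
    row$accuracy <- m$accuracy
    row$macro_f1 <- m$macro_f1
    fw_t <- model_forward(teacher, x_test)
    row$teacher_accuracy <- 100 * mean(
      (max.col(fw_t$probabilities, ties.method = "first") - 1L) == y_test
    )
  }
  if (!is.null(truth)) {
    fw_u <- model_forward(teacher, x_u_pool)
    pl <- max.col(fw_u$probabilities, ties.method = "first") - 1L
    flagged <- rep(FALSE, nrow(x_u_pool))
    if (cleaning_live && !is.null(state$centroid)) {
      s <- rowSums(sweep(fw_u$features, 2L, state$centroid)^2)
      flagged <- s > state$threshold
    }
    effective <- ifelse(flagged, inactive_class(), pl)
    target <- ifelse(truth$is_inactive, inactive_class(), truth$true_label)
    row$pseudo_label_accuracy <- 100 * mean(effective == target)
    tp <- sum(flagged & truth$is_inactive)
    row$noise_precision <- if (sum(flagged) > 0) tp / sum(flagged) else NA_real_
    row$noise_recall <- if (sum(truth$is_inactive) > 0) tp / sum(truth$is_inactive) else NA_real_
    row$n_flagged_pool <- sum(flagged)
  }
  row
}

#' Detect inactive windows with a trained fit
#'
#' Scores every window of `data` with the fitted teacher's embedding and the
#' final threshold; windows whose score strictly exceeds the threshold are
#' flagged inactive.
#'
#' @param fit A `cmpl_fit` trained with cleaning enabled.
#' @param data Window-set tibble (or flattened matrix) to score.
#' @return A tibble with `score` and `flagged`.
#' @export
detect_inactive <- function(fit, data) {
  if (is.null(fit$state$centroid)) stopf("fit has no embedding state (cleaning disabled?).")
  x <- if (is.data.frame(data)) windows_matrix(data) else data
  s <- distance_scores(fit$teacher, x, fit$state)
  tibble::tibble(score = s, flagged = s > fit$state$threshold)
}

#' Supervised baseline training
#'
#' Plain SGD cross-entropy training of a single backbone on the labeled pool
#' alone — the baseline the semi-supervised methods are compared
#' against, and the reduction target when every semi-supervised component is
#' disabled.
#'
#' @inheritParams cmpl_train
#' @return An object of class `cmpl_supervised_fit` with `model`, `history`
#'   and `eval_history`.
#' @export
supervised_train <- function(labeled, config = desk_config(),
                             backbone = backbone_config(), test = NULL) {
  check_window_set(labeled, "labeled")
  if (any(labeled$has_missing)) stopf("pools must not contain missing values.")
  x_pool <- windows_matrix(labeled)
  y_pool <- labeled$label
  backbone$input_dim <- ncol(x_pool)
  x_test <- if (!is.null(test)) windows_matrix(test)
  y_test <- if (!is.null(test)) test$label

  set.seed(config$seed)
  model <- build_model(backbone, seed = NULL)
  ts <- config$total_steps
  loss <- numeric(ts)
  evals <- list()
  for (t in seq_len(ts)) {
    idx <- sample.int(nrow(x_pool), config$batch_size, replace = TRUE)
    res <- model_grad_ce(model, x_pool[idx, , drop = FALSE],
                         onehot(y_pool[idx], model$cfg$n_classes))
    model <- sgd_step(model, clip_grads(res$grads, config$clip_norm), config$teacher_lr)
    loss[t] <- res$loss
    if ((t %% config$eval_every == 0L || t == ts) && !is.null(x_test)) {
      fw <- model_forward(model, x_test)
      pred <- max.col(fw$probabilities, ties.method = "first") - 1L
      m <- compute_metrics(pred, y_test, loss = ce_loss(fw$probabilities, onehot(y_test)))
      evals[[length(evals) + 1L]] <- tibble::tibble(
        step = t, test_loss = m$test_loss, accuracy = m$accuracy, macro_f1 = m$macro_f1
      )
    }
  }
  structure(
    list(model = model, config = config, backbone = backbone,
         history = tibble::tibble(step = seq_len(ts), supervised_loss = loss),
         eval_history = dplyr::bind_rows(evals)),
    class = "cmpl_supervised_fit"
  )
}

#' @export
print.cmpl_fit <- function(x, ...) {
  cat(sprintf(
    "<cmpl_fit> %d steps, batch %d (uda %s, cleaning %s, noise mode %s)\n",
    x$config$total_steps, x$config$batch_size,
    if (x$config$uda_enabled) "on" else "off",
    if (x$config$cleaning_enabled) "on" else "off",
    x$config$noise_mode
  ))
  if (nrow(x$eval_history) > 0L && "accuracy" %in% names(x$eval_history)) {
    last <- utils::tail(x$eval_history, 1L)
    cat(sprintf("  final test accuracy %.1f%%, macro F1 %.1f%%\n",
                last$accuracy, last$macro_f1))
  }
  invisible(x)
}

#' @export
print.cmpl_supervised_fit <- function(x, ...) {
  cat(sprintf("<cmpl_supervised_fit> %d steps, batch %d\n",
              x$config$total_steps, x$config$batch_size))
  if (nrow(x$eval_history) > 0L) {
    last <- utils::tail(x$eval_history, 1L)
    cat(sprintf("  final test accuracy %.1f%%, macro F1 %.1f%%\n",
                last$accuracy, last$macro_f1))
  }
  invisible(x)
}
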