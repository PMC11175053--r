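#' Embedding-cleaning state
#'
#' Running state of the inactive-data detector: the labeled-feature centroid
#' C, exponential moving averages of the mean (mu) and standard deviation
#' (sigma) of labeled distance scores, the ramped coefficient beta, and the
#' resulting threshold T = mu + beta * sigma. A window whose distance score
#' strictly exceeds T is flagged as inactive.
#'
#' @param centroid Feature-space centroid (NULL before initialization).
#' @param mu,sigma EMA of labeled distance-score mean / standard deviation.
#' @param beta Current threshold coefficient.
#' @param step Number of updates applied so far.
#' @return An object of class `embedding_state`; `threshold` is `Inf` until
#'   the state has been initialized from a first labeled batch.
#' @export
embedding_state <- function(centroid = NULL, mu = NULL, sigma = NULL,
                            beta = 0, step = 0L) {
  if (!is.null(centroid)) centroid <- as.numeric(centroid)
  thr <- if (is.null(mu) || is.null(sigma)) Inf else mu + beta * sigma
  structure(
    list(centroid = centroid, mu = mu, sigma = sigma, beta = beta,
         threshold = thr, step = as.integer(step)),
    class = "embedding_state"
  )
}

#' @export
print.embedding_state <- function(x, ...) {
  if (is.null(x$centroid)) {
    cat("<embedding_state> uninitialized\n")
  } else {
    cat(sprintf(
      "<embedding_state> step %d: mu = %.4g, sigma = %.4g, beta = %.3g, T = %.4g\n",
      x$step, x$mu, x$sigma, x$beta, x$threshold
    ))
  }
  invisible(x)
}

#' Teacher pseudo labels for an unlabeled batch
#'
#' Hard pseudo labels are the argmax of the teacher's class probabilities
#' over all 6 classes; ties break to the lowest class index. Soft
#' predictions are retained for the consistency loss and diagnostics.
#'
#' @param teacher A `cmpl_model`.
#' @param x Unlabeled batch (matrix of flattened windows or window-set
#'   tibble).
#' @param forward Optional precomputed [model_forward()] output for `x`.
#' @return An object of class `pseudo_label_batch`: `probs` (n x 6),
#'   `labels` (0-based hard labels), `scores`, `noise_mask` and `weights`
#'   (filled in by [clean_pseudo_labels()]).
#' @export
pseudo_label <- function(teacher, x, forward = NULL) {
  if (is.null(forward)) forward <- model_forward(teacher, x)
  labels <- max.col(forward$probabilities, ties.method = "first") - 1L
  structure(
    list(probs = forward$probabilities, labels = labels,
         scores = NULL, noise_mask = rep(FALSE, length(labels)),
         weights = rep(1, length(labels))),
    class = "pseudo_label_batch"
  )
}

#' Distance scores against the embedding centroid
#'
#' The score of a window is the squared Euclidean distance between its
#' feature vector phi(x) and the centroid C; large scores indicate data far
#' from the labeled embedding, i.e. candidate inactive windows.
#'
#' @param teacher A `cmpl_model` (used to extract features), or pass
#'   `features` directly.
#' @param x Batch to score.
#' @param state An initialized [embedding_state()].
#' @param features Optional precomputed n x feature_dim matrix.
#' @return Non-negative numeric vector of scores.
#' @export
distance_scores <- function(teacher, x, state, features = NULL) {
  if (is.null(state$centroid)) stopf("embedding centroid is not initialized.")
  if (is.null(features)) features <- model_forward(teacher, x)$features
  rowSums(sweep(features, 2L, state$centroid)^2)
}

#' Threshold-based cleaning of pseudo labels
#'
#' Flags entries whose distance score strictly exceeds the state's threshold
#' as inactive noise. In `"relabel"` mode flagged entries are relabeled to
#' the inactive class (5) and keep full weight; in `"exclude"` mode they get
#' weight 0 and drop out of the student's loss.
#'
#' @param plb A [pseudo_label_batch][pseudo_label()] with `scores` set, or
#'   pass `scores` directly.
#' @param state An [embedding_state()].
#' @param noise_mode `"relabel"` or `"exclude"`.
#' @param scores Optional score vector overriding `plb$scores`.
#' @return The cleaned `pseudo_label_batch`.
#' @export
clean_pseudo_labels <- function(plb, state, noise_mode = c("relabel", "exclude"),
                                scores = NULL) {
  noise_mode <- match.arg(noise_mode)
  if (!is.null(scores)) plb$scores <- scores
  if (is.null(plb$scores)) stopf("distance scores must be computed before cleaning.")
  mask <- plb$scores > state$threshold
  plb$noise_mask <- mask
  if (noise_mode == "relabel") {
    plb$labels[mask] <- inactive_class()
    plb$weights <- rep(1, length(plb$labels))
  } else {
    plb$weights <- as.numeric(!mask)
  }
  plb
}

#' One SGD step of the student on cleaned pseudo labels
#'
#' Performs one gradient step of the cross-entropy between the student's
#' predictions on the unlabeled batch and the (cleaned) pseudo labels. When
#' every entry is excluded the step is skipped and reported.
#'
#' @param student A `cmpl_model`.
#' @param x Unlabeled batch.
#' @param labels 0-based (cleaned) pseudo labels.
#' @param lr Student learning rate (eta_S).
#' @param weights Per-entry weights (0 drops an entry from the loss).
#' @param clip_norm Global L2 gradient-norm clip (`Inf` disables).
#' @return A list with the updated `model`, the scalar `loss`, and `skipped`.
#' @export
student_step <- function(student, x, labels, lr, weights = NULL, clip_norm = Inf) {
  if (!is.null(weights) && sum(weights) == 0) {
    message("student step skipped: every unlabeled entry was excluded")
    return(list(model = student, loss = NA_real_, skipped = TRUE))
  }
  res <- model_grad_ce(student, x, onehot(labels, student$cfg$n_classes), weights)
  list(model = sgd_step(student, clip_grads(res$grads, clip_norm), lr),
       loss = res$loss, skipped = FALSE)
}

#' Teacher feedback signal h
#'
#' The scalar improvement of the student on the labeled batch across its
#' pseudo-label update: `h = CE(y_l, student_before) - CE(y_l,
#' student_after)`. Positive h means the pseudo labels helped (the labeled
#' loss went down); negative h means they hurt.
#'
#' @param student_before,student_after Student snapshots around the step.
#' @param x Labeled batch.
#' @param labels 0-based true labels.
#' @return Scalar h.
#' @export
compute_h <- function(student_before, student_after, x, labels) {
  y <- onehot(labels, student_before$cfg$n_classes)
  ce_loss(model_forward(student_before, x)$probabilities, y) -
    ce_loss(model_forward(student_after, x)$probabilities, y)
}

#' Meta pseudo labels teacher loss
#'
#' `L_MPL = h * CE(y_hat_u, T(x_u))` with the pseudo labels treated as fixed
#' targets (no gradient through the argmax). With h > 0 (pseudo labels
#' reduced the student's labeled loss) minimizing L_MPL increases the
#' teacher's confidence in those labels; with h < 0 it backs away from them.
#'
#' @param h Feedback signal from [compute_h()].
#' @param teacher A `cmpl_model`.
#' @param x Unlabeled batch (the same view the pseudo labels came from).
#' @param labels 0-based pseudo labels (fixed targets).
#' @param weights Optional per-entry weights (exclude mode).
#' @param forward Optional precomputed cached forward of `teacher` on `x`.
#' @return A list with the scalar `loss`, the `d_logits` matrix to
#'   backpropagate, and the cached `forward`.
#' @export
mpl_loss <- function(h, teacher, x, labels, weights = NULL, forward = NULL) {
  if (is.null(forward)) forward <- model_forward(teacher, x, keep_cache = TRUE)
  y <- onehot(labels, teacher$cfg$n_classes)
  ce <- ce_loss(forward$probabilities, y, weights)
  list(
    loss = h * ce,
    d_logits = h * ce_dlogits(forward$probabilities, y, weights),
    forward = forward
  )
}

#' Teacher gradient of the meta pseudo labels objective
#'
#' Two routes to the teacher gradient of the bilevel objective
#' `CE(y_l, student after one pseudo-label step)`:
#'
#' * `mode = "hard"` — the practical surrogate used in training: hard argmax
#'   pseudo labels, one real student step, feedback `h` from [compute_h()],
#'   gradient of `h * CE(y_hat, T(x_u))`. Its expectation over pseudo labels
#'   sampled from the teacher's distribution matches the exact gradient to
#'   first order in the student learning rate, up to a factor `1/n` from the
#'   batch-mean cross-entropies that is absorbed into the teacher learning
#'   rate.
#' * `mode = "exact"` — the exact soft-path gradient: the student's
#'   hypothetical update uses the teacher's full soft distribution, and the
#'   chain rule through that update is evaluated with a forward-mode
#'   directional derivative (JVP). Used for verification and analysis.
#'
#' @param teacher,student `cmpl_model`s (the student is not modified).
#' @param x_u Unlabeled batch.
#' @param x_l,y_l Labeled batch and its 0-based labels.
#' @param student_lr Student learning rate used in the hypothetical step.
#' @param mode `"hard"` or `"exact"`.
#' @return A list with `grads` (teacher parameter gradients), `value` (the
#'   surrogate loss in hard mode; the post-step labeled CE in exact mode),
#'   `h` (hard mode only) and `labels` (hard mode only).
#' @export
mpl_teacher_grad <- function(teacher, student, x_u, x_l, y_l, student_lr,
                             mode = c("hard", "exact")) {
  mode <- match.arg(mode)
  if (is.data.frame(x_u)) x_u <- windows_matrix(x_u)
  if (is.data.frame(x_l)) x_l <- windows_matrix(x_l)
  fw_t <- model_forward(teacher, x_u, keep_cache = TRUE)
  if (mode == "hard") {
    plb <- pseudo_label(teacher, x_u, forward = fw_t)
    stepped <- student_step(student, x_u, plb$labels, student_lr)
    h <- compute_h(student, stepped$model, x_l, y_l)
    l <- mpl_loss(h, teacher, x_u, plb$labels, forward = fw_t)
    return(list(
      grads = model_backward(teacher, fw_t$cache, d_logits = l$d_logits),
      value = l$loss, h = h, labels = plb$labels
    ))
  }
  q <- fw_t$probabilities
  n <- nrow(q)
  sg <- model_grad_ce(student, x_u, q)
  student_after <- sgd_step(student, sg$grads, student_lr)
  vres <- model_grad_ce(student_after, x_l, onehot(y_l, student$cfg$n_classes))
  cache_s <- model_forward(student, x_u, keep_cache = TRUE)
  u <- model_jvp(student, cache_s$cache, vres$grads)
  p_s <- cache_s$probabilities
  a <- student_lr * (u - rowSums(p_s * u))          # a_ik = -lr * (p_i - e_k) . u_i
  d_logits <- q * (a - rowSums(a * q)) / n
  list(
    grads = model_backward(teacher, fw_t$cache, d_logits = d_logits),
    value = vres$loss, h = NULL, labels = NULL
  )
}

#' UDA consistency loss between weak and strong views
#'
#' `L_cons = CE(T(x_weak) as a detached target, T(x_strong))`, averaged over
#' the batch; the gradient flows only through the strong view. For identical
#' views this reduces to the teacher's own prediction entropy, and a teacher
#' outputting uniform distributions gives `log(6)`.
#'
#' @param teacher A `cmpl_model`.
#' @param x_weak,x_strong Index-aligned weak/strong views of the unlabeled
#'   batch.
#' @param forward_weak,forward_strong Optional precomputed forwards
#'   (`forward_strong` must carry a cache).
#' @return A list with `loss`, `d_logits` (for the strong view) and both
#'   forwards.
#' @export
consistency_loss <- function(teacher, x_weak, x_strong,
                             forward_weak = NULL, forward_strong = NULL) {
  if (is.data.frame(x_weak)) x_weak <- windows_matrix(x_weak)
  if (is.data.frame(x_strong)) x_strong <- windows_matrix(x_strong)
  if (is.null(forward_weak)) forward_weak <- model_forward(teacher, x_weak)
  if (is.null(forward_strong)) forward_strong <- model_forward(teacher, x_strong, keep_cache = TRUE)
  if (nrow(forward_weak$probabilities) != nrow(forward_strong$probabilities)) {
    stopf("weak and strong views must align index-wise.")
  }
  target <- forward_weak$probabilities  # detached
  list(
    loss = ce_loss(forward_strong$probabilities, target),
    d_logits = ce_dlogits(forward_strong$probabilities, target),
    forward_weak = forward_weak, forward_strong = forward_strong
  )
}

#' UDA loss
#'
#' `L_UDA = CE(y_l, T(x_l)) + L_cons`: supervised cross-entropy of the
#' teacher on the labeled batch plus the weak/strong consistency term.
#'
#' @param teacher A `cmpl_model`.
#' @param x_l,y_l Labeled batch and 0-based labels.
#' @param l_cons Scalar consistency loss (0 when consistency is disabled).
#' @param forward Optional precomputed cached forward on `x_l`.
#' @return A list with `loss`, the supervised part `ce`, `d_logits` for the
#'   labeled forward, and the `forward`.
#' @export
uda_loss <- function(teacher, x_l, y_l, l_cons = 0, forward = NULL) {
  if (is.null(forward)) forward <- model_forward(teacher, x_l, keep_cache = TRUE)
  y <- onehot(y_l, teacher$cfg$n_classes)
  ce <- ce_loss(forward$probabilities, y)
  list(loss = ce + l_cons, ce = ce,
       d_logits = ce_dlogits(forward$probabilities, y), forward = forward)
}

#' Embedding distance loss
#'
#' `L_dis = mean_i || phi(x_l_i) - C ||^2` over the labeled batch, with the
#' centroid treated as a constant within the step; minimizing it compresses
#' the labeled embedding around the centroid so that distance scores become
#' informative.
#'
#' @param teacher A `cmpl_model`.
#' @param x_l Labeled batch.
#' @param state An initialized [embedding_state()].
#' @param forward Optional precomputed cached forward on `x_l`.
#' @param weight Scalar loss weight (center-loss convention): the component
#'   entering the teacher objective is `weight * mean squared distance`. The
#'   raw squared distance has far higher curvature than the cross-entropy
#'   terms, so the training loop uses a weight well below 1 (see
#'   [train_config()]'s `dis_weight`).
#' @return A list with `loss`, `d_features` to backpropagate, and `forward`.
#' @export
distance_loss <- function(teacher, x_l, state, forward = NULL, weight = 1) {
  if (is.null(state$centroid)) stopf("embedding centroid is not initialized.")
  if (is.null(forward)) forward <- model_forward(teacher, x_l, keep_cache = TRUE)
  diffs <- sweep(forward$features, 2L, state$centroid)
  n <- nrow(diffs)
  list(loss = weight * mean(rowSums(diffs^2)),
       d_features = weight * 2 * diffs / n, forward = forward)
}

#' Update the embedding centroid
#'
#' Exponential step of the centroid toward the labeled-batch feature mean:
#' `C <- C - eta_c * (C - mean(phi(X_l)))`, a gradient step on
#' `0.5 * ||C - mean||^2`. With `eta_c = 1` the centroid jumps to the batch
#' mean; the gap to the batch mean contracts by exactly `1 - eta_c` per call.
#'
#' @param state An [embedding_state()] (an uninitialized one is initialized
#'   to the batch mean).
#' @param features Labeled-batch feature matrix.
#' @param eta_c Centroid step size in `(0, 1]`.
#' @return The updated `embedding_state`.
#' @export
update_centroid <- function(state, features, eta_c = 0.1) {
  if (!is.numeric(eta_c) || length(eta_c) != 1L || eta_c <= 0 || eta_c > 1) {
    stopf("`eta_c` must lie in (0, 1].")
  }
  m <- colMeans(features)
  state$centroid <- if (is.null(state$centroid)) m else state$centroid - eta_c * (state$centroid - m)
  state
}

#' Update the score threshold
#'
#' EMA updates of the labeled distance-score statistics and the resulting
#' threshold: `mu <- alpha * mean(S) + (1 - alpha) * mu`, `sigma <- alpha *
#' sd(S) + (1 - alpha) * sigma`, `T <- mu + beta * sigma` (population sd; an
#' uninitialized state adopts the batch statistics outright).
#'
#' @param state An [embedding_state()].
#' @param scores Distance scores of the current labeled batch.
#' @param alpha EMA rate in `(0, 1]`, akin to a learning rate.
#' @param beta Current threshold coefficient (see [beta_schedule()]).
#' @return The updated `embedding_state`, with `threshold = mu + beta *
#'   sigma` restored as an exact identity.
#' @export
update_threshold <- function(state, scores, alpha, beta) {
  alpha <- check_number(alpha, "alpha", lower = 0, upper = 1)
  m <- mean(scores)
  s <- sqrt(mean((scores - m)^2))
  if (is.null(state$mu)) {
    state$mu <- m
    state$sigma <- s
  } else {
    state$mu <- alpha * m + (1 - alpha) * state$mu
    state$sigma <- alpha * s + (1 - alpha) * state$sigma
  }
  state$beta <- beta
  state$threshold <- state$mu + beta * state$sigma
  state$step <- state$step + 1L
  state
}

#' Ramped threshold coefficient
#'
#' Linear interpolation of beta from `beta_start` at step 0 to `beta_end` at
#' `total_steps`; monotone non-decreasing. Because sigma shrinks as the
#' embedding compresses, the growing beta keeps the threshold selective.
#'
#' @param cfg A [train_config()] (or any list with `beta_start`, `beta_end`,
#'   `total_steps`).
#' @param step Current step in `0..total_steps`.
#' @return Scalar beta.
#' @export
beta_schedule <- function(cfg, step) {
  frac <- min(1, max(0, step / cfg$total_steps))
  cfg$beta_start + (cfg$beta_end - cfg$beta_start) * frac
}

#' One SGD step of the teacher on the combined loss
#'
#' Applies `theta_T <- theta_T - eta_T * grad(L_MPL + L_UDA + L_dis)` with
#' the component gradients already summed. Aborts with a diagnostic dump of
#' the loss breakdown if any component is non-finite.
#'
#' @param teacher A `cmpl_model`.
#' @param grads Summed parameter gradients of the enabled components.
#' @param lr Teacher learning rate (eta_T).
#' @param breakdown Optional named list of component losses for diagnostics.
#' @param clip_norm Global L2 gradient-norm clip (`Inf` disables). Plain SGD
#'   on the combined objective occasionally meets extreme batches (strongly
#'   out-of-distribution inactive windows); clipping bounds the step as in
#'   standard meta-pseudo-labels practice.
#' @return The updated teacher.
#' @export
teacher_step <- function(teacher, grads, lr, breakdown = NULL, clip_norm = Inf) {
  if (!is.null(breakdown)) {
    vals <- unlist(breakdown)
    if (any(!is.finite(vals))) {
      stopf(
        "non-finite teacher loss; breakdown: %s",
        paste(sprintf("%s = %g", names(vals), vals), collapse = ", ")
      )
    }
  }
  sgd_step(teacher, clip_grads(grads, clip_norm), lr)
}

# rescale a gradient list so its global L2 norm is at most clip_norm
clip_grads <- function(grads, clip_norm) {
  if (!is.finite(clip_norm)) return(grads)
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (gn <= clip_norm || gn == 0) return(grads)
  lapply(grads, function(g) g * (clip_norm / gn))
}

# elementwise sum of gradient lists
add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  purrr::map2(a, b[names(a)], `+`)
}

zero_grads <- function(model) lapply(model$params, function(p) p * 0)
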