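# Shared fixtures: everything is generated in code at test time.

# a small, fast dataset for pipeline tests
tiny_dataset <- function(seed = 101L, n_labeled = 12L, n_unlabeled = 40L,
                         inactive_fraction = 0.3, missing_rate = 0) {
  make_dataset(stream_spec(
    n_labeled_per_class = n_labeled, n_unlabeled = n_unlabeled,
    inactive_fraction = inactive_fraction, missing_rate = missing_rate,
    seed = seed
  ))
}

# a toy linear backbone (<= 10 parameters when input_dim = 1, feature_dim = 2,
# n_classes = 2) used for gradient-level verification
toy_backbone <- function(input_dim = 1L, feature_dim = 2L, n_classes = 2L) {
  backbone_config(preset = "linear", input_dim = input_dim,
                  feature_dim = feature_dim, n_classes = n_classes)
}

n_params <- function(model) sum(vapply(model$params, length, integer(1)))

# flatten a parameter list into one numeric vector (fixed order)
flatten_params <- function(params) unlist(lapply(params, as.vector), use.names = FALSE)

# independent cross-entropy on probabilities (reference implementation)
ref_ce <- function(probs, target_rows) {
  mean(-rowSums(target_rows * log(probs)))
}

# reference softmax
ref_softmax <- function(logits) {
  t(apply(logits, 1L, function(z) {
    e <- exp(z - max(z))
    e / sum(e)
  }))
}

# independent forward pass for the linear toy model (input -> W2,b2 -> W3,b3)
ref_linear_forward <- function(params, x) {
  feats <- sweep(x %*% params$W2, 2L, params$b2, `+`)
  logits <- sweep(feats %*% params$W3, 2L, params$b3, `+`)
  list(features = feats, logits = logits, probs = ref_softmax(logits))
}

# independent gradient of mean CE(targets, linear model(x)) for the toy model
ref_linear_ce_grad <- function(params, x, targets) {
  fw <- ref_linear_forward(params, x)
  n <- nrow(x)
  dlog <- (fw$probs - targets) / n
  dfeat <- dlog %*% t(params$W3)
  list(
    W2 = crossprod(x, dfeat), b2 = colSums(dfeat),
    W3 = crossprod(fw$features, dlog), b3 = colSums(dlog)
  )
}

# simulate the soft-target two-step objective for the toy problem:
# CE_l(theta_S - eta * grad_theta_S CE(q(theta_T), student(x_u)))
ref_bilevel_objective <- function(teacher_params, student_params,
                                  x_u, x_l, y_onehot, eta) {
  q <- ref_linear_forward(teacher_params, x_u)$probs
  g <- ref_linear_ce_grad(student_params, x_u, q)
  stepped <- purrr::map2(student_params, g[names(student_params)],
                         function(p, gg) p - eta * gg)
  fw <- ref_linear_forward(stepped, x_l)
  ref_ce(fw$probs, y_onehot)
}

expect_identical_history <- function(a, b) {
  expect_equal(a, b, tolerance = 0)
}

# reference plain-MPL loop assembled from exported primitives; mirrors
# cmpl_train with UDA and cleaning disabled
ref_plain_mpl <- function(labeled, unlabeled, cfg, backbone = backbone_config()) {
  x_l <- windows_matrix(labeled)
  y_l <- labeled$label
  x_u <- windows_matrix(unlabeled)
  backbone$input_dim <- ncol(x_l)
  set.seed(cfg$seed)
  teacher <- build_model(backbone, seed = NULL)
  student <- build_model(backbone, seed = NULL)
  hist <- list(l_mpl = numeric(cfg$total_steps), l_uda = numeric(cfg$total_steps),
               student_loss = numeric(cfg$total_steps), h = numeric(cfg$total_steps))
  for (t in seq_len(cfg$total_steps)) {
    b <- assemble_batch(x_l, x_u, cfg, labels = y_l)
    fw_weak <- model_forward(teacher, b$x_weak, keep_cache = TRUE)
    plb <- pseudo_label(teacher, b$x_weak, forward = fw_weak)
    stu <- student_step(student, b$x_weak, plb$labels, cfg$student_lr,
                        weights = plb$weights, clip_norm = cfg$clip_norm)
    h <- compute_h(student, stu$model, b$x_l, b$y_l)
    student <- stu$model
    mpl <- mpl_loss(h, teacher, b$x_weak, plb$labels, weights = plb$weights,
                    forward = fw_weak)
    grads <- cmpl:::model_backward(teacher, fw_weak$cache, d_logits = mpl$d_logits)
    sup <- uda_loss(teacher, b$x_l, b$y_l, l_cons = 0)
    grads <- cmpl:::add_grads(
      grads, cmpl:::model_backward(teacher, sup$forward$cache, d_logits = sup$d_logits)
    )
    teacher <- teacher_step(teacher, grads, cfg$teacher_lr, clip_norm = cfg$clip_norm)
    hist$l_mpl[t] <- mpl$loss
    hist$l_uda[t] <- sup$loss
    hist$student_loss[t] <- stu$loss
    hist$h[t] <- h
  }
  list(history = hist, teacher = teacher, student = student)
}

# reference supervised loop (plain SGD CE on labeled batches)
ref_supervised <- function(labeled, cfg, backbone = backbone_config()) {
  x <- windows_matrix(labeled)
  y <- labeled$label
  backbone$input_dim <- ncol(x)
  set.seed(cfg$seed)
  model <- build_model(backbone, seed = NULL)
  losses <- numeric(cfg$total_steps)
  for (t in seq_len(cfg$total_steps)) {
    idx <- sample.int(nrow(x), cfg$batch_size, replace = TRUE)
    res <- cmpl:::model_grad_ce(model, x[idx, , drop = FALSE],
                                cmpl:::onehot(y[idx], 6L))
    model <- cmpl:::sgd_step(model, cmpl:::clip_grads(res$grads, cfg$clip_norm),
                             cfg$teacher_lr)
    losses[t] <- res$loss
  }
  list(losses = losses, model = model)
}

# independent brute-force behavior metrics (shared oracle)
brute_metrics <- function(pred, lab) {
  acc <- 100 * sum(pred == lab) / length(lab)
  f1s <- recs <- c()
  for (cl in 0:4) {
    if (sum(lab == cl) == 0) next
    tp <- sum(pred == cl & lab == cl)
    fp <- sum(pred == cl & lab != cl)
    fn <- sum(pred != cl & lab == cl)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- tp / (tp + fn)
    f1s <- c(f1s, if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec))
    recs <- c(recs, rec)
  }
  conf <- matrix(0, 5, 5)
  for (i in 0:4) {
    for (j in 0:4) {
      if (sum(lab == i) > 0) conf[i + 1, j + 1] <- sum(lab == i & pred == j) / sum(lab == i)
    }
  }
  list(accuracy = acc, macro_f1 = 100 * mean(f1s), macro_recall = 100 * mean(recs),
       confusion = conf)
}
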