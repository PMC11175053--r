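# gradient-level unit tests for the cleaned meta pseudo labels components

toy_models <- function(seed = 1, input_dim = 2L, feature_dim = 2L, n_classes = 2L) {
  cfg <- backbone_config(preset = "linear", input_dim = input_dim,
                         feature_dim = feature_dim, n_classes = n_classes)
  set.seed(seed)
  list(teacher = build_model(cfg, seed = NULL),
       student = build_model(cfg, seed = NULL), cfg = cfg)
}

test_that("pseudo labels are the argmax with ties to the lowest class", {
  tm <- toy_models(2)
  # force uniform outputs: zero heads
  uni <- tm$teacher
  uni$params$W3[] <- 0; uni$params$b3[] <- 0
  x <- matrix(rnorm(6), 3, 2)
  plb <- pseudo_label(uni, x)
  expect_true(all(plb$labels == 0L))

  biased <- tm$teacher
  biased$params$W3[] <- 0
  biased$params$b3 <- c(0, 5)
  plb2 <- pseudo_label(biased, x)
  expect_true(all(plb2$labels == 1L))
  expect_equal(plb2$labels, max.col(plb2$probs, ties.method = "first") - 1L)
})

test_that("distance scores are squared Euclidean distances to the centroid", {
  st <- embedding_state(centroid = c(1, 0), mu = 0, sigma = 0, beta = 0)
  expect_equal(distance_scores(NULL, NULL, st, features = matrix(c(1, 2), 1)), 4)
  expect_equal(distance_scores(NULL, NULL, st, features = matrix(c(1, 0), 1)), 0)
  set.seed(3)
  f <- matrix(rnorm(40), 8, 5)
  st5 <- embedding_state(centroid = rnorm(5))
  s <- distance_scores(NULL, NULL, st5, features = f)
  brute <- apply(f, 1L, function(r) sum((r - st5$centroid)^2))
  expect_equal(s, brute, tolerance = 1e-12)
  expect_error(distance_scores(NULL, NULL, embedding_state(), features = f),
               "not initialized")
})

test_that("cleaning flags strictly above the threshold, per noise mode", {
  plb <- structure(list(probs = matrix(0.5, 3, 2), labels = c(0L, 1L, 0L),
                        scores = c(1, 3, 5), noise_mask = rep(FALSE, 3),
                        weights = rep(1, 3)),
                   class = "pseudo_label_batch")
  st <- embedding_state(mu = 3, sigma = 0, beta = 0)  # threshold exactly 3
  out <- clean_pseudo_labels(plb, st, "relabel")
  expect_identical(out$noise_mask, c(FALSE, FALSE, TRUE))
  expect_identical(out$labels, c(0L, 1L, 5L))
  expect_identical(out$weights, rep(1, 3))

  out2 <- clean_pseudo_labels(plb, st, "exclude")
  expect_identical(out2$labels, c(0L, 1L, 0L))
  expect_identical(out2$weights, c(1, 1, 0))

  none <- clean_pseudo_labels(plb, embedding_state(), "relabel")
  expect_false(any(none$noise_mask))
  zero <- clean_pseudo_labels(plb, embedding_state(mu = 0, sigma = 0, beta = 0), "relabel")
  expect_true(all(zero$noise_mask))
})

test_that("student_step descends and matches finite-difference gradients", {
  tm <- toy_models(4)
  set.seed(9)
  x <- matrix(rnorm(20), 10, 2)
  labels <- sample(0:1, 10, TRUE)
  frozen <- student_step(tm$student, x, labels, lr = 0)
  expect_identical(frozen$model$params, tm$student$params)

  # finite-difference oracle: update must equal -lr * grad within 1e-4
  lr <- 0.01
  stepped <- student_step(tm$student, x, labels, lr = lr)
  y <- cmpl:::onehot(labels, 2L)
  eps <- 1e-6
  for (nm in names(tm$student$params)) {
    for (j in seq_along(tm$student$params[[nm]])) {
      up <- tm$student; up$params[[nm]][j] <- up$params[[nm]][j] + eps
      dn <- tm$student; dn$params[[nm]][j] <- dn$params[[nm]][j] - eps
      fd <- (ref_ce(ref_linear_forward(up$params, x)$probs, y) -
             ref_ce(ref_linear_forward(dn$params, x)$probs, y)) / (2 * eps)
      delta <- stepped$model$params[[nm]][j] - tm$student$params[[nm]][j]
      expect_equal(delta, -lr * fd, tolerance = 1e-4)
    }
  }

  # descent on a fixed batch for a small learning rate
  before <- ref_ce(ref_linear_forward(tm$student$params, x)$probs, y)
  after <- ref_ce(ref_linear_forward(stepped$model$params, x)$probs, y)
  expect_lt(after, before)

  skipped <- student_step(tm$student, x, labels, lr = 1, weights = rep(0, 10))
  expect_true(skipped$skipped)
  expect_identical(skipped$model$params, tm$student$params)
})

test_that("h is the labeled-loss improvement and is recomputable", {
  tm <- toy_models(5)
  set.seed(10)
  x_l <- matrix(rnorm(12), 6, 2)
  y_l <- sample(0:1, 6, TRUE)
  expect_equal(compute_h(tm$student, tm$student, x_l, y_l), 0)

  stepped <- student_step(tm$student, x_l, y_l, lr = 0.5)
  h <- compute_h(tm$student, stepped$model, x_l, y_l)
  # training on the labeled batch itself must improve it: h > 0 means helped
  expect_gt(h, 0)
  y <- cmpl:::onehot(y_l, 2L)
  ref <- ref_ce(ref_linear_forward(tm$student$params, x_l)$probs, y) -
    ref_ce(ref_linear_forward(stepped$model$params, x_l)$probs, y)
  expect_equal(h, ref, tolerance = 1e-12)
})

test_that("the MPL loss scales with h and reuses the teacher CE", {
  tm <- toy_models(6)
  set.seed(11)
  x_u <- matrix(rnorm(16), 8, 2)
  labels <- sample(0:1, 8, TRUE)
  zero <- mpl_loss(0, tm$teacher, x_u, labels)
  expect_equal(zero$loss, 0)
  expect_true(all(zero$d_logits == 0))

  l1 <- mpl_loss(0.7, tm$teacher, x_u, labels)
  l2 <- mpl_loss(-0.7, tm$teacher, x_u, labels)
  expect_equal(l1$d_logits, -l2$d_logits, tolerance = 1e-12)

  fw <- model_forward(tm$teacher, x_u)
  ce <- ref_ce(fw$probabilities, cmpl:::onehot(labels, 2L))
  expect_equal(l1$loss, 0.7 * ce, tolerance = 1e-12)
})

test_that("consistency loss realizes its closed forms and brute force", {
  tm <- toy_models(7)
  uni <- tm$teacher
  uni$params$W3[] <- 0; uni$params$b3[] <- 0
  x <- matrix(rnorm(10), 5, 2)
  # uniform outputs over 2 classes -> CE = ln 2 (and ln 6 for the 6-class head)
  expect_equal(consistency_loss(uni, x, x)$loss, log(2), tolerance = 1e-12)

  full <- build_model(backbone_config(preset = "linear", input_dim = 2L,
                                      feature_dim = 3L), seed = 8)
  full$params$W3[] <- 0; full$params$b3[] <- 0
  expect_equal(consistency_loss(full, x, x)$loss, log(6), tolerance = 1e-12)

  # identical views: CE(p, p) equals the prediction entropy H(p)
  cl <- consistency_loss(tm$teacher, x, x)
  p <- model_forward(tm$teacher, x)$probabilities
  expect_equal(cl$loss, mean(-rowSums(p * log(p))), tolerance = 1e-12)

  # brute force on distinct views
  x2 <- matrix(rnorm(10), 5, 2)
  cl2 <- consistency_loss(tm$teacher, x, x2)
  pw <- model_forward(tm$teacher, x)$probabilities
  ps <- model_forward(tm$teacher, x2)$probabilities
  expect_equal(cl2$loss, mean(-rowSums(pw * log(ps))), tolerance = 1e-12)
  expect_error(consistency_loss(tm$teacher, x, x2[1:3, ]), "align")
})

test_that("UDA loss is the supervised CE plus the consistency term", {
  tm <- toy_models(8)
  set.seed(12)
  x_l <- matrix(rnorm(12), 6, 2)
  y_l <- sample(0:1, 6, TRUE)
  u0 <- uda_loss(tm$teacher, x_l, y_l, l_cons = 0)
  ce <- ref_ce(model_forward(tm$teacher, x_l)$probabilities, cmpl:::onehot(y_l, 2L))
  expect_equal(u0$loss, ce, tolerance = 1e-12)
  u1 <- uda_loss(tm$teacher, x_l, y_l, l_cons = 0.42)
  expect_equal(u1$loss, ce + 0.42, tolerance = 1e-12)
})

test_that("distance loss matches the brute-force mean squared distance", {
  st <- embedding_state(centroid = c(0, 0))
  one <- structure(list(features = matrix(c(1, 0), 1),
                        cache = list(x = matrix(0, 1, 2))), class = "list")
  tm <- toy_models(9)
  fw <- model_forward(tm$teacher, matrix(rnorm(10), 5, 2), keep_cache = TRUE)
  stc <- embedding_state(centroid = colMeans(fw$features))
  dl <- distance_loss(tm$teacher, NULL, stc, forward = fw)
  brute <- mean(apply(fw$features, 1, function(r) sum((r - stc$centroid)^2)))
  expect_equal(dl$loss, brute, tolerance = 1e-12)

  # all features at the centroid -> 0; single feature (1,0) vs origin -> 1
  same <- fw; same$features <- matrix(rep(stc$centroid, 5), 5, byrow = TRUE)
  expect_equal(distance_loss(tm$teacher, NULL, stc, forward = same)$loss, 0)
  single <- fw; single$features <- matrix(c(1, 0), 1)
  expect_equal(distance_loss(tm$teacher, NULL, st, forward = single)$loss, 1)
  # the weighted component scales linearly
  expect_equal(distance_loss(tm$teacher, NULL, stc, forward = fw, weight = 0.05)$loss,
               0.05 * brute, tolerance = 1e-12)
})

test_that("centroid updates contract toward the batch mean exactly", {
  set.seed(13)
  f <- matrix(rnorm(30), 10, 3)
  m <- colMeans(f)
  st <- embedding_state(centroid = c(5, -5, 2))
  expect_equal(update_centroid(st, f, eta_c = 1)$centroid, m)
  at_mean <- embedding_state(centroid = m)
  expect_equal(update_centroid(at_mean, f, eta_c = 0.3)$centroid, m)
  for (eta in c(0.1, 0.5, 0.9)) {
    upd <- update_centroid(st, f, eta_c = eta)
    expect_equal(sqrt(sum((upd$centroid - m)^2)),
                 (1 - eta) * sqrt(sum((st$centroid - m)^2)), tolerance = 1e-12)
  }
  expect_error(update_centroid(st, f, eta_c = 0), "0, 1")
  expect_error(update_centroid(st, f, eta_c = 1.5), "0, 1")
})

test_that("threshold updates follow the EMA equations exactly", {
  scores <- c(1, 2, 3, 4)
  m <- mean(scores)
  s <- sqrt(mean((scores - m)^2))
  st <- embedding_state(mu = 10, sigma = 5, beta = 1)

  full <- update_threshold(st, scores, alpha = 1, beta = 2)
  expect_equal(full$mu, m)
  expect_equal(full$sigma, s)
  frozen <- update_threshold(st, scores, alpha = 0, beta = 2)
  expect_equal(frozen$mu, 10)
  expect_equal(frozen$sigma, 5)

  mid <- update_threshold(st, scores, alpha = 0.25, beta = 3)
  expect_equal(mid$mu, 0.25 * m + 0.75 * 10)
  expect_equal(mid$sigma, 0.25 * s + 0.75 * 5)
  expect_equal(mid$threshold, mid$mu + 3 * mid$sigma)

  # the printed arithmetic example: mu 2.0, sigma 0.5, beta 2 -> T = 3.0
  expect_equal(embedding_state(mu = 2, sigma = 0.5, beta = 2)$threshold, 3)
})

test_that("beta ramps linearly over the training budget", {
  cfg <- train_config(beta_start = 0.5, beta_end = 3, total_steps = 1000L)
  expect_equal(beta_schedule(cfg, 0), 0.5)
  expect_equal(beta_schedule(cfg, 1000), 3)
  expect_equal(beta_schedule(cfg, 500), 1.75)
  b <- vapply(seq(0, 1000, by = 50), beta_schedule, numeric(1), cfg = cfg)
  expect_true(all(diff(b) >= 0))
})

test_that("teacher_step combines gradients linearly and guards finiteness", {
  tm <- toy_models(14)
  set.seed(15)
  x_l <- matrix(rnorm(12), 6, 2)
  y_l <- sample(0:1, 6, TRUE)
  res <- cmpl:::model_grad_ce(tm$teacher, x_l, cmpl:::onehot(y_l, 2L))

  frozen <- teacher_step(tm$teacher, res$grads, lr = 0)
  expect_identical(frozen$params, tm$teacher$params)

  # with only the supervised CE enabled the step is a plain supervised step
  stepped <- teacher_step(tm$teacher, res$grads, lr = 0.1)
  manual <- purrr::map2(tm$teacher$params, res$grads, function(p, g) p - 0.1 * g)
  expect_equal(stepped$params, manual, tolerance = 1e-15)

  # combined backward equals the sum of per-component backwards
  fw <- model_forward(tm$teacher, x_l, keep_cache = TRUE)
  dlog <- cmpl:::ce_dlogits(fw$probabilities, cmpl:::onehot(y_l, 2L))
  dfeat <- matrix(rnorm(12), 6, 2)
  combined <- cmpl:::model_backward(tm$teacher, fw$cache, d_logits = dlog,
                                    d_features = dfeat)
  separate <- cmpl:::add_grads(
    cmpl:::model_backward(tm$teacher, fw$cache, d_logits = dlog),
    cmpl:::model_backward(tm$teacher, fw$cache, d_features = dfeat)
  )
  expect_equal(combined, separate[names(combined)], tolerance = 1e-12)

  bad <- list(l_mpl = NaN, l_uda = 1)
  expect_error(teacher_step(tm$teacher, res$grads, 0.1, breakdown = bad),
               "non-finite")
})

test_that("gradient clipping preserves direction and bounds the norm", {
  g <- list(a = matrix(c(3, 4), 1), b = 0)
  clipped <- cmpl:::clip_grads(g, 2.5)
  expect_equal(sqrt(sum(unlist(clipped)^2)), 2.5)
  expect_equal(clipped$a / sqrt(sum(clipped$a^2)), g$a / 5, tolerance = 1e-12)
  expect_identical(cmpl:::clip_grads(g, Inf), g)
  expect_identical(cmpl:::clip_grads(g, 100), g)
})
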