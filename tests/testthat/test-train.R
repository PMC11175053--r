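desk_tiny <- function(...) {
  desk_config(total_steps = 60L, eval_every = 30L, batch_size = 8L, ...)
}

prep_tiny <- function(seed = 31L) {
  preprocess_dataset(tiny_dataset(seed = seed, n_labeled = 8L, n_unlabeled = 30L))
}

test_that("assemble_batch draws balanced, reproducible batches with views", {
  prep <- prep_tiny()
  cfg <- desk_config(batch_size = 10L)
  b1 <- assemble_batch(prep$labeled, prep$unlabeled, cfg, seed = 4)
  b2 <- assemble_batch(prep$labeled, prep$unlabeled, cfg, seed = 4)
  expect_identical(b1, b2)
  expect_equal(nrow(b1$x_l), 10L)
  expect_equal(nrow(b1$x_u), 10L)
  expect_equal(length(b1$y_l), 10L)

  # weak view differs from the raw batch whenever jitter is on
  for (s in 1:10) {
    b <- assemble_batch(prep$labeled, prep$unlabeled, cfg, seed = s)
    expect_false(isTRUE(all.equal(b$x_weak, b$x_u)))
    expect_false(isTRUE(all.equal(b$x_strong, b$x_u)))
  }
  expect_error(assemble_batch(prep$labeled[0, ], prep$unlabeled, cfg), "non-empty")
})

test_that("training runs are reproducible and keep the threshold identity", {
  prep <- prep_tiny()
  cfg <- desk_tiny(seed = 5)
  f1 <- cmpl_train(prep$labeled, prep$unlabeled, cfg, test = prep$test)
  f2 <- cmpl_train(prep$labeled, prep$unlabeled, cfg, test = prep$test)
  expect_identical_history(f1$history, f2$history)
  expect_equal(f1$teacher$params, f2$teacher$params, tolerance = 0)
  expect_equal(f1$student$params, f2$student$params, tolerance = 0)

  # T = mu + beta * sigma after every recorded update; sigma >= 0 always
  h <- f1$history
  rec <- !is.na(h$mu)
  expect_true(any(rec))
  expect_equal(h$threshold[rec], h$mu[rec] + h$beta[rec] * h$sigma[rec],
               tolerance = 1e-12)
  expect_true(all(h$sigma[rec] >= 0))
  expect_true(all(is.finite(h$teacher_total)))
})

test_that("disabling cleaning and UDA zeroes their loss channels", {
  prep <- prep_tiny()
  fit <- cmpl_train(prep$labeled, prep$unlabeled,
                    desk_tiny(seed = 6, uda_enabled = FALSE, cleaning_enabled = FALSE))
  expect_true(all(fit$history$l_cons == 0))
  expect_true(all(fit$history$l_dis == 0))
  expect_true(all(fit$history$n_flagged == 0L))
  expect_true(all(is.na(fit$history$mu)))
})

test_that("the plain-MPL configuration equals a reference loop built from primitives", {
  prep <- prep_tiny(seed = 33L)
  cfg <- desk_tiny(seed = 9, uda_enabled = FALSE, cleaning_enabled = FALSE)
  fit <- cmpl_train(prep$labeled, prep$unlabeled, cfg)
  ref <- ref_plain_mpl(prep$labeled, prep$unlabeled, cfg)
  expect_equal(fit$history$l_mpl, ref$history$l_mpl, tolerance = 0)
  expect_equal(fit$history$l_uda, ref$history$l_uda, tolerance = 0)
  expect_equal(fit$history$student_loss, ref$history$student_loss, tolerance = 0)
  expect_equal(fit$history$h, ref$history$h, tolerance = 0)
  expect_equal(fit$teacher$params, ref$teacher$params, tolerance = 0)
  expect_equal(fit$student$params, ref$student$params, tolerance = 0)
})

test_that("the supervised baseline equals a reference supervised loop", {
  prep <- prep_tiny(seed = 34L)
  cfg <- desk_tiny(seed = 12)
  fit <- supervised_train(prep$labeled, cfg, test = prep$test)
  ref <- ref_supervised(prep$labeled, cfg)
  expect_equal(fit$history$supervised_loss, ref$losses, tolerance = 0)
  expect_equal(fit$model$params, ref$model$params, tolerance = 0)
})

test_that("excluded windows contribute exactly zero student gradient", {
  tm_cfg <- backbone_config(preset = "small", input_dim = 240L, hidden_dim = 6L,
                            feature_dim = 4L)
  m <- build_model(tm_cfg, seed = 3)
  set.seed(8)
  x <- matrix(rnorm(10 * 240), 10, 240)
  labels <- sample(0:5, 10, TRUE)
  w <- c(1, 1, 0, 1, 0, 0, 1, 1, 0, 1)
  full <- cmpl:::model_grad_ce(m, x, cmpl:::onehot(labels), weights = w)
  kept <- w == 1
  filtered <- cmpl:::model_grad_ce(m, x[kept, ], cmpl:::onehot(labels[kept]))
  expect_equal(full$grads, filtered$grads, tolerance = 1e-12)
  expect_equal(full$loss, filtered$loss, tolerance = 1e-12)
})

test_that("short runs beat chance accuracy on the synthetic task", {
  # desk-scale smoke benchmark: 200 steps, 3 seeds, all above the 20% chance
  # level of 5 balanced classes
  for (s in 1:3) {
    prep <- preprocess_dataset(tiny_dataset(seed = 40L + s, n_labeled = 20L,
                                            n_unlabeled = 60L))
    fit <- cmpl_train(prep$labeled, prep$unlabeled,
                      desk_config(total_steps = 200L, eval_every = 200L, seed = s),
                      test = prep$test)
    acc <- utils::tail(fit$eval_history$accuracy, 1)
    expect_gt(acc, 20)
    expect_true(all(is.finite(unlist(fit$history[, c("l_mpl", "l_uda", "l_dis")]))))
  }
})

test_that("detect_inactive scores with the fitted state", {
  prep <- prep_tiny(seed = 35L)
  fit <- cmpl_train(prep$labeled, prep$unlabeled, desk_tiny(seed = 2),
                    unlabeled_truth = prep$unlabeled_truth)
  det <- detect_inactive(fit, prep$unlabeled)
  expect_equal(nrow(det), nrow(prep$unlabeled))
  expect_true(all(det$score >= 0))
  expect_identical(det$flagged, det$score > fit$state$threshold)
  nocl <- cmpl_train(prep$labeled, prep$unlabeled,
                     desk_tiny(seed = 2, cleaning_enabled = FALSE))
  expect_error(detect_inactive(nocl, prep$unlabeled), "embedding state")
})

test_that("tidiers expose evaluation history and final summaries", {
  prep <- prep_tiny(seed = 36L)
  fit <- cmpl_train(prep$labeled, prep$unlabeled, desk_tiny(seed = 3),
                    test = prep$test, unlabeled_truth = prep$unlabeled_truth)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2L)  # eval_every 30 over 60 steps
  expect_true(all(c("accuracy", "pseudo_label_accuracy") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$accuracy, utils::tail(td$accuracy, 1))
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
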