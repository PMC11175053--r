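#' Backbone configuration
#'
#' The default backbone is a small residual convolutional network over time:
#' a strided temporal convolution over the 12 input channels, a stack of
#' same-length residual convolution blocks whose depth grows with the
#' preset, global average pooling over time (making the embedding robust to
#' phase shifts within the window), a linear feature head producing the
#' embedding phi(x) used by the distance-based cleaning, and a linear
#' classification head over the 5 behavior classes plus the reserved
#' inactive class (6 logits). The `"small"` preset (no residual block,
#' 32 filters) is the desk-scale default; `"resnet18"`, `"resnet30"` and
#' `"resnet50"` add 2, 3 and 4 residual blocks with more filters. The
#' `"linear"` preset (two stacked linear maps, no convolution) exists for
#' small-scale analyses such as gradient verification on toy problems.
#'
#' The 1D (time x 12) and 4D (time x 4 x 3) input layouts contain the same
#' values up to a fixed index permutation, which the first convolution's
#' channel mixing absorbs; the layout choice matters for the augmentation
#' structure and is recorded here for bookkeeping.
#'
#' @param input_layout `"4d"` or `"1d"`.
#' @param preset Depth preset: `"small"`, `"resnet18"`, `"resnet30"`,
#'   `"resnet50"`, or `"linear"`.
#' @param feature_dim Dimension of the embedding phi(x) (>= 2).
#' @param hidden_dim Number of convolution filters; `NULL` takes the preset
#'   default.
#' @param n_classes Number of output classes; fixed at 6 (5 behaviors +
#'   inactive) for the convolutional presets, free for `"linear"`.
#' @param input_dim Flattened input dimension (window_len x 12 channels for
#'   the convolutional presets).
#' @param n_channels Input channels (12 for sensor windows).
#' @return An object of class `backbone_config`.
#' @export
backbone_config <- function(input_layout = c("4d", "1d"),
                            preset = c("small", "resnet18", "resnet30",
                                       "resnet50", "linear"),
                            feature_dim = 16L, hidden_dim = NULL,
                            n_classes = 6L, input_dim = 1200L,
                            n_channels = 12L) {
  input_layout <- match.arg(input_layout)
  preset <- match.arg(preset)
  feature_dim <- as.integer(check_number(feature_dim, "feature_dim", lower = 1))
  if (preset != "linear") {
    if (n_classes != 6L) stopf("`n_classes` is fixed at 6 (5 behaviors + inactive).")
    if (feature_dim < 2L) stopf("`feature_dim` must be >= 2.")
    if (as.integer(input_dim) %% as.integer(n_channels) != 0L) {
      stopf("`input_dim` must be a multiple of `n_channels`.")
    }
  }
  depth <- switch(preset, small = 0L, resnet18 = 2L, resnet30 = 3L,
                  resnet50 = 4L, linear = 0L)
  if (is.null(hidden_dim)) {
    hidden_dim <- switch(preset, small = 32L, resnet18 = 64L, resnet30 = 64L,
                         resnet50 = 128L, linear = 0L)
  }
  structure(
    list(input_layout = input_layout, preset = preset, n_blocks = depth,
         hidden_dim = as.integer(hidden_dim), feature_dim = feature_dim,
         n_classes = as.integer(n_classes), input_dim = as.integer(input_dim),
         n_channels = as.integer(n_channels)),
    class = "backbone_config"
  )
}

# im2col layout for one temporal convolution: a (k * c_in) x t_out matrix of
# column indices into the flattened (channel-major, padded) activations;
# out-of-range taps point at the zero sentinel column t_in * c_in + 1.
conv_layout <- function(t_in, c_in, k, stride, pad) {
  t_out <- (t_in + 2L * pad - k) %/% stride + 1L
  sentinel <- t_in * c_in + 1L
  idx <- matrix(sentinel, k * c_in, t_out)
  for (t2 in seq_len(t_out)) {
    times <- (t2 - 1L) * stride - pad + seq_len(k)  # 1-based input times
    for (c in seq_len(c_in)) {
      ok <- times >= 1L & times <= t_in
      rows <- (c - 1L) * k + seq_len(k)
      idx[rows[ok], t2] <- (c - 1L) * t_in + times[ok]
    }
  }
  list(idx = idx, idx_vec = as.vector(idx), t_out = t_out, k = k,
       c_in = c_in, stride = stride, sentinel = sentinel)
}

# gather the im2col patch matrix: (n * t_out) x (k * c_in), rows t-major
conv_gather <- function(flat, layout) {
  n <- nrow(flat)
  g <- cbind(flat, 0)[, layout$idx_vec, drop = FALSE]
  dim(g) <- c(n, nrow(layout$idx), layout$t_out)
  matrix(aperm(g, c(1L, 3L, 2L)), n * layout$t_out, nrow(layout$idx))
}

# scatter-add the gradient of conv_gather back onto the flat activations
conv_scatter <- function(d_patch, layout, n, flat_len) {
  d_g <- aperm(array(d_patch, c(n, layout$t_out, nrow(layout$idx))), c(1L, 3L, 2L))
  dim(d_g) <- c(n, nrow(layout$idx) * layout$t_out)
  sums <- rowsum(t(d_g), layout$idx_vec)
  out <- matrix(0, n, flat_len + 1L)
  out[, as.integer(rownames(sums))] <- t(sums)
  out[, seq_len(flat_len), drop = FALSE]
}

#' Build an initialized backbone
#'
#' Weights use scaled (He-style) Gaussian initialization; initialization is
#' deterministic given `seed`. Teacher and student are built independently
#' (call twice; each call consumes the RNG stream or takes its own seed).
#'
#' @param cfg A [backbone_config()].
#' @param seed Integer seed for the weight draw; `NULL` uses the current RNG
#'   stream.
#' @return An object of class `cmpl_model`: parameters, config and the
#'   precomputed convolution layouts.
#' @export
build_model <- function(cfg = backbone_config(), seed = 1L) {
  if (!inherits(cfg, "backbone_config")) stopf("`cfg` must be a `backbone_config`.")
  with_seed_(seed, {
    init <- function(n_in, n_out) {
      matrix(stats::rnorm(n_in * n_out, 0, sqrt(2 / n_in)), n_in, n_out)
    }
    layouts <- NULL
    params <- list()
    if (cfg$preset == "linear") {
      params$W2 <- init(cfg$input_dim, cfg$feature_dim)
      params$b2 <- rep(0, cfg$feature_dim)
    } else {
      t_in <- cfg$input_dim %/% cfg$n_channels
      l1 <- conv_layout(t_in, cfg$n_channels, k = 7L, stride = 2L, pad = 0L)
      layouts <- list(conv1 = l1)
      params$Wc1 <- init(7L * cfg$n_channels, cfg$hidden_dim)
      params$bc1 <- rep(0, cfg$hidden_dim)
      if (cfg$n_blocks > 0L) {
        lb <- conv_layout(l1$t_out, cfg$hidden_dim, k = 5L, stride = 1L, pad = 2L)
        layouts$block <- lb
        for (i in seq_len(cfg$n_blocks)) {
          params[[paste0("Wb", i)]] <- init(5L * cfg$hidden_dim, cfg$hidden_dim) * 0.5
          params[[paste0("bb", i)]] <- rep(0, cfg$hidden_dim)
        }
      }
      # global average pooling as a fixed (t_out * hidden) x hidden matrix
      pool <- matrix(0, l1$t_out * cfg$hidden_dim, cfg$hidden_dim)
      for (hh in seq_len(cfg$hidden_dim)) {
        pool[(hh - 1L) * l1$t_out + seq_len(l1$t_out), hh] <- 1 / l1$t_out
      }
      layouts$pool <- pool
      params$W2 <- init(cfg$hidden_dim, cfg$feature_dim)
      params$b2 <- rep(0, cfg$feature_dim)
    }
    params$W3 <- init(cfg$feature_dim, cfg$n_classes)
    params$b3 <- rep(0, cfg$n_classes)
    structure(list(params = params, cfg = cfg, layouts = layouts),
              class = "cmpl_model")
  })
}

#' @export
print.cmpl_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf(
    "<cmpl_model> preset %s (%d residual block(s), %d filters), features %d, %d parameters\n",
    x$cfg$preset, x$cfg$n_blocks, x$cfg$hidden_dim, x$cfg$feature_dim, n_par
  ))
  invisible(x)
}

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Forward pass
#'
#' Computes the embedding `features` (phi(x)), class `logits` and softmax
#' `probabilities` for a batch of flattened windows (channel-major, the
#' `windows_matrix()` convention). With `keep_cache = TRUE` the intermediate
#' activations needed by the backward pass are retained.
#'
#' @param model A `cmpl_model`.
#' @param x An n x input_dim numeric matrix or a window-set tibble.
#' @param keep_cache Retain activations for the backward pass.
#' @return A list with `features` (n x feature_dim), `logits` and
#'   `probabilities` (n x n_classes), and optionally `cache`.
#' @export
model_forward <- function(model, x, keep_cache = FALSE) {
  if (is.data.frame(x)) x <- windows_matrix(x)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  p <- model$params
  cfg <- model$cfg
  if (ncol(x) != cfg$input_dim) {
    stopf("input has %d columns but the model expects %d.", ncol(x), cfg$input_dim)
  }
  n <- nrow(x)
  cache <- list(x = x)
  if (cfg$preset == "linear") {
    feats <- sweep(x %*% p$W2, 2L, p$b2, `+`)
    cache$pre_feat <- x
  } else {
    l1 <- model$layouts$conv1
    b1 <- conv_gather(x, l1)
    z1 <- sweep(b1 %*% p$Wc1, 2L, p$bc1, `+`)
    h1 <- pmax(z1, 0)
    flat <- matrix(as.vector(h1), n, l1$t_out * cfg$hidden_dim)
    cache$b1 <- b1
    cache$z1 <- z1
    if (cfg$n_blocks > 0L) {
      lb <- model$layouts$block
      cache$block_in <- vector("list", cfg$n_blocks)
      cache$block_b <- vector("list", cfg$n_blocks)
      cache$block_z <- vector("list", cfg$n_blocks)
      for (i in seq_len(cfg$n_blocks)) {
        cache$block_in[[i]] <- flat
        bb <- conv_gather(flat, lb)
        zb <- sweep(bb %*% p[[paste0("Wb", i)]], 2L, p[[paste0("bb", i)]], `+`)
        rb <- pmax(zb, 0)
        cache$block_b[[i]] <- bb
        cache$block_z[[i]] <- zb
        flat <- flat + matrix(as.vector(rb), n, ncol(flat))
      }
    }
    gap <- flat %*% model$layouts$pool
    feats <- sweep(gap %*% p$W2, 2L, p$b2, `+`)
    cache$flat <- flat
    cache$gap <- gap
    cache$pre_feat <- gap
  }
  logits <- sweep(feats %*% p$W3, 2L, p$b3, `+`)
  cache$features <- feats
  out <- list(features = feats, logits = logits,
              probabilities = softmax_rows(logits))
  if (keep_cache) out$cache <- cache
  out
}

# Backpropagate d(loss)/d(logits) and/or d(loss)/d(features); returns a
# gradient list shaped like model$params. Input gradients are not needed
# (inputs are data) and are not computed for the first convolution.
model_backward <- function(model, cache, d_logits = NULL, d_features = NULL) {
  p <- model$params
  cfg <- model$cfg
  n <- nrow(cache$x)
  g <- list()
  if (is.null(d_logits)) d_logits <- matrix(0, n, cfg$n_classes)
  g$W3 <- crossprod(cache$features, d_logits)
  g$b3 <- colSums(d_logits)
  d_feats <- d_logits %*% t(p$W3)
  if (!is.null(d_features)) d_feats <- d_feats + d_features
  g$W2 <- crossprod(cache$pre_feat, d_feats)
  g$b2 <- colSums(d_feats)
  if (cfg$preset == "linear") return(g[names(p)])

  d_flat <- (d_feats %*% t(p$W2)) %*% t(model$layouts$pool)
  if (cfg$n_blocks > 0L) {
    lb <- model$layouts$block
    for (i in rev(seq_len(cfg$n_blocks))) {
      d_rb <- matrix(as.vector(d_flat), n * lb$t_out, cfg$hidden_dim)
      d_zb <- d_rb * (cache$block_z[[i]] > 0)
      g[[paste0("Wb", i)]] <- crossprod(cache$block_b[[i]], d_zb)
      g[[paste0("bb", i)]] <- colSums(d_zb)
      d_patch <- d_zb %*% t(p[[paste0("Wb", i)]])
      d_flat <- d_flat + conv_scatter(d_patch, lb, n, ncol(d_flat))
    }
  }
  l1 <- model$layouts$conv1
  d_h1 <- matrix(as.vector(d_flat), n * l1$t_out, cfg$hidden_dim)
  d_z1 <- d_h1 * (cache$z1 > 0)
  g$Wc1 <- crossprod(cache$b1, d_z1)
  g$bc1 <- colSums(d_z1)
  g[names(p)]
}

# Forward-mode directional derivative of the logits along parameter
# direction v (a list shaped like model$params); needed for the exact
# soft-path MPL teacher gradient.
model_jvp <- function(model, cache, v) {
  p <- model$params
  cfg <- model$cfg
  n <- nrow(cache$x)
  if (cfg$preset == "linear") {
    d_feats <- sweep(cache$x %*% v$W2, 2L, v$b2, `+`)
  } else {
    l1 <- model$layouts$conv1
    d_z1 <- sweep(cache$b1 %*% v$Wc1, 2L, v$bc1, `+`)
    d_h1 <- d_z1 * (cache$z1 > 0)
    d_flat <- matrix(as.vector(d_h1), n, l1$t_out * cfg$hidden_dim)
    if (cfg$n_blocks > 0L) {
      lb <- model$layouts$block
      for (i in seq_len(cfg$n_blocks)) {
        d_bb <- conv_gather(d_flat, lb)
        d_zb <- d_bb %*% p[[paste0("Wb", i)]] +
          sweep(cache$block_b[[i]] %*% v[[paste0("Wb", i)]], 2L,
                v[[paste0("bb", i)]], `+`)
        d_rb <- d_zb * (cache$block_z[[i]] > 0)
        d_flat <- d_flat + matrix(as.vector(d_rb), n, ncol(d_flat))
      }
    }
    d_gap <- d_flat %*% model$layouts$pool
    d_feats <- d_gap %*% p$W2 + sweep(cache$gap %*% v$W2, 2L, v$b2, `+`)
  }
  d_feats %*% p$W3 + sweep(cache$features %*% v$W3, 2L, v$b3, `+`)
}

# One SGD step: params <- params - lr * grads.
sgd_step <- function(model, grads, lr) {
  model$params <- purrr::map2(model$params, grads[names(model$params)],
                              function(p, g) p - lr * g)
  model
}

onehot <- function(labels, n_classes = 6L) {
  y <- matrix(0, length(labels), n_classes)
  y[cbind(seq_along(labels), labels + 1L)] <- 1
  y
}

# Weighted mean cross-entropy from probabilities against a target matrix
# (rows summing to 1). Weights are renormalized over included rows.
ce_loss <- function(probs, targets, weights = NULL, eps = 1e-12) {
  rowwise <- -rowSums(targets * log(pmax(probs, eps)))
  if (is.null(weights)) return(mean(rowwise))
  if (sum(weights) == 0) return(0)
  sum(rowwise * weights) / sum(weights)
}

# d(ce_loss)/d(logits) for softmax + cross-entropy.
ce_dlogits <- function(probs, targets, weights = NULL) {
  n <- nrow(probs)
  if (is.null(weights)) return((probs - targets) / n)
  if (sum(weights) == 0) return(matrix(0, n, ncol(probs)))
  (probs - targets) * (weights / sum(weights))
}

# Convenience: loss and parameter gradients of weighted CE on a batch.
model_grad_ce <- function(model, x, targets, weights = NULL) {
  fw <- model_forward(model, x, keep_cache = TRUE)
  list(
    loss = ce_loss(fw$probabilities, targets, weights),
    grads = model_backward(model, fw$cache,
                           d_logits = ce_dlogits(fw$probabilities, targets, weights)),
    forward = fw
  )
}

#' Save and load a model checkpoint
#'
#' Checkpoints are plain JSON archives holding the backbone configuration,
#' all parameters, and (optionally) the embedding-cleaning state.
#'
#' @param model A `cmpl_model`.
#' @param file Path to the checkpoint file.
#' @param state Optional `embedding_state` stored alongside the parameters.
#' @return `save_checkpoint()` returns `file` invisibly; `load_checkpoint()`
#'   a list with `model` and `state` (possibly `NULL`).
#' @export
save_checkpoint <- function(model, file, state = NULL) {
  payload <- list(
    cfg = unclass(model$cfg),
    params = lapply(model$params, function(p) {
      if (is.matrix(p)) list(dim = dim(p), data = as.vector(p)) else list(dim = NULL, data = p)
    }),
    state = if (!is.null(state)) unclass(state)
  )
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(file) {
  payload <- jsonlite::read_json(file, simplifyVector = TRUE)
  cfg <- do.call(backbone_config, payload$cfg[c("input_layout", "preset", "feature_dim",
                                                "hidden_dim", "n_classes", "input_dim",
                                                "n_channels")])
  skeleton <- build_model(cfg, seed = 1L)
  params <- lapply(payload$params, function(p) {
    if (!is.null(p$dim) && length(p$dim) == 2L) {
      matrix(p$data, p$dim[1L], p$dim[2L])
    } else {
      as.numeric(p$data)
    }
  })
  skeleton$params <- params[names(skeleton$params)]
  state <- NULL
  if (!is.null(payload$state) && !is.null(payload$state$centroid)) {
    state <- embedding_state(
      centroid = payload$state$centroid, mu = payload$state$mu,
      sigma = payload$state$sigma, beta = payload$state$beta,
      step = payload$state$step
    )
  }
  list(model = skeleton, state = state)
}
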