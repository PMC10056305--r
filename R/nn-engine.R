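# Minimal CNN engine on base R matrices.
#
# Batches are matrices (h*w*c) x B with pixels vectorized column-major as
# array(h, w, c); convolutions run as im2col gathers followed by one BLAS
# GEMM per layer, the transposed path implements the backward pass, and
# max-pooling tracks argmax positions for gradient routing. All weights
# live in plain matrices so parameter enumeration is trivial.

init_model <- function(spec, seed = 0) {
  stopifnot(inherits(spec, "network_spec"))
  shapes <- propagate_shapes(spec)
  withr::with_seed(as.integer(seed), {
    layers <- vector("list", length(spec$layers))
    shape <- spec$input_shape
    for (i in seq_along(spec$layers)) {
      l <- spec$layers[[i]]
      rt <- l
      if (l$kind == "conv2d") {
        rt <- c(rt, conv_plan(shape, l))
        fan_in <- l$kernel^2 * l$in_channels
        rt$W <- matrix(stats::rnorm(l$out_channels * fan_in,
                                    sd = sqrt(2 / fan_in)),
                       l$out_channels, fan_in)
        rt$b <- numeric(l$out_channels)
      } else if (l$kind == "maxpool2d") {
        rt <- c(rt, pool_plan(shape, l))
      } else if (l$kind == "fully_connected") {
        rt$W <- matrix(stats::rnorm(l$out_channels * l$in_channels,
                                    sd = sqrt(2 / l$in_channels)),
                       l$out_channels, l$in_channels)
        rt$b <- numeric(l$out_channels)
      }
      layers[[i]] <- rt
      shape <- shapes[[i]]
    }
    structure(list(spec = spec, layers = layers), class = "cnn_model")
  })
}

# Precomputed gather indices for a conv layer given its input shape.
conv_plan <- function(shape, l) {
  h <- shape[1]; w <- shape[2]; ch <- shape[3]
  k <- l$kernel; p <- l$padding; s <- l$stride
  ph <- h + 2 * p; pw <- w + 2 * p
  oh <- conv_output_size(h, k, p, s)
  ow <- conv_output_size(w, k, p, s)
  # original pixel -> position inside the zero-padded plane stack
  ci <- rep(seq_len(ch) - 1L, each = h * w)
  wi <- rep(rep(seq_len(w) - 1L, each = h), times = ch)
  hi <- rep(seq_len(h), times = w * ch)
  pos_in_pad <- ci * ph * pw + (wi + p) * ph + (hi + p)
  # im2col rows ordered (ki, kj, channel); columns ordered (oi, oj)
  ki <- rep(seq_len(k), times = k * ch)
  kj <- rep(rep(seq_len(k), each = k), times = ch)
  kc <- rep(seq_len(ch) - 1L, each = k * k)
  oi <- rep(seq_len(oh), times = ow)
  oj <- rep(seq_len(ow), each = oh)
  row_base <- kc * ph * pw + (kj - 1L) * ph + ki        # length k*k*ch
  col_base <- (s * (oj - 1L)) * ph + s * (oi - 1L)      # length oh*ow
  idx <- outer(row_base, col_base, `+`)
  storage.mode(idx) <- "integer"
  list(oh = oh, ow = ow, in_h = h, in_w = w, in_c = ch,
       pad_n = ph * pw * ch, pos_in_pad = as.integer(pos_in_pad), idx = idx)
}

pool_plan <- function(shape, l) {
  h <- shape[1]; w <- shape[2]; ch <- shape[3]
  k <- l$kernel; s <- l$stride
  oh <- conv_output_size(h, k, 0, s)
  ow <- conv_output_size(w, k, 0, s)
  ki <- rep(seq_len(k), times = k)
  kj <- rep(seq_len(k), each = k)
  oi <- rep(seq_len(oh), times = ow)
  oj <- rep(seq_len(ow), each = oh)
  row_base <- (kj - 1L) * h + ki
  col_base <- (s * (oj - 1L)) * h + s * (oi - 1L)
  idx <- outer(row_base, col_base, `+`)   # (k*k) x (oh*ow), per channel plane
  storage.mode(idx) <- "integer"
  list(oh = oh, ow = ow, in_h = h, in_w = w, in_c = ch, idx = idx)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

conv_forward <- function(rt, x) {
  bsz <- ncol(x)
  k2c <- nrow(rt$idx); ohow <- ncol(rt$idx)
  xp <- matrix(0, rt$pad_n, bsz)
  xp[rt$pos_in_pad, ] <- x
  m <- xp[as.vector(rt$idx), , drop = FALSE]
  dim(m) <- c(k2c, ohow * bsz)
  y <- rt$W %*% m + rt$b
  pre <- y
  if (identical(rt$activation, "relu")) y <- relu(y)
  dim(y) <- c(rt$out_channels, ohow, bsz)
  ya <- aperm(y, c(2, 1, 3))
  dim(ya) <- c(ohow * rt$out_channels, bsz)
  list(out = ya, cache = list(m = m, pre = pre, bsz = bsz))
}

conv_backward <- function(rt, cache, dout) {
  bsz <- cache$bsz
  k2c <- nrow(rt$idx); ohow <- ncol(rt$idx)
  dim(dout) <- c(ohow, rt$out_channels, bsz)
  dy <- aperm(dout, c(2, 1, 3))
  dim(dy) <- c(rt$out_channels, ohow * bsz)
  if (identical(rt$activation, "relu")) dy[cache$pre <= 0] <- 0
  dW <- tcrossprod(dy, cache$m)
  db <- rowSums(dy)
  dm <- crossprod(rt$W, dy)
  dim(dm) <- c(k2c, ohow, bsz)
  dxp <- matrix(0, rt$pad_n, bsz)
  for (j in seq_len(k2c)) {
    tgt <- rt$idx[j, ]
    slice <- dm[j, , ]
    dim(slice) <- c(ohow, bsz)
    dxp[tgt, ] <- dxp[tgt, ] + slice
  }
  list(dx = dxp[rt$pos_in_pad, , drop = FALSE], dW = dW, db = db)
}

pool_forward <- function(rt, x) {
  bsz <- ncol(x)
  hw <- rt$in_h * rt$in_w
  xm <- matrix(x, hw, rt$in_c * bsz)
  k2 <- nrow(rt$idx); ohow <- ncol(rt$idx)
  best <- xm[rt$idx[1, ], , drop = FALSE]
  arg <- matrix(1L, ohow, ncol(best))
  if (k2 > 1) {
    for (j in 2:k2) {
      cand <- xm[rt$idx[j, ], , drop = FALSE]
      upd <- cand > best
      best[upd] <- cand[upd]
      arg[upd] <- j
    }
  }
  dim(best) <- c(ohow * rt$in_c, bsz)
  list(out = best, cache = list(arg = arg, bsz = bsz))
}

pool_backward <- function(rt, cache, dout) {
  bsz <- cache$bsz
  hw <- rt$in_h * rt$in_w
  ohow <- ncol(rt$idx)
  dm <- dout
  dim(dm) <- c(ohow, rt$in_c * bsz)
  dxm <- matrix(0, hw, rt$in_c * bsz)
  for (j in seq_len(nrow(rt$idx))) {
    sel <- cache$arg == j
    if (!any(sel)) next
    contrib <- dm * sel
    tgt <- rt$idx[j, ]
    dxm[tgt, ] <- dxm[tgt, ] + contrib
  }
  dim(dxm) <- c(hw * rt$in_c, bsz)
  list(dx = dxm)
}

#' @keywords internal
forward_pass <- function(model, x, training = FALSE) {
  caches <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    if (l$kind == "conv2d") {
      fw <- conv_forward(l, x)
      x <- fw$out; caches[[i]] <- fw$cache
    } else if (l$kind == "maxpool2d") {
      fw <- pool_forward(l, x)
      x <- fw$out; caches[[i]] <- fw$cache
    } else if (l$kind == "flatten") {
      # layout already flat column-major; nothing to do
    } else if (l$kind == "fully_connected") {
      pre <- l$W %*% x + l$b
      act <- if (identical(l$activation, "relu")) relu(pre) else pre
      caches[[i]] <- list(x = x, pre = pre)
      x <- act
    } else if (l$kind == "dropout") {
      if (training) {
        mask <- matrix(stats::runif(length(x)) >= l$p, nrow(x), ncol(x)) /
          (1 - l$p)
        caches[[i]] <- list(mask = mask)
        x <- x * mask
      }
    }
  }
  list(out = x, caches = caches)
}

backward_pass <- function(model, caches, dout) {
  grads <- vector("list", length(model$layers))
  for (i in rev(seq_along(model$layers))) {
    l <- model$layers[[i]]
    if (l$kind == "conv2d") {
      bw <- conv_backward(l, caches[[i]], dout)
      grads[[i]] <- list(dW = bw$dW, db = bw$db)
      dout <- bw$dx
    } else if (l$kind == "maxpool2d") {
      dout <- pool_backward(l, caches[[i]], dout)$dx
    } else if (l$kind == "fully_connected") {
      if (identical(l$activation, "relu")) dout[caches[[i]]$pre <= 0] <- 0
      grads[[i]] <- list(dW = tcrossprod(dout, caches[[i]]$x),
                         db = rowSums(dout))
      dout <- crossprod(l$W, dout)
    } else if (l$kind == "dropout") {
      if (!is.null(caches[[i]])) dout <- dout * caches[[i]]$mask
    }
  }
  grads
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# cross-entropy gradient wrt logits, averaged over the batch
ce_grad <- function(logits, labels) {
  p <- softmax_cols(logits)
  p[cbind(labels, seq_along(labels))] <-
    p[cbind(labels, seq_along(labels))] - 1
  p / length(labels)
}

adam_init <- function(model) {
  purrr::map(model$layers, function(l) {
    if (!is.null(l$W)) {
      list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
    } else NULL
  })
}

# Bias-corrected Adam, fused and in place (C kernel): mutates the model's
# weight buffers and the optimizer state by reference, so the caller keeps
# using the same model object.
adam_step <- function(model, grads, state, t, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  a <- lr * sqrt(c2) / c1
  b <- eps * sqrt(c2)
  for (i in seq_along(model$layers)) {
    if (is.null(state[[i]])) next
    g <- grads[[i]]
    s <- state[[i]]
    .Call(C_adam_fused, model$layers[[i]]$W, s$mW, s$vW, g$dW,
          beta1, beta2, a, b)
    .Call(C_adam_fused, model$layers[[i]]$b, s$mb, s$vb, g$db,
          beta1, beta2, a, b)
  }
  invisible(NULL)
}

#' Class probabilities for a batch of portraits
#'
#' @param model A `cnn_model` (from [train_model()]'s `$model` or
#'   [instantiate_network()]).
#' @param x Matrix of vectorized images, one column per portrait, or a
#'   list of `phase_portrait` objects.
#' @return Matrix `num_classes x B` of softmax probabilities (columns sum
#'   to 1).
#' @export
predict_proba <- function(model, x) {
  stopifnot(inherits(model, "cnn_model"))
  if (is.list(x) && !is.matrix(x)) x <- portraits_to_matrix(x)
  softmax_cols(forward_pass(model, x, training = FALSE)$out)
}

#' Instantiate a network with random weights
#'
#' Builds a runnable model from a specification using fan-in-scaled
#' Gaussian initialization under the given seed.
#'
#' @param spec A `network_spec`.
#' @param seed Integer seed for the weight draw.
#' @return A `cnn_model`.
#' @export
instantiate_network <- function(spec, seed = 0) init_model(spec, seed)

#' Enumerate the weight tensors of an instantiated model
#'
#' @param model A `cnn_model`.
#' @return Tibble with one row per tensor: `layer`, `kind`, `tensor`
#'   (`"W"` or `"b"`), `n_params`.
#' @export
model_tensors <- function(model) {
  stopifnot(inherits(model, "cnn_model"))
  rows <- purrr::imap(model$layers, function(l, i) {
    if (is.null(l$W)) return(NULL)
    tibble::tibble(layer = i, kind = l$kind, tensor = c("W", "b"),
                   n_params = c(length(l$W), length(l$b)))
  })
  dplyr::bind_rows(rows)
}

# stack portraits' images into the engine's column layout
portraits_to_matrix <- function(portraits) {
  mats <- purrr::map(portraits, function(p) {
    img <- if (inherits(p, "phase_portrait")) p$image else p
    # matrix is already array(h, w); column-major vectorization matches the
    # engine's (h, w, c) layout for single-channel input
    as.numeric(img)
  })
  do.call(cbind, mats)
}
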