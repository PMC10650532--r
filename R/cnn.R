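# Compact convolutional network built from the pipeline's layer
# operators: cross-correlation convolution, max pooling, elementwise
# activation, one fully connected softmax stage. Implemented with
# vectorized im2col gathers and base matrix multiplication; gradients are
# hand-derived. Exact arithmetic parity with nested-loop definitions is
# what the unit oracles check.

#' Convolutional layer specification
#'
#' @param kernel_size Odd kernel side in pixels (>= 1).
#' @param n_kernels Number of kernels (output feature maps).
#' @param stride Step in pixels (>= 1).
#' @param padding `"valid"` (no padding) or `"same"` (zero-pad so that a
#'   stride-1 convolution preserves the spatial size).
#' @return A `conv_layer_spec`.
#' @export
conv_layer_spec <- function(kernel_size, n_kernels, stride = 1L,
                            padding = c("valid", "same")) {
  assert_scalar_number(kernel_size, "kernel_size", 1)
  assert_scalar_number(n_kernels, "n_kernels", 1)
  assert_scalar_number(stride, "stride", 1)
  padding <- match.arg(padding)
  if (padding == "same" && kernel_size %% 2 == 0) {
    stop("`kernel_size` must be odd for 'same' padding", call. = FALSE)
  }
  structure(list(kernel_size = as.integer(kernel_size),
                 n_kernels = as.integer(n_kernels),
                 stride = as.integer(stride),
                 padding = padding),
            class = "conv_layer_spec")
}

# Coerce input to a (H, W, C, B) array.
as_nhwc <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("conv input must be a matrix or array", call. = FALSE)
  if (length(d) == 2L) {
    dim(x) <- c(d, 1L, 1L)
  } else if (length(d) == 3L) {
    dim(x) <- c(d, 1L)
  } else if (length(d) != 4L) {
    stop("conv input must have 2, 3 or 4 dimensions", call. = FALSE)
  }
  x
}

pad_input <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  xp
}

# Gather plan for im2col on a padded (Hp, Wp, C) image: idx[p, j] is the
# linear index of kernel element j for output cell p (output cells
# enumerated row-fastest).
conv_plan <- function(hp, wp, n_channels, k, stride) {
  h2 <- (hp - k) %/% stride + 1L
  w2 <- (wp - k) %/% stride + 1L
  if (h2 < 1L || w2 < 1L) {
    stop("kernel does not fit the input (", hp, "x", wp, ")", call. = FALSE)
  }
  p_rows <- rep((seq_len(h2) - 1L) * stride, times = w2)
  p_cols <- rep((seq_len(w2) - 1L) * stride, each = h2)
  npix_plane <- hp * wp
  cols <- vector("list", k * k * n_channels)
  j <- 0L
  for (cc in seq_len(n_channels)) {
    for (kj in seq_len(k)) {
      for (ki in seq_len(k)) {
        j <- j + 1L
        cols[[j]] <- (p_rows + ki) + (p_cols + kj - 1L) * hp +
          (cc - 1L) * npix_plane
      }
    }
  }
  # column order must be (ki, kj, c) fastest-to-slowest to match the
  # memory layout of a (k, k, C, F) weight array flattened to a matrix
  idx <- matrix(unlist(cols, use.names = FALSE), ncol = k * k * n_channels)
  list(idx = idx, h2 = h2, w2 = w2, hp = hp, wp = wp)
}

#' Convolution (cross-correlation) forward pass
#'
#' Computes `f[p, q, f] = sum_c sum_{ki, kj} x[(p-1)s + ki, (q-1)s + kj, c]
#' * w[ki, kj, c, f] + b[f]`: the kernel is slid without flipping, i.e.
#' the multiplication is a correlation.
#'
#' @param input Matrix (H x W), array (H x W x C), or batch array
#'   (H x W x C x B).
#' @param layer A [conv_layer_spec()].
#' @param weights Array of dimension `(kernel, kernel, C, n_kernels)`.
#' @param bias Numeric vector of length `n_kernels` (default zeros).
#' @return Array `(H' x W' x n_kernels)` (or `... x B` for batch input).
#' @export
conv2d_forward <- function(input, layer, weights, bias = NULL) {
  stopifnot(inherits(layer, "conv_layer_spec"))
  x <- as_nhwc(input)
  d <- dim(x)
  k <- layer$kernel_size
  wd <- dim(weights)
  if (length(wd) == 2L) dim(weights) <- wd <- c(wd, 1L, 1L)
  if (length(wd) == 3L) dim(weights) <- wd <- c(wd, 1L)
  if (wd[1] != k || wd[2] != k || wd[3] != d[3]) {
    stop("weight dimensions ", paste(wd, collapse = "x"),
         " incompatible with kernel ", k, " and input channels ", d[3],
         call. = FALSE)
  }
  bias <- bias %||% numeric(wd[4])
  pad <- if (layer$padding == "same") (k - 1L) %/% 2L else 0L
  xp <- pad_input(x, pad)
  plan <- conv_plan(dim(xp)[1], dim(xp)[2], d[3], k, layer$stride)
  out <- conv_apply(xp, plan, matrix(weights, ncol = wd[4]), bias)$out
  drop_batchless(out, input)
}

# Replicate a single-image gather plan across a batch of B images,
# returned as a plain index vector (column-major over kernel elements) so
# array indexing stays linear, never coordinate-style.
make_big_idx <- function(plan, n_channels, B) {
  P <- plan$h2 * plan$w2
  npix <- plan$hp * plan$wp * n_channels
  m <- plan$idx[rep(seq_len(P), B), , drop = FALSE] +
    rep((seq_len(B) - 1L) * npix, each = P)
  dim(m) <- NULL
  m
}

# Shared forward machinery: gather + matmul. Returns out (H2, W2, F, B)
# plus the column matrix for reuse in backprop.
conv_apply <- function(xp, plan, w_mat, bias, big_idx = NULL) {
  d <- dim(xp)
  B <- d[4]
  P <- plan$h2 * plan$w2
  if (is.null(big_idx)) big_idx <- make_big_idx(plan, d[3], B)
  col <- xp[big_idx]
  dim(col) <- c(P * B, length(col) %/% (P * B))
  out <- col %*% w_mat
  if (any(bias != 0)) out <- sweep(out, 2L, bias, "+")
  dim(out) <- c(plan$h2, plan$w2, B, ncol(w_mat))
  list(out = aperm(out, c(1L, 2L, 4L, 3L)), col = col, big_idx = big_idx)
}

# Gradients of a stride-1 valid cross-correlation. The input gradient is
# itself a valid cross-correlation: dOut zero-padded by k-1 against the
# spatially flipped kernels with in/out channels swapped, which keeps the
# heavy lifting inside BLAS.
conv_backward <- function(dout, cache, plan_cache = NULL) {
  B <- dim(dout)[4]
  P <- dim(dout)[1] * dim(dout)[2]
  dmat <- aperm(dout, c(1L, 2L, 4L, 3L))
  dim(dmat) <- c(P * B, dim(dout)[3])
  dw <- crossprod(cache$col, dmat)
  db <- colSums(dmat)
  dxp <- NULL
  if (isTRUE(cache$need_dx)) {
    k <- cache$k
    w_arr <- array(cache$w_mat, c(k, k, cache$in_channels, ncol(cache$w_mat)))
    w_back <- aperm(w_arr[k:1, k:1, , , drop = FALSE], c(1L, 2L, 4L, 3L))
    dpad <- pad_input(dout, k - 1L)
    dp <- dim(dpad)
    key <- paste0("bw", dp[1], "x", dp[3], "x", B)
    plan <- if (!is.null(plan_cache) && !is.null(plan_cache[[key]])) {
      plan_cache[[key]]
    } else {
      pl <- conv_plan(dp[1], dp[2], dp[3], k, 1L)
      pl$big_idx <- make_big_idx(pl, dp[3], B)
      if (!is.null(plan_cache)) plan_cache[[key]] <- pl
      pl
    }
    dxp <- conv_apply(dpad, plan,
                      matrix(w_back, ncol = cache$in_channels),
                      numeric(cache$in_channels), plan$big_idx)$out
  }
  list(dw = dw, db = db, dxp = dxp)
}

drop_batchless <- function(out, original_input) {
  d <- dim(original_input)
  if (is.null(d) || length(d) == 2L) {
    out[, , , 1, drop = TRUE]
  } else if (length(d) == 3L) {
    array(out, dim(out)[1:3])
  } else {
    out
  }
}

#' Max pooling (downsampling)
#'
#' Each output cell is the maximum over its `window x window` receptive
#' field.
#'
#' @param input Matrix, 3D array, or batch array as in [conv2d_forward()].
#' @param window Pooling window side (>= 1, at most the input side).
#' @param stride Step between windows; defaults to `window`
#'   (non-overlapping).
#' @return Pooled array with the same trailing dimensions as the input.
#' @export
max_pool <- function(input, window, stride = window) {
  assert_scalar_number(window, "window", 1)
  assert_scalar_number(stride, "stride", 1)
  x <- as_nhwc(input)
  d <- dim(x)
  if (window > d[1] || window > d[2]) {
    stop("pooling window larger than input", call. = FALSE)
  }
  drop_batchless(pool_forward(x, as.integer(window), as.integer(stride))$out,
                 input)
}

pool_forward <- function(x, window, stride) {
  d <- dim(x)
  h2 <- (d[1] - window) %/% stride + 1L
  w2 <- (d[2] - window) %/% stride + 1L
  n_cells <- h2 * w2 * d[3] * d[4]
  # linear index of each output cell's top-left corner in x
  r0 <- rep((seq_len(h2) - 1L) * stride, times = w2)
  c0 <- rep((seq_len(w2) - 1L) * stride, each = h2)
  base <- rep(r0 + c0 * d[1], times = d[3] * d[4]) +
    rep((seq_len(d[3] * d[4]) - 1L) * (d[1] * d[2]), each = h2 * w2)
  cand <- matrix(0, n_cells, window * window)
  off <- 0L
  for (kj in seq_len(window)) {
    for (ki in seq_len(window)) {
      off <- off + 1L
      cand[, off] <- x[base + ki + (kj - 1L) * d[1]]
    }
  }
  arg <- max.col(cand, ties.method = "first")
  out <- array(cand[cbind(seq_len(n_cells), arg)], c(h2, w2, d[3], d[4]))
  ki <- (arg - 1L) %% window + 1L
  kj <- (arg - 1L) %/% window + 1L
  list(out = out, arg_lin = base + ki + (kj - 1L) * d[1],
       in_dim = d, window = window, stride = stride)
}

pool_backward <- function(dout, cache) {
  dx_v <- numeric(prod(cache$in_dim))
  if (cache$stride >= cache$window) {
    # receptive fields are disjoint: each input position wins at most once
    dx_v[cache$arg_lin] <- as.vector(dout)
  } else {
    agg <- rowsum(as.vector(dout), cache$arg_lin)
    dx_v[as.integer(rownames(agg))] <- agg
  }
  array(dx_v, cache$in_dim)
}

#' Elementwise activation
#'
#' @param input Numeric vector, matrix or array.
#' @param kind `"relu"` (`max(0, x)`), `"sigmoid"` or `"tanh"`.
#' @return Activated values, same shape.
#' @export
activate <- function(input, kind = c("relu", "sigmoid", "tanh")) {
  kind <- match.arg(kind)
  switch(kind,
         relu = pmax(input, 0),
         sigmoid = 1 / (1 + exp(-input)),
         tanh = tanh(input))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Build a compact CNN
#'
#' Default architecture: two convolution/ReLU/max-pool blocks (5x5x8 and
#' 3x3x16 kernels, 2x2 pooling) followed by a single fully connected
#' softmax stage -- small enough to train on a CPU in seconds while
#' retaining the conv/pool/activation/FC structure of the larger image
#' backbones.
#'
#' @param input_side Image side N accepted by the model.
#' @param n_classes 2 (normal vs seizure) or 3 (adds preictal).
#' @param conv_specs List of [conv_layer_spec()] objects.
#' @param pool_window Pooling window applied after each conv block.
#' @param seed Seed for weight initialization (He-scaled normal).
#' @return A `cnn_model`.
#' @export
compact_cnn <- function(input_side, n_classes = 3L,
                        conv_specs = list(conv_layer_spec(5L, 8L),
                                          conv_layer_spec(3L, 16L)),
                        pool_window = 2L, seed = 1L) {
  assert_scalar_number(input_side, "input_side", 8)
  if (!n_classes %in% c(2L, 3L)) stop("`n_classes` must be 2 or 3", call. = FALSE)
  with_local_seed(seed, {
    side <- as.integer(input_side)
    in_ch <- 1L
    stages <- vector("list", length(conv_specs))
    for (i in seq_along(conv_specs)) {
      sp <- conv_specs[[i]]
      stopifnot(inherits(sp, "conv_layer_spec"))
      k <- sp$kernel_size
      w <- array(stats::rnorm(k * k * in_ch * sp$n_kernels,
                              sd = sqrt(2 / (k * k * in_ch))),
                 c(k, k, in_ch, sp$n_kernels))
      stages[[i]] <- list(spec = sp, w = w, b = numeric(sp$n_kernels))
      side <- if (sp$padding == "same") {
        (side - 1L) %/% sp$stride + 1L
      } else {
        (side - k) %/% sp$stride + 1L
      }
      side <- (side - pool_window) %/% pool_window + 1L
      if (side < 1L) stop("architecture collapses below 1 pixel", call. = FALSE)
      in_ch <- sp$n_kernels
    }
    d_flat <- side * side * in_ch
    fc <- list(w = matrix(stats::rnorm(d_flat * n_classes,
                                       sd = sqrt(2 / d_flat)),
                          d_flat, n_classes),
               b = numeric(n_classes))
    structure(
      list(input_side = as.integer(input_side), n_classes = as.integer(n_classes),
           stages = stages, pool_window = as.integer(pool_window), fc = fc,
           classes = NULL),
      class = "cnn_model"
    )
  })
}

#' @export
print.cnn_model <- function(x, ...) {
  convs <- vapply(x$stages, function(s)
    sprintf("%dx%dx%d", s$spec$kernel_size, s$spec$kernel_size,
            s$spec$n_kernels), character(1))
  cat(sprintf("<cnn_model> input %dx%d, conv blocks [%s], %d classes\n",
              x$input_side, x$input_side, paste(convs, collapse = ", "),
              x$n_classes))
  invisible(x)
}

# Coerce a list of spectrogram images / matrices, or a 3D array, into the
# (side, side, 1, B) batch array expected by the network, scaled to [0, 1].
images_to_batch <- function(images, input_side) {
  mats <- if (is.array(images) && length(dim(images)) == 3L) {
    lapply(seq_len(dim(images)[3]), function(i) images[, , i])
  } else if (is.list(images)) {
    lapply(images, function(im) {
      if (inherits(im, "spectrogram_image")) im$pixels else im
    })
  } else if (is.matrix(images)) {
    list(images)
  } else {
    stop("unsupported image container", call. = FALSE)
  }
  B <- length(mats)
  xb <- array(0, c(input_side, input_side, 1L, B))
  for (i in seq_len(B)) {
    m <- mats[[i]]
    if (nrow(m) != input_side || ncol(m) != input_side) {
      stop("image side ", nrow(m), "x", ncol(m),
           " does not match model input side ", input_side, call. = FALSE)
    }
    xb[, , 1L, i] <- m / 255
  }
  xb
}

# Full forward pass; optionally keeps caches for backprop. `plan_cache`
# (an environment) memoizes gather indices across minibatches.
cnn_batch_forward <- function(model, xb, keep_caches = FALSE,
                              plan_cache = NULL) {
  caches <- if (keep_caches) vector("list", length(model$stages))
  x <- xb
  for (i in seq_along(model$stages)) {
    st <- model$stages[[i]]
    sp <- st$spec
    k <- sp$kernel_size
    pad <- if (sp$padding == "same") (k - 1L) %/% 2L else 0L
    xp <- pad_input(x, pad)
    dpx <- dim(xp)
    key <- paste0("fw", i, "x", dpx[4])
    plan <- if (!is.null(plan_cache) && !is.null(plan_cache[[key]])) {
      plan_cache[[key]]
    } else {
      pl <- conv_plan(dpx[1], dpx[2], dpx[3], k, sp$stride)
      pl$big_idx <- make_big_idx(pl, dpx[3], dpx[4])
      if (!is.null(plan_cache)) plan_cache[[key]] <- pl
      pl
    }
    w_mat <- matrix(st$w, ncol = sp$n_kernels)
    cv <- conv_apply(xp, plan, w_mat, st$b, plan$big_idx)
    a <- pmax(cv$out, 0)
    pl <- pool_forward(a, model$pool_window, model$pool_window)
    if (keep_caches) {
      caches[[i]] <- list(col = cv$col, w_mat = w_mat,
                          k = k, in_channels = dpx[3],
                          need_dx = i > 1L && sp$stride == 1L,
                          pre_act = cv$out, pool = pl, pad = pad,
                          in_dim = dim(x))
    }
    x <- pl$out
  }
  B <- dim(x)[4]
  flat <- t(matrix(x, ncol = B))        # B x D
  logits <- sweep(flat %*% model$fc$w, 2L, model$fc$b, "+")
  probs <- softmax_rows(logits)
  list(probs = probs, flat = flat, caches = caches, top_dim = dim(x))
}

#' Class probabilities for one image or a batch
#'
#' @param model A trained or freshly built `cnn_model`.
#' @param images A `spectrogram_image`, pixel matrix, list of either, or
#'   a `side x side x B` array.
#' @return A `B x n_classes` matrix of softmax probabilities (rows sum to
#'   1); column names are class labels when the model has been trained.
#' @export
cnn_forward <- function(model, images) {
  stopifnot(inherits(model, "cnn_model"))
  xb <- images_to_batch(images, model$input_side)
  probs <- cnn_batch_forward(model, xb)$probs
  if (!is.null(model$classes)) colnames(probs) <- model$classes
  probs
}

#' Train a compact CNN with minibatch gradient descent
#'
#' Cross-entropy loss, plain SGD with a fixed learning rate, seeded
#' shuffling -- fully reproducible given `seed`.
#'
#' @param model A `cnn_model` from [compact_cnn()].
#' @param images Training images (see [cnn_forward()]).
#' @param labels Factor or character vector of class labels (>= 2 classes
#'   must be present).
#' @param epochs Number of passes over the data.
#' @param batch_size Minibatch size.
#' @param lr Learning rate (0 leaves the weights untouched).
#' @param momentum Classical momentum coefficient in [0, 1).
#' @param class_weights `"balanced"` to weight each sample inversely to
#'   its class frequency (mean weight 1), `"uniform"` for none, or a
#'   named numeric vector of per-class weights.
#' @param seed RNG seed for shuffling.
#' @return A list with `model` (trained) and `history` (data frame with
#'   per-epoch `epoch`, `loss`, `accuracy`).
#' @export
cnn_train <- function(model, images, labels, epochs = 10L, batch_size = 32L,
                      lr = 0.02, momentum = 0.9,
                      class_weights = c("uniform", "balanced"), seed = 1L) {
  stopifnot(inherits(model, "cnn_model"))
  labels <- as.factor(labels)
  classes <- levels(droplevels(labels))
  if (length(classes) < 2L) {
    stop("training requires at least 2 classes present", call. = FALSE)
  }
  if (length(classes) != model$n_classes) {
    stop("model expects ", model$n_classes, " classes but data has ",
         length(classes), call. = FALSE)
  }
  xb_all <- images_to_batch(images, model$input_side)
  plan_cache <- new.env(parent = emptyenv())
  n <- dim(xb_all)[4]
  if (n == 0L) stop("empty training set", call. = FALSE)
  if (length(labels) != n) stop("labels/images length mismatch", call. = FALSE)
  y_idx <- match(as.character(labels), classes)
  if (is.character(class_weights)) {
    class_weights <- match.arg(class_weights)
    cw <- if (class_weights == "balanced") {
      w <- n / (length(classes) * tabulate(y_idx, length(classes)))
      w / mean(w[y_idx])
    } else {
      rep(1, length(classes))
    }
  } else {
    if (is.null(names(class_weights)) ||
        !all(classes %in% names(class_weights))) {
      stop("numeric `class_weights` must be named by class", call. = FALSE)
    }
    cw <- unname(class_weights[classes])
    cw <- cw / mean(cw[y_idx])
  }
  sample_w <- cw[y_idx]
  model$classes <- classes
  vel <- list(fc_w = 0 * model$fc$w, fc_b = 0 * model$fc$b,
              w = lapply(model$stages, function(s) 0 * s$w),
              b = lapply(model$stages, function(s) 0 * s$b))

  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        accuracy = numeric(0))
  with_local_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      ep_correct <- 0L
      for (start in seq(1L, n, by = batch_size)) {
        sel <- ord[start:min(start + batch_size - 1L, n)]
        xb <- xb_all[, , , sel, drop = FALSE]
        yb <- y_idx[sel]
        fw <- cnn_batch_forward(model, xb, keep_caches = TRUE,
                                plan_cache = plan_cache)
        B <- length(sel)
        p_true <- fw$probs[cbind(seq_len(B), yb)]
        ep_loss <- ep_loss - sum(log(pmax(p_true, 1e-12)))
        ep_correct <- ep_correct + sum(max.col(fw$probs, ties.method = "first") == yb)
        if (lr > 0) {
          dz <- fw$probs
          dz[cbind(seq_len(B), yb)] <- dz[cbind(seq_len(B), yb)] - 1
          dz <- dz * (sample_w[sel] / B)
          dfc_w <- crossprod(fw$flat, dz)
          dfc_b <- colSums(dz)
          dflat <- tcrossprod(dz, model$fc$w)   # B x D
          dx <- array(t(dflat), fw$top_dim)
          for (i in rev(seq_along(model$stages))) {
            ca <- fw$caches[[i]]
            dact <- pool_backward(dx, ca$pool)
            dact[ca$pre_act <= 0] <- 0
            gr <- conv_backward(dact, ca, plan_cache)
            st <- model$stages[[i]]
            vel$w[[i]] <- momentum * vel$w[[i]] + array(gr$dw, dim(st$w))
            vel$b[[i]] <- momentum * vel$b[[i]] + gr$db
            model$stages[[i]]$w <- st$w - lr * vel$w[[i]]
            model$stages[[i]]$b <- st$b - lr * vel$b[[i]]
            if (i > 1L) {
              dxp <- gr$dxp
              if (ca$pad > 0L) {
                h <- ca$in_dim[1]; w <- ca$in_dim[2]
                dxp <- dxp[ca$pad + seq_len(h), ca$pad + seq_len(w), , ,
                           drop = FALSE]
              }
              dx <- dxp
            }
          }
          vel$fc_w <- momentum * vel$fc_w + dfc_w
          vel$fc_b <- momentum * vel$fc_b + dfc_b
          model$fc$w <- model$fc$w - lr * vel$fc_w
          model$fc$b <- model$fc$b - lr * vel$fc_b
        }
      }
      history <- rbind(history,
                       data.frame(epoch = ep, loss = ep_loss / n,
                                  accuracy = ep_correct / n))
    }
  })
  list(model = model, history = history)
}

#' Ensemble fusion parameters
#'
#' @param weights Per-member soft-voting weights, each in \[0, 1\], at
#'   least one positive; they need not sum to one (fusion renormalizes).
#' @param selected_features Optional logical mask over feature indices
#'   (at least one `TRUE`); defaults to all members selected.
#' @return A `fusion_params`.
#' @export
fusion_params <- function(weights, selected_features = NULL) {
  if (!is.numeric(weights) || length(weights) < 1L ||
      any(weights < 0 | weights > 1)) {
    stop("`weights` must lie in [0, 1]", call. = FALSE)
  }
  if (all(weights == 0)) stop("at least one weight must be > 0", call. = FALSE)
  selected_features <- selected_features %||% rep(TRUE, length(weights))
  if (!is.logical(selected_features) || !any(selected_features)) {
    stop("`selected_features` must be a logical mask with at least one TRUE",
         call. = FALSE)
  }
  structure(list(weights = weights, selected_features = selected_features),
            class = "fusion_params")
}

#' Fuse ensemble members' class probabilities by weighted soft voting
#'
#' @param member_probs List of probability matrices (or vectors), one per
#'   member, identical dimensions.
#' @param params A [fusion_params()] with one weight per member.
#' @return Fused probability matrix, rows renormalized to sum to 1.
#' @export
ensemble_fuse <- function(member_probs, params) {
  stopifnot(inherits(params, "fusion_params"))
  if (length(member_probs) != length(params$weights)) {
    stop("need exactly one weight per ensemble member", call. = FALSE)
  }
  mats <- lapply(member_probs, function(p) {
    if (is.null(dim(p))) matrix(p, nrow = 1L) else as.matrix(p)
  })
  d1 <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) all(dim(m) == d1), logical(1)))) {
    stop("all members must output the same class count", call. = FALSE)
  }
  acc <- matrix(0, d1[1], d1[2])
  for (i in seq_along(mats)) acc <- acc + params$weights[i] * mats[[i]]
  fused <- acc / sum(params$weights)
  fused / rowSums(fused)
}

backbone_input_sides <- c(alexnet = 227L, darknet19 = 256L, googlenet = 224L,
                          resnet50 = 224L, squeezenet = 227L)

#' Optional transfer-learning hook for pretrained image backbones
#'
#' Declares a model shell with the published input size of the named
#' architecture and a fresh final layer for `n_classes`. Actual pretrained
#' weights must be supplied locally; none are downloaded. Without them
#' this errors with an "optional feature" message and callers fall back
#' to [compact_cnn()].
#'
#' @param name One of `"alexnet"`, `"darknet19"`, `"googlenet"`,
#'   `"resnet50"`, `"squeezenet"`.
#' @param n_classes Classes for the replacement final layer.
#' @param weights_path Path to locally available weights, if any.
#' @return A `cnn_model` shell with `input_side` set per architecture.
#' @export
load_pretrained_backbone <- function(name, n_classes = 2L, weights_path = NULL) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% names(backbone_input_sides)) {
    stop("unknown backbone '", name, "'; expected one of ",
         paste(names(backbone_input_sides), collapse = ", "), call. = FALSE)
  }
  if (is.null(weights_path) || !file.exists(weights_path)) {
    stop("optional feature: pretrained '", name, "' weights are not available ",
         "locally; falling back to compact_cnn() is recommended",
         call. = FALSE)
  }
  model <- compact_cnn(backbone_input_sides[[name]], n_classes = n_classes)
  model$backbone <- name
  model
}
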