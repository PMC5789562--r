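# Two-level 1-D CNN + MLP, implemented from scratch: batched forward pass,
# hand-derived exact gradients (through the softmax Jacobian of a
# squared-error objective), and SGD with a per-iteration multiplicative
# learning-rate decay.
#
# Architecture (fixed by construction, audited at build time):
#   object branch: 56 -conv5-> 52 -mean2-> 26 -conv5-> 22 -mean2-> 11, 5 maps
#   part branch:   56 -conv5-> 52 -mean2-> 26, 5 maps
#   concat 5*11 + 5*26 = 185 -> dense 20 ReLU -> dense 4 softmax
# "1-D convolution" is cross-correlation (no kernel flip); with learned
# kernels the two conventions differ only by re-parameterization.

#' Network architecture specification
#'
#' Derived feature lengths are recomputed from the layer parameters and
#' audited at construction: the object branch must emit 55 features, the
#' part branch 130, concatenated 185.
#'
#' @param input_length Samples per input window (56).
#' @param kernel_length Convolution kernel length (5).
#' @param n_maps Feature maps per convolution layer (5).
#' @param pool Mean-subsampling factor (2).
#' @param n_hidden Neurons in the MLP hidden layer (20).
#' @param n_classes Output classes (4: Q, R, S, non-QRS).
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(input_length = 56L, kernel_length = 5L, n_maps = 5L,
                         pool = 2L, n_hidden = 20L, n_classes = 4L) {
  stopifnot(kernel_length >= 1, pool >= 1, n_maps >= 1, n_hidden >= 1)
  l1 <- input_length - kernel_length + 1L
  p1 <- l1 %/% pool
  l2 <- p1 - kernel_length + 1L
  p2 <- l2 %/% pool
  obj_feats <- n_maps * p2
  part_feats <- n_maps * p1
  concat <- obj_feats + part_feats
  if (input_length == 56L && kernel_length == 5L && n_maps == 5L && pool == 2L) {
    # default geometry must reproduce the published feature counts
    stopifnot(l1 == 52L, p1 == 26L, l2 == 22L, p2 == 11L,
              obj_feats == 55L, part_feats == 130L, concat == 185L)
  }
  structure(
    list(input_length = as.integer(input_length),
         kernel_length = as.integer(kernel_length),
         n_maps = as.integer(n_maps), pool = as.integer(pool),
         n_hidden = as.integer(n_hidden), n_classes = as.integer(n_classes),
         len_conv1 = l1, len_pool1 = p1, len_conv2 = l2, len_pool2 = p2,
         object_features = obj_feats, part_features = part_feats,
         concat_features = concat),
    class = "network_spec"
  )
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf(
    "<network_spec> object: %d->%d->%d->%d->%d (x%d maps = %d feats); part: %d->%d->%d (x%d = %d); concat %d -> dense %d relu -> dense %d softmax\n",
    x$input_length, x$len_conv1, x$len_pool1, x$len_conv2, x$len_pool2,
    x$n_maps, x$object_features, x$input_length, x$len_conv1, x$len_pool1,
    x$n_maps, x$part_features, x$concat_features, x$n_hidden, x$n_classes))
  invisible(x)
}

#' Initialize network parameters
#'
#' Zero-mean Gaussian weights scaled by `sqrt(2/fan_in)` (ReLU-appropriate),
#' zero biases; deterministic given the seed.
#'
#' @param spec A [network_spec()].
#' @param seed Integer seed.
#' @return An object of class `network_params`: a named list of kernel
#'   arrays (`taps x in_maps x out_maps`), dense weight matrices
#'   (`out x in`) and bias vectors.
#' @export
init_network_params <- function(spec, seed = 1L) {
  k <- spec$kernel_length
  m <- spec$n_maps
  with_seed_(seed, function() {
    he <- function(dims, fan_in) array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
    structure(
      list(
        w1_obj = he(c(k, 1L, m), k), b1_obj = numeric(m),
        w2_obj = he(c(k, m, m), k * m), b2_obj = numeric(m),
        w1_part = he(c(k, 1L, m), k), b1_part = numeric(m),
        w_h = matrix(rnorm(spec$n_hidden * spec$concat_features,
                           0, sqrt(2 / spec$concat_features)),
                     spec$n_hidden, spec$concat_features),
        b_h = numeric(spec$n_hidden),
        w_out = matrix(rnorm(spec$n_classes * spec$n_hidden,
                             0, sqrt(2 / spec$n_hidden)),
                       spec$n_classes, spec$n_hidden),
        b_out = numeric(spec$n_classes)
      ),
      class = "network_params"
    )
  })
}

relu_ <- function(z) pmax(z, 0)

softmax_rows <- function(z) {
  e <- exp(sweep(z, 1L, apply(z, 1L, max)))
  e / rowSums(e)
}

# ---- batched primitives (n x length x maps arrays) ----

conv_fwd_b <- function(X, W, b) {
  d <- dim(X)
  n <- d[1L]; L <- d[2L]; cin <- d[3L]
  K <- dim(W)[1L]; cout <- dim(W)[3L]
  lo <- L - K + 1L
  if (lo < 1L) stop("input shorter than kernel", call. = FALSE)
  Z <- array(0, c(n, lo, cout))
  for (k in seq_len(cout)) {
    acc <- matrix(b[k], n, lo)
    for (i in seq_len(cin)) {
      for (tau in seq_len(K)) {
        sl <- X[, tau:(tau + lo - 1L), i, drop = FALSE]
        dim(sl) <- c(n, lo)
        acc <- acc + sl * W[tau, i, k]
      }
    }
    Z[, , k] <- acc
  }
  Z
}

pool_fwd_b <- function(A, f) {
  d <- dim(A)
  nb <- d[2L] %/% f
  out <- array(0, c(d[1L], nb, d[3L]))
  for (j in seq_len(f)) {
    out <- out + A[, seq.int(j, by = f, length.out = nb), , drop = FALSE]
  }
  out / f
}

pool_bwd_b <- function(dP, f, len_in) {
  d <- dim(dP)
  dA <- array(0, c(d[1L], len_in, d[3L]))
  for (j in seq_len(f)) {
    dA[, seq.int(j, by = f, length.out = d[2L]), ] <- dP / f
  }
  dA
}

conv_bwd_b <- function(X, W, dZ, need_dx = TRUE) {
  d <- dim(X)
  n <- d[1L]; L <- d[2L]; cin <- d[3L]
  K <- dim(W)[1L]; cout <- dim(W)[3L]
  lo <- dim(dZ)[2L]
  gW <- array(0, dim(W))
  gb <- numeric(cout)
  dX <- if (need_dx) array(0, c(n, L, cin)) else NULL
  for (k in seq_len(cout)) {
    dzk <- dZ[, , k, drop = FALSE]
    dim(dzk) <- c(n, lo)
    gb[k] <- sum(dzk) / n
    for (i in seq_len(cin)) {
      for (tau in seq_len(K)) {
        idx <- tau:(tau + lo - 1L)
        sl <- X[, idx, i, drop = FALSE]
        dim(sl) <- c(n, lo)
        gW[tau, i, k] <- sum(sl * dzk) / n
        if (need_dx) dX[, idx, i] <- dX[, idx, i] + dzk * W[tau, i, k]
      }
    }
  }
  list(gW = gW, gb = gb, dX = dX)
}

# ---- exported single-instance primitives ----

#' Valid 1-D convolution layer (forward)
#'
#' Cross-correlates each input map with its kernel, sums over input maps,
#' adds the bias and applies the activation; no padding, so the output is
#' `in_len - kernel_len + 1` long.
#'
#' @param inputs Numeric vector (one map) or `length x n_maps` matrix.
#' @param kernels Numeric vector (single in/out map), `taps x in_maps`
#'   matrix (one output map) or `taps x in_maps x out_maps` array.
#' @param bias Numeric vector, one per output map.
#' @param activation `"relu"` or `"linear"`.
#' @return `out_len x out_maps` matrix (dropped to a vector for one map).
#' @export
conv1d_forward <- function(inputs, kernels, bias = 0, activation = c("relu", "linear")) {
  activation <- match.arg(activation)
  Xm <- if (is.matrix(inputs)) inputs else matrix(as.numeric(inputs), ncol = 1L)
  if (is.null(dim(kernels))) kernels <- array(kernels, c(length(kernels), 1L, 1L))
  if (length(dim(kernels)) == 2L) kernels <- array(kernels, c(dim(kernels), 1L))
  if (dim(kernels)[2L] != ncol(Xm)) stop("kernel/input map count mismatch", call. = FALSE)
  if (nrow(Xm) < dim(kernels)[1L]) stop("input shorter than kernel", call. = FALSE)
  cout <- dim(kernels)[3L]
  if (length(bias) == 1L) bias <- rep(bias, cout)
  if (length(bias) != cout) stop("bias length must match output maps", call. = FALSE)
  X <- array(0, c(1L, nrow(Xm), ncol(Xm)))
  for (i in seq_len(ncol(Xm))) X[1L, , i] <- Xm[, i]
  Z <- conv_fwd_b(X, kernels, bias)
  out <- matrix(Z, dim(Z)[2L], cout)
  if (activation == "relu") out <- relu_(out)
  if (cout == 1L) drop(out) else out
}

#' Mean-subsampling (mean pooling)
#'
#' Replaces each non-overlapping block of `factor` consecutive values with
#' its mean; a trailing partial block is discarded.
#'
#' @param x Numeric vector or `length x n_maps` matrix.
#' @param factor Integer subsampling factor >= 1.
#' @return Pooled vector/matrix of length `floor(length/factor)`.
#' @export
mean_subsample <- function(x, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 || factor != round(factor)) {
    stop("`factor` must be a positive integer", call. = FALSE)
  }
  f <- as.integer(factor)
  vec <- !is.matrix(x)
  Xm <- if (vec) matrix(as.numeric(x), ncol = 1L) else x
  if (nrow(Xm) < f) stop("input shorter than the subsampling factor", call. = FALSE)
  nb <- nrow(Xm) %/% f
  out <- matrix(0, nb, ncol(Xm))
  for (j in seq_len(f)) out <- out + Xm[seq.int(j, by = f, length.out = nb), , drop = FALSE]
  out <- out / f
  if (vec) drop(out) else out
}

#' Fully connected layer (forward)
#'
#' @param x Numeric input vector.
#' @param weights `out x in` weight matrix.
#' @param bias Bias vector, one per output neuron.
#' @param activation `"linear"`, `"relu"` or `"softmax"`. The softmax output
#'   is strictly positive and sums to 1.
#' @return Output vector.
#' @export
dense_forward <- function(x, weights, bias = 0,
                          activation = c("linear", "relu", "softmax")) {
  activation <- match.arg(activation)
  if (ncol(weights) != length(x)) stop("weight/input shape mismatch", call. = FALSE)
  z <- drop(weights %*% x) + bias
  switch(activation,
         linear = z,
         relu = relu_(z),
         softmax = drop(softmax_rows(matrix(z, 1L))))
}

# ---- full network ----

# Batched forward. Xobj/Xpart: n x 56 matrices. Returns posterior matrix
# and, optionally, every intermediate needed by the backward pass.
forward_batch <- function(params, spec, Xobj, Xpart, keep_cache = FALSE) {
  n <- nrow(Xobj)
  to3 <- function(M) {
    X <- array(0, c(nrow(M), ncol(M), 1L))
    X[, , 1L] <- M
    X
  }
  X0o <- to3(Xobj)
  Z1o <- conv_fwd_b(X0o, params$w1_obj, params$b1_obj)
  P1o <- pool_fwd_b(relu_(Z1o), spec$pool)
  Z2o <- conv_fwd_b(P1o, params$w2_obj, params$b2_obj)
  P2o <- pool_fwd_b(relu_(Z2o), spec$pool)
  Fo <- matrix(P2o, n, spec$object_features)

  X0p <- to3(Xpart)
  Z1p <- conv_fwd_b(X0p, params$w1_part, params$b1_part)
  P1p <- pool_fwd_b(relu_(Z1p), spec$pool)
  Fp <- matrix(P1p, n, spec$part_features)

  Fc <- cbind(Fo, Fp)
  Hz <- sweep(Fc %*% t(params$w_h), 2L, params$b_h, "+")
  H <- relu_(Hz)
  Zl <- sweep(H %*% t(params$w_out), 2L, params$b_out, "+")
  Y <- softmax_rows(Zl)
  colnames(Y) <- CLASS_LEVELS
  if (!keep_cache) return(Y)
  list(Y = Y, Hz = Hz, H = H, Fc = Fc,
       X0o = X0o, Z1o = Z1o, P1o = P1o, Z2o = Z2o,
       X0p = X0p, Z1p = Z1p)
}

# Batched backward for the squared-error-on-softmax objective
# E = sum_j (t_j - y_j)^2 (or cross-entropy when loss = "cross_entropy").
# Gradients are averaged over the batch. Returns list(grads, loss).
backward_batch <- function(params, spec, cache, Tm,
                           loss = c("squared_error", "cross_entropy")) {
  loss <- match.arg(loss)
  Y <- cache$Y
  n <- nrow(Y)
  if (loss == "squared_error") {
    G <- 2 * (Y - Tm)                       # dE/dy
    dZl <- Y * sweep(G, 1L, rowSums(G * Y)) # through the softmax Jacobian
    loss_val <- mean(rowSums((Tm - Y)^2))
  } else {
    dZl <- Y - Tm                           # softmax + CE shortcut
    loss_val <- -mean(rowSums(Tm * log(pmax(Y, 1e-300))))
  }
  gW_out <- crossprod(dZl, cache$H) / n
  gb_out <- unname(colMeans(dZl))
  dH <- dZl %*% params$w_out
  dHz <- dH * (cache$Hz > 0)
  gW_h <- crossprod(dHz, cache$Fc) / n
  gb_h <- colMeans(dHz)
  dF <- dHz %*% params$w_h

  dFo <- dF[, seq_len(spec$object_features), drop = FALSE]
  dFp <- dF[, spec$object_features + seq_len(spec$part_features), drop = FALSE]

  dP2o <- array(dFo, c(n, spec$len_pool2, spec$n_maps))
  dA2o <- pool_bwd_b(dP2o, spec$pool, spec$len_conv2)
  dZ2o <- dA2o * (cache$Z2o > 0)
  g2o <- conv_bwd_b(cache$P1o, params$w2_obj, dZ2o, need_dx = TRUE)
  dA1o <- pool_bwd_b(g2o$dX, spec$pool, spec$len_conv1)
  dZ1o <- dA1o * (cache$Z1o > 0)
  g1o <- conv_bwd_b(cache$X0o, params$w1_obj, dZ1o, need_dx = FALSE)

  dP1p <- array(dFp, c(n, spec$len_pool1, spec$n_maps))
  dA1p <- pool_bwd_b(dP1p, spec$pool, spec$len_conv1)
  dZ1p <- dA1p * (cache$Z1p > 0)
  g1p <- conv_bwd_b(cache$X0p, params$w1_part, dZ1p, need_dx = FALSE)

  grads <- list(
    w1_obj = g1o$gW, b1_obj = g1o$gb,
    w2_obj = g2o$gW, b2_obj = g2o$gb,
    w1_part = g1p$gW, b1_part = g1p$gb,
    w_h = gW_h, b_h = gb_h, w_out = gW_out, b_out = gb_out
  )
  list(grads = grads, loss = loss_val)
}

#' Forward pass of the full two-level network
#'
#' @param params A [init_network_params()] parameter set.
#' @param spec The matching [network_spec()].
#' @param pair A [extract_pair()] segment pair, or `NULL` if `object` and
#'   `part` windows are given directly.
#' @param object,part Optional length-56 windows (used when `pair` is NULL).
#' @return Named 4-class posterior (Q, R, S, NONQRS); strictly positive,
#'   sums to 1.
#' @export
qrsnet_forward <- function(params, spec, pair = NULL, object = NULL, part = NULL) {
  if (!is.null(pair)) {
    object <- pair$object_window
    part <- pair$part_window
  }
  stopifnot(length(object) == spec$input_length, length(part) == spec$input_length)
  drop(forward_batch(params, spec, matrix(object, 1L), matrix(part, 1L)))
}

#' Squared-error objective on the softmax outputs
#'
#' `E = sum_j (t_j - y_j)^2` over the four output neurons.
#'
#' @param y Posterior vector (length 4).
#' @param t One-hot target vector (length 4).
#' @return Nonnegative loss value.
#' @export
squared_error_loss <- function(y, t) {
  if (length(y) != length(t)) stop("length mismatch", call. = FALSE)
  if (!all(t %in% c(0, 1)) || sum(t) != 1) stop("`t` must be one-hot", call. = FALSE)
  sum((t - y)^2)
}

#' Exact gradients of the objective for one or more segment pairs
#'
#' Back-propagates the squared-error objective through the softmax
#' Jacobian, the dense layers, mean-subsampling (gradient `1/factor`
#' broadcast), ReLU (subgradient 0 at 0) and the valid convolutions
#' (summing over shared-weight positions). Gradients are averaged over the
#' rows of `object`/`part`.
#'
#' @param params,spec Network parameters and specification.
#' @param object,part `n x 56` window matrices (or length-56 vectors).
#' @param targets `n x 4` one-hot matrix (or length-4 vector).
#' @param loss `"squared_error"` (default) or `"cross_entropy"`.
#' @return List with `grads` (same shapes as `params`) and `loss`.
#' @export
qrsnet_gradients <- function(params, spec, object, part, targets,
                             loss = c("squared_error", "cross_entropy")) {
  if (!is.matrix(object)) object <- matrix(object, 1L)
  if (!is.matrix(part)) part <- matrix(part, 1L)
  if (!is.matrix(targets)) targets <- matrix(targets, 1L)
  cache <- forward_batch(params, spec, object, part, keep_cache = TRUE)
  backward_batch(params, spec, cache, targets, loss = match.arg(loss))
}

#' One SGD step
#'
#' `p <- p - eta * dE/dp` for every weight and bias.
#'
#' @param params,grads Matching parameter/gradient lists.
#' @param eta Learning rate.
#' @return Updated `network_params`.
#' @export
sgd_update <- function(params, grads, eta) {
  out <- params
  for (nm in names(params)) out[[nm]] <- params[[nm]] - eta * grads[[nm]]
  out
}

#' Learning rate after t iterations
#'
#' The schedule multiplies the rate by `decay` once per mini-batch
#' iteration: `eta_t = eta0 * decay^t`. With the defaults
#' (`eta0 = 0.005`, `decay = 1 - 1e-6`, a 0.0001% relative decrement) the
#' rate reaches `0.005/e` after one million iterations.
#'
#' @param t Iteration count (0-based).
#' @param eta0 Initial learning rate.
#' @param decay Per-iteration multiplicative factor.
#' @return Learning rate at iteration `t`.
#' @export
learning_rate_at <- function(t, eta0 = 0.005, decay = 1 - 1e-6) {
  eta0 * decay^t
}

#' Training configuration
#'
#' @param eta0 Initial learning rate (0.005).
#' @param decay_per_iter Multiplicative learning-rate factor per mini-batch
#'   iteration (`1 - 1e-6`, i.e. a 0.0001% decrement).
#' @param max_epochs Maximum training epochs.
#' @param batch_size Mini-batch size.
#' @param seed Seed for initialization, the validation split and shuffling.
#' @param val_fraction Fraction held out for validation-based early
#'   stopping (0 disables).
#' @param patience Early-stopping patience in epochs.
#' @param loss `"squared_error"` (the trained objective) or
#'   `"cross_entropy"` (available for comparison).
#' @return An object of class `train_config`.
#' @export
train_config <- function(eta0 = 0.005, decay_per_iter = 1 - 1e-6,
                         max_epochs = 200L, batch_size = 16L, seed = 7L,
                         val_fraction = 0.1, patience = 20L,
                         loss = c("squared_error", "cross_entropy")) {
  if (eta0 <= 0) stop("`eta0` must be positive", call. = FALSE)
  if (decay_per_iter <= 0 || decay_per_iter > 1) {
    stop("`decay_per_iter` must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(eta0 = eta0, decay_per_iter = decay_per_iter,
         max_epochs = as.integer(max_epochs), batch_size = as.integer(batch_size),
         seed = as.integer(seed), val_fraction = val_fraction,
         patience = as.integer(patience), loss = match.arg(loss)),
    class = "train_config"
  )
}

#' Train the two-level network on a labeled segment dataset
#'
#' Seeded Gaussian initialization, shuffled mini-batch SGD with the
#' multiplicative learning-rate decay, optional validation split with early
#' stopping; returns the parameters with the best validation loss.
#'
#' @param dataset A `segment_dataset` from [build_dataset()] /
#'   [make_training_corpus()]; all four classes must be present.
#' @param spec A [network_spec()].
#' @param config A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return An object of class `qrs_model`: `spec`, `params`, `config`,
#'   `n_i`, `sampling_rate`, and a per-epoch training `log` data frame
#'   (epoch, lr, batch_loss = running mean over the epoch's mini-batches,
#'   train_loss = deterministic end-of-epoch loss on the training split,
#'   val_loss, val_acc).
#' @export
train_qrsnet <- function(dataset, spec = network_spec(), config = train_config(),
                         verbose = FALSE) {
  stopifnot(inherits(dataset, "segment_dataset"))
  counts <- tabulate(dataset$label, length(CLASS_LEVELS))
  if (any(counts == 0L)) {
    stop("class missing from dataset: ", paste(CLASS_LEVELS[counts == 0L], collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(dataset$object)
  Tm <- one_hot(as.character(dataset$label))

  params0 <- init_network_params(spec, seed = sub_seed(config$seed, 1L))
  run <- with_seed_(sub_seed(config$seed, 2L), function() {
    params <- params0
    perm <- sample.int(n)
    n_val <- floor(config$val_fraction * n)
    val_idx <- if (n_val > 0L) perm[seq_len(n_val)] else integer(0)
    tr_idx <- if (n_val > 0L) perm[-seq_len(n_val)] else perm

    eval_split <- function(p, idx) {
      Y <- forward_batch(p, spec, dataset$object[idx, , drop = FALSE],
                         dataset$part[idx, , drop = FALSE])
      Ti <- Tm[idx, , drop = FALSE]
      lv <- if (config$loss == "squared_error") mean(rowSums((Ti - Y)^2))
            else -mean(rowSums(Ti * log(pmax(Y, 1e-300))))
      acc <- mean(max.col(Y, ties.method = "first") ==
                  max.col(Ti, ties.method = "first"))
      c(loss = lv, acc = acc)
    }

    titer <- 0L
    best_loss <- Inf
    best_params <- params
    bad_epochs <- 0L
    log <- vector("list", config$max_epochs)
    for (epoch in seq_len(config$max_epochs)) {
      ord <- tr_idx[sample.int(length(tr_idx))]
      batch_losses <- c()
      for (s in seq.int(1L, length(ord), by = config$batch_size)) {
        b <- ord[s:min(s + config$batch_size - 1L, length(ord))]
        cache <- forward_batch(params, spec,
                               dataset$object[b, , drop = FALSE],
                               dataset$part[b, , drop = FALSE],
                               keep_cache = TRUE)
        bw <- backward_batch(params, spec, cache, Tm[b, , drop = FALSE],
                             loss = config$loss)
        eta <- config$eta0 * config$decay_per_iter^titer
        params <- sgd_update(params, bw$grads, eta)
        titer <- titer + 1L
        batch_losses <- c(batch_losses, bw$loss)
      }
      train_eval <- eval_split(params, tr_idx) # deterministic end-of-epoch loss
      monitor <- if (length(val_idx)) eval_split(params, val_idx) else train_eval
      log[[epoch]] <- data.frame(
        epoch = epoch,
        lr = config$eta0 * config$decay_per_iter^titer,
        batch_loss = mean(batch_losses),
        train_loss = train_eval[["loss"]],
        val_loss = monitor[["loss"]],
        val_acc = monitor[["acc"]]
      )
      if (verbose) {
        message(sprintf("epoch %3d  train %.5f  val %.5f  acc %.4f",
                        epoch, mean(batch_losses), monitor[["loss"]], monitor[["acc"]]))
      }
      if (monitor[["loss"]] < best_loss - 1e-12) {
        best_loss <- monitor[["loss"]]
        best_params <- params
        bad_epochs <- 0L
      } else {
        bad_epochs <- bad_epochs + 1L
        if (bad_epochs >= config$patience) break
      }
    }
    list(params = best_params, log = do.call(rbind, log[!vapply(log, is.null, TRUE)]),
         iterations = titer)
  })

  structure(
    list(spec = spec, params = run$params, config = config,
         n_i = dataset$n_i, sampling_rate = dataset$sampling_rate,
         iterations = run$iterations, log = run$log),
    class = "qrs_model"
  )
}

#' @export
print.qrs_model <- function(x, ...) {
  cat(sprintf("<qrs_model> trained %d epochs (%d iterations), n_i=%d, fs=%g Hz\n",
              if (is.null(x$log)) 0L else nrow(x$log), x$iterations, x$n_i,
              x$sampling_rate))
  invisible(x)
}
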