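test_that("architecture audit: default geometry yields 55 + 130 = 185 features", {
  spec <- network_spec()
  expect_equal(spec$object_features, 55L)
  expect_equal(spec$part_features, 130L)
  expect_equal(spec$concat_features, 185L)
  expect_equal(spec$n_hidden, 20L)
  expect_equal(spec$n_classes, 4L)
  expect_equal(spec$len_conv1, 52L) # 56 - 5 + 1
})

test_that("conv1d_forward matches direct arithmetic and the brute-force oracle", {
  expect_equal(conv1d_forward(c(1, 2, 3, 4), c(1, 0), activation = "linear"),
               c(1, 2, 3))
  expect_length(conv1d_forward(rnorm(56), rnorm(5), activation = "linear"), 52)

  set.seed(51)
  for (rep in 1:20) {
    L <- sample(6:30, 1)
    cin <- sample(1:4, 1)
    cout <- sample(1:4, 1)
    K <- sample(2:5, 1)
    X <- matrix(rnorm(L * cin), L, cin)
    W <- array(rnorm(K * cin * cout), c(K, cin, cout))
    b <- rnorm(cout)
    got <- conv1d_forward(X, W, b, activation = "linear")
    expect_equal(matrix(got, ncol = cout), oracle_conv1d(X, W, b),
                 tolerance = 1e-12)
  }
})

test_that("mean subsampling pools non-overlapping blocks and conserves mass", {
  expect_equal(mean_subsample(c(2, 4, 6, 8), 2), c(3, 7))
  x <- rnorm(52)
  expect_equal(mean_subsample(x, 1), x)
  out <- mean_subsample(x, 2)
  expect_length(out, 26)
  expect_equal(sum(out) * 2, sum(x))
  expect_error(mean_subsample(x, 0), "positive integer")
  # trailing partial block discarded
  expect_equal(mean_subsample(c(1, 3, 100), 2), 2)
})

test_that("dense layer: identity map, softmax symmetry and shift invariance", {
  expect_equal(dense_forward(c(1, 2, 3), diag(3), activation = "linear"),
               c(1, 2, 3))
  expect_equal(dense_forward(rep(0, 4), diag(4), activation = "softmax"),
               rep(0.25, 4))
  set.seed(52)
  z <- rnorm(4)
  s1 <- dense_forward(z, diag(4), activation = "softmax")
  s2 <- dense_forward(z + 5, diag(4), activation = "softmax")
  expect_equal(s1, s2, tolerance = 1e-12)
  expect_equal(sum(s1), 1, tolerance = 1e-12)
  expect_true(all(s1 > 0))
  expect_error(dense_forward(c(1, 2), diag(3)), "mismatch")
})

test_that("full forward pass: uniform posterior at zero params, 185-feature concat, positive homogeneity", {
  spec <- network_spec()
  zero <- init_network_params(spec, seed = 1)
  for (nm in names(zero)) zero[[nm]][] <- 0
  obj <- rnorm(56); part <- rnorm(56)
  y <- qrsnet_forward(zero, spec, object = obj, part = part)
  expect_equal(unname(y), rep(0.25, 4), tolerance = 1e-12)

  # doubling the inputs through a bias-free ReLU chain doubles every logit
  p <- init_network_params(spec, seed = 2)
  for (nm in grep("^b", names(p), value = TRUE)) p[[nm]][] <- 0
  logits <- function(o, pt) {
    cache <- qrscnn:::forward_batch(p, spec, matrix(o, 1), matrix(pt, 1),
                                    keep_cache = TRUE)
    drop(cache$H %*% t(p$w_out))
  }
  expect_equal(logits(2 * obj, 2 * part), 2 * logits(obj, part),
               tolerance = 1e-10)
})

test_that("softmax posteriors are strictly positive and sum to one everywhere", {
  spec <- network_spec()
  set.seed(53)
  for (s in 1:5) {
    p <- init_network_params(spec, seed = s)
    Y <- qrscnn:::forward_batch(p, spec, matrix(rnorm(20 * 56), 20),
                                matrix(rnorm(20 * 56), 20))
    expect_true(all(Y > 0))
    expect_equal(rowSums(Y), rep(1, 20), tolerance = 1e-12)
  }
})

test_that("squared-error objective matches direct arithmetic", {
  expect_equal(squared_error_loss(c(1, 0, 0, 0), c(1, 0, 0, 0)), 0)
  expect_equal(squared_error_loss(c(0.7, 0.1, 0.1, 0.1), c(1, 0, 0, 0)), 0.12)
  expect_equal(squared_error_loss(rep(0.25, 4), c(0, 1, 0, 0)), 0.75)
  expect_error(squared_error_loss(rep(0.25, 4), c(1, 1, 0, 0)), "one-hot")
})

test_that("analytic gradients match central finite differences", {
  spec <- network_spec()
  set.seed(54)
  obj <- matrix(rnorm(2 * 56), 2)
  part <- matrix(rnorm(2 * 56), 2)
  Tm <- one_hot(c("R", "NONQRS"))
  fd_loss <- function(p) {
    Y <- qrscnn:::forward_batch(p, spec, obj, part)
    mean(rowSums((Tm - Y)^2))
  }
  for (s in 1:2) {
    p <- init_network_params(spec, seed = s + 60)
    g <- qrsnet_gradients(p, spec, obj, part, Tm)$grads
    for (nm in c("w1_obj", "b1_obj", "w2_obj", "b2_obj", "w1_part",
                 "b1_part", "b_h", "w_out", "b_out")) {
      ks <- seq_len(min(length(p[[nm]]), 20L))
      for (k in ks) {
        pp <- p; pp[[nm]][k] <- pp[[nm]][k] + 1e-5
        pm <- p; pm[[nm]][k] <- pm[[nm]][k] - 1e-5
        fd <- (fd_loss(pp) - fd_loss(pm)) / 2e-5
        expect_equal(as.numeric(g[[nm]][k]), fd, tolerance = 1e-4)
      }
    }
  }
})

test_that("gradients vanish where the chain rule says they must", {
  spec <- network_spec()
  p <- init_network_params(spec, seed = 55)
  # kill hidden unit 1: its ReLU is dead for nonnegative-feature inputs,
  # so gradients of its incoming weights are exactly zero
  p$w_h[1, ] <- -1
  p$b_h[1] <- -100
  obj <- abs(rnorm(56)); part <- abs(rnorm(56))
  g <- qrsnet_gradients(p, spec, obj, part, one_hot("R"))$grads
  expect_equal(unname(g$w_h[1, ]), rep(0, 185))
  expect_equal(g$b_h[1], 0)
})

test_that("SGD update applies p <- p - eta * grad; decay breaks additivity", {
  spec <- network_spec()
  p <- init_network_params(spec, seed = 56)
  g <- p # arbitrary matching shapes
  up <- sgd_update(p, g, 0.005)
  expect_equal(up$w_h, p$w_h - 0.005 * g$w_h)
  expect_equal(sgd_update(list(w = 1), list(w = 2), 0.005)$w, 0.99)
  zero <- lapply(g, function(x) { x[] <- 0; x })
  expect_equal(sgd_update(p, zero, 0.005), p, ignore_attr = TRUE)

  # two sequential updates under the decaying schedule differ from one
  # update with summed gradients at the initial rate
  e0 <- 0.005; d <- 1 - 1e-6
  two_step <- 1 - e0 * 2 - (e0 * d) * 2
  one_step <- 1 - e0 * (2 + 2)
  expect_gt(abs(two_step - one_step), 0) # decay breaks additivity...
  expect_equal(1 - e0 * 2 - e0 * 2, one_step) # ...constant eta preserves it
})

test_that("learning-rate schedule follows eta0 * (1 - 1e-6)^t", {
  expect_equal(learning_rate_at(0), 0.005)
  expect_equal(learning_rate_at(10), 0.005 * (1 - 1e-6)^10)
  expect_equal(learning_rate_at(1e6), 0.005 * exp(-1), tolerance = 1e-6)
})

test_that("training reaches 100% accuracy on a separable corpus and is deterministic", {
  model <- small_model()
  log <- model$log
  expect_equal(log$val_acc[nrow(log)], 1)
  expect_lt(log$train_loss[nrow(log)], log$train_loss[1])

  # determinism: same seed, same data -> identical parameters
  corpus <- make_training_corpus(n_qrs = 8, seed = 5)
  cfgt <- train_config(max_epochs = 3, seed = 9)
  m1 <- train_qrsnet(corpus, config = cfgt)
  m2 <- train_qrsnet(corpus, config = cfgt)
  expect_identical(m1$params, m2$params)
})

test_that("epoch loss is non-increasing early in training for most seeds", {
  corpus <- make_training_corpus(n_qrs = 10, seed = 13)
  ok <- 0L
  for (s in 1:10) {
    m <- train_qrsnet(corpus, config = train_config(max_epochs = 5, seed = s,
                                                    val_fraction = 0))
    if (all(diff(m$log$train_loss) <= 1e-9)) ok <- ok + 1L
  }
  expect_gte(ok, 9L)
})

test_that("training refuses a dataset with a missing class", {
  corpus <- make_training_corpus(n_qrs = 8, seed = 5)
  broken <- corpus
  keep <- corpus$label != "S"
  broken$object <- corpus$object[keep, ]
  broken$part <- corpus$part[keep, ]
  broken$label <- factor(as.character(corpus$label[keep]),
                         levels = levels(corpus$label))
  expect_error(train_qrsnet(broken), "class missing")
})
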