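test_that("feature extraction has the shape and determinism contract", {
  ex <- tiny_extractor(size = c(16, 16), f = 12)
  vid <- rand_video(n = 5, h = 16, w = 16, seed = 6)
  feats <- extract_features(vid, ex)
  expect_identical(dim(feats), c(5L, 12L))
  # identical frames give identical features; extraction is deterministic
  feats2 <- extract_features(list(vid[[2]], vid[[2]]), ex)
  expect_identical(feats2[1, ], feats2[2, ])
  expect_identical(extract_features(vid, ex), feats)
  # a reconstructed spec with the same seed reproduces the features
  ex2 <- tiny_extractor(size = c(16, 16), f = 12)
  expect_identical(extract_features(vid, ex2), feats)
  expect_error(extract_features(rand_video(2, h = 8, w = 8), ex), "expects")
  expect_error(extract_features(list(), ex), "no frames")
})

test_that("the full residual backbone demands a user-supplied function", {
  ex <- feature_extractor_spec("resnet50", input_size = c(16, 16))
  expect_identical(ex$feature_dim, 2048L)
  expect_error(extract_features(rand_video(1, 16, 16), ex), "weights")
  custom <- feature_extractor_spec("resnet50", feature_dim = 4,
                                   input_size = c(16, 16),
                                   fun = function(fr) apply(fr, 3, mean)[c(1, 2, 3, 1)])
  feats <- extract_features(rand_video(2, 16, 16, seed = 9), custom)
  expect_identical(dim(feats), c(2L, 4L))
})

test_that("the feature buffer is append-only within a video and empty after reset", {
  buf <- feature_buffer("vid1", feature_dim = 6)
  expect_identical(nrow(buffer_features(buf)), 0L)
  buffer_append(buf, matrix(1, 3, 6))
  buffer_append(buf, matrix(2, 2, 6))
  expect_identical(nrow(buffer_features(buf)), 5L)
  expect_identical(buffer_features(buf)[4, 1], 2)
  expect_error(buffer_append(buf, matrix(0, 1, 5)), "mismatch")
  buffer_reset(buf)
  expect_identical(nrow(buffer_features(buf)), 0L)
})

test_that("the SS-TCN is causal: the future never changes the past", {
  spec <- tiny_tcn(n_classes = 4, f = 10, layers = 4)
  params <- sstcn_init(spec, seed = 3)
  set.seed(77)
  for (rep in 1:40) {
    n <- sample(5:50, 1)
    X <- matrix(rnorm(n * 10), n, 10)
    t0 <- sample(seq_len(n), 1)
    X2 <- X
    X2[t0:n, ] <- matrix(rnorm((n - t0 + 1) * 10) * 10, ncol = 10)
    s1 <- sstcn_forward(X, params, spec)$scores
    s2 <- sstcn_forward(X2, params, spec)$scores
    if (t0 > 1) {
      expect_identical(s1[seq_len(t0 - 1), , drop = FALSE],
                       s2[seq_len(t0 - 1), , drop = FALSE])
    }
    # scores at/after the perturbation generally do change
    expect_false(isTRUE(all.equal(s1[t0, ], s2[t0, ])))
  }
})

test_that("outputs beyond the receptive field are unaffected by distant history", {
  spec <- sstcn_spec(n_classes = 3, feature_dim = 6, n_layers = 3,
                     kernel_size = 3, hidden_dim = 8)
  rf <- spec$receptive_field
  expect_identical(rf, 1L + 2L * (1L + 2L + 4L))
  params <- sstcn_init(spec, seed = 5)
  set.seed(11)
  n <- rf + 20
  X <- matrix(rnorm(n * 6), n, 6)
  X2 <- X
  X2[1:3, ] <- matrix(rnorm(18) * 10, ncol = 6)  # outside rf of late frames
  s1 <- sstcn_forward(X, params, spec)$scores
  s2 <- sstcn_forward(X2, params, spec)$scores
  late <- (3 + rf):n   # frames whose receptive field excludes frames 1..3
  expect_equal(s1[late, ], s2[late, ], tolerance = 1e-12)
  # two videos identical through frame k agree exactly through frame k
  Y <- rbind(X[1:15, ], matrix(rnorm(10 * 6), 10, 6))
  sa <- sstcn_forward(X[1:25, ], params, spec)$scores
  sb <- sstcn_forward(Y, params, spec)$scores
  expect_identical(sa[1:15, ], sb[1:15, ])
})

test_that("forward pass validates inputs and flags non-finite scores", {
  spec <- tiny_tcn(f = 10)
  params <- sstcn_init(spec, 1)
  expect_error(sstcn_forward(matrix(0, 3, 4), params, spec), "dimension")
  expect_error(sstcn_forward(matrix(numeric(0), 0, 10), params, spec), "empty")
})

test_that("class weights follow inverse frequency with mean-1 normalization", {
  expect_equal(compute_class_weights(c(10, 10)), c(1, 1))
  expect_equal(compute_class_weights(c(30, 10)), c(0.5, 1.5))
  w <- compute_class_weights(c(5, 0, 5))
  expect_identical(w[2], 0)
  expect_equal(mean(w[c(1, 3)]), 1)
  expect_error(compute_class_weights(c(0, 0)), "positive")
  expect_error(compute_class_weights(c(-1, 2)), ">= 0")
})

test_that("weighted cross-entropy matches its closed forms", {
  # uniform scores over C classes with unit weights -> log C
  expect_equal(weighted_cross_entropy(matrix(0, 5, 4), c(0, 1, 2, 3, 0)),
               log(4), tolerance = 1e-12)
  expect_equal(weighted_cross_entropy(matrix(1.7, 3, 2), c(0, 1, 1)),
               log(2), tolerance = 1e-12)
  # a huge margin on the true class drives the loss to 0
  sc <- matrix(0, 2, 3); sc[cbind(1:2, c(1, 3))] <- 50
  expect_lt(weighted_cross_entropy(sc, c(0, 2)), 1e-12)
  # rescaling all weights leaves the normalized loss unchanged
  set.seed(3)
  sc <- matrix(rnorm(12), 4, 3); y <- c(0, 2, 1, 1)
  w <- c(0.5, 1.5, 1)
  expect_equal(weighted_cross_entropy(sc, y, w),
               weighted_cross_entropy(sc, y, 2 * w), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(weighted_cross_entropy(sc, y, w),
                                weighted_cross_entropy(sc, y))))
  expect_error(weighted_cross_entropy(sc, c(0, 1, 3, 1)), "labels must lie")
})

test_that("analytic gradients match numerical differentiation", {
  spec <- sstcn_spec(n_classes = 2, feature_dim = 3, n_layers = 2,
                     kernel_size = 3, hidden_dim = 4)
  params <- sstcn_init(spec, seed = 3)
  set.seed(4)
  X <- matrix(rnorm(18), 6, 3)
  y <- c(0L, 1L, 0L, 1L, 1L, 0L)
  w <- c(1, 1.5)
  fwd <- trandaug:::sstcn_forward_pass(params, X, spec, keep = TRUE)
  dlg <- trandaug:::weighted_ce_grad(fwd$logits, y, w, 1:6)
  grads <- trandaug:::sstcn_backward_pass(params, spec, fwd$cache, dlg)
  lossfn <- function(pp) {
    weighted_cross_entropy(trandaug:::sstcn_forward_pass(pp, X, spec), y, w)
  }
  eps <- 1e-6
  for (nm in names(params)) {
    for (i in seq_len(min(length(params[[nm]]), 6))) {
      pp <- params
      pp[[nm]][i] <- pp[[nm]][i] + eps
      lp <- lossfn(pp)
      pp[[nm]][i] <- pp[[nm]][i] - 2 * eps
      lm <- lossfn(pp)
      expect_equal(grads[[nm]][i], (lp - lm) / (2 * eps), tolerance = 1e-4,
                   label = paste("grad", nm, i))
    }
  }
})

test_that("one optimizer step decreases the loss on a two-class toy sequence", {
  spec <- sstcn_spec(n_classes = 2, feature_dim = 4, n_layers = 2,
                     hidden_dim = 6)
  params <- sstcn_init(spec, seed = 9)
  set.seed(10)
  X <- matrix(rnorm(40), 10, 4)
  y <- rep(c(0L, 1L), 5)
  w <- c(1, 1)
  loss0 <- weighted_cross_entropy(sstcn_forward(X, params, spec), y, w)
  fwd <- trandaug:::sstcn_forward_pass(params, X, spec, keep = TRUE)
  dlg <- trandaug:::weighted_ce_grad(fwd$logits, y, w, 1:10)
  grads <- trandaug:::sstcn_backward_pass(params, spec, fwd$cache, dlg)
  upd <- trandaug:::adam_step(params, grads, trandaug:::adam_state(params),
                              lr = 0.01)
  loss1 <- weighted_cross_entropy(sstcn_forward(X, upd$params, spec), y, w)
  expect_lt(loss1, loss0)
})
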