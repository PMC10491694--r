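# Fixtures are built in code; nothing binary ships with the package.

rand_frame <- function(h = 12, w = 12, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(runif(h * w * 3), c(h, w, 3))
}

const_frame <- function(value = 0.5, h = 12, w = 12) {
  array(value, c(h, w, 3))
}

rand_video <- function(n = 8, h = 12, w = 12, seed = 1) {
  set.seed(seed)
  replicate(n, array(runif(h * w * 3), c(h, w, 3)), simplify = FALSE)
}

const_video <- function(n = 8, value = 0.5, h = 12, w = 12) {
  replicate(n, const_frame(value, h, w), simplify = FALSE)
}

# frames whose values are exact multiples of 1/255 (PNG-representable)
quantized_video <- function(n = 4, h = 8, w = 8, seed = 1) {
  set.seed(seed)
  replicate(n, {
    array(sample(0:255, h * w * 3, replace = TRUE) / 255, c(h, w, 3))
  }, simplify = FALSE)
}

# Independent macro-metrics oracle: explicit confusion matrix via table(),
# a different code path from the package's per-class loop.
oracle_video_metrics <- function(pred, truth) {
  cls <- sort(unique(truth))
  cm <- table(factor(truth, levels = 0:max(c(pred, truth))),
              factor(pred, levels = 0:max(c(pred, truth))))
  pr <- re <- f1 <- numeric(length(cls))
  for (i in seq_along(cls)) {
    k <- as.character(cls[i])
    tp <- cm[k, k]
    pred_pos <- sum(cm[, k])
    true_pos <- sum(cm[k, ])
    pr[i] <- if (pred_pos > 0) tp / pred_pos else 0
    re[i] <- if (true_pos > 0) tp / true_pos else 0
    f1[i] <- if (pr[i] + re[i] > 0) 2 * pr[i] * re[i] / (pr[i] + re[i]) else 0
  }
  c(ACC = mean(pred == truth), PR = mean(pr), RE = mean(re), F1 = mean(f1))
}

# mean absolute pixel difference: the scalar distortion measure used for
# the monotone-strength property
mad_distortion <- function(a, b) mean(abs(a - b))

tiny_extractor <- function(size = c(16, 16), f = 12, seed = 1) {
  feature_extractor_spec("tiny", feature_dim = f, input_size = size,
                         n_filters = 4, seed = seed)
}

tiny_tcn <- function(n_classes = 3, f = 12, layers = 3) {
  sstcn_spec(n_classes = n_classes, feature_dim = f, n_layers = layers,
             hidden_dim = 8)
}
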