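#' Specify a causal single-stage temporal convolutional network
#'
#' The temporal model is a single-stage TCN: a 1x1 input projection into
#' `hidden_dim` channels, `n_layers` residual blocks of dilated *causal*
#' 1-D convolutions (kernel `kernel_size`, dilations doubling by default),
#' and a 1x1 output projection onto the class scores. Causal convolutions
#' pad only the past, so the prediction at frame `t` depends on the current
#' and the `n` previous frames only -- the property that makes the model
#' usable for online recognition. The receptive field is
#' \eqn{n + 1 = 1 + (k - 1)\sum_l d_l}.
#'
#' @param n_classes Number of activity classes.
#' @param feature_dim Input feature size `f` per frame.
#' @param n_layers Number of residual dilated-convolution blocks.
#' @param kernel_size Convolution kernel width (taps into the past).
#' @param hidden_dim Channel width of the hidden layers.
#' @param dilations Integer dilation per layer; default `2^(0:(n_layers-1))`.
#' @return An object of class `"sstcn_spec"`. The implied receptive field
#'   (in frames, including the current one) is in `$receptive_field`.
#' @export
sstcn_spec <- function(n_classes, feature_dim, n_layers = 10,
                       kernel_size = 3, hidden_dim = 64,
                       dilations = NULL) {
  if (is.null(dilations)) dilations <- 2^(seq_len(n_layers) - 1)
  if (length(dilations) != n_layers) {
    stop("dilations must have one entry per layer")
  }
  spec <- list(n_classes = as.integer(n_classes),
               feature_dim = as.integer(feature_dim),
               n_layers = as.integer(n_layers),
               kernel_size = as.integer(kernel_size),
               hidden_dim = as.integer(hidden_dim),
               dilations = as.integer(dilations))
  spec$receptive_field <- 1L + (spec$kernel_size - 1L) * sum(spec$dilations)
  structure(spec, class = "sstcn_spec")
}

#' @export
print.sstcn_spec <- function(x, ...) {
  cat(sprintf(
    "<sstcn_spec> f=%d -> %d x [causal conv k=%d, h=%d, dil %s] -> %d classes (receptive field %d frames)\n",
    x$feature_dim, x$n_layers, x$kernel_size, x$hidden_dim,
    paste(x$dilations, collapse = ","), x$n_classes, x$receptive_field))
  invisible(x)
}

#' Initialize SS-TCN parameters
#'
#' Draws Glorot-scaled initial weights for every layer. Parameters are kept
#' as a flat named list of arrays so optimizer state can mirror them.
#'
#' @param spec An [sstcn_spec()].
#' @param seed Seed for the initial draw.
#' @return Named list of numeric arrays.
#' @export
sstcn_init <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "sstcn_spec"))
  h <- spec$hidden_dim; f <- spec$feature_dim
  k <- spec$kernel_size; C <- spec$n_classes
  glorot <- function(nin, nout, dims) {
    array(stats::rnorm(prod(dims), sd = sqrt(2 / (nin + nout))), dims)
  }
  with_stream(derive_seed(seed, "sstcn-init"), {
    params <- list(W_in = glorot(f, h, c(f, h)), b_in = numeric(h))
    for (l in seq_len(spec$n_layers)) {
      params[[paste0("Wc", l)]] <- glorot(k * h, h, c(k, h, h))
      params[[paste0("bc", l)]] <- numeric(h)
      params[[paste0("Wp", l)]] <- glorot(h, h, c(h, h))
      params[[paste0("bp", l)]] <- numeric(h)
    }
    params$W_out <- glorot(h, C, c(h, C))
    params$b_out <- numeric(C)
    params
  })
}

# shift rows of X down by `by` (causal delay), zero-filling the past border
shift_down <- function(X, by) {
  if (by == 0L) return(X)
  n <- nrow(X)
  out <- matrix(0, n, ncol(X))
  if (by < n) out[(by + 1):n, ] <- X[1:(n - by), , drop = FALSE]
  out
}

# adjoint of shift_down: shift rows up by `by`
shift_up <- function(X, by) {
  if (by == 0L) return(X)
  n <- nrow(X)
  out <- matrix(0, n, ncol(X))
  if (by < n) out[1:(n - by), ] <- X[(by + 1):n, , drop = FALSE]
  out
}

# Forward pass over a feature matrix X (frames x f). Returns logits and,
# if keep = TRUE, the intermediates needed for backprop.
sstcn_forward_pass <- function(params, X, spec, keep = FALSE) {
  H <- sweep(X %*% params$W_in, 2, params$b_in, "+")
  cache <- if (keep) list(X = X, H = vector("list", spec$n_layers),
                          Z = vector("list", spec$n_layers),
                          A = vector("list", spec$n_layers))
  k <- spec$kernel_size
  for (l in seq_len(spec$n_layers)) {
    d <- spec$dilations[l]
    Wc <- params[[paste0("Wc", l)]]
    Z <- sweep(matrix(0, nrow(H), spec$hidden_dim), 2,
               params[[paste0("bc", l)]], "+")
    for (tap in seq_len(k)) {
      Z <- Z + shift_down(H, (tap - 1L) * d) %*% Wc[tap, , ]
    }
    A <- Z
    A[A < 0] <- 0
    U <- sweep(A %*% params[[paste0("Wp", l)]], 2,
               params[[paste0("bp", l)]], "+")
    if (keep) {
      cache$H[[l]] <- H; cache$Z[[l]] <- Z; cache$A[[l]] <- A
    }
    H <- H + U
  }
  logits <- sweep(H %*% params$W_out, 2, params$b_out, "+")
  if (keep) {
    cache$H_final <- H
    list(logits = logits, cache = cache)
  } else {
    logits
  }
}

# Backward pass: dlogits (frames x C) -> gradients for every parameter.
sstcn_backward_pass <- function(params, spec, cache, dlogits) {
  grads <- list()
  H <- cache$H_final
  grads$W_out <- t(H) %*% dlogits
  grads$b_out <- colSums(dlogits)
  dH <- dlogits %*% t(params$W_out)
  k <- spec$kernel_size
  for (l in rev(seq_len(spec$n_layers))) {
    A <- cache$A[[l]]; Z <- cache$Z[[l]]; Hl <- cache$H[[l]]
    Wp <- params[[paste0("Wp", l)]]
    # residual: H_out = H_in + relu(conv(H_in)) %*% Wp + bp
    dU <- dH
    grads[[paste0("Wp", l)]] <- t(A) %*% dU
    grads[[paste0("bp", l)]] <- colSums(dU)
    dA <- dU %*% t(Wp)
    dZ <- dA * (Z > 0)
    Wc <- params[[paste0("Wc", l)]]
    dWc <- array(0, dim(Wc))
    dH_in <- dH  # residual path
    for (tap in seq_len(k)) {
      by <- (tap - 1L) * spec$dilations[l]
      dWc[tap, , ] <- t(shift_down(Hl, by)) %*% dZ
      dH_in <- dH_in + shift_up(dZ %*% t(Wc[tap, , ]), by)
    }
    grads[[paste0("Wc", l)]] <- dWc
    grads[[paste0("bc", l)]] <- colSums(dZ)
    dH <- dH_in
  }
  grads$W_in <- t(cache$X) %*% dH
  grads$b_in <- colSums(dH)
  grads
}

#' Run the SS-TCN over a feature sequence
#'
#' Computes frame-wise class scores for a whole feature sequence. The
#' network is causal: the score at frame `t` is invariant to arbitrary
#' changes of the features at frames `> t`, and to changes at frames
#' earlier than `t - (receptive_field - 1)`.
#'
#' @param features Numeric matrix, frames x `feature_dim`, or a
#'   [feature_buffer()].
#' @param params Parameters from [sstcn_init()] (or a fitted model's
#'   `coef()`).
#' @param spec The [sstcn_spec()].
#' @return An object of class `"frame_predictions"`: a list with `scores`
#'   (frames x classes logits) and `labels` (0-based argmax class per
#'   frame; ties resolved to the lowest class id).
#' @export
sstcn_forward <- function(features, params, spec) {
  stopifnot(inherits(spec, "sstcn_spec"))
  if (inherits(features, "feature_buffer")) features <- buffer_features(features)
  features <- rbind(features)
  if (nrow(features) == 0L) stop("empty feature sequence")
  if (ncol(features) != spec$feature_dim) {
    stop("feature dimension ", ncol(features), " does not match spec (",
         spec$feature_dim, ")")
  }
  logits <- sstcn_forward_pass(params, features, spec, keep = FALSE)
  frame_predictions(logits)
}

frame_predictions <- function(scores) {
  if (any(!is.finite(scores))) stop("non-finite class scores")
  structure(list(scores = scores,
                 labels = max.col(scores, ties.method = "first") - 1L),
            class = "frame_predictions")
}

#' @export
print.frame_predictions <- function(x, ...) {
  cat(sprintf("<frame_predictions> %d frames x %d classes\n",
              nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

#' Inverse-frequency class weights
#'
#' Phase/step label distributions are heavily imbalanced (short phases are
#' rare), so the cross-entropy loss is class-weighted. Weights are inverse
#' frequency, `total / (n_classes * count_c)`, set to 0 for classes absent
#' from the counts, and normalized so the present classes average to 1.
#'
#' @param label_counts Non-negative integer vector of per-class frame
#'   counts (index `c` is class id `c - 1`).
#' @return Numeric weight vector of the same length.
#' @examples
#' compute_class_weights(c(30, 10))  # 0.5, 1.5
#' @export
compute_class_weights <- function(label_counts) {
  if (any(label_counts < 0)) stop("label counts must be >= 0")
  total <- sum(label_counts)
  if (total == 0) stop("at least one class must have a positive count")
  C <- length(label_counts)
  w <- ifelse(label_counts > 0, total / (C * label_counts), 0)
  present <- label_counts > 0
  w[present] <- w[present] / mean(w[present])
  w
}

softmax_rows <- function(scores) {
  m <- apply(scores, 1, max)
  e <- exp(scores - m)
  e / rowSums(e)
}

#' Class-weighted cross-entropy loss
#'
#' The frame-wise loss is
#' \deqn{L = \frac{\sum_t w_{y_t} \, (-\log \mathrm{softmax}(s_t)_{y_t})}
#'                {\sum_t w_{y_t}},}
#' i.e. a weighted mean over frames normalized by the total frame weight,
#' so rescaling all class weights leaves the loss unchanged.
#'
#' @param scores Frames x classes logit matrix (or a
#'   `"frame_predictions"`).
#' @param labels 0-based true class per frame.
#' @param weights Per-class non-negative weights (default: all 1).
#' @return Scalar loss.
#' @export
weighted_cross_entropy <- function(scores, labels, weights = NULL) {
  if (inherits(scores, "frame_predictions")) scores <- scores$scores
  scores <- rbind(scores)
  C <- ncol(scores)
  labels <- as.integer(labels)
  if (length(labels) != nrow(scores)) stop("labels/scores length mismatch")
  if (any(labels < 0L | labels >= C)) {
    stop("labels must lie in [0, ", C, ")")
  }
  if (is.null(weights)) weights <- rep(1, C)
  if (length(weights) != C || any(weights < 0)) {
    stop("weights must be ", C, " non-negative values")
  }
  p <- softmax_rows(scores)
  idx <- cbind(seq_along(labels), labels + 1L)
  w <- weights[labels + 1L]
  if (sum(w) == 0) stop("all frames carry zero class weight")
  sum(w * -log(pmax(p[idx], 1e-300))) / sum(w)
}

# Gradient of the weighted CE w.r.t. the logits, restricted to `rows`
# (other frames contribute prediction context but no loss).
weighted_ce_grad <- function(scores, labels, weights, rows) {
  C <- ncol(scores)
  p <- softmax_rows(scores[rows, , drop = FALSE])
  y <- labels[rows] + 1L
  w <- weights[y]
  G <- p * w
  G[cbind(seq_along(y), y)] <- G[cbind(seq_along(y), y)] - w
  G <- G / sum(w)
  out <- matrix(0, nrow(scores), C)
  out[rows, ] <- G
  out
}

# ---- Adam -------------------------------------------------------------------

adam_state <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
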