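#' Training configuration
#'
#' Defaults mirror the reference training setup for surgical activity
#' recognition: 50 epochs, learning rate 1e-5, batches of 64 frames, with
#' the augmentation policy resampled for every video at every epoch.
#' Desk-scale experiments on the synthetic generator use far fewer epochs
#' and a larger rate (see the package vignette); pass them explicitly.
#'
#' @param epochs Number of passes over the training videos (`>= 1`).
#' @param learning_rate Adam step size (`> 0`).
#' @param batch_size Frames per optimizer step (`>= 1`); frames are
#'   batched in temporal order within each video.
#' @param augment_mode One of `"none"`, `"custom"` (flip + saturation +
#'   rotation applied per-video uniformly), `"ra"`, `"ura"`, `"tra"`.
#' @param policy The [augment_policy()] realized each epoch (ignored for
#'   `"none"`; for `"custom"` its subset is overridden).
#' @param seed Master seed for shuffling, initialization and per-epoch
#'   augmentation streams.
#' @return An object of class `"train_config"`.
#' @export
train_config <- function(epochs = 50, learning_rate = 1e-5, batch_size = 64,
                         augment_mode = c("none", "custom", "ra", "ura", "tra"),
                         policy = augment_policy(), seed = 1L) {
  augment_mode <- match.arg(augment_mode)
  if (epochs < 1) stop("epochs must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (batch_size < 1) stop("batch_size must be >= 1")
  structure(list(epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 augment_mode = augment_mode, policy = policy,
                 seed = as.integer(seed)),
            class = "train_config")
}

custom_subset <- c("horizontal_flip", "saturation", "rotate")

# Augment one video for one epoch under the configured mode. Returns the
# (possibly new) frame list; the plan (or NULL) is attached as "plan".
augment_for_epoch <- function(frames, config, video_id, epoch) {
  mode <- config$augment_mode
  if (mode == "none") return(frames)
  pol <- config$policy
  pol$seed <- derive_seed(config$seed, pol$seed, epoch)
  if (mode == "custom") {
    pol$subset <- intersect(custom_subset, names(pol$bank))
    return(uniform_randaugment(frames, pol, video_id))
  }
  switch(mode,
         tra = trandaugment(frames, pol, video_id),
         ura = uniform_randaugment(frames, pol, video_id),
         ra  = randaugment(frames, pol, video_id))
}

#' Per-video macro-averaged recognition metrics
#'
#' The evaluation protocol for frame-wise activity recognition: for each
#' video, frame accuracy (ACC) plus precision (PR), recall (RE) and
#' F1-score (F1) macro-averaged over the classes present in that video's
#' ground truth; the aggregate is the unweighted mean of each metric over
#' videos. A class that is never predicted within a video contributes
#' precision 0 (and F1 0 when recall is also 0).
#'
#' @param predictions Named list (by video id) of `"frame_predictions"` or
#'   plain 0-based label vectors.
#' @param truths Named list of 0-based true label vectors, same order.
#' @return An object of class `"metric_report"`: `$per_video` (data frame
#'   of video_id, ACC, PR, RE, F1) and `$aggregate` (named numeric).
#' @examples
#' evaluate_predictions(list(v = c(0L, 1L, 1L, 1L)),
#'                      list(v = c(0L, 0L, 1L, 1L)))
#' @export
evaluate_predictions <- function(predictions, truths) {
  if (length(predictions) == 0L) stop("no videos to evaluate")
  if (length(predictions) != length(truths)) {
    stop("predictions and truths must have the same number of videos")
  }
  ids <- names(predictions) %||% paste0("video", seq_along(predictions))
  rows <- lapply(seq_along(predictions), function(i) {
    pred <- predictions[[i]]
    if (inherits(pred, "frame_predictions")) pred <- pred$labels
    truth <- as.integer(truths[[i]])
    pred <- as.integer(pred)
    if (length(pred) != length(truth)) {
      stop("video ", ids[i], ": prediction/truth length mismatch")
    }
    cls <- sort(unique(truth))
    pr <- re <- f1 <- numeric(length(cls))
    for (j in seq_along(cls)) {
      c0 <- cls[j]
      tp <- sum(pred == c0 & truth == c0)
      fp <- sum(pred == c0 & truth != c0)
      fn <- sum(pred != c0 & truth == c0)
      pr[j] <- if (tp + fp > 0) tp / (tp + fp) else 0
      re[j] <- if (tp + fn > 0) tp / (tp + fn) else 0
      f1[j] <- if (pr[j] + re[j] > 0) 2 * pr[j] * re[j] / (pr[j] + re[j]) else 0
    }
    data.frame(video_id = ids[i], ACC = mean(pred == truth),
               PR = mean(pr), RE = mean(re), F1 = mean(f1))
  })
  per_video <- do.call(rbind, rows)
  aggregate <- colMeans(per_video[c("ACC", "PR", "RE", "F1")])
  structure(list(per_video = per_video, aggregate = aggregate),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, digits = 4, ...) {
  cat(sprintf("<metric_report> %d video(s)\n", nrow(x$per_video)))
  print(cbind(x$per_video["video_id"],
              round(x$per_video[c("ACC", "PR", "RE", "F1")], digits)),
        row.names = FALSE)
  cat("aggregate:",
      paste(sprintf("%s %.4f", names(x$aggregate), x$aggregate),
            collapse = "  "), "\n")
  invisible(x)
}

# Predict one video: features through the buffer, then the TCN.
predict_video <- function(vs, extractor, params, tcn, target_size = NULL) {
  frames <- vs$frames
  if (!is.null(target_size)) frames <- lapply(frames, resize_frame, target_size)
  buf <- feature_buffer(vs$video_id, extractor$feature_dim)
  buffer_append(buf, extract_features(frames, extractor))
  pred <- sstcn_forward(buffer_features(buf), params, tcn)
  buffer_reset(buf)
  pred
}

#' Fit the spatiotemporal recognizer
#'
#' Trains the causal SS-TCN on top of the (frozen) per-frame feature
#' extractor for frame-wise activity recognition, with the class-weighted
#' cross-entropy loss and per-epoch augmentation resampling: at every
#' epoch each training video is re-augmented with a fresh random plan
#' under the configured mode, so the model effectively sees an extended
#' dataset of videos whose segments are transformed differently each time.
#'
#' Within a video, frames are processed in temporal order through a
#' feature buffer (reset at the end of each video); each optimizer step
#' scores all frames buffered so far and takes the loss on the current
#' batch only. Videos are shuffled every epoch. After each epoch the model
#' is evaluated on the validation split and the parameters with the best
#' validation F1 are kept.
#'
#' @param manifest A [dataset_manifest()] with non-empty train and val
#'   splits.
#' @param extractor A [feature_extractor_spec()].
#' @param tcn An [sstcn_spec()], or `NULL` for defaults inferred from the
#'   manifest and extractor.
#' @param config A [train_config()].
#' @return An object of class `"trandaug_model"` with `print()`,
#'   `summary()`, `coef()`, `predict()` and `plot()` methods. Contains the
#'   best-validation-F1 parameters, the per-epoch `history` and the
#'   validation `val_report` of the selected epoch.
#' @export
train_recognizer <- function(manifest, extractor, tcn = NULL,
                             config = train_config()) {
  stopifnot(inherits(manifest, "dataset_manifest"),
            inherits(extractor, "feature_extractor_spec"),
            inherits(config, "train_config"))
  n_classes <- length(manifest$class_names)
  if (is.null(tcn)) {
    tcn <- sstcn_spec(n_classes, extractor$feature_dim,
                      n_layers = 6, hidden_dim = 32)
  }
  stopifnot(inherits(tcn, "sstcn_spec"))
  target <- extractor$input_size
  train_videos <- load_split(manifest, "train", target_size = target)
  val_videos <- load_split(manifest, "val", target_size = target)
  if (length(train_videos) == 0L) stop("manifest has an empty train split")
  if (length(val_videos) == 0L) stop("manifest has an empty val split")

  counts <- integer(n_classes)
  for (vs in train_videos) {
    if (is.null(vs$labels)) stop("training video '", vs$video_id,
                                 "' has no labels")
    tab <- tabulate(vs$labels + 1L, nbins = n_classes)
    counts <- counts + tab
  }
  weights <- compute_class_weights(counts)

  params <- sstcn_init(tcn, seed = derive_seed(config$seed, "init"))
  opt <- adam_state(params)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_ACC = numeric(0), val_F1 = numeric(0))
  best <- list(f1 = -Inf, params = params, epoch = 0L, report = NULL)

  for (epoch in seq_len(config$epochs)) {
    order_v <- with_stream(derive_seed(config$seed, "shuffle", epoch),
                           sample.int(length(train_videos)))
    losses <- c()
    for (vi in order_v) {
      vs <- train_videos[[vi]]
      frames <- augment_for_epoch(vs$frames, config, vs$video_id, epoch)
      attr(frames, "plan") <- NULL
      buf <- feature_buffer(vs$video_id, extractor$feature_dim)
      n <- length(frames)
      starts <- seq.int(1L, n, by = config$batch_size)
      for (bs in starts) {
        be <- min(bs + config$batch_size - 1L, n)
        buffer_append(buf, extract_features(frames[bs:be], extractor))
        X <- buffer_features(buf)   # all frames seen so far, as constants
        fwd <- sstcn_forward_pass(params, X, tcn, keep = TRUE)
        rows <- bs:be
        loss <- weighted_cross_entropy(fwd$logits[rows, , drop = FALSE],
                                       vs$labels[rows], weights)
        if (!is.finite(loss)) {
          stop("non-finite training loss at epoch ", epoch, ", video '",
               vs$video_id, "' (frames ", bs, "-", be, ")")
        }
        dlogits <- weighted_ce_grad(fwd$logits, vs$labels, weights, rows)
        grads <- sstcn_backward_pass(params, tcn, fwd$cache, dlogits)
        upd <- adam_step(params, grads, opt, config$learning_rate)
        params <- upd$params
        opt <- upd$state
        losses <- c(losses, loss)
      }
      buffer_reset(buf)  # feature buffer is reset at the end of the video
    }
    preds <- lapply(val_videos, predict_video, extractor = extractor,
                    params = params, tcn = tcn)
    names(preds) <- vapply(val_videos, `[[`, character(1), "video_id")
    truths <- lapply(val_videos, `[[`, "labels")
    names(truths) <- names(preds)
    rep_ <- evaluate_predictions(preds, truths)
    history <- rbind(history, data.frame(
      epoch = epoch, loss = mean(losses),
      val_ACC = rep_$aggregate[["ACC"]], val_F1 = rep_$aggregate[["F1"]]))
    if (rep_$aggregate[["F1"]] > best$f1) {
      best <- list(f1 = rep_$aggregate[["F1"]], params = params,
                   epoch = epoch, report = rep_)
    }
  }

  structure(list(params = best$params, extractor = extractor, tcn = tcn,
                 config = config, class_names = manifest$class_names,
                 class_weights = weights, history = history,
                 best_epoch = best$epoch, val_report = best$report),
            class = "trandaug_model")
}

#' @export
print.trandaug_model <- function(x, ...) {
  cat(sprintf(
    "<trandaug_model> %d-class recognizer (%s features f=%d -> SS-TCN %d layers)\n",
    length(x$class_names), x$extractor$variant, x$extractor$feature_dim,
    x$tcn$n_layers))
  cat(sprintf("trained %d epoch(s), augment mode '%s'; best epoch %d (val F1 %.4f)\n",
              nrow(x$history), x$config$augment_mode, x$best_epoch,
              x$val_report$aggregate[["F1"]]))
  invisible(x)
}

#' @export
summary.trandaug_model <- function(object, ...) {
  print(object)
  cat("\nclasses:", paste(object$class_names, collapse = ", "), "\n")
  cat("class weights:", paste(sprintf("%.3f", object$class_weights),
                              collapse = ", "), "\n")
  cat(sprintf("receptive field: %d frames\n", object$tcn$receptive_field))
  cat("\ntraining history (last 5 epochs):\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  cat("\nvalidation report at selected epoch:\n")
  print(object$val_report)
  invisible(object)
}

#' @export
coef.trandaug_model <- function(object, ...) object$params

#' Predict frame-wise activity labels
#'
#' @param object A fitted [train_recognizer()] model.
#' @param newdata A [video_sample()], a list of them, or a
#'   [dataset_manifest()] (with `split` selecting the videos to score).
#' @param split Manifest split to score when `newdata` is a manifest.
#' @param ... Unused.
#' @return A `"frame_predictions"` for a single video, otherwise a named
#'   list of them.
#' @export
predict.trandaug_model <- function(object, newdata, split = "test", ...) {
  target <- object$extractor$input_size
  if (inherits(newdata, "dataset_manifest")) {
    newdata <- load_split(newdata, split, target_size = target)
  }
  single <- inherits(newdata, "video_sample")
  if (single) newdata <- list(newdata)
  preds <- lapply(newdata, predict_video, extractor = object$extractor,
                  params = object$params, tcn = object$tcn,
                  target_size = target)
  names(preds) <- vapply(newdata, `[[`, character(1), "video_id")
  if (single) preds[[1]] else preds
}

#' Evaluate a fitted model on a manifest split
#'
#' Convenience wrapper: scores every video of a split and runs the
#' per-video macro-averaged protocol.
#'
#' @inheritParams predict.trandaug_model
#' @param manifest A [dataset_manifest()].
#' @return A `"metric_report"`.
#' @export
evaluate_model <- function(object, manifest, split = "test") {
  stopifnot(inherits(object, "trandaug_model"))
  videos <- load_split(manifest, split,
                       target_size = object$extractor$input_size)
  if (length(videos) == 0L) stop("split '", split, "' is empty")
  preds <- predict(object, videos)
  truths <- lapply(videos, `[[`, "labels")
  names(truths) <- names(preds)
  evaluate_predictions(preds, truths)
}

#' @export
plot.trandaug_model <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$loss, type = "b", xlab = "epoch",
                 ylab = "training loss", main = "loss", ...)
  graphics::plot(h$epoch, h$val_F1, type = "b", xlab = "epoch",
                 ylab = "validation F1", main = "validation F1",
                 ylim = c(0, 1), ...)
  graphics::abline(v = x$best_epoch, lty = 2)
  invisible(x)
}

#' Save or load a model checkpoint
#'
#' Checkpoints are plain RDS serializations of the fitted object.
#'
#' @param object A `"trandaug_model"`.
#' @param path File path.
#' @export
save_checkpoint <- function(object, path) {
  stopifnot(inherits(object, "trandaug_model"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "trandaug_model")) stop("not a trandaug_model checkpoint")
  obj
}
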