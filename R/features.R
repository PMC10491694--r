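#' Specify the per-frame visual feature extractor
#'
#' The spatiotemporal model is a per-frame visual backbone feeding a causal
#' temporal network. Two variants are supported:
#'
#' * `"tiny"` -- a small, deterministic, seeded random-feature CNN
#'   (strided 3x3 convolutions with fixed random filters, ReLU, global
#'   average/max pooling plus raw channel statistics, followed by a fixed
#'   random projection to `feature_dim`). It is untrained and frozen; it
#'   exists so the temporal model can be trained and tested on any machine
#'   with no downloaded weights. Random-feature convolutions preserve the
#'   color/texture statistics the synthetic videos (and the augmentations)
#'   manipulate, which is all the temporal head needs.
#' * `"resnet50"` -- a placeholder for a full 2048-dimensional residual
#'   backbone. No pretrained weights ship with this package; supply the
#'   per-frame feature function yourself via `fun` (e.g. wrapping an
#'   external runtime) and it will be used verbatim.
#'
#' @param variant `"tiny"` or `"resnet50"`.
#' @param feature_dim Output feature size `f` per frame (2048 for the full
#'   backbone; default 32 for the tiny variant).
#' @param input_size Expected `c(H, W)` frame size. Frames of any other
#'   size raise an error at extraction time.
#' @param n_filters Number of random convolution filters (tiny variant).
#' @param seed Seed fixing the tiny variant's random filters/projection.
#' @param fun Optional function `frame -> numeric(feature_dim)` implementing
#'   the backbone (required for `"resnet50"`).
#' @return An object of class `"feature_extractor_spec"` with the frozen
#'   weights materialized.
#' @export
feature_extractor_spec <- function(variant = c("tiny", "resnet50"),
                                   feature_dim = NULL,
                                   input_size = c(224, 224),
                                   n_filters = 8, seed = 1L, fun = NULL) {
  variant <- match.arg(variant)
  if (is.null(feature_dim)) {
    feature_dim <- if (variant == "tiny") 32L else 2048L
  }
  spec <- list(variant = variant, feature_dim = as.integer(feature_dim),
               input_size = as.integer(input_size),
               n_filters = as.integer(n_filters), seed = as.integer(seed),
               fun = fun)
  if (variant == "tiny") {
    # frozen weights drawn once at spec construction
    spec$weights <- with_stream(derive_seed(seed, "tiny-extractor"), {
      k <- spec$n_filters
      d_raw <- 2L * k + 6L   # mean+max pool per filter, channel means + sds
      list(
        filters = array(stats::rnorm(3 * 3 * 3 * k, sd = 0.5), c(3, 3, 3, k)),
        bias = stats::rnorm(k, sd = 0.1),
        proj = matrix(stats::rnorm(d_raw * feature_dim, sd = 1 / sqrt(d_raw)),
                      d_raw, feature_dim)
      )
    })
  } else if (is.null(fun)) {
    # constructed lazily-erroring so tests can still build the spec
    spec$weights <- NULL
  }
  structure(spec, class = "feature_extractor_spec")
}

#' @export
print.feature_extractor_spec <- function(x, ...) {
  cat(sprintf("<feature_extractor_spec> %s: f=%d, input %dx%d\n",
              x$variant, x$feature_dim, x$input_size[1], x$input_size[2]))
  invisible(x)
}

# valid 3x3 convolution, stride 2, over one frame; returns (h' x w' x k)
conv3x3_s2 <- function(frame, filters, bias) {
  d <- dim(frame)
  rows <- seq.int(1L, d[1] - 2L, by = 2L)
  cols <- seq.int(1L, d[2] - 2L, by = 2L)
  k <- dim(filters)[4]
  out <- array(0, c(length(rows), length(cols), k))
  for (f in seq_len(k)) {
    acc <- matrix(bias[f], length(rows), length(cols))
    for (dy in 0:2) for (dx in 0:2) for (ch in 1:3) {
      acc <- acc + filters[dy + 1, dx + 1, ch, f] *
        frame[rows + dy, cols + dx, ch]
    }
    out[, , f] <- acc
  }
  out
}

tiny_features <- function(frame, spec) {
  wts <- spec$weights
  a <- conv3x3_s2(frame, wts$filters, wts$bias)
  a[a < 0] <- 0
  k <- dim(a)[3]
  pooled <- c(apply(a, 3, mean), apply(a, 3, max))
  chan <- c(apply(frame, 3, mean), apply(frame, 3, stats::sd))
  as.numeric(c(pooled, chan) %*% wts$proj)
}

#' Extract per-frame visual features
#'
#' Runs the configured backbone over every frame, in order, and returns the
#' stacked feature matrix. Extraction is deterministic: identical frames
#' yield identical feature vectors.
#'
#' @param frames A list of frames or a [video_sample()], each frame sized
#'   to `spec$input_size`.
#' @param spec A [feature_extractor_spec()].
#' @return A numeric matrix with one row per frame and
#'   `spec$feature_dim` columns.
#' @export
extract_features <- function(frames, spec) {
  stopifnot(inherits(spec, "feature_extractor_spec"))
  if (inherits(frames, "video_sample")) frames <- frames$frames
  if (length(frames) == 0L) stop("no frames to extract features from")
  for (fr in frames) {
    d <- dim(fr)
    if (d[1] != spec$input_size[1] || d[2] != spec$input_size[2]) {
      stop("frame is ", d[1], "x", d[2], " but extractor expects ",
           spec$input_size[1], "x", spec$input_size[2])
    }
  }
  fn <- switch(spec$variant,
    tiny = function(fr) tiny_features(fr, spec),
    resnet50 = {
      if (is.null(spec$fun)) {
        stop("the full residual backbone ships no weights; supply its ",
             "per-frame feature function via feature_extractor_spec(fun = ...)")
      }
      spec$fun
    })
  out <- t(vapply(frames, fn, numeric(spec$feature_dim)))
  dimnames(out) <- NULL
  out
}

#' Per-video feature buffer
#'
#' During training the temporal network needs the features of all past
#' frames of the current video: they are cached in a feature buffer which
#' is append-only within a video and reset at the end of each video.
#' Buffered features are treated as constants by the optimizer.
#'
#' @param video_id Identifier of the video being buffered.
#' @param feature_dim Feature size `f`.
#' @return An object of class `"feature_buffer"`.
#' @export
feature_buffer <- function(video_id = "video", feature_dim) {
  env <- new.env(parent = emptyenv())
  env$video_id <- video_id
  env$feature_dim <- as.integer(feature_dim)
  env$features <- matrix(numeric(0), 0, feature_dim)
  class(env) <- "feature_buffer"
  env
}

#' @rdname feature_buffer
#' @param buffer A `"feature_buffer"`.
#' @param features Matrix of new rows (frames in order) to append.
#' @export
buffer_append <- function(buffer, features) {
  stopifnot(inherits(buffer, "feature_buffer"))
  features <- rbind(features)
  if (ncol(features) != buffer$feature_dim) {
    stop("feature dimension mismatch: got ", ncol(features), ", buffer holds ",
         buffer$feature_dim)
  }
  buffer$features <- rbind(buffer$features, features)
  invisible(buffer)
}

#' @rdname feature_buffer
#' @export
buffer_reset <- function(buffer) {
  stopifnot(inherits(buffer, "feature_buffer"))
  buffer$features <- matrix(numeric(0), 0, buffer$feature_dim)
  invisible(buffer)
}

#' @rdname feature_buffer
#' @export
buffer_features <- function(buffer) {
  stopifnot(inherits(buffer, "feature_buffer"))
  buffer$features
}

#' @export
print.feature_buffer <- function(x, ...) {
  cat(sprintf("<feature_buffer> '%s': %d frame(s) of f=%d cached\n",
              x$video_id, nrow(x$features), x$feature_dim))
  invisible(x)
}
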