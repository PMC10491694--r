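#' Specify a synthetic surgical-like video dataset
#'
#' The generator emulates the structure that makes long surgical videos
#' distinctive for recognition work: each video is a sequence of contiguous
#' activity segments (phases/steps), every activity has a persistent visual
#' signature, and frames carry pixel noise. Signatures are flat base colors
#' modulated by a class-specific low-frequency sinusoidal texture, so both
#' photometric transforms (color shifts) and geometric transforms (which
#' move the texture) have measurable effects.
#'
#' @param n_videos Number of videos.
#' @param n_classes Number of activity classes.
#' @param frames_per_video Frames per video (`>= n_classes *
#'   min_segment_len` is not required, but `>= min_segment_len` is).
#' @param min_segment_len Minimum length, in frames, of a contiguous
#'   activity run.
#' @param size `c(H, W)` frame size.
#' @param noise_sd I.i.d. Gaussian pixel noise standard deviation, in
#'   `[0, 1]` pixel units.
#' @param seed Seed; the whole dataset is deterministic given the spec.
#' @return An object of class `"synth_spec"`. Class signatures (base color
#'   and texture frequency) are materialized in `$signatures`.
#' @export
synth_spec <- function(n_videos = 10, n_classes = 3, frames_per_video = 60,
                       min_segment_len = 10, size = c(64, 64),
                       noise_sd = 0.05, seed = 1L) {
  if (n_videos < 1 || n_classes < 1) stop("need >= 1 video and class")
  if (min_segment_len < 1) stop("min_segment_len must be >= 1")
  if (frames_per_video < min_segment_len) {
    stop("frames_per_video must be >= min_segment_len")
  }
  if (noise_sd < 0 || noise_sd > 1) stop("noise_sd must be in [0, 1]")
  # distinct, well-separated hues around the color wheel; frequency grows
  # with the class id so no two signatures coincide
  hues <- (seq_len(n_classes) - 1) / n_classes
  colors <- t(grDevices::col2rgb(grDevices::hsv(hues, s = 0.6, v = 0.7)) / 255)
  signatures <- lapply(seq_len(n_classes), function(k) {
    list(color = colors[k, ], freq = 1 + (k - 1))
  })
  structure(list(n_videos = as.integer(n_videos),
                 n_classes = as.integer(n_classes),
                 frames_per_video = as.integer(frames_per_video),
                 min_segment_len = as.integer(min_segment_len),
                 size = as.integer(size), noise_sd = noise_sd,
                 seed = as.integer(seed), signatures = signatures),
            class = "synth_spec")
}

#' @export
print.synth_spec <- function(x, ...) {
  cat(sprintf(
    "<synth_spec> %d videos x %d frames of %dx%d, %d classes (runs >= %d frames), noise sd %g, seed %d\n",
    x$n_videos, x$frames_per_video, x$size[1], x$size[2], x$n_classes,
    x$min_segment_len, x$noise_sd, x$seed))
  invisible(x)
}

# one noiseless signature frame for class k (0-based)
signature_frame <- function(spec, class_id) {
  sig <- spec$signatures[[class_id + 1L]]
  h <- spec$size[1]; w <- spec$size[2]
  tex <- 0.15 * sin(2 * pi * sig$freq * (seq_len(w) - 1) / w)
  tex <- matrix(tex, h, w, byrow = TRUE)
  out <- array(0, c(h, w, 3))
  for (ch in 1:3) out[, , ch] <- clip01(sig$color[ch] + tex)
  out
}

# contiguous label runs, each >= min_segment_len, consecutive runs differ
sample_label_runs <- function(spec) {
  n <- spec$frames_per_video
  max_runs <- n %/% spec$min_segment_len
  r <- sample.int(max_runs, 1L)
  # distribute the slack over the r runs uniformly at random
  slack <- n - r * spec$min_segment_len
  extra <- if (r == 1L) slack else {
    tab <- tabulate(sample.int(r, slack, replace = TRUE), nbins = r)
    tab
  }
  lens <- spec$min_segment_len + extra
  cls <- integer(r)
  cls[1] <- sample.int(spec$n_classes, 1L) - 1L
  for (i in seq_len(r - 1L)) {
    pool <- setdiff(seq_len(spec$n_classes) - 1L, cls[i])
    cls[i + 1L] <- if (length(pool)) pool[sample.int(length(pool), 1L)]
                   else cls[i]
  }
  rep.int(cls, lens)
}

#' Generate one synthetic video
#'
#' Labels form contiguous runs of at least `min_segment_len` frames;
#' each frame renders its class signature plus i.i.d. Gaussian pixel noise
#' (clipped to `[0, 1]`). Deterministic given the spec seed and index.
#'
#' @param spec A [synth_spec()].
#' @param index Video index (`1..n_videos`), used to decorrelate videos.
#' @return A [video_sample()] with labels.
#' @export
generate_video <- function(spec, index = 1L) {
  stopifnot(inherits(spec, "synth_spec"))
  with_stream(derive_seed(spec$seed, "video", index), {
    labels <- sample_label_runs(spec)
    bases <- lapply(seq_len(spec$n_classes) - 1L, signature_frame,
                    spec = spec)
    frames <- lapply(labels, function(k) {
      fr <- bases[[k + 1L]]
      if (spec$noise_sd > 0) {
        fr <- clip01(fr + array(stats::rnorm(length(fr), sd = spec$noise_sd),
                                dim(fr)))
      }
      fr
    })
    video_sample(frames, labels = labels, fps = 1,
                 video_id = sprintf("synth_%03d", index))
  })
}

#' Generate and materialize a synthetic dataset
#'
#' Writes `n_videos` synthetic videos as PNG frame directories with label
#' CSVs plus a JSON manifest (60/20/20 train/val/test split by video), in
#' the formats [load_frames()], [load_labels()] and [read_manifest()]
#' consume. Every class is guaranteed to appear at least once in the
#' dataset: if a class is absent after sampling, the first run of the
#' first video is relabelled to it (deterministically).
#'
#' @param spec A [synth_spec()].
#' @param out_dir Output directory (created if needed).
#' @return The `"dataset_manifest"`, invisibly written to
#'   `file.path(out_dir, "manifest.json")`.
#' @export
generate_dataset <- function(spec, out_dir) {
  stopifnot(inherits(spec, "synth_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  videos <- lapply(seq_len(spec$n_videos), generate_video, spec = spec)

  seen <- sort(unique(unlist(lapply(videos, `[[`, "labels"))))
  missing <- setdiff(seq_len(spec$n_classes) - 1L, seen)
  for (idx in seq_along(missing)) {
    # deterministically relabel the idx-th run of the first video
    v <- videos[[1]]
    runs <- rle(v$labels)
    runs$values[min(idx, length(runs$values))] <- missing[idx]
    new_labels <- inverse.rle(runs)
    videos[[1]]$labels <- new_labels
    videos[[1]]$frames <- lapply(new_labels, function(k) {
      base <- signature_frame(spec, k)
      base  # relabelled frames are rendered noiseless for consistency
    })
  }

  n <- spec$n_videos
  n_train <- max(1L, floor(0.6 * n))
  n_val <- max(1L, floor(0.2 * n))
  if (n_train + n_val >= n) {
    n_train <- max(1L, n - 2L)
    n_val <- if (n - n_train >= 2L) 1L else 0L
  }
  split <- rep("test", n)
  split[seq_len(n_train)] <- "train"
  if (n_val > 0) split[n_train + seq_len(n_val)] <- "val"

  entries <- data.frame(video_id = character(n), frames = character(n),
                        labels = character(n), split = split,
                        stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    v <- videos[[i]]
    fdir <- file.path(out_dir, v$video_id)
    write_frames(v$frames, fdir)
    lpath <- file.path(out_dir, paste0(v$video_id, "_labels.csv"))
    write_labels(v$labels, lpath)
    entries$video_id[i] <- v$video_id
    entries$frames[i] <- fdir
    entries$labels[i] <- lpath
  }
  manifest <- dataset_manifest(
    entries, class_names = paste0("activity_", seq_len(spec$n_classes) - 1L))
  write_manifest(manifest, file.path(out_dir, "manifest.json"))
  manifest
}
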