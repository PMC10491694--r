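#' Construct an in-memory video sample
#'
#' A video sample is the unit the whole package operates on: an ordered
#' sequence of RGB frames \eqn{x_{1:\Upsilon}} with optional frame-wise
#' integer class labels \eqn{y_{1:\Upsilon}} (0-based class ids) and
#' minimal metadata.
#'
#' @param frames List of numeric `H x W x 3` arrays, all the same size.
#' @param labels Optional integer vector, one 0-based class id per frame.
#' @param fps Sampling rate of the stored frames (frames per second).
#' @param video_id Identifier string.
#' @return An object of class `"video_sample"`.
#' @export
video_sample <- function(frames, labels = NULL, fps = 1, video_id = "video") {
  if (!is.list(frames) || length(frames) < 1L) {
    stop("frames must be a non-empty list of H x W x 3 arrays")
  }
  lapply(frames, check_rgb_frame)
  dims <- vapply(frames, function(f) dim(f)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all frames must share identical dimensions")
  }
  if (!is.null(labels)) {
    if (length(labels) != length(frames)) {
      stop("labels length (", length(labels), ") must equal frame count (",
           length(frames), ")")
    }
    labels <- as.integer(labels)
  }
  structure(list(frames = frames, labels = labels, fps = fps,
                 video_id = video_id),
            class = "video_sample")
}

#' @export
print.video_sample <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<video_sample> '%s': %d frames of %dx%d @ %g fps%s\n",
              x$video_id, length(x$frames), d[1], d[2], x$fps,
              if (is.null(x$labels)) "" else
                sprintf(", %d classes labelled",
                        length(unique(x$labels)))))
  invisible(x)
}

#' @export
length.video_sample <- function(x) length(x$frames)

# Bilinear resize (plain stretch, no aspect preservation) to target (H, W).
resize_frame <- function(frame, target_size) {
  d <- dim(frame)
  if (d[1] == target_size[1] && d[2] == target_size[2]) return(frame)
  h <- target_size[1]; w <- target_size[2]
  # map output pixel centers onto input pixel centers
  sy <- if (h == 1) (d[1] + 1) / 2 else 1 + (seq_len(h) - 1) * (d[1] - 1) / (h - 1)
  sx <- if (w == 1) (d[2] + 1) / 2 else 1 + (seq_len(w) - 1) * (d[2] - 1) / (w - 1)
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0;   fx <- sx - x0
  y1 <- pmin(y0 + 1, d[1]); x1 <- pmin(x0 + 1, d[2])
  out <- array(0, c(h, w, 3))
  for (ch in 1:3) {
    p <- frame[, , ch]
    a <- p[y0, x0, drop = FALSE] * (1 - fy) + p[y1, x0, drop = FALSE] * fy
    b <- p[y0, x1, drop = FALSE] * (1 - fy) + p[y1, x1, drop = FALSE] * fy
    out[, , ch] <- a * (1 - matrix(fx, h, w, byrow = TRUE)) +
                   b * matrix(fx, h, w, byrow = TRUE)
  }
  out
}

#' Load a frame sequence from a directory of images
#'
#' Reads the PNG (or JPEG) frames of one video in filename order,
#' temporally subsamples them from `fps_in` to `fps_out` by keeping every
#' `round(fps_in / fps_out)`-th frame starting at index 0 (the convention
#' used when extracting surgical videos at 1 fps), and stretches each frame
#' to `target_size` with bilinear interpolation (default 224 x 224, the
#' backbone's input size).
#'
#' @param path Directory containing the frames.
#' @param target_size `c(H, W)` output size, or `NULL` to keep the stored
#'   size.
#' @param fps_in Frame rate of the stored frames.
#' @param fps_out Desired frame rate after subsampling (`<= fps_in`).
#' @param labels_path Optional label CSV to attach (see [load_labels()]);
#'   labels are subsampled with the same stride.
#' @param video_id Identifier; defaults to the directory name.
#' @return A [video_sample()].
#' @export
load_frames <- function(path, target_size = c(224, 224), fps_in = 1,
                        fps_out = 1, labels_path = NULL, video_id = NULL) {
  if (!dir.exists(path)) stop("frame directory not found: ", path)
  if (!is.numeric(fps_in) || !is.numeric(fps_out) || fps_in <= 0 ||
      fps_out <= 0) {
    stop("fps values must be positive")
  }
  if (fps_out > fps_in) stop("fps_out must be <= fps_in")
  files <- sort(list.files(path, pattern = "\\.(png|jpe?g)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L) stop("no PNG/JPEG frames found in ", path)
  stride <- max(1L, as.integer(round(fps_in / fps_out)))
  keep <- seq.int(1L, length(files), by = stride)
  read_one <- function(f) {
    img <- if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
           else jpeg_read(f)
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
    if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
    if (!is.null(target_size)) img <- resize_frame(img, target_size)
    img
  }
  frames <- lapply(files[keep], read_one)
  labels <- NULL
  if (!is.null(labels_path)) {
    labels <- load_labels(labels_path, n_frames = length(files))[keep]
  }
  video_sample(frames, labels = labels, fps = fps_out,
               video_id = if (is.null(video_id)) basename(path) else video_id)
}

# isolated so the jpeg package stays an undeclared soft dependency; the
# package's own writers only emit PNG
jpeg_read <- function(f) {
  if (!requireNamespace("jpeg", quietly = TRUE)) {
    stop("reading JPEG frames requires the 'jpeg' package")
  }
  jpeg::readJPEG(f)
}

#' Write a frame sequence as zero-padded PNGs
#'
#' Writes `frame_000000.png`, `frame_000001.png`, ... into `path`
#' (created if needed). PNG storage is lossless after 8-bit quantization,
#' so `load_frames(write_frames(x))` round-trips pixel-identically for
#' frames whose values are already multiples of 1/255.
#'
#' @param frames A list of frames or a [video_sample()].
#' @param path Output directory.
#' @return Invisibly, the written file paths.
#' @export
write_frames <- function(frames, path) {
  if (inherits(frames, "video_sample")) frames <- frames$frames
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  files <- file.path(path, sprintf("frame_%06d.png", seq_along(frames) - 1L))
  for (i in seq_along(frames)) {
    png::writePNG(clip01(frames[[i]]), files[i])
  }
  invisible(files)
}

#' Load frame-wise labels from CSV
#'
#' Labels are stored one CSV per video with columns `frame_index`
#' (0-based) and `class_id` (0-based integer). Every frame index in
#' `[0, n_frames)` must be present exactly once.
#'
#' @param path CSV file path.
#' @param n_frames Expected number of frames.
#' @param n_classes Optional class count; ids outside `[0, n_classes)`
#'   raise an error.
#' @return Integer vector of length `n_frames`.
#' @export
load_labels <- function(path, n_frames, n_classes = NULL) {
  if (!file.exists(path)) stop("label file not found: ", path)
  df <- utils::read.csv(path)
  if (!all(c("frame_index", "class_id") %in% names(df))) {
    stop("label CSV must have columns frame_index, class_id")
  }
  if (nrow(df) != n_frames ||
      !setequal(df$frame_index, seq_len(n_frames) - 1L)) {
    stop("label CSV must enumerate every frame index 0..", n_frames - 1L,
         " exactly once (got ", nrow(df), " rows)")
  }
  df <- df[order(df$frame_index), ]
  labels <- as.integer(df$class_id)
  if (anyNA(labels)) stop("non-integer class_id in ", path)
  if (!is.null(n_classes) && any(labels < 0L | labels >= n_classes)) {
    stop("class_id outside [0, ", n_classes, ") in ", path)
  }
  labels
}

#' @rdname load_labels
#' @param labels Integer vector of 0-based class ids.
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(
    data.frame(frame_index = seq_along(labels) - 1L,
               class_id = as.integer(labels)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Dataset manifests
#'
#' A manifest lists the videos of a dataset: for each, an id, the frame
#' directory, the label CSV and its split (`train`, `val` or `test`),
#' plus the ordered class names. Stored as JSON or YAML.
#'
#' @param entries Data frame with columns `video_id`, `frames`, `labels`,
#'   `split`.
#' @param class_names Character vector; class id `k` (0-based) is
#'   `class_names[k + 1]`.
#' @return An object of class `"dataset_manifest"`.
#' @export
dataset_manifest <- function(entries, class_names) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  need <- c("video_id", "frames", "labels", "split")
  if (!all(need %in% names(entries))) {
    stop("manifest entries need columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(entries$video_id)) stop("video_ids must be unique")
  bad <- setdiff(unique(entries$split), c("train", "val", "test"))
  if (length(bad)) stop("unknown split(s): ", paste(bad, collapse = ", "))
  structure(list(entries = entries[need],
                 class_names = as.character(class_names)),
            class = "dataset_manifest")
}

#' @export
print.dataset_manifest <- function(x, ...) {
  tab <- table(factor(x$entries$split, c("train", "val", "test")))
  cat(sprintf(
    "<dataset_manifest> %d videos (train %d / val %d / test %d), %d classes: %s\n",
    nrow(x$entries), tab["train"], tab["val"], tab["test"],
    length(x$class_names), paste(x$class_names, collapse = ", ")))
  invisible(x)
}

#' @rdname dataset_manifest
#' @param manifest A `"dataset_manifest"`.
#' @param path File path (`.json`, `.yaml` or `.yml`).
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  lst <- list(class_names = manifest$class_names,
              entries = manifest$entries)
  if (grepl("\\.ya?ml$", path)) {
    lst$entries <- lapply(seq_len(nrow(manifest$entries)),
                          function(i) as.list(manifest$entries[i, ]))
    yaml::write_yaml(lst, path)
  } else {
    jsonlite::write_json(lst, path, dataframe = "rows", auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname dataset_manifest
#' @export
read_manifest <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) {
    l <- yaml::read_yaml(path)
    l$entries <- do.call(rbind, lapply(l$entries, as.data.frame))
    l
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  dataset_manifest(lst$entries, unlist(lst$class_names))
}

# Convenience: load every video of one split, with labels, at stored size.
load_split <- function(manifest, split, target_size = NULL) {
  idx <- which(manifest$entries$split == split)
  lapply(idx, function(i) {
    e <- manifest$entries[i, ]
    load_frames(e$frames, target_size = target_size,
                labels_path = e$labels, video_id = e$video_id)
  })
}
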