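#' Define a single image transformation
#'
#' A transform spec describes one member of the transform set \eqn{\tau}:
#' its parameter range over the integer magnitude scale 0--30, whether its
#' direction is randomized (signed), and whether it is geometric or
#' photometric.
#'
#' @param name Transform identifier. One of the names understood by
#'   [apply_transform()]: `"rotate"`, `"translate_x"`, `"translate_y"`,
#'   `"shear_x"`, `"shear_y"`, `"horizontal_flip"`, `"brightness"`,
#'   `"contrast"`, `"saturation"`, `"sharpness"`.
#' @param param_min,param_max Parameter value at magnitude 0 and 30
#'   respectively, in transform-specific units (degrees for rotation,
#'   fraction of the image extent for translation, shear factor, or an
#'   enhancement factor for the photometric transforms).
#' @param signed Should a random direction sign be sampled when the
#'   transform is drawn? For geometric transforms the sign multiplies the
#'   parameter; for enhancement-factor transforms a negative sign mirrors
#'   the factor below 1 (factor `f` becomes `2 - f`).
#' @param kind `"geometric"` or `"photometric"`.
#' @param identity_at_zero Is `param_min` the identity point of the
#'   transform (so magnitude 0 leaves frames pixel-identical)?
#'
#' @return An object of class `"transform_spec"`.
#' @seealso [default_transform_bank()], [scale_magnitude()], [apply_transform()]
#' @export
transform_spec <- function(name, param_min, param_max, signed, kind,
                           identity_at_zero = TRUE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  kind <- match.arg(kind, c("geometric", "photometric"))
  param_min <- as.numeric(param_min)
  param_max <- as.numeric(param_max)
  if (param_min > param_max) {
    stop("param_min must be <= param_max for transform '", name, "'")
  }
  structure(
    list(name = name, param_min = param_min, param_max = param_max,
         signed = isTRUE(signed), kind = kind,
         identity_at_zero = isTRUE(identity_at_zero)),
    class = "transform_spec"
  )
}

#' @export
print.transform_spec <- function(x, ...) {
  cat(sprintf("<transform_spec> %s (%s): param in [%g, %g]%s%s\n",
              x$name, x$kind, x$param_min, x$param_max,
              if (x$signed) ", signed" else "",
              if (x$identity_at_zero) ", identity at M=0" else ""))
  invisible(x)
}

#' Assemble a transform bank
#'
#' A transform bank is an ordered collection of [transform_spec()] entries
#' with unique names; subsets \eqn{\tau' \subset \tau} are selected by name.
#'
#' @param specs A list of `transform_spec` objects.
#' @return An object of class `"transform_bank"`.
#' @export
transform_bank <- function(specs) {
  if (!is.list(specs) || length(specs) == 0L ||
      !all(vapply(specs, inherits, logical(1), "transform_spec"))) {
    stop("specs must be a non-empty list of transform_spec objects")
  }
  nm <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("transform names must be unique")
  names(specs) <- nm
  structure(specs, class = "transform_bank")
}

#' @export
print.transform_bank <- function(x, ...) {
  cat(sprintf("<transform_bank> %d transforms:\n", length(x)))
  for (s in x) {
    cat(sprintf("  %-16s %-12s [%g, %g]%s\n", s$name, s$kind,
                s$param_min, s$param_max, if (s$signed) " signed" else ""))
  }
  invisible(x)
}

#' The default transform set
#'
#' The default bank contains the ten transformations used for augmenting
#' endoscopic video: five geometric (rotation, horizontal/vertical
#' translation, horizontal/vertical shear), a horizontal flip, and four
#' photometric enhancements (brightness, contrast, saturation, sharpness).
#' Pixel-histogram transforms that produce frames unlike anything seen in
#' surgical video (posterize, solarize, equalize) are deliberately absent.
#'
#' Parameter ranges over the magnitude scale: rotation 0--30 degrees,
#' translations 0--0.3 of the image extent, shears 0--0.3, enhancement
#' factors 1.0--1.9. The horizontal flip is parameter-free (its magnitude
#' is ignored and it is not an identity at M = 0).
#'
#' @return A `"transform_bank"` with 10 entries.
#' @export
default_transform_bank <- function() {
  transform_bank(list(
    transform_spec("rotate",          0,   30,  TRUE,  "geometric"),
    transform_spec("translate_x",     0,   0.3, TRUE,  "geometric"),
    transform_spec("translate_y",     0,   0.3, TRUE,  "geometric"),
    transform_spec("shear_x",         0,   0.3, TRUE,  "geometric"),
    transform_spec("shear_y",         0,   0.3, TRUE,  "geometric"),
    transform_spec("horizontal_flip", 0,   0,   FALSE, "geometric",
                   identity_at_zero = FALSE),
    transform_spec("brightness",      1.0, 1.9, TRUE,  "photometric"),
    transform_spec("contrast",        1.0, 1.9, TRUE,  "photometric"),
    transform_spec("saturation",      1.0, 1.9, TRUE,  "photometric"),
    transform_spec("sharpness",       1.0, 1.9, TRUE,  "photometric")
  ))
}

#' Map an integer magnitude onto a transform's parameter range
#'
#' The strength of every transform is controlled by a single shared
#' magnitude \eqn{M} on an integer scale 0--30, linearly mapped onto the
#' transform's `[param_min, param_max]` range:
#' \deqn{p(M) = p_{min} + \frac{M}{30} (p_{max} - p_{min}).}
#' For signed transforms the caller additionally samples a direction sign;
#' the scaling itself is always toward `param_max`.
#'
#' @param spec A [transform_spec()].
#' @param M Magnitude in `[0, 30]`.
#' @return The resolved parameter value (numeric scalar).
#' @examples
#' bank <- default_transform_bank()
#' scale_magnitude(bank$rotate, 0)       # 0 degrees
#' scale_magnitude(bank$rotate, 30)      # 30 degrees
#' scale_magnitude(bank$brightness, 15)  # factor 1.45
#' @export
scale_magnitude <- function(spec, M) {
  stopifnot(inherits(spec, "transform_spec"))
  if (!is.numeric(M) || length(M) != 1L || is.na(M) || M < 0 || M > 30) {
    stop("magnitude M must be a number in [0, 30]")
  }
  spec$param_min + (M / 30) * (spec$param_max - spec$param_min)
}

# ---- transform application --------------------------------------------------

check_rgb_frame <- function(frame) {
  if (!is.array(frame) || length(dim(frame)) != 3L || dim(frame)[3] != 3L ||
      !is.numeric(frame)) {
    stop("frame must be a numeric H x W x 3 RGB array")
  }
  invisible(frame)
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Inverse-map affine resampling with bilinear interpolation and
# edge-replicate fill. `inv` maps centered output coords (dx, dy) to
# centered source coords; rows index y (top-down), columns x.
affine_resample <- function(frame, inv) {
  d <- dim(frame)
  h <- d[1]; w <- d[2]
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  dx <- matrix(seq_len(w) - cx, h, w, byrow = TRUE)
  dy <- matrix(seq_len(h) - cy, h, w)
  src <- inv(dx, dy)
  sx <- src$x + cx
  sy <- src$y + cy
  # edge replication: clamp source coordinates to the image
  sx <- pmin(pmax(sx, 1), w)
  sy <- pmin(pmax(sy, 1), h)
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0;   fy <- sy - y0
  x1 <- pmin(x0 + 1, w); y1 <- pmin(y0 + 1, h)
  i00 <- cbind(as.vector(y0), as.vector(x0))
  i01 <- cbind(as.vector(y0), as.vector(x1))
  i10 <- cbind(as.vector(y1), as.vector(x0))
  i11 <- cbind(as.vector(y1), as.vector(x1))
  w00 <- as.vector((1 - fy) * (1 - fx))
  w01 <- as.vector((1 - fy) * fx)
  w10 <- as.vector(fy * (1 - fx))
  w11 <- as.vector(fy * fx)
  out <- frame
  for (ch in 1:3) {
    plane <- frame[, , ch]
    out[, , ch] <- matrix(
      w00 * plane[i00] + w01 * plane[i01] + w10 * plane[i10] + w11 * plane[i11],
      h, w)
  }
  out
}

# Photometric blend: out = img + (f - 1) * (img - base). Written this way so
# that f == 1 returns the input bit-exactly.
blend_toward <- function(frame, base, f) {
  clip01(frame + (f - 1) * (frame - base))
}

# 3x3 smoothing with edge-replicate padding (kernel [1 1 1; 1 5 1; 1 1 1]/13),
# used as the "soft" anchor image for the sharpness enhancement.
smooth3x3 <- function(frame) {
  d <- dim(frame); h <- d[1]; w <- d[2]
  up <- c(1, seq_len(h - 1)); down <- c(seq_len(h - 1) + 1, h)
  left <- c(1, seq_len(w - 1)); right <- c(seq_len(w - 1) + 1, w)
  out <- frame
  for (ch in 1:3) {
    p <- frame[, , ch]
    out[, , ch] <- (p[up, left] + p[up, ] + p[up, right] +
                    p[, left] + 5 * p + p[, right] +
                    p[down, left] + p[down, ] + p[down, right]) / 13
  }
  out
}

luminance <- function(frame) {
  0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
}

#' Apply one transformation to a frame
#'
#' Applies a single transform at a resolved parameter value to an RGB frame.
#' Geometric transforms use bilinear interpolation with edge-replicate fill
#' (black borders do not occur in endoscopic video, so none are introduced);
#' photometric transforms blend the frame toward an anchor image (black,
#' mean gray, per-pixel gray, or a smoothed copy) and clip to `[0, 1]`.
#' The input frame is never modified and the output always has the same
#' dimensions.
#'
#' @param frame Numeric `H x W x 3` array with values in `[0, 1]`.
#' @param spec A [transform_spec()].
#' @param param Resolved parameter, normally from [scale_magnitude()].
#' @param sign Direction sign, `+1` or `-1`. Ignored for unsigned
#'   transforms. For enhancement factors, `-1` mirrors the factor below 1.
#' @return A new `H x W x 3` array.
#' @export
apply_transform <- function(frame, spec, param, sign = 1) {
  stopifnot(inherits(spec, "transform_spec"))
  check_rgb_frame(frame)
  if (!is.numeric(param) || length(param) != 1L || is.na(param) ||
      param < spec$param_min - 1e-12 || param > spec$param_max + 1e-12) {
    stop("resolved parameter ", param, " outside [", spec$param_min, ", ",
         spec$param_max, "] for transform '", spec$name, "'")
  }
  if (!sign %in% c(-1, 1)) stop("sign must be +1 or -1")
  s <- if (spec$signed) sign else 1
  d <- dim(frame); h <- d[1]; w <- d[2]
  switch(spec$name,
    rotate = {
      if (s * param == 0) return(frame)
      th <- s * param * pi / 180
      affine_resample(frame, function(dx, dy) {
        # inverse rotation of the forward CCW rotation by th
        list(x = cos(th) * dx + sin(th) * dy,
             y = -sin(th) * dx + cos(th) * dy)
      })
    },
    translate_x = {
      t <- s * param * w
      if (t == 0) return(frame)
      affine_resample(frame, function(dx, dy) list(x = dx - t, y = dy))
    },
    translate_y = {
      t <- s * param * h
      if (t == 0) return(frame)
      affine_resample(frame, function(dx, dy) list(x = dx, y = dy - t))
    },
    shear_x = {
      if (s * param == 0) return(frame)
      k <- s * param
      affine_resample(frame, function(dx, dy) list(x = dx - k * dy, y = dy))
    },
    shear_y = {
      if (s * param == 0) return(frame)
      k <- s * param
      affine_resample(frame, function(dx, dy) list(x = dx, y = dy - k * dx))
    },
    horizontal_flip = frame[, rev(seq_len(w)), , drop = FALSE],
    brightness = blend_toward(frame, 0, resolve_factor(param, s)),
    contrast = {
      m <- mean(luminance(frame))
      blend_toward(frame, m, resolve_factor(param, s))
    },
    saturation = {
      g <- luminance(frame)
      gray <- array(g, dim = d)  # recycled across the 3 channels
      blend_toward(frame, gray, resolve_factor(param, s))
    },
    sharpness = blend_toward(frame, smooth3x3(frame),
                             resolve_factor(param, s)),
    stop("unknown transform name '", spec$name, "'")
  )
}

# An enhancement factor f >= 1 mirrored below 1 when the sign is negative:
# f -> 2 - f, so magnitude 30 maps to 1.9 (stronger) or 0.1 (weaker).
resolve_factor <- function(f, sign) {
  if (sign < 0) 2 - f else f
}

# ---- serialization ----------------------------------------------------------

bank_to_list <- function(bank) {
  lapply(unname(bank), function(s) {
    list(name = s$name, param_min = s$param_min, param_max = s$param_max,
         signed = s$signed, kind = s$kind,
         identity_at_zero = s$identity_at_zero)
  })
}

#' Read or write a transform bank
#'
#' Banks are stored as a YAML or JSON list of
#' `{name, param_min, param_max, signed, kind, identity_at_zero}` records;
#' the format is chosen from the file extension (`.yaml`/`.yml` vs `.json`).
#'
#' @param bank A [transform_bank()].
#' @param path File path.
#' @return `read_transform_bank()` returns a `"transform_bank"`;
#'   `write_transform_bank()` returns `path` invisibly.
#' @export
write_transform_bank <- function(bank, path) {
  stopifnot(inherits(bank, "transform_bank"))
  lst <- bank_to_list(bank)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(lst, path)
  } else {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_transform_bank
#' @export
read_transform_bank <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path)
  }
  transform_bank(lapply(lst, function(e) {
    transform_spec(e$name, e$param_min, e$param_max, e$signed, e$kind,
                   if (is.null(e$identity_at_zero)) TRUE else e$identity_at_zero)
  }))
}
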