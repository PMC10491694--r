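#' Construct an augmentation policy
#'
#' The whole augmentation search space is the triple `(M, N, T)`:
#' magnitude `M` (shared integer strength scale 0--30), `N` transforms
#' applied per segment, and `T`, the maximum number of temporal segments a
#' video may be split into. A policy optionally restricts the transform set
#' to a named subset \eqn{\tau'} of the bank and carries a seed so that
#' augmentation is reproducible.
#'
#' Setting `T = 1` makes the policy apply one consistent composition to the
#' whole video (uniform augmentation); forcing one segment per frame
#' recovers independent per-frame augmentation.
#'
#' @param M Integer magnitude in `[0, 30]`.
#' @param N Integer number of transforms per segment (`>= 0`).
#' @param T Integer maximum number of temporal segments (`>= 1`).
#' @param subset Character vector of transform names (\eqn{\tau'});
#'   defaults to every transform in `bank`.
#' @param seed Integer seed for the per-video random stream.
#' @param boundary_mode `"equal"` for deterministic equal-length contiguous
#'   segments (remainder frames go to the final segment) or `"random"` for
#'   uniformly drawn distinct cut points.
#' @param bank The [transform_bank()] to draw from.
#' @return An object of class `"augment_policy"`.
#' @export
augment_policy <- function(M = 30, N = 1, T = 5, subset = NULL, seed = 1L,
                           boundary_mode = c("equal", "random"),
                           bank = default_transform_bank()) {
  boundary_mode <- match.arg(boundary_mode)
  stopifnot(inherits(bank, "transform_bank"))
  if (!is.numeric(M) || M < 0 || M > 30) stop("M must be in [0, 30]")
  if (!is.numeric(N) || N < 0) stop("N must be >= 0")
  if (!is.numeric(T) || T < 1) stop("T must be >= 1")
  if (is.null(subset)) subset <- names(bank)
  subset <- as.character(subset)
  if (length(subset) == 0L) stop("subset must be non-empty")
  missing <- setdiff(subset, names(bank))
  if (length(missing)) {
    stop("subset names not in bank: ", paste(missing, collapse = ", "))
  }
  structure(
    list(M = as.integer(M), N = as.integer(N), T = as.integer(T),
         subset = subset, seed = as.integer(seed),
         boundary_mode = boundary_mode, bank = bank),
    class = "augment_policy"
  )
}

#' @export
print.augment_policy <- function(x, ...) {
  cat(sprintf(
    "<augment_policy> M=%d N=%d T=%d | tau'=%d/%d transforms | %s boundaries | seed %d\n",
    x$M, x$N, x$T, length(x$subset), length(x$bank), x$boundary_mode, x$seed))
  invisible(x)
}

#' Read or write a policy file
#'
#' Policies are stored as YAML or JSON records
#' `{M, N, T, subset, seed, boundary_mode}` (format chosen by extension).
#' The transform bank itself is not serialized with the policy; pass one to
#' `read_policy()` if the default is not wanted.
#'
#' @param policy An [augment_policy()].
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @param bank Bank used to resolve names when reading.
#' @return `read_policy()` returns an `"augment_policy"`.
#' @export
write_policy <- function(policy, path) {
  stopifnot(inherits(policy, "augment_policy"))
  lst <- list(M = policy$M, N = policy$N, T = policy$T,
              subset = policy$subset, seed = policy$seed,
              boundary_mode = policy$boundary_mode)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(lst, path)
  } else {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_policy
#' @export
read_policy <- function(path, bank = default_transform_bank()) {
  lst <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  augment_policy(M = lst$M, N = lst$N, T = lst$T,
                 subset = unlist(lst$subset), seed = lst$seed,
                 boundary_mode = lst$boundary_mode, bank = bank)
}

#' Sample a segment plan
#'
#' Realizes a policy for a video of `n_frames` frames: the number of
#' segments \eqn{T'} is drawn uniformly from `1:min(T, n_frames)` (so no
#' segment is ever empty), the frame range `[0, n_frames)` is partitioned
#' into \eqn{T'} contiguous half-open intervals, and each segment receives
#' `N` transforms drawn independently and uniformly with replacement from
#' \eqn{\tau'}, each resolved through [scale_magnitude()] with a direction
#' sign sampled per segment (not per frame, preserving within-segment
#' consistency).
#'
#' Draws consume the current R random stream in a fixed order --
#' \eqn{T'}, boundaries (random mode only), then per-segment transforms and
#' signs in segment order -- so two calls from the same RNG state produce
#' identical plans. [trandaugment()] seeds the stream from the policy.
#'
#' @param n_frames Number of frames (`>= 1`).
#' @param policy An [augment_policy()].
#' @param t_prime Optional forced number of segments (used by the per-frame
#'   reduction); skips the \eqn{T'} draw.
#' @return An object of class `"segment_plan"` with fields `n_frames`,
#'   `t_prime`, `boundaries` (data frame of 0-based half-open
#'   `start`/`end`), and `ops` (one data frame of `name`, `param`, `sign`
#'   per segment).
#' @export
sample_segment_plan <- function(n_frames, policy, t_prime = NULL) {
  stopifnot(inherits(policy, "augment_policy"))
  if (!is.numeric(n_frames) || n_frames < 1) stop("n_frames must be >= 1")
  n_frames <- as.integer(n_frames)
  if (is.null(t_prime)) {
    t_max <- min(policy$T, n_frames)
    # no draw is consumed when the support is {1}: this keeps the T = 1 and
    # single-frame reductions byte-exact against the dedicated policies
    t_prime <- if (t_max == 1L) 1L else sample.int(t_max, 1L)
  } else {
    t_prime <- as.integer(t_prime)
    if (t_prime < 1L || t_prime > n_frames) stop("invalid forced t_prime")
  }
  if (policy$boundary_mode == "random" && t_prime > 1L) {
    cuts <- sort(sample.int(n_frames - 1L, t_prime - 1L))
    starts <- c(0L, cuts)
    ends <- c(cuts, n_frames)
  } else {
    base <- n_frames %/% t_prime
    sizes <- rep.int(base, t_prime)
    sizes[t_prime] <- sizes[t_prime] + n_frames %% t_prime
    ends <- cumsum(sizes)
    starts <- c(0L, ends[-t_prime])
  }
  specs <- policy$bank[policy$subset]
  ops <- vector("list", t_prime)
  for (i in seq_len(t_prime)) {
    if (policy$N == 0L) {
      ops[[i]] <- data.frame(name = character(0), param = numeric(0),
                             sign = numeric(0))
      next
    }
    idx <- sample.int(length(specs), policy$N, replace = TRUE)
    sgn <- numeric(policy$N)
    par <- numeric(policy$N)
    for (j in seq_len(policy$N)) {
      sp <- specs[[idx[j]]]
      par[j] <- scale_magnitude(sp, policy$M)
      sgn[j] <- if (sp$signed) sample(c(-1, 1), 1L) else 1
    }
    ops[[i]] <- data.frame(name = names(specs)[idx], param = par, sign = sgn)
  }
  structure(
    list(n_frames = n_frames, t_prime = t_prime,
         boundaries = data.frame(start = as.integer(starts),
                                 end = as.integer(ends)),
         ops = ops, policy = policy),
    class = "segment_plan"
  )
}

#' @export
print.segment_plan <- function(x, ...) {
  cat(sprintf("<segment_plan> %d frames in %d segment(s)\n",
              x$n_frames, x$t_prime))
  for (i in seq_len(x$t_prime)) {
    o <- x$ops[[i]]
    desc <- if (nrow(o) == 0) "identity" else
      paste(sprintf("%s(%+.3g)", o$name, o$sign * o$param), collapse = " o ")
    cat(sprintf("  [%d, %d): %s\n", x$boundaries$start[i],
                x$boundaries$end[i], desc))
  }
  invisible(x)
}

# Canonical string form of one segment's composition (used to count
# distinct compositions across a plan).
composition_key <- function(ops) {
  if (nrow(ops) == 0) return("identity")
  paste(sprintf("%s:%.10g:%g", ops$name, ops$param, ops$sign), collapse = "|")
}

#' Apply a segment plan to a frame sequence
#'
#' Every frame in segment `i` receives the same ordered composition of the
#' segment's `N` resolved transforms (applied in draw order), so frames
#' within one segment are augmented identically. The input is not modified;
#' output length and frame dimensions equal the input's.
#'
#' @param frames A list of `H x W x 3` arrays or a [video_sample()].
#' @param plan A [sample_segment_plan()] result with matching `n_frames`.
#' @return The augmented frames, in the same container type as the input.
#' @export
apply_plan <- function(frames, plan) {
  stopifnot(inherits(plan, "segment_plan"))
  vs <- NULL
  if (inherits(frames, "video_sample")) {
    vs <- frames
    frames <- frames$frames
  }
  if (length(frames) != plan$n_frames) {
    stop("plan was sampled for ", plan$n_frames, " frames but ",
         length(frames), " were supplied")
  }
  bank <- plan$policy$bank
  out <- frames
  for (i in seq_len(plan$t_prime)) {
    idx <- (plan$boundaries$start[i] + 1L):plan$boundaries$end[i]
    o <- plan$ops[[i]]
    if (nrow(o) == 0) next
    specs <- bank[o$name]
    for (t in idx) {
      fr <- frames[[t]]
      for (j in seq_len(nrow(o))) {
        fr <- apply_transform(fr, specs[[j]], o$param[j], o$sign[j])
      }
      out[[t]] <- fr
    }
  }
  if (!is.null(vs)) {
    vs$frames <- out
    return(vs)
  }
  out
}

# Derive a 32-bit seed from the policy seed and an optional video id / extra
# stream labels, via a small deterministic string hash.
derive_seed <- function(seed, ...) {
  parts <- c(as.character(seed), vapply(list(...), as.character, character(1)))
  s <- paste(parts, collapse = "/")
  h <- 0
  for (cc in utf8ToInt(s)) h <- (h * 31 + cc) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's stream.
with_stream <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

#' Temporally consistent random augmentation of a video
#'
#' `trandaugment()` splits a video into a random number \eqn{T' \le T} of
#' contiguous temporal segments and augments each segment with its own
#' random composition of `N` transforms at magnitude `M`, applied
#' identically to every frame of the segment. Its two degenerate cases are
#' exposed directly: `uniform_randaugment()` (one composition for the whole
#' video, i.e. `T = 1`) and `randaugment()` (independent draws per frame,
#' i.e. one segment per frame).
#'
#' All three are deterministic given `(frames, policy, video_id)`: the
#' random stream is seeded from `policy$seed` (combined with `video_id`
#' when given, so different videos of a dataset receive different plans).
#'
#' @param frames A list of `H x W x 3` arrays or a [video_sample()].
#' @param policy An [augment_policy()].
#' @param video_id Optional identifier mixed into the seed.
#' @return Augmented frames in the same container type as the input. The
#'   realized plan is attached as attribute `"plan"`.
#' @examples
#' vid <- replicate(6, array(runif(3 * 8 * 8), c(8, 8, 3)), simplify = FALSE)
#' pol <- augment_policy(M = 20, N = 1, T = 3, seed = 7)
#' aug <- trandaugment(vid, pol)
#' attr(aug, "plan")
#' @export
trandaugment <- function(frames, policy, video_id = NULL) {
  stopifnot(inherits(policy, "augment_policy"))
  n <- if (inherits(frames, "video_sample")) length(frames$frames)
       else length(frames)
  if (n < 1) stop("frames must contain at least one frame")
  seed <- if (is.null(video_id)) derive_seed(policy$seed)
          else derive_seed(policy$seed, video_id)
  plan <- with_stream(seed, sample_segment_plan(n, policy))
  out <- apply_plan(frames, plan)
  attr(out, "plan") <- plan
  out
}

#' @rdname trandaugment
#' @export
uniform_randaugment <- function(frames, policy, video_id = NULL) {
  policy$T <- 1L
  trandaugment(frames, policy, video_id)
}

#' @rdname trandaugment
#' @export
randaugment <- function(frames, policy, video_id = NULL) {
  stopifnot(inherits(policy, "augment_policy"))
  n <- if (inherits(frames, "video_sample")) length(frames$frames)
       else length(frames)
  if (n < 1) stop("frames must contain at least one frame")
  seed <- if (is.null(video_id)) derive_seed(policy$seed)
          else derive_seed(policy$seed, video_id)
  plan <- with_stream(seed, sample_segment_plan(n, policy, t_prime = n))
  out <- apply_plan(frames, plan)
  attr(out, "plan") <- plan
  out
}
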