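test_that("segment plans partition the frame range for random (n, T) pairs", {
  set.seed(101)
  for (rep in 1:200) {
    n <- sample(1:80, 1)
    Tmax <- sample(1:8, 1)
    mode <- sample(c("equal", "random"), 1)
    pol <- augment_policy(M = 15, N = 1, T = Tmax, seed = rep,
                          boundary_mode = mode)
    plan <- sample_segment_plan(n, pol)
    b <- plan$boundaries
    expect_lte(plan$t_prime, min(Tmax, n))
    expect_gte(plan$t_prime, 1)
    expect_identical(b$start[1], 0L)
    expect_identical(b$end[nrow(b)], as.integer(n))
    if (nrow(b) > 1) expect_identical(b$start[-1], b$end[-nrow(b)])
    expect_true(all(b$end > b$start))          # every segment non-empty
    expect_length(plan$ops, plan$t_prime)
    expect_true(all(vapply(plan$ops, nrow, integer(1)) == pol$N))
  }
})

test_that("degenerate plans: T = 1 and single-frame videos give one segment", {
  pol1 <- augment_policy(M = 10, N = 1, T = 1, seed = 1)
  plan <- sample_segment_plan(100, pol1)
  expect_identical(plan$t_prime, 1L)
  expect_identical(plan$boundaries, data.frame(start = 0L, end = 100L))
  pol5 <- augment_policy(M = 10, N = 1, T = 5, seed = 1)
  plan1 <- sample_segment_plan(1, pol5)
  expect_identical(plan1$t_prime, 1L)
  expect_error(sample_segment_plan(0, pol5), ">= 1")
})

test_that("T' is uniform on 1..min(T, n): chi-square over resamples", {
  pol <- augment_policy(M = 30, N = 0, T = 5, seed = 1)
  set.seed(2024)
  tp <- replicate(4000, sample_segment_plan(10, pol)$t_prime)
  counts <- tabulate(tp, nbins = 5)
  p <- stats::chisq.test(counts, p = rep(1 / 5, 5))$p.value
  expect_gt(p, 0.01)
})

test_that("plans draw transforms from the policy subset with resolved parameters", {
  bank <- default_transform_bank()
  pol <- augment_policy(M = 30, N = 3, T = 4, seed = 8,
                        subset = c("rotate", "brightness"))
  set.seed(5)
  plan <- sample_segment_plan(40, pol)
  for (ops in plan$ops) {
    expect_true(all(ops$name %in% c("rotate", "brightness")))
    for (j in seq_len(nrow(ops))) {
      s <- bank[[ops$name[j]]]
      expect_equal(ops$param[j], scale_magnitude(s, 30))
      expect_true(ops$sign[j] %in% c(-1, 1))
    }
  }
  expect_error(augment_policy(subset = "no_such_transform"), "not in bank")
  expect_error(augment_policy(M = 31), "M must be")
})

test_that("apply_plan: N = 0 is the identity and segment mates are identical", {
  vid <- rand_video(n = 10, seed = 21)
  pol0 <- augment_policy(M = 30, N = 0, T = 3, seed = 4)
  out <- trandaugment(vid, pol0)
  expect_identical(vid, `attributes<-`(out, NULL))
  # constant video: frames inside one segment stay pairwise identical
  cvid <- const_video(n = 12, value = 0.4)
  pol <- augment_policy(M = 25, N = 2, T = 4, seed = 17)
  aug <- trandaugment(cvid, pol)
  plan <- attr(aug, "plan")
  for (i in seq_len(plan$t_prime)) {
    idx <- (plan$boundaries$start[i] + 1):plan$boundaries$end[i]
    for (t in idx[-1]) expect_identical(aug[[t]], aug[[idx[1]]])
  }
  # and the number of distinct output frames is at most T'
  keys <- vapply(aug, function(f) paste(f, collapse = ","), character(1))
  expect_lte(length(unique(keys)), plan$t_prime)
})

test_that("apply_plan validates the frame count", {
  pol <- augment_policy(M = 5, N = 1, T = 2, seed = 3)
  set.seed(1)
  plan <- sample_segment_plan(6, pol)
  expect_error(apply_plan(rand_video(5), plan), "sampled for 6")
})

test_that("T = 1 reduces to uniform augmentation and per-frame forcing to independent augmentation", {
  for (seed in c(1, 7, 23)) {
    vid <- rand_video(n = 7, seed = seed)
    pol <- augment_policy(M = 30, N = 2, T = 6, seed = seed)
    pol_t1 <- pol; pol_t1$T <- 1L
    expect_identical(unclass(trandaugment(vid, pol_t1)),
                     unclass(uniform_randaugment(vid, pol)))
    plan_forced <- trandaug:::with_stream(
      trandaug:::derive_seed(pol$seed),
      sample_segment_plan(length(vid), pol, t_prime = length(vid)))
    expect_identical(apply_plan(vid, plan_forced),
                     `attributes<-`(randaugment(vid, pol), NULL))
  }
  # a single-frame video collapses all three policies
  one <- rand_video(n = 1, seed = 2)
  pol <- augment_policy(M = 20, N = 1, T = 5, seed = 5)
  a <- trandaugment(one, pol); b <- uniform_randaugment(one, pol)
  c_ <- randaugment(one, pol)
  expect_identical(a[[1]], b[[1]])
  expect_identical(a[[1]], c_[[1]])
})

test_that("uniform augmentation makes a constant video uniformly augmented", {
  cvid <- const_video(n = 6, value = 0.62)
  pol <- augment_policy(M = 28, N = 2, T = 4, seed = 31)
  out <- uniform_randaugment(cvid, pol)
  for (t in 2:6) expect_identical(out[[t]], out[[1]])
})

test_that("augmentation is deterministic in the policy seed and varies across seeds", {
  vid <- rand_video(n = 9, seed = 40)
  pol <- augment_policy(M = 30, N = 2, T = 5, seed = 99)
  expect_identical(trandaugment(vid, pol), trandaugment(vid, pol))
  expect_identical(trandaugment(vid, pol, video_id = "a"),
                   trandaugment(vid, pol, video_id = "a"))
  expect_false(identical(trandaugment(vid, pol, video_id = "a"),
                         trandaugment(vid, pol, video_id = "b")))
  # across seeds, plans almost surely differ
  plans <- lapply(1:30, function(s) {
    p <- pol; p$seed <- s
    attr(trandaugment(vid, p), "plan")
  })
  keys <- vapply(plans, function(pl) {
    paste(vapply(pl$ops, trandaug:::composition_key, character(1)),
          collapse = ";")
  }, character(1))
  expect_gte(length(unique(keys)), 28)
})

test_that("per-frame augmentation of a time-constant video yields one distinct frame per distinct composition", {
  # the same textured frame repeated, so every non-identity warp is visible
  cvid <- replicate(20, rand_frame(12, 12, seed = 45), simplify = FALSE)
  pol <- augment_policy(M = 30, N = 1, T = 5, seed = 12)
  out <- randaugment(cvid, pol)
  plan <- attr(out, "plan")
  expect_identical(plan$t_prime, 20L)
  keys <- vapply(plan$ops, trandaug:::composition_key, character(1))
  frame_keys <- vapply(out, function(f) paste(f, collapse = ","), character(1))
  expect_identical(length(unique(frame_keys)), length(unique(keys)))
})

test_that("policies round-trip through YAML and JSON", {
  pol <- augment_policy(M = 22, N = 2, T = 4, subset = c("rotate", "shear_x"),
                        seed = 77, boundary_mode = "random")
  for (ext in c("json", "yaml")) {
    path <- file.path(tempdir(), paste0("policy.", ext))
    write_policy(pol, path)
    back <- read_policy(path)
    expect_identical(back[c("M", "N", "T", "subset", "seed", "boundary_mode")],
                     pol[c("M", "N", "T", "subset", "seed", "boundary_mode")])
  }
})
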