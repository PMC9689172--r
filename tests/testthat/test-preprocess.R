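test_that("min-max normalization matches the closed form", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(-5, 0, 5, 15)), c(0, 0.25, 0.5, 1))
  # already [0,1]-spanning input is a fixed point
  x <- matrix(c(0, 0.3, 0.7, 1), 2, 2)
  expect_equal(minmax_normalize(x), x)
  expect_error(minmax_normalize(matrix(3, 4, 4)), "degenerate")
  expect_error(minmax_normalize(c(1, NA, 2)), "finite")
})

test_that("normalization attains both endpoints and is affine-invariant", {
  set.seed(10)
  for (i in 1:20) {
    x <- matrix(rnorm(200), 20, 10)
    nx <- minmax_normalize(x)
    expect_identical(dim(nx), dim(x))
    expect_equal(min(nx), 0)
    expect_equal(max(nx), 1)
    a <- runif(1, 0.1, 10); b <- rnorm(1, sd = 5)
    expect_equal(minmax_normalize(a * x + b), nx, tolerance = 1e-12)
  }
})

test_that("augmentation plan reproduces the geF1 cohort arithmetic", {
  # 23 minority vs 207 majority frames: 9-fold augmentation, step 76/9
  plan <- plan_augmentation(23, 207)
  expect_identical(plan$n_aug, 9L)
  expect_identical(plan$offsets, c(0L, 8L, 16L, 25L, 33L, 42L, 50L, 59L, 67L))
  # geF3 grouping of the same cohort: 110 vs 120 frames, no augmentation
  expect_identical(plan_augmentation(110, 120)$n_aug, 1L)
  expect_identical(plan_augmentation(110, 120)$offsets, 0L)
  # half-way ratios round up
  expect_identical(plan_augmentation(2, 3)$n_aug, 2L)
  expect_identical(plan_augmentation(10, 25)$n_aug, 3L)
})

test_that("augmentation offsets stay in bounds for random class sizes", {
  set.seed(11)
  for (i in 1:50) {
    n0 <- sample(1:60, 1); n1 <- n0 + sample(0:300, 1)
    plan <- plan_augmentation(n0, n1)
    expect_identical(length(plan$offsets), plan$n_aug)
    expect_true(all(diff(plan$offsets) >= 0))
    expect_true(all(plan$offsets >= 0L &
                      plan$offsets <= plan$roi_axial - plan$window_axial))
    expect_identical(plan$offsets[1], 0L)
  }
  expect_error(plan_augmentation(5, 10, roi_axial = 100, window_axial = 200),
               "longer")
})

test_that("sliding windows equal brute-force row slices", {
  set.seed(12)
  roi <- matrix(rnorm(1100 * 8), 1100, 8)
  plan <- plan_augmentation(23, 207)
  ws <- slide_windows(roi, plan)
  expect_length(ws, 9L)
  for (i in seq_along(ws)) {
    expect_identical(dim(ws[[i]]), c(1024L, 8L))
    expect_identical(ws[[i]], roi[plan$offsets[i] + 1:1024, ])
  }
  one <- slide_windows(roi, plan_augmentation(1, 1))
  expect_identical(one[[1]], roi[1:1024, ])
  expect_error(slide_windows(roi[1:500, ], plan), "shorter")
})

test_that("task labels dichotomize stages at the right thresholds", {
  thr <- c(geF1 = 1L, geF2 = 2L, geF3 = 3L, geF4 = 4L)
  for (task in names(thr))
    expect_identical(label_task(0:4, task), as.integer(0:4 >= thr[task]))
  expect_identical(label_task(0, "geF1"), 0L)
  expect_identical(label_task(1, "geF1"), 1L)
  expect_identical(label_task(3, "geF4"), 0L)
  expect_identical(label_task(4, "geF4"), 1L)
  expect_error(label_task(2, "geF5"), "unknown task")
  expect_error(label_task(7, "geF1"), "0..4", fixed = TRUE)
})

test_that("split sizes follow the floor rule with remainder to test", {
  s100 <- split_dataset(rep(0:1, 50), seed = 1)
  expect_identical(lengths(s100[c("train", "val", "test")]),
                   c(train = 80L, val = 10L, test = 10L))
  s101 <- split_dataset(rep(0:1, length.out = 101), seed = 1)
  expect_identical(lengths(s101[c("train", "val", "test")]),
                   c(train = 80L, val = 10L, test = 11L))
})

test_that("splits are deterministic, disjoint and exhaustive in all modes", {
  set.seed(13)
  labels <- rbinom(60, 1, 0.4)
  cases <- rep(sprintf("c%02d", 1:20), each = 3)  # 3 windows per case
  for (grp in c(FALSE, TRUE)) for (str in c(FALSE, TRUE)) {
    s1 <- split_dataset(labels, seed = 5, case_ids = cases,
                        group_by_case = grp, stratify = str)
    s2 <- split_dataset(labels, seed = 5, case_ids = cases,
                        group_by_case = grp, stratify = str)
    expect_identical(s1[c("train", "val", "test")],
                     s2[c("train", "val", "test")])
    all_idx <- sort(c(s1$train, s1$val, s1$test))
    expect_identical(all_idx, seq_along(labels))  # disjoint + exhaustive
    if (grp) {
      # every case lands entirely in one partition
      for (part in list(s1$train, s1$val, s1$test)) {
        inside <- unique(cases[part])
        outside <- unique(cases[setdiff(seq_along(labels), part)])
        expect_length(intersect(inside, outside), 0L)
      }
    }
  }
  expect_error(split_dataset(rep(0:1, 30), ratios = c(0.7, 0.2, 0.2)),
               "summing to 1")
  expect_error(split_dataset(rep(0:1, 3)), "at least 10")
})

test_that("frame_to_segments maps A-lines to rows order-preservingly", {
  set.seed(14)
  w <- matrix(rnorm(1024 * 5), 1024, 5)
  segs <- frame_to_segments(w)
  expect_identical(dim(segs), c(5L, 1024L))
  for (j in 1:5) expect_identical(segs[j, ], w[, j])
  one <- frame_to_segments(w[, 1, drop = FALSE])
  expect_identical(dim(one), c(1L, 1024L))
  expect_error(frame_to_segments(w[1:500, ]), "expected 1024")
})

test_that("task dataset balances classes within rounding slack", {
  co <- small_cohort(c("0" = 3L, "2" = 7L), seed = 6)
  ds <- build_task_dataset(co, "geF2", roi = small_roi(), window_axial = 256L)
  # N0=3, N1=7 -> n_aug = round(7/3) = 2; 3*2 + 7 = 13 windows
  expect_identical(ds$plan$n_aug, 2L)
  expect_identical(length(ds$windows), 13L)
  n_min <- sum(ds$meta$label == 0L); n_maj <- sum(ds$meta$label == 1L)
  expect_lte(abs(n_min - n_maj), 3L)
  # every window normalized to [0,1] with attained endpoints
  for (w in ds$windows) {
    expect_equal(min(w), 0)
    expect_equal(max(w), 1)
    expect_identical(dim(w), c(256L, 16L))
  }
  # majority frames contribute exactly one window at offset 0
  expect_true(all(ds$meta$offset[ds$meta$label == 1L] == 0L))
})

test_that("windows_to_segments stacks windows with provenance", {
  ws <- list(matrix(1, 8, 3), matrix(2, 8, 2))
  seg <- windows_to_segments(ws)
  expect_identical(dim(seg$x), c(5L, 8L))
  expect_identical(seg$window_id, c(1L, 1L, 1L, 2L, 2L))
})
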