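#' Min-max normalization of a signal window
#'
#' Rescales a window of ROI signals to `[0, 1]` using one global minimum and
#' maximum over the whole window: `X' = (X - Xmin) / (Xmax - Xmin)`.
#' Normalization removes acquisition-dependent amplitude scale before the
#' segments enter the network; it is invariant under positive affine
#' transforms of the input.
#'
#' @param window Finite numeric matrix (or vector).
#' @return Numeric array of the same shape with `min = 0`, `max = 1`.
#' @examples
#' minmax_normalize(c(2, 4, 6))
#' @export
minmax_normalize <- function(window) {
  if (!is.numeric(window) || !all(is.finite(window)))
    stop("window must be finite numeric")
  lo <- min(window); hi <- max(window)
  if (hi == lo)
    stop("degenerate input: constant window cannot be min-max normalized")
  (window - lo) / (hi - lo)
}

#' Task label thresholds
#'
#' The four binary staging tasks dichotomize METAVIR stages at successive
#' cut-offs: `geF1` = F0 vs F1-F4, `geF2` = F0-F1 vs F2-F4, `geF3` = F0-F2
#' vs F3-F4, `geF4` = F0-F3 vs F4. Label 1 is the higher-fibrosis group.
#'
#' @param stage Integer vector of stages in 0..4.
#' @param task One of `"geF1"`, `"geF2"`, `"geF3"`, `"geF4"`.
#' @return Integer vector of 0/1 labels.
#' @export
label_task <- function(stage, task) {
  thr <- c(geF1 = 1L, geF2 = 2L, geF3 = 3L, geF4 = 4L)[task]
  if (is.na(thr)) stop("unknown task: ", task,
                       " (expected geF1, geF2, geF3 or geF4)")
  stage <- as.integer(stage)
  if (anyNA(stage) || any(stage < 0L | stage > 4L))
    stop("stages must be integers in 0..4")
  as.integer(stage >= thr)
}

#' Class-balancing sliding-window augmentation plan
#'
#' With `n_minority` frames in the rarer class and `n_majority` in the
#' other, the minority class is augmented `n_aug = round(n_majority /
#' n_minority)` times (ties up, minimum 1) by sliding a window of
#' `window_axial` samples through the `roi_axial`-sample ROI in steps of
#' `(roi_axial - window_axial) / n_aug`. Offsets are integer,
#' `floor(i * (roi_axial - window_axial) / n_aug)` for `i = 0 .. n_aug - 1`,
#' which guarantees exactly `n_aug` in-bounds windows.
#'
#' @param n_minority,n_majority Frame counts of the two classes
#'   (`n_majority >= n_minority >= 1`).
#' @param roi_axial Axial extent of the ROI (default 1100).
#' @param window_axial Axial window size fed to the network (default 1024).
#' @return An object of class `augmentation_plan`: list with `n_minority`,
#'   `n_majority`, `n_aug`, `window_axial`, `roi_axial` and the 0-based
#'   non-decreasing `offsets`.
#' @examples
#' plan_augmentation(23, 207)$offsets
#' @export
plan_augmentation <- function(n_minority, n_majority,
                              roi_axial = 1100L, window_axial = 1024L) {
  if (n_minority < 1L) stop("n_minority must be >= 1")
  if (n_majority < n_minority) stop("n_majority must be >= n_minority")
  if (window_axial > roi_axial)
    stop(sprintf("window (%d) longer than ROI (%d)", window_axial, roi_axial))
  # round half up; base round() is round-half-even
  n_aug <- max(1L, as.integer(floor(n_majority / n_minority + 0.5)))
  span <- roi_axial - window_axial
  offsets <- as.integer(floor(seq_len(n_aug) - 1L) * span / n_aug)
  structure(list(n_minority = as.integer(n_minority),
                 n_majority = as.integer(n_majority),
                 n_aug = n_aug, window_axial = as.integer(window_axial),
                 roi_axial = as.integer(roi_axial), offsets = offsets),
            class = "augmentation_plan")
}

#' Slide augmentation windows through an ROI frame
#'
#' @param roi_frame An [rf_frame()] (or matrix) whose axial extent is at
#'   least the plan's `window_axial`.
#' @param plan An [plan_augmentation()] plan.
#' @return List of `n_aug` matrices, each `window_axial x n_lines`; window
#'   `i` covers axial rows `[offset_i, offset_i + window_axial)` (0-based,
#'   half-open).
#' @export
slide_windows <- function(roi_frame, plan) {
  stopifnot(inherits(plan, "augmentation_plan"))
  x <- if (inherits(roi_frame, "rf_frame")) roi_frame$samples else roi_frame
  if (nrow(x) < plan$window_axial)
    stop("ROI shorter than the sliding window")
  if (any(plan$offsets + plan$window_axial > nrow(x)))
    stop("augmentation offset out of bounds for this ROI")
  lapply(plan$offsets, function(o) x[o + seq_len(plan$window_axial), , drop = FALSE])
}

#' Split windows into train / validation / test partitions
#'
#' Shuffles uniformly under `seed` and slices contiguously into
#' `floor(r1*n)` train, `floor(r2*n)` validation, and the remainder test.
#' The default per-window granularity mirrors a frame-level split;
#' `group_by_case = TRUE` keeps all windows of a case in one partition
#' (recommended against leakage when augmentation windows of one case
#' overlap), and `stratify = TRUE` splits each label class separately.
#'
#' @param labels Integer 0/1 label per window (length `n >= 10`).
#' @param ratios Numeric triple summing to 1 (default `c(0.8, 0.1, 0.1)`).
#' @param seed RNG seed for the shuffle.
#' @param case_ids Character vector parallel to `labels`; required when
#'   `group_by_case = TRUE`.
#' @param group_by_case,stratify Logical switches, see Details.
#' @return An object of class `dataset_split`: list of integer index vectors
#'   `train`, `val`, `test` (disjoint, exhaustive).
#' @export
split_dataset <- function(labels, ratios = c(0.8, 0.1, 0.1), seed = 1L,
                          case_ids = NULL, group_by_case = FALSE,
                          stratify = FALSE) {
  n <- length(labels)
  if (n < 10L) stop("need at least 10 windows to split")
  if (length(ratios) != 3L || abs(sum(ratios) - 1) > 1e-8)
    stop("ratios must be three proportions summing to 1")
  resample <- function(v) v[sample.int(length(v))]  # safe for length 1
  slice3 <- function(idx) {
    m <- length(idx)
    n_tr <- floor(ratios[1] * m); n_va <- floor(ratios[2] * m)
    list(train = idx[seq_len(n_tr)],
         val = idx[n_tr + seq_len(n_va)],
         test = idx[setdiff(seq_len(m), seq_len(n_tr + n_va))])
  }
  parts <- with_seed(seed, {
    if (group_by_case) {
      if (is.null(case_ids)) stop("case_ids required when group_by_case = TRUE")
      units <- unique(case_ids)
      ul <- if (stratify) vapply(units, function(u)
        labels[match(u, case_ids)], integer(1)) else NULL
      take <- function(us) {
        sp <- slice3(resample(us))
        lapply(sp, function(u) which(case_ids %in% u))
      }
      if (stratify) {
        combine_strata(lapply(split(units, ul), take))
      } else take(units)
    } else if (stratify) {
      combine_strata(lapply(split(seq_len(n), labels), function(idx)
        slice3(resample(idx))))
    } else {
      slice3(sample.int(n))
    }
  })
  structure(c(parts, list(n = n, ratios = ratios, seed = seed,
                          group_by_case = group_by_case, stratify = stratify)),
            class = "dataset_split")
}

combine_strata <- function(sps) {
  list(train = unlist(lapply(sps, `[[`, "train"), use.names = FALSE),
       val = unlist(lapply(sps, `[[`, "val"), use.names = FALSE),
       test = unlist(lapply(sps, `[[`, "test"), use.names = FALSE))
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> n = %d: train %d / val %d / test %d%s%s\n",
              x$n, length(x$train), length(x$val), length(x$test),
              if (x$group_by_case) ", grouped by case" else "",
              if (x$stratify) ", stratified" else ""))
  invisible(x)
}

#' Split a window into per-A-line segments
#'
#' Each of the window's `L` A-lines becomes one 1024-sample input segment
#' for the network, order-preserving: segment `j` is column `j` of the
#' window. A 1024 x 256 window therefore yields 256 segments, and the frame
#' decision later aggregates their 256 predictions.
#'
#' @param window Numeric matrix with `window_axial` (default 1024) rows.
#' @param window_axial Expected axial length.
#' @return Numeric matrix, one segment per row (`L x window_axial`).
#' @export
frame_to_segments <- function(window, window_axial = 1024L) {
  stopifnot(is.matrix(window), is.numeric(window))
  if (nrow(window) != window_axial)
    stop(sprintf("window has %d axial samples, expected %d",
                 nrow(window), window_axial))
  t(window)
}

#' Build the windowed, labelled dataset for one staging task
#'
#' Runs the full preprocessing chain on a cohort: read each frame, extract
#' the fixed ROI, dichotomize stages for `task`, augment the minority class
#' with sliding windows ([plan_augmentation()]; majority frames contribute a
#' single window at offset 0), and min-max normalize every window.
#'
#' @param cohort Cohort data frame from [read_cohort_manifest()] or
#'   [simulate_cohort()].
#' @param task Staging task, see [label_task()].
#' @param roi ROI placement ([roi_spec()]).
#' @param window_axial Axial window size (default 1024).
#' @param normalize Normalize each window to `[0,1]` (default TRUE).
#' @return A list of class `task_dataset`: `windows` (list of matrices),
#'   `meta` (data.frame with `case_id`, `stage`, `label`, `offset`), `plan`,
#'   `task`.
#' @export
build_task_dataset <- function(cohort, task, roi = roi_spec(),
                               window_axial = 1024L, normalize = TRUE) {
  stopifnot(is.data.frame(cohort), nrow(cohort) >= 1L)
  labels <- label_task(cohort$stage, task)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n0 == 0L || n1 == 0L)
    stop("task ", task, " has a single class in this cohort")
  minority <- if (n0 <= n1) 0L else 1L
  plan <- plan_augmentation(min(n0, n1), max(n0, n1),
                            roi_axial = roi$axial_len,
                            window_axial = window_axial)
  single <- plan_augmentation(1L, 1L, roi_axial = roi$axial_len,
                              window_axial = window_axial)
  windows <- list(); meta <- list(); k <- 0L
  for (i in seq_len(nrow(cohort))) {
    fr <- read_rf_frame(cohort$frame_path[i])
    roi_fr <- extract_roi(fr, roi)
    pl <- if (labels[i] == minority) plan else single
    ws <- slide_windows(roi_fr, pl)
    for (j in seq_along(ws)) {
      k <- k + 1L
      windows[[k]] <- if (normalize) minmax_normalize(ws[[j]]) else ws[[j]]
      meta[[k]] <- data.frame(case_id = cohort$case_id[i],
                              stage = cohort$stage[i], label = labels[i],
                              offset = pl$offsets[j],
                              stringsAsFactors = FALSE)
    }
  }
  structure(list(windows = windows, meta = do.call(rbind, meta),
                 plan = plan, task = task, window_axial = window_axial),
            class = "task_dataset")
}

#' Stack windows into a segment matrix
#'
#' Concatenates the per-A-line segments of a set of windows into one input
#' matrix for the network, with bookkeeping of the source window of every
#' segment.
#'
#' @param windows List of `window_axial x L` matrices.
#' @return List with `x` (segments x samples matrix) and `window_id`
#'   (integer source-window index per segment).
#' @export
windows_to_segments <- function(windows) {
  xs <- lapply(windows, t)
  list(x = do.call(rbind, xs),
       window_id = rep.int(seq_along(windows),
                           vapply(xs, nrow, integer(1))))
}
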