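#' Envelope detection of an RF frame
#'
#' Computes the per-A-line magnitude of the analytic signal (Hilbert
#' transform along the axial axis), the standard first step of B-mode
#' reconstruction from backscattered RF. The analytic signal is formed in
#' the frequency domain: negative frequencies are zeroed and positive ones
#' doubled, all A-lines at once via [stats::mvfft()].
#'
#' @param frame An [rf_frame()] (or a numeric matrix, axial x lines) with at
#'   least 8 axial samples.
#' @return Non-negative numeric matrix of the same shape as the input.
#' @export
compute_envelope <- function(frame) {
  x <- if (inherits(frame, "rf_frame")) frame$samples else frame
  stopifnot(is.matrix(x), is.numeric(x))
  n <- nrow(x)
  if (n < 8L) stop("need at least 8 axial samples for envelope detection")
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n %/% 2L + 1L)] <- 1
    h[2:(n %/% 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) %/% 2L)] <- 2
  }
  analytic <- stats::mvfft(stats::mvfft(x + 0i) * h, inverse = TRUE) / n
  env <- Mod(analytic)
  dim(env) <- dim(x)
  env
}

#' Log compression to a B-mode image
#'
#' Normalizes the envelope to its maximum and converts to decibels,
#' clipping at the display dynamic range: `20*log10(env/max)` with floor
#' `-dynamic_range_db`. The brightest pixel is 0 dB.
#'
#' @param envelope Non-negative matrix from [compute_envelope()].
#' @param dynamic_range_db Display dynamic range in dB (default 40).
#' @return An object of class `bmode_image`: list with `pixels` (dB matrix)
#'   and `dynamic_range_db`.
#' @export
log_compress <- function(envelope, dynamic_range_db = 40) {
  stopifnot(is.matrix(envelope), is.numeric(envelope))
  if (any(envelope < 0)) stop("envelope must be non-negative")
  mx <- max(envelope)
  if (mx <= 0) stop("degenerate input: all-zero envelope cannot be log-compressed")
  if (dynamic_range_db <= 0) stop("dynamic range must be positive")
  px <- pmax(20 * log10(envelope / mx), -dynamic_range_db)
  structure(list(pixels = px, dynamic_range_db = dynamic_range_db),
            class = "bmode_image")
}

#' @export
print.bmode_image <- function(x, ...) {
  cat(sprintf("<bmode_image> %d x %d pixels, dynamic range %g dB\n",
              nrow(x$pixels), ncol(x$pixels), x$dynamic_range_db))
  invisible(x)
}

#' Region-of-interest specification
#'
#' A fixed-size rectangular ROI within an RF frame, with 0-based start
#' indices and half-open windows `[start, start + len)`. The default is the
#' automatic liver ROI used by the pipeline: 1100 x 256 (axial x lateral),
#' centered axially in a 1247-sample frame (offset `floor((1247-1100)/2)` =
#' 73). Pass explicit starts to emulate manual ROI placement.
#'
#' @param axial_start 0-based first axial sample (default 73).
#' @param axial_len Axial extent in samples (default 1100).
#' @param line_start 0-based first A-line (default 0).
#' @param line_len Lateral extent in lines (default 256).
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(axial_start = 73L, axial_len = 1100L,
                     line_start = 0L, line_len = 256L) {
  s <- lapply(list(axial_start = axial_start, axial_len = axial_len,
                   line_start = line_start, line_len = line_len), as.integer)
  if (s$axial_len < 1L || s$line_len < 1L || s$axial_start < 0L || s$line_start < 0L)
    stop("ROI starts must be >= 0 and lengths >= 1")
  structure(s, class = "roi_spec")
}

#' Extract an ROI sub-frame
#'
#' @param frame An [rf_frame()].
#' @param roi An [roi_spec()]; must fit inside the frame.
#' @return An [rf_frame()] of shape `axial_len x line_len`, metadata
#'   preserved.
#' @export
extract_roi <- function(frame, roi = roi_spec()) {
  stopifnot(inherits(frame, "rf_frame"), inherits(roi, "roi_spec"))
  if (roi$axial_start + roi$axial_len > frame$n_axial ||
      roi$line_start + roi$line_len > frame$n_lines)
    stop(sprintf("ROI [%d,%d) x [%d,%d) exceeds frame %d x %d",
                 roi$axial_start, roi$axial_start + roi$axial_len,
                 roi$line_start, roi$line_start + roi$line_len,
                 frame$n_axial, frame$n_lines))
  sub <- frame$samples[roi$axial_start + seq_len(roi$axial_len),
                       roi$line_start + seq_len(roi$line_len), drop = FALSE]
  rf_frame(sub, fs_hz = frame$fs_hz, fc_hz = frame$fc_hz,
           case_id = frame$case_id)
}
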