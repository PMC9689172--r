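#' RF frame container
#'
#' An `rf_frame` holds one frame of raw backscattered ultrasound
#' radiofrequency (RF) data: a real-valued matrix of axial samples by
#' A-lines, together with the acquisition metadata needed downstream
#' (sampling frequency, transducer center frequency, case identifier).
#' The scanner emulated throughout the package acquires 256 A-lines of
#' 1247 samples each at 12 MHz sampling with a 3 MHz transducer.
#'
#' @param samples Numeric matrix, axial sample index in rows and A-line
#'   index in columns. All values must be finite.
#' @param fs_hz Sampling frequency in Hz (default 12e6).
#' @param fc_hz Transducer center frequency in Hz (default 3e6).
#' @param case_id Character identifier of the originating case.
#'
#' @return An object of class `rf_frame`: a list with elements `samples`,
#'   `n_axial`, `n_lines`, `fs_hz`, `fc_hz`, `case_id`.
#' @examples
#' f <- rf_frame(matrix(rnorm(40), 10, 4), case_id = "demo")
#' f$n_axial
#' @export
rf_frame <- function(samples, fs_hz = 12e6, fc_hz = 3e6, case_id = "") {
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("'samples' must be a numeric matrix (axial x lines)")
  if (nrow(samples) < 1L || ncol(samples) < 1L)
    stop("frame must have at least one axial sample and one A-line")
  if (!all(is.finite(samples)))
    stop("frame samples must all be finite")
  if (!is.numeric(fs_hz) || fs_hz <= 0 || !is.numeric(fc_hz) || fc_hz <= 0)
    stop("'fs_hz' and 'fc_hz' must be positive")
  structure(
    list(samples = samples,
         n_axial = nrow(samples),
         n_lines = ncol(samples),
         fs_hz = as.numeric(fs_hz),
         fc_hz = as.numeric(fc_hz),
         case_id = as.character(case_id)),
    class = "rf_frame")
}

#' @export
print.rf_frame <- function(x, ...) {
  cat(sprintf("<rf_frame> %d axial samples x %d A-lines", x$n_axial, x$n_lines))
  if (nzchar(x$case_id)) cat(sprintf("  [case %s]", x$case_id))
  cat(sprintf("\n  fs = %.3g MHz, fc = %.3g MHz, amplitude range [%.3g, %.3g]\n",
              x$fs_hz / 1e6, x$fc_hz / 1e6,
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
dim.rf_frame <- function(x) c(x$n_axial, x$n_lines)
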