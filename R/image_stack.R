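#' ImageStack: a grayscale microscopy stack with axis semantics
#'
#' The common container for all pipeline stages. `data` is a numeric 3D array
#' indexed `[frame_or_slice, row, col]`; `axis_kind` states whether the first
#' axis is time (time-lapse, `step` in seconds/frame) or z (confocal stack,
#' `step` in micrometres/slice). All physical geometry downstream is derived
#' from `pixel_size_um` and `step`, never from pixel counts alone.
#'
#' @param data numeric array, either `frames x rows x cols` or a single
#'   matrix (promoted to one frame). All intensities must be finite and
#'   non-negative.
#' @param axis_kind `"time"` or `"z"`.
#' @param pixel_size_um pixel size in micrometres (> 0).
#' @param step frame interval in seconds (`axis_kind = "time"`) or z-spacing
#'   in micrometres (`axis_kind = "z"`); must be > 0.
#' @return an object of class `ImageStack`.
#' @examples
#' st <- image_stack(array(1, c(5, 8, 8)), "time", pixel_size_um = 2, step = 5)
#' n_frames(st)
#' @export
image_stack <- function(data, axis_kind = c("time", "z"),
                        pixel_size_um, step) {
  axis_kind <- match.arg(axis_kind)
  if (is.matrix(data)) data <- array(data, c(1L, dim(data)))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a frames x rows x cols array or a matrix")
  storage.mode(data) <- "double"
  if (anyNA(data) || any(!is.finite(data)))
    stop("stack intensities must be finite")
  if (any(data < 0))
    stop("stack intensities must be non-negative")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number")
  if (!is.numeric(step) || length(step) != 1L || step <= 0)
    stop("`step` must be a single positive number")
  structure(
    list(data = data, axis_kind = axis_kind,
         pixel_size_um = as.numeric(pixel_size_um), step = as.numeric(step)),
    class = "ImageStack")
}

#' @rdname image_stack
#' @param x an `ImageStack`.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "ImageStack"))
  dim(x$data)[1L]
}

# Frame i as a plain matrix
frame_of <- function(x, i) {
  stopifnot(inherits(x, "ImageStack"))
  matrix(x$data[i, , ], dim(x$data)[2L], dim(x$data)[3L])
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ImageStack> %d %s x %d x %d px, pixel %g um, step %g %s\n",
              d[1L], if (x$axis_kind == "time") "frames" else "slices",
              d[2L], d[3L], x$pixel_size_um, x$step,
              if (x$axis_kind == "time") "s" else "um"))
  invisible(x)
}

#' Time (or z) coordinate vector of a stack
#' @param x an `ImageStack`.
#' @return numeric vector `0, step, 2*step, ...` of length `n_frames(x)`.
#' @export
stack_times <- function(x) (seq_len(n_frames(x)) - 1L) * x$step
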