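#' Grayscale time-lapse stack
#'
#' Container for an ordered grayscale frame stack with the two pieces of
#' metadata every downstream stage needs: the pixel scale (um/pixel) and the
#' frame rate (Hz). Frames are stored as a numeric `height x width x n_frames`
#' array with intensities on an arbitrary linear scale (files are read to
#' [0, 1]).
#'
#' @param frames Numeric 3-D array (`height x width x n_frames`) or a list of
#'   equally sized matrices.
#' @param pixel_scale_um Spatial scale in micrometres per pixel.
#' @param frame_rate_hz Acquisition rate in frames per second.
#' @return A `video_stack` object.
#' @examples
#' v <- video_stack(array(runif(16 * 16 * 3), c(16, 16, 3)), 3.79, 30)
#' n_frames(v)
#' @export
video_stack <- function(frames, pixel_scale_um = 3.79, frame_rate_hz) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L) {
      abort("inconsistent frame shapes in frame list")
    }
    frames <- array(unlist(frames), c(dims[[1]], length(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    abort("`frames` must be a height x width x n_frames array")
  }
  if (dim(frames)[3] < 2L) {
    abort("a video stack needs at least 2 frames")
  }
  if (!all(is.finite(frames))) abort("non-finite pixel values in frames")
  stopifnot(is.numeric(pixel_scale_um), pixel_scale_um > 0,
            is.numeric(frame_rate_hz), frame_rate_hz > 0)
  structure(
    list(frames = frames,
         pixel_scale_um = pixel_scale_um,
         frame_rate_hz = frame_rate_hz),
    class = "video_stack"
  )
}

#' @rdname video_stack
#' @param x A `video_stack`.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "video_stack"))
  dim(x$frames)[3]
}

#' @export
print.video_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<video_stack> %d frames of %d x %d px, %.3g um/px, %g fps\n",
              d[3], d[1], d[2], x$pixel_scale_um, x$frame_rate_hz))
  invisible(x)
}

#' Read a grayscale video from a multi-page TIFF or an image directory
#'
#' Accepts either a multi-page TIFF file or a directory of single-frame image
#' files (TIFF or PNG) ordered lexicographically. Multi-channel frames are
#' averaged to grayscale. Intensities are returned on the [0, 1] scale used
#' by the `tiff` and `png` readers.
#'
#' @param path Path to a `.tif`/`.tiff` file or to a directory of frames.
#' @param pixel_scale_um Micrometres per pixel (not stored in plain TIFFs, so
#'   it must be supplied; the default is the platform's calibrated scale).
#' @param frame_rate_hz Frame rate in Hz; required, because plain image
#'   containers carry no timing metadata.
#' @return A [video_stack()].
#' @export
read_video <- function(path, pixel_scale_um = 3.79, frame_rate_hz = NULL) {
  if (is.null(frame_rate_hz)) {
    abort(paste("`frame_rate_hz` is required: image containers carry no",
                "timing metadata. Supply the acquisition rate, e.g.",
                "read_video(path, frame_rate_hz = 30)."))
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tiff?|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) < 2L) abort("need at least 2 frame files in directory")
    frames <- lapply(files, read_frame_file)
  } else if (file.exists(path)) {
    if (!grepl("\\.tiff?$", path, ignore.case = TRUE)) {
      abort("single-file input must be a multi-page TIFF")
    }
    frames <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(frames)) frames <- list(frames)
    if (length(frames) < 2L) abort("a video stack needs at least 2 frames")
    frames <- lapply(frames, to_gray)
  } else {
    abort(sprintf("no such file or directory: %s", path))
  }
  dims <- unique(lapply(frames, dim))
  if (length(dims) != 1L) {
    bad <- which(vapply(frames, function(f) !identical(dim(f), dim(frames[[1]])),
                        logical(1)))[1]
    abort(sprintf("inconsistent frame shape at frame %d", bad))
  }
  video_stack(frames, pixel_scale_um, frame_rate_hz)
}

read_frame_file <- function(f) {
  img <- if (grepl("\\.png$", f, ignore.case = TRUE)) {
    png::readPNG(f)
  } else {
    tiff::readTIFF(f)
  }
  to_gray(img)
}

to_gray <- function(img) {
  if (length(dim(img)) == 3L)

    img <- apply(img, c(1, 2), mean)
  img
}

#' Write a video stack to a 16-bit grayscale multi-page TIFF
#'
#' Intensities are clipped to [0, 1] before writing (the in-memory stack is
#' double precision and synthetic noise can leave the unit range).
#'
#' @param video A [video_stack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_video <- function(video, path) {
  stopifnot(inherits(video, "video_stack"))
  frames <- lapply(seq_len(n_frames(video)), function(i) {
    f <- video$frames[, , i]
    f[f < 0] <- 0
    f[f > 1] <- 1
    f
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}
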