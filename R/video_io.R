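#' Construct a frame stack
#'
#' The unit every image stage consumes: an ordered list of RGB frames from
#' one recording segment, with its frame rate and absolute (UTC) start time.
#' Frames are `height x width x 3` numeric arrays with 8-bit intensities in
#' `[0, 255]`; row 1 is the top image row.
#'
#' @param frames list of `H x W x 3` numeric arrays, all the same shape.
#' @param fps frames per second (> 0).
#' @param start_time POSIXct UTC time of frame 0.
#' @param segment_id character identifier.
#' @return a `frame_stack` object.
#' @export
frame_stack <- function(frames, fps, start_time, segment_id = "segment") {
  if (!is.list(frames) || length(frames) == 0L)
    stop("'frames' must be a non-empty list of arrays", call. = FALSE)
  stopifnot_scalar(fps, "fps", positive = TRUE)
  shp <- dim(frames[[1]])
  if (length(shp) != 3L || shp[3] != 3L)
    stop("frames must be H x W x 3 arrays", call. = FALSE)
  for (i in seq_along(frames)) {
    if (!identical(dim(frames[[i]]), shp))
      stop(sprintf("frame %d has inconsistent shape", i - 1L), call. = FALSE)
  }
  structure(list(frames = frames, fps = fps, start_time = as_utc(start_time),
                 segment_id = as.character(segment_id)),
            class = "frame_stack")
}

#' @export
length.frame_stack <- function(x) length(x$frames)

#' @export
print.frame_stack <- function(x, ...) {
  shp <- dim(x$frames[[1]])
  cat(sprintf("<frame_stack '%s': %d frames %dx%d @ %g fps, start %s>\n",
              x$segment_id, length(x$frames), shp[2], shp[1], x$fps,
              fmt_utc(x$start_time)))
  invisible(x)
}

#' Per-frame timestamps of a stack
#' @param stack a `frame_stack`.
#' @return POSIXct vector, `start_time + k/fps` for k = 0, 1, ...
#' @export
frame_times <- function(stack) {
  stack$start_time + (seq_along(stack$frames) - 1L) / stack$fps
}

#' Write a frame stack as a lossless PNG directory
#'
#' Frames are written as `frame_000001.png`, ... plus a JSON sidecar
#' (`segment.json`) holding fps, ISO-8601 UTC start time, and segment id.
#' This is the canonical interchange format: lossless, deterministic, and
#' codec-free.
#'
#' @param stack a `frame_stack`.
#' @param path directory to create (must not contain a previous segment
#'   unless `overwrite = TRUE`).
#' @param overwrite replace an existing segment directory.
#' @return `path`, invisibly.
#' @export
write_segment <- function(stack, path, overwrite = FALSE) {
  if (dir.exists(path) && length(dir(path)) > 0L && !overwrite)
    stop(sprintf("'%s' exists and is non-empty; use overwrite = TRUE", path), call. = FALSE)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(stack$frames)) {
    img <- pmin(pmax(stack$frames[[k]], 0), 255) / 255
    png::writePNG(img, file.path(path, sprintf("frame_%06d.png", k)))
  }
  sidecar <- list(fps = stack$fps, start_time = fmt_utc(stack$start_time),
                  segment_id = stack$segment_id, n_frames = length(stack$frames))
  jsonlite::write_json(sidecar, file.path(path, "segment.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Load a recording segment
#'
#' Reads a PNG frame directory with its JSON sidecar. Start time and frame
#' rate come from the sidecar (or, failing that, a
#' `<prefix>_YYYYMMDDThhmmssZ` timestamp in the directory name together with
#' `fps_override`); missing metadata is an explicit error, never guessed.
#' Compressed video containers are not decoded; re-export them as PNG
#' directories upstream.
#'
#' @param path segment directory.
#' @param fps_override frame rate to use when the sidecar lacks one.
#' @return a `frame_stack`.
#' @export
load_segment <- function(path, fps_override = NULL) {
  if (!dir.exists(path)) {
    if (grepl("\\.(mov|mp4|avi)$", tolower(path)))
      stop("video containers are not decoded here; export the segment as a PNG frame directory first",
           call. = FALSE)
    stop(sprintf("segment path '%s' does not exist", path), call. = FALSE)
  }
  files <- sort(dir(path, pattern = "^frame_[0-9]+\\.png$", full.names = TRUE))
  if (length(files) == 0L)
    stop(sprintf("no frames found in '%s'", path), call. = FALSE)
  sidecar_path <- file.path(path, "segment.json")
  fps <- fps_override; start_time <- NULL; seg_id <- basename(path)
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path)
    if (is.null(fps)) fps <- sc$fps
    if (!is.null(sc$start_time))
      start_time <- as.POSIXct(sc$start_time, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
    if (!is.null(sc$segment_id)) seg_id <- sc$segment_id
  }
  if (is.null(start_time)) {
    m <- regmatches(basename(path),
                    regexpr("[0-9]{8}T[0-9]{6}Z", basename(path)))
    if (length(m) == 1L)
      start_time <- as.POSIXct(m, format = "%Y%m%dT%H%M%SZ", tz = "UTC")
  }
  if (is.null(fps))
    stop("frame rate unknown: no sidecar fps and no fps_override", call. = FALSE)
  if (is.null(start_time) || is.na(start_time))
    stop("start time unknown: no sidecar and no timestamp in directory name", call. = FALSE)
  frames <- vector("list", length(files))
  for (k in seq_along(files)) {
    img <- tryCatch(png::readPNG(files[k]),
                    error = function(e) stop(sprintf(
                      "frame %d ('%s') unreadable: %s", k - 1L, basename(files[k]),
                      conditionMessage(e)), call. = FALSE))
    if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
    if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
    frames[[k]] <- round(img * 255)
  }
  frame_stack(frames, fps = fps, start_time = start_time, segment_id = seg_id)
}

#' Take a consecutive subsample of frames
#'
#' Analysis of full 10-minute files is unnecessary for flow estimation; a
#' short burst (default convention: the first 10 frames, 0.33 s at 30 fps)
#' suffices. Metadata is preserved; when `from_start = FALSE` the central
#' `n` frames are taken and `start_time` is advanced accordingly.
#'
#' @param stack a `frame_stack`.
#' @param n number of frames to keep (1 <= n <= length).
#' @param from_start take the first `n` frames (default) or the central ones.
#' @return a `frame_stack` of `n` frames.
#' @export
subsample <- function(stack, n, from_start = TRUE) {
  if (!is.numeric(n) || n <= 0) stop("'n' must be a positive count", call. = FALSE)
  n <- as.integer(n)
  if (n > length(stack$frames))
    stop("'n' exceeds the number of frames", call. = FALSE)
  first <- if (from_start) 1L else (length(stack$frames) - n) %/% 2L + 1L
  idx <- first:(first + n - 1L)
  frame_stack(stack$frames[idx], fps = stack$fps,
              start_time = stack$start_time + (first - 1L) / stack$fps,
              segment_id = stack$segment_id)
}
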