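#' Frame naming convention
#'
#' Frames are stored as `VV_FFFFF.tiff`, zero-padded, where `VV` is the
#' colonoscopy video number and `FFFFF` the 1-based frame index (e.g.
#' `04_07563.tiff` is the 7563rd frame of video 4). The convention is
#' bijective: `parse_frame_filename(frame_filename(v, f))` recovers
#' `(v, f)`.
#'
#' @param video_id Positive integer video number.
#' @param frame_index Positive integer frame index (1-based).
#' @return `frame_filename`: character vector of file names.
#'   `parse_frame_filename`: data frame with columns `video_id`,
#'   `frame_index`.
#' @export
frame_filename <- function(video_id, frame_index) {
  stopifnot(all(video_id >= 1), all(frame_index >= 1))
  sprintf("%02d_%05d.tiff", as.integer(video_id), as.integer(frame_index))
}

#' @rdname frame_filename
#' @param name File name(s) in the convention (directory part ignored).
#' @export
parse_frame_filename <- function(name) {
  base <- basename(name)
  m <- regmatches(base, regexec("^([0-9]{2,})_([0-9]{5,})\\.tiff?$", base))
  bad <- lengths(m) != 3L
  if (any(bad)) stop("not in VV_FFFFF.tiff form: ", base[bad][1])
  data.frame(
    video_id = as.integer(vapply(m, `[`, "", 2L)),
    frame_index = as.integer(vapply(m, `[`, "", 3L))
  )
}

#' Extract frames into the on-disk frame database layout
#'
#' Writes each frame of an ordered source as an uncompressed 24-bit RGB
#' TIFF named by the [frame_filename()] convention, with dense 1-based
#' indices. The source is either a list of in-memory RGB frames or a
#' directory of image files taken in lexicographic order (the
#' codec-independent equivalent of a decoded 25 fps video; decoding a
#' container to ordered images is left to the host system).
#'
#' @param source List of RGB frames, or a directory path of TIFF/PNG files.
#' @param out_dir Output directory (created if missing).
#' @param video_id Video number used in the file names.
#' @return Data frame of frame references (`video_id`, `frame_index`,
#'   `path`).
#' @export
extract_frames <- function(source, out_dir, video_id = 1L) {
  if (is.character(source) && length(source) == 1L && dir.exists(source)) {
    files <- sort(list.files(source, pattern = "\\.(tiff?|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    source <- as.list(files)
  }
  if (!is.list(source) || length(source) == 0L) {
    stop("source must be a nonempty list of frames or a directory of images")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(source))
  for (i in seq_along(source)) {
    img <- tryCatch({
      x <- source[[i]]
      if (is.character(x)) {
        if (grepl("\\.png$", x, ignore.case = TRUE)) {
          as_byte_image(png::readPNG(x))
        } else {
          read_frame(x)
        }
      } else {
        as_byte_image(x)
      }
    }, error = function(e) {
      stop(sprintf("failed to read frame %d (%d frames written so far): %s",
                   i, i - 1L, conditionMessage(e)), call. = FALSE)
    })
    paths[i] <- file.path(out_dir, frame_filename(video_id, i))
    write_frame(img, paths[i])
  }
  data.frame(video_id = as.integer(video_id),
             frame_index = seq_along(source), path = paths)
}

#' Sample every step-th frame as annotation-review candidates
#'
#' Browsing one frame in every ten is enough for review: at 25 fps, ten
#' frames span 0.4 s and consecutive frames barely change.
#'
#' @param frames Data frame of frame references (or anything indexable by
#'   row).
#' @param step Sampling stride (>= 1); 1 returns the input unchanged.
#' @return The rows at indices 1, 1+step, 1+2*step, ... in order.
#' @export
sample_candidates <- function(frames, step = 10L) {
  step <- as.integer(step)
  if (is.na(step) || step < 1L) stop("step must be a positive integer")
  n <- if (is.data.frame(frames)) nrow(frames) else length(frames)
  idx <- seq.int(1L, n, by = step)
  if (is.data.frame(frames)) frames[idx, , drop = FALSE] else frames[idx]
}

#' Convert a video timestamp to a 1-based frame index
#'
#' `floor((60 * minute + second) * fps) + 1`, so 0:00 is frame 1 and at
#' 25 fps a full second spans 25 frames (0:01 begins at frame 26). Used to
#' turn the clinicians' segment-transition timestamps into frame numbers.
#'
#' @param minute,second Nonnegative integers, `second < 60`.
#' @param fps Frame rate (default 25, the video standard used).
#' @return Integer frame index (vectorised).
#' @export
timestamp_to_frame <- function(minute, second, fps = 25) {
  if (any(minute < 0) || any(second < 0) || any(second >= 60)) {
    stop("require minute >= 0 and 0 <= second < 60")
  }
  as.integer(floor((60 * minute + second) * fps) + 1)
}
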