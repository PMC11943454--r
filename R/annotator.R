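#' Write a colour-coded annotation TIFF
#'
#' Encodes a label map as a 24-bit TIFF using the pure marking colours
#' (mucosa red, residue green, artifact blue, lumen black). Pixels the
#' rule-based classifier left unclassified keep the original frame's pixel
#' when `frame` is supplied (so annotations can be reviewed against the
#' source), otherwise mid-gray (128,128,128). TIFF is mandatory: lossy
#' formats would alter the pure colours.
#'
#' @param m A [label_map()].
#' @param path Output TIFF path.
#' @param frame Optional source RGB frame backing unclassified pixels.
#' @return `path`, invisibly.
#' @export
write_color_annotation <- function(m, path, frame = NULL) {
  m <- label_map(unclass(m))
  enc <- label_encoding()$color
  h <- nrow(m); w <- ncol(m)
  img <- array(0L, c(h, w, 3L))
  for (ch in 1:3) {
    plane <- enc[m, ch]
    img[, , ch] <- matrix(plane, h, w)
  }
  uncl <- m == region_classes()[["unclassified"]]
  if (any(uncl)) {
    if (!is.null(frame)) {
      frame <- as_byte_image(frame)
      if (!all(dim(frame)[1:2] == c(h, w))) {
        stop("frame dimensions do not match the label map")
      }
      for (ch in 1:3) img[, , ch][uncl] <- frame[, , ch][uncl]
    } else {
      for (ch in 1:3) img[, , ch][uncl] <- 128L
    }
  }
  write_frame(img, path)
}

#' Write a grayscale training-label PNG
#'
#' Encodes a label map as the single-channel 8-bit PNG the network trainer
#' consumes: gray 64 / 94 / 124 / 154 for mucosa / residue / artifact /
#' lumen, background 0 for unclassified (ignored by the training loss).
#' The levels are far enough apart that annotations remain legible on
#' screen.
#'
#' @inheritParams write_color_annotation
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_training_label <- function(m, path) {
  m <- label_map(unclass(m))
  gray <- label_encoding()$gray
  img <- matrix(gray[m], nrow(m), ncol(m))
  png::writePNG(img / 255, path)
  invisible(path)
}

#' Read an annotation file back into a label map
#'
#' Inverse of [write_color_annotation()] and [write_training_label()];
#' the encoding is chosen by file extension. Pixel values outside the code
#' table raise a format error naming the offending value, unless
#' `unknown = "unclassified"` (useful for colour annotations written over a
#' source frame, where unclassified pixels hold arbitrary frame colours).
#'
#' @param path A colour-coded TIFF or grayscale PNG.
#' @param unknown How to treat values outside the code table: `"error"`
#'   (default) or `"unclassified"`.
#' @return A [label_map()].
#' @export
read_label <- function(path, unknown = c("error", "unclassified")) {
  unknown <- match.arg(unknown)
  enc <- label_encoding()
  uncl <- region_classes()[["unclassified"]]
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    v <- as.integer(round(img * 255))
    code <- match(v, enc$gray) # gray table order == region code order
    if (anyNA(code)) {
      if (unknown == "error") {
        stop(sprintf("gray value %d is not a known label code",
                     v[which(is.na(code))[1]]))
      }
      code[is.na(code)] <- uncl
    }
    # match() finds 'unclassified' (0) at position 5 already
    return(label_map(matrix(code, nrow(img), ncol(img))))
  }
  img <- read_frame(path)
  key <- img[, , 1] * 65536L + img[, , 2] * 256L + img[, , 3]
  ckeys <- enc$color[1:4, 1] * 65536L + enc$color[1:4, 2] * 256L +
    enc$color[1:4, 3]
  code <- match(key, c(ckeys, 128L * 65536L + 128L * 256L + 128L))
  code[code == 5L] <- uncl
  if (anyNA(code)) {
    if (unknown == "error") {
      i <- which(is.na(code))[1]
      stop(sprintf("RGB value (%d,%d,%d) is not a known label colour",
                   img[, , 1][i], img[, , 2][i], img[, , 3][i]))
    }
    code[is.na(code)] <- uncl
  }
  label_map(matrix(code, nrow(img), ncol(img)))
}
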