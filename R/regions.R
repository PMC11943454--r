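#' Region classes
#'
#' The five region classes a pixel can take. The segmentation network emits
#' only the first four; `unclassified` is produced exclusively by the
#' rule-based colour-cube classifier when a nuance belongs to no cube.
#'
#' @return Named integer vector mapping region names to their integer codes.
#' @examples
#' region_classes()
#' @export
region_classes <- function() {
  c(mucosa = 1L, residue = 2L, artifact = 3L, lumen = 4L, unclassified = 5L)
}

# Names in code order 1..5
region_names <- function() names(region_classes())

#' Label encodings for annotation files
#'
#' The colour code used in annotation TIFFs (pure red / green / blue / black
#' for mucosa / residue / artifact / lumen) and the grayscale code used in
#' training-label PNGs (64 / 94 / 124 / 154, background 0 for unclassified).
#'
#' @return A list with elements `color` (5 x 3 integer matrix of RGB bytes,
#'   row `unclassified` is `NA` because unclassified pixels keep the source
#'   pixel or mid-gray) and `gray` (named integer vector).
#' @export
label_encoding <- function() {
  color <- rbind(
    mucosa       = c(255L, 0L, 0L),
    residue      = c(0L, 255L, 0L),
    artifact     = c(0L, 0L, 255L),
    lumen        = c(0L, 0L, 0L),
    unclassified = c(NA_integer_, NA_integer_, NA_integer_)
  )
  colnames(color) <- c("r", "g", "b")
  gray <- c(mucosa = 64L, residue = 94L, artifact = 124L, lumen = 154L,
            unclassified = 0L)
  list(color = color, gray = gray)
}

#' Construct a label map
#'
#' A label map is an integer matrix whose cells hold region codes (see
#' [region_classes()]). This constructor validates the values and attaches
#' the `label_map` class.
#'
#' @param x Integer matrix with values in `1:5`.
#' @return The validated matrix with class `label_map`.
#' @export
label_map <- function(x) {
  if (!is.matrix(x)) stop("label map must be a matrix")
  storage.mode(x) <- "integer"
  if (anyNA(x) || any(x < 1L) || any(x > 5L)) {
    stop("label map values must be region codes in 1..5")
  }
  class(x) <- c("label_map", class(x))
  x
}

#' @export
print.label_map <- function(x, ...) {
  tab <- tabulate(x, nbins = 5L)
  pct <- 100 * tab / length(x)
  cat(sprintf("<label_map %d x %d>\n", nrow(x), ncol(x)))
  for (i in seq_len(5L)) {
    if (tab[i] > 0) cat(sprintf("  %-12s %6.2f%%\n", region_names()[i], pct[i]))
  }
  invisible(x)
}

# Coerce an image to an integer byte array (H x W x 3, values 0..255).
# Accepts doubles in [0,1] (tiff/png convention) or integers in [0,255].
as_byte_image <- function(img) {
  if (is.character(img) && length(img) == 1L) img <- read_frame(img)
  if (length(dim(img)) == 3L && dim(img)[3] >= 3L) {
    img <- img[, , 1:3, drop = FALSE]
  } else {
    stop("expected an H x W x 3 RGB image array")
  }
  if (is.double(img) && max(img) <= 1 + 1e-9) {
    img <- round(img * 255)
  }
  storage.mode(img) <- "integer"
  if (anyNA(img) || any(img < 0L) || any(img > 255L)) {
    stop("RGB values must lie in [0, 255]")
  }
  img
}

#' Read / write an RGB frame as TIFF
#'
#' Frames are held in memory as `H x W x 3` integer arrays with byte values
#' 0-255. On disk they are lossless 24-bit RGB TIFFs, the format that keeps
#' annotation colours exact (lossy compression would corrupt the pure
#' marking colours).
#'
#' @param path File path.
#' @return `read_frame`: an integer byte array. `write_frame`: `path`,
#'   invisibly.
#' @export
read_frame <- function(path) {
  img <- tiff::readTIFF(path)
  as_byte_image(img)
}

#' @rdname read_frame
#' @param img RGB image (byte array or doubles in `[0,1]`).
#' @export
write_frame <- function(img, path) {
  img <- as_byte_image(img)
  tiff::writeTIFF(img / 255, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}
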