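#' Convert 8-bit RGB to byte-coded CIELAB
#'
#' Converts sRGB bytes to CIELAB (D65, 2 degree observer) and codes the
#' result into bytes: `L_coded = round(L* * 255/100)`,
#' `a_coded = round(a* + 128)`, `b_coded = round(b* + 128)`, clamped to
#' `[0, 255]`. This byte coding makes the full gamut addressable as a
#' 256 x 256 x 256 occupancy cube.
#'
#' @param r,g,b Integer vectors of equal length with values in 0-255.
#' @return Integer matrix with columns `L`, `a`, `b`, one row per input
#'   pixel, values in 0-255.
#' @examples
#' rgb_to_lab8(0, 0, 0)       # black: L = 0, a = b = 128
#' rgb_to_lab8(255, 255, 255) # reference white: L = 255, a = b = 128
#' @export
rgb_to_lab8 <- function(r, g, b) {
  m <- cbind(as.vector(r), as.vector(g), as.vector(b))
  if (anyNA(m) || any(m < 0) || any(m > 255)) {
    stop("RGB components must lie in [0, 255]")
  }
  lab8_code(farver::convert_colour(m, from = "rgb", to = "lab"))
}

# Byte-code a continuous Lab matrix (columns L*, a*, b*).
lab8_code <- function(lab) {
  out <- cbind(
    L = round(lab[, 1] * 255 / 100),
    a = round(lab[, 2] + 128),
    b = round(lab[, 3] + 128)
  )
  out[out < 0] <- 0
  out[out > 255] <- 255
  storage.mode(out) <- "integer"
  out
}

# Coded-Lab triplet -> single integer key in [0, 2^24).
lab8_key <- function(lab8) {
  lab8[, 1] * 65536L + lab8[, 2] * 256L + lab8[, 3]
}

key_to_lab8 <- function(key) {
  cbind(L = key %/% 65536L, a = (key %/% 256L) %% 256L, b = key %% 256L)
}

# Coded-Lab matrix for all pixels of a byte image, rows in column-major
# pixel order (matching as.vector on an H x W matrix).
frame_lab8 <- function(img) {
  img <- as_byte_image(img)
  n <- prod(dim(img)[1:2])
  rgb_to_lab8(img[seq_len(n)], img[n + seq_len(n)], img[2L * n + seq_len(n)])
}

#' Build a colour-occupancy cube from a patch library
#'
#' Accumulates, for one region class, how often every coded-Lab colour
#' nuance occurs across a library of small rectangular patch images sampled
#' from that region. The cube is logically a 256 x 256 x 256 count array;
#' it is stored sparsely (sorted keys + counts) because a region library
#' touches only a tiny fraction of the 16.7 million possible nuances.
#' Nuances occurring more often are treated as more characteristic of the
#' region, which the classifier's highest-count tie-break exploits.
#'
#' @param patches A list of RGB patch images (byte arrays or `[0,1]`
#'   doubles), or a character vector of TIFF file paths, or a directory
#'   containing the patch TIFFs.
#' @param class_name Region the library describes (e.g. `"mucosa"`).
#' @return An object of class `color_cube` with fields `keys` (sorted
#'   integer Lab keys), `counts`, `n_patches`, `n_pixels` and `class`.
#' @seealso [classify_frame()], [write_cube()]
#' @export
build_cube <- function(patches, class_name = "unknown") {
  if (is.character(patches) && length(patches) == 1L && dir.exists(patches)) {
    patches <- list.files(patches, pattern = "\\.tiff?$", ignore.case = TRUE,
                          full.names = TRUE)
  }
  if (is.character(patches)) patches <- lapply(patches, read_frame)
  if (!is.list(patches) || length(patches) == 0L) {
    stop("no patch images supplied: cannot build colour features for class '",
         class_name, "'")
  }
  keys <- unlist(lapply(patches, function(p) lab8_key(frame_lab8(p))))
  agg <- sort_counts(keys)
  structure(
    list(keys = agg$keys, counts = agg$counts,
         n_patches = length(patches), n_pixels = length(keys),
         class = class_name),
    class = "color_cube"
  )
}

sort_counts <- function(keys) {
  tab <- table(keys)
  list(keys = as.integer(names(tab)), counts = as.integer(tab))
}

#' @export
print.color_cube <- function(x, ...) {
  cat(sprintf("<color_cube '%s': %d nuances from %d patches (%d pixels)>\n",
              x$class, length(x$keys), x$n_patches, x$n_pixels))
  invisible(x)
}

# Look up counts for a vector of Lab keys; absent keys count 0.
cube_counts_at <- function(cube, keys) {
  idx <- match(keys, cube$keys)
  out <- integer(length(keys))
  hit <- !is.na(idx)
  out[hit] <- cube$counts[idx[hit]]
  out
}

#' Serialize a colour cube to a sparse triplet file
#'
#' Plain-text format: first line is a JSON header with the class name and
#' accumulation totals, followed by `L,a,b,count` CSV rows. A `.gz` suffix
#' triggers gzip compression.
#'
#' @param cube A `color_cube`.
#' @param path Output path (use `.gz` for compressed output).
#' @return `read_cube`: the reconstructed `color_cube`. `write_cube`:
#'   `path`, invisibly.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "color_cube"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  header <- jsonlite::toJSON(
    list(class = cube$class, n_patches = cube$n_patches,
         n_pixels = cube$n_pixels, n_nuances = length(cube$keys)),
    auto_unbox = TRUE)
  writeLines(as.character(header), con)
  lab <- key_to_lab8(cube$keys)
  writeLines(sprintf("%d,%d,%d,%d", lab[, 1], lab[, 2], lab[, 3],
                     cube$counts), con)
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  header <- jsonlite::fromJSON(readLines(con, n = 1L))
  rows <- utils::read.csv(con, header = FALSE,
                          col.names = c("L", "a", "b", "count"))
  keys <- rows$L * 65536L + rows$a * 256L + rows$b
  o <- order(keys)
  cube <- structure(
    list(keys = as.integer(keys[o]), counts = as.integer(rows$count[o]),
         n_patches = header$n_patches, n_pixels = header$n_pixels,
         class = header$class),
    class = "color_cube")
  if (sum(cube$counts) != cube$n_pixels) {
    stop("corrupt cube file: counts do not sum to n_pixels")
  }
  cube
}

#' Rule thresholds and precedence for the colour-cube classifier
#'
#' Two luminance rules bracket the cubes: very bright pixels (coded
#' L >= `artifact_l_min`, default 253) are artifacts regardless of hue
#' (specular reflections, overexposure, text overlays), and very dark
#' pixels (coded L < `lumen_l_max`, default 50) are lumen. For the
#' remaining pixels, cube membership decides, highest count first;
#' `precedence` breaks count ties (residues first: they are rarer and
#' clinically critical).
#'
#' @param artifact_l_min Coded-L lower bound for the artifact rule.
#' @param lumen_l_max Coded-L upper bound (exclusive) for the lumen rule.
#' @param precedence Character vector ordering cube classes for ties.
#' @return An object of class `classifier_rules`.
#' @export
classifier_rules <- function(artifact_l_min = 253L, lumen_l_max = 50L,
                             precedence = c("residue", "mucosa", "lumen")) {
  artifact_l_min <- as.integer(artifact_l_min)
  lumen_l_max <- as.integer(lumen_l_max)
  if (!(0L <= lumen_l_max && lumen_l_max < artifact_l_min &&
        artifact_l_min <= 255L)) {
    stop("require 0 <= lumen_l_max < artifact_l_min <= 255")
  }
  structure(list(artifact_l_min = artifact_l_min, lumen_l_max = lumen_l_max,
                 precedence = precedence),
            class = "classifier_rules")
}

check_cubes <- function(cubes) {
  need <- c("mucosa", "residue", "lumen")
  if (!is.list(cubes) || !all(need %in% names(cubes))) {
    stop("cubes must be a named list containing at least ",
         paste(need, collapse = ", "))
  }
  ok <- vapply(cubes, inherits, logical(1), what = "color_cube")
  if (!all(ok)) stop("all elements of `cubes` must be color_cube objects")
  cubes
}

# Vectorised classification of an N x 3 coded-Lab matrix.
classify_lab8 <- function(lab8, cubes, rules = classifier_rules()) {
  cubes <- check_cubes(cubes)
  codes <- region_classes()
  n <- nrow(lab8)
  out <- rep.int(codes[["unclassified"]], n)
  is_art <- lab8[, 1] >= rules$artifact_l_min
  is_lum <- !is_art & lab8[, 1] < rules$lumen_l_max
  out[is_art] <- codes[["artifact"]]
  out[is_lum] <- codes[["lumen"]]
  rest <- which(!is_art & !is_lum)
  if (length(rest)) {
    keys <- lab8_key(lab8[rest, , drop = FALSE])
    ord <- intersect(rules$precedence, names(cubes))
    ord <- c(ord, setdiff(names(cubes), ord))
    cnt <- vapply(cubes[ord], cube_counts_at, integer(length(rest)),
                  keys = keys)
    cnt <- matrix(cnt, nrow = length(rest))
    best <- max.col(cnt, ties.method = "first") # first = precedence order
    bestcnt <- cnt[cbind(seq_along(rest), best)]
    hit <- bestcnt > 0L
    out[rest[hit]] <- codes[ord[best[hit]]]
  }
  unname(out)
}

#' Classify a single pixel by rules and cube membership
#'
#' Decision order: (1) coded L >= `artifact_l_min` is artifact; (2) coded
#' L < `lumen_l_max` is lumen; (3) among cubes containing the nuance, the
#' class with the largest count wins, ties broken by rule precedence;
#' (4) otherwise unclassified.
#'
#' @param p Coded-Lab triplet (length-3 integer vector `L, a, b`).
#' @param cubes Named list of `color_cube`s; `mucosa`, `residue` and
#'   `lumen` are required (artifacts are rule-only).
#' @param rules A [classifier_rules()] object.
#' @return Region code (named integer, see [region_classes()]).
#' @export
classify_pixel <- function(p, cubes, rules = classifier_rules()) {
  stopifnot(length(p) == 3L)
  code <- classify_lab8(matrix(as.integer(p), nrow = 1L), cubes, rules)
  structure(code, names = region_names()[code])
}

#' Classify every pixel of an RGB frame
#'
#' Applies [classify_pixel()]'s decision rule to all pixels of a frame,
#' producing the automatic annotation used to train the segmentation
#' network.
#'
#' @param frame RGB frame (byte array, `[0,1]` double array, or TIFF path).
#' @inheritParams classify_pixel
#' @return A [label_map()] with the frame's dimensions.
#' @export
classify_frame <- function(frame, cubes, rules = classifier_rules()) {
  img <- as_byte_image(frame)
  lab <- frame_lab8(img)
  label_map(matrix(classify_lab8(lab, cubes, rules),
                   nrow = dim(img)[1], ncol = dim(img)[2]))
}
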