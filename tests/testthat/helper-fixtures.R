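# Shared fixtures. Small palettes/cubes keep unit tests fast; the
# full-size study conditions live in test-acceptance.R.

tiny_palette <- function(overlap = 0) {
  region_palette(overlap = overlap, n_nuances = 400L, seed = 99L)
}

tiny_cubes <- function(pal = tiny_palette(),
                       n = c(mucosa = 25L, residue = 10L, lumen = 10L),
                       seed = 1L) {
  set.seed(seed)
  cubes <- lapply(names(n), function(cls) {
    build_cube(generate_patch_library(cls, n[[cls]], pal,
                                      size_range = c(8, 16)), cls)
  })
  stats::setNames(cubes, names(n))
}

rand_label_map <- function(h = 8L, w = 8L, classes = 1:5) {
  label_map(matrix(sample(classes, h * w, replace = TRUE), h, w))
}

rand_frame <- function(h = 8L, w = 8L) {
  array(sample(0:255, h * w * 3L, replace = TRUE), c(h, w, 3L))
}

key_to_lab8_test <- function(key) {
  c(key %/% 65536L, (key %/% 256L) %% 256L, key %% 256L)
}

# Independent colorimetry oracle: hand-coded sRGB (D65/2deg) -> CIELAB.
srgb_to_lab_ref <- function(rgb) {
  v <- rgb / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  xyz <- lin %*% t(M)
  wp <- c(0.95047, 1, 1.08883)
  xr <- sweep(xyz, 2, wp, "/")
  f <- ifelse(xr > (6 / 29)^3, xr^(1 / 3), xr * (29 / 6)^2 / 3 + 4 / 29)
  cbind(L = 116 * f[, 2] - 16,
        a = 500 * (f[, 1] - f[, 2]),
        b = 200 * (f[, 2] - f[, 3]))
}

# The scaled-down trained network is shared across test files (training it
# is the expensive step); built lazily, once.
.model_cache <- new.env(parent = emptyenv())

study_palette <- function() region_palette(overlap = 0.3, seed = 1L)

study_model <- function() {
  if (is.null(.model_cache$model)) {
    pal <- study_palette()
    set.seed(42)
    libs <- list(
      mucosa = generate_patch_library("mucosa", 209L, pal),
      residue = generate_patch_library("residue", 84L, pal),
      lumen = generate_patch_library("lumen", 154L, pal))
    cubes <- Map(build_cube, libs, names(libs))
    train_set <- lapply(1:60, function(i) {
      generate_frame(scene_spec(seed = 1000L + i), pal)
    })
    annotations <- lapply(train_set, function(g) {
      classify_frame(g$frame, cubes)
    })
    cfg <- segnet_config(64L, 64L, base_channels = 32L,
                         schedule = list(c(15, 1e-3), c(15, 7e-4),
                                         c(15, 4.9e-4)),
                         batch_size = 8L, seed = 42L)
    .model_cache$model <- train_segnet(build_segnet(cfg),
                                       lapply(train_set, `[[`, "frame"),
                                       annotations)
  }
  .model_cache$model
}
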