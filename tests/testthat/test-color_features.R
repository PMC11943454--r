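test_that("rgb_to_lab8 maps black, white and all grays to the neutral axis", {
  expect_equal(unname(rgb_to_lab8(0, 0, 0)[1, ]), c(0L, 128L, 128L))
  expect_equal(unname(rgb_to_lab8(255, 255, 255)[1, ]), c(255L, 128L, 128L))
  v <- 0:255
  lab <- rgb_to_lab8(v, v, v)
  expect_true(all(lab[, "a"] == 128L))
  expect_true(all(lab[, "b"] == 128L))
  expect_true(all(diff(lab[, "L"]) >= 0)) # luminance monotone in gray level
})

test_that("rgb_to_lab8 agrees with an independent colorimetry oracle", {
  set.seed(1)
  rgb <- matrix(sample(0:255, 1500, replace = TRUE), ncol = 3)
  got <- rgb_to_lab8(rgb[, 1], rgb[, 2], rgb[, 3])
  ref <- srgb_to_lab_ref(rgb)
  ref8 <- cbind(round(ref[, 1] * 255 / 100), round(ref[, 2] + 128),
                round(ref[, 3] + 128))
  # oracle uses its own matrix constants; allow 1 coded unit of rounding play
  expect_true(all(abs(got - ref8) <= 1))
  expect_error(rgb_to_lab8(-1, 0, 0), "\\[0, 255\\]")
  expect_error(rgb_to_lab8(0, 256, 0), "\\[0, 255\\]")
})

test_that("build_cube counts nuances and is additive", {
  uni <- array(0L, c(2, 2, 3))
  uni[, , 1] <- 180L; uni[, , 2] <- 60L; uni[, , 3] <- 40L
  cube <- build_cube(list(uni), "mucosa")
  expect_length(cube$keys, 1L)
  expect_equal(cube$counts, 4L)
  expect_equal(cube$n_pixels, 4L)
  expect_equal(cube$n_patches, 1L)

  set.seed(2)
  a <- replicate(3, rand_frame(6, 5), simplify = FALSE)
  b <- replicate(2, rand_frame(4, 7), simplify = FALSE)
  ca <- build_cube(a); cb <- build_cube(b); cab <- build_cube(c(a, b))
  expect_equal(sum(cab$counts), ca$n_pixels + cb$n_pixels)
  merged <- merge(data.frame(k = ca$keys, n = ca$counts),
                  data.frame(k = cb$keys, n = cb$counts),
                  by = "k", all = TRUE)
  merged[is.na(merged)] <- 0
  expect_equal(data.frame(k = cab$keys, n = cab$counts),
               data.frame(k = merged$k, n = as.integer(merged$n.x + merged$n.y)))
  expect_lte(length(cab$keys), cab$n_pixels)
  expect_error(build_cube(list(), "residue"), "no patch images")
})

test_that("classify_pixel follows rule order, membership and precedence", {
  cubes <- tiny_cubes()
  expect_equal(unname(classify_pixel(c(255, 128, 128), cubes)),
               unname(region_classes()[["artifact"]]))
  expect_equal(unname(classify_pixel(c(30, 140, 150), cubes)),
               unname(region_classes()[["lumen"]]))
  # nuance present only in the residue cube
  p <- key_to_lab8_test(cubes$residue$keys[1])
  only_res <- !(cubes$residue$keys[1] %in% cubes$mucosa$keys) &&
    !(cubes$residue$keys[1] %in% cubes$lumen$keys)
  expect_true(only_res) # disjoint palettes
  expect_equal(unname(classify_pixel(p, cubes)),
               unname(region_classes()[["residue"]]))
  # nuance in no cube, mid-luminance gray
  expect_equal(unname(classify_pixel(c(128, 128, 128), cubes)),
               unname(region_classes()[["unclassified"]]))
  expect_error(classify_pixel(c(100, 128, 128), cubes["mucosa"]),
               "named list")
})

test_that("classification matches a naive per-pixel reference on random pixels", {
  cubes <- tiny_cubes()
  rules <- classifier_rules()
  naive <- function(p) {
    if (p[1] >= rules$artifact_l_min) return(3L)
    if (p[1] < rules$lumen_l_max) return(4L)
    key <- p[1] * 65536L + p[2] * 256L + p[3]
    best_class <- 5L; best_count <- 0L
    for (cls in rules$precedence) {
      cube <- cubes[[cls]]
      cnt <- 0L
      for (j in seq_along(cube$keys)) {
        if (cube$keys[j] == key) { cnt <- cube$counts[j]; break }
      }
      if (cnt > best_count) {
        best_count <- cnt
        best_class <- region_classes()[[cls]]
      }
    }
    best_class
  }
  set.seed(3)
  # random pixels plus cube nuances (so membership paths are exercised)
  labs <- rbind(
    matrix(sample(0:255, 3 * 5000, replace = TRUE), ncol = 3),
    do.call(rbind, lapply(cubes, function(cc) {
      t(vapply(sample(cc$keys, 1500, replace = TRUE), key_to_lab8_test,
               integer(3)))
    }))
  )
  got <- apply(labs, 1, function(p) unname(classify_pixel(p, cubes, rules)))
  want <- apply(labs, 1, naive)
  expect_equal(got, want)
})

test_that("luminance rules always pre-empt cube membership", {
  cubes <- tiny_cubes()
  set.seed(4)
  ab <- matrix(sample(0:255, 400, replace = TRUE), ncol = 2)
  bright <- cbind(sample(253:255, 200, replace = TRUE), ab)
  dark <- cbind(sample(0:49, 200, replace = TRUE), ab)
  for (i in 1:200) {
    expect_equal(unname(classify_pixel(bright[i, ], cubes)), 3L)
    expect_equal(unname(classify_pixel(dark[i, ], cubes)), 4L)
  }
})

test_that("classify_frame labels whole frames per the pixel rule", {
  cubes <- tiny_cubes()
  white <- array(255L, c(6, 7, 3))
  m <- classify_frame(white, cubes)
  expect_s3_class(m, "label_map")
  expect_equal(dim(m), c(6L, 7L))
  expect_true(all(m == region_classes()[["artifact"]]))

  # a frame built from a mucosa patch: every nuance is in the mucosa cube,
  # so each pixel is mucosa unless a luminance rule pre-empts it
  pal <- tiny_palette()
  set.seed(5)
  patch <- generate_patch_library("mucosa", 1, pal, size_range = c(12, 12))[[1]]
  cube <- build_cube(list(patch), "mucosa")
  cubes2 <- list(mucosa = cube, residue = cubes$residue, lumen = cubes$lumen)
  m2 <- classify_frame(patch, cubes2)
  expect_true(all(m2 %in% region_classes()[c("mucosa", "artifact", "lumen")]))
  expect_gt(mean(m2 == region_classes()[["mucosa"]]), 0.99)
})

test_that("synthetic frames with known masks are recovered where nuances are known", {
  pal <- tiny_palette()
  set.seed(6)
  g <- generate_frame(scene_spec(height = 48, width = 48, seed = 7), pal)
  # inject the frame's own pixels into the cubes: recovery is then exact on
  # every pixel (rule classes agree by palette construction)
  n <- 48 * 48
  split_px <- function(cls) {
    idx <- which(unclass(g$labels) == region_classes()[[cls]])
    p <- array(0L, c(length(idx), 1, 3))
    for (ch in 1:3) p[, 1, ch] <- g$frame[idx + (ch - 1L) * n]
    p
  }
  cubes <- list(mucosa = build_cube(list(split_px("mucosa")), "mucosa"),
                residue = build_cube(list(split_px("residue")), "residue"),
                lumen = build_cube(list(split_px("lumen")), "lumen"))
  m <- classify_frame(g$frame, cubes)
  agree <- mean(m == g$labels)
  expect_gte(agree, 0.99)
})

test_that("cube serialization round-trips, compressed or not", {
  cubes <- tiny_cubes()
  for (ext in c(".cube", ".cube.gz")) {
    path <- withr::local_tempfile(fileext = ext)
    write_cube(cubes$residue, path)
    back <- read_cube(path)
    expect_equal(back, cubes$residue)
  }
})
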