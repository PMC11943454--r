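test_that("generated frames are deterministic and hit requested fractions", {
  pal <- tiny_palette()
  sp <- scene_spec(height = 48, width = 48,
                   fractions = c(mucosa = 0.7, residue = 0.1,
                                 artifact = 0.1, lumen = 0.1), seed = 5)
  g1 <- generate_frame(sp, pal)
  g2 <- generate_frame(sp, pal)
  expect_identical(g1$frame, g2$frame)
  expect_identical(g1$labels, g2$labels)
  got <- tabulate(g1$labels, 5) / (48 * 48)
  expect_true(all(abs(got[1:4] - c(0.7, 0.1, 0.1, 0.1)) <= 0.02))
  expect_equal(got[5], 0) # ground truth has no unclassified

  all_muc <- generate_frame(
    scene_spec(fractions = c(mucosa = 1, residue = 0, artifact = 0,
                             lumen = 0), seed = 1), pal)
  expect_true(all(all_muc$labels == region_classes()[["mucosa"]]))
  expect_error(scene_spec(fractions = c(mucosa = 0.9, residue = 0.9,
                                        artifact = 0, lumen = 0)),
               "infeasible")
})

test_that("palette samples satisfy the luminance rules by construction", {
  pal <- tiny_palette()
  rules <- classifier_rules()
  set.seed(1)
  lum <- coloqc:::sample_region_colors(pal, "lumen", 2000)
  lab <- rgb_to_lab8(lum[, 1], lum[, 2], lum[, 3])
  expect_true(all(lab[, 1] < rules$lumen_l_max))
  art <- coloqc:::sample_region_colors(pal, "artifact", 2000)
  lab <- rgb_to_lab8(art[, 1], art[, 2], art[, 3])
  expect_true(all(lab[, 1] >= rules$artifact_l_min))
  for (cls in c("mucosa", "residue")) {
    x <- coloqc:::sample_region_colors(pal, cls, 2000)
    lab <- rgb_to_lab8(x[, 1], x[, 2], x[, 3])
    expect_true(all(lab[, 1] >= rules$lumen_l_max &
                      lab[, 1] < rules$artifact_l_min))
  }
})

test_that("mucosa and residue palettes are disjoint at overlap 0, shared above", {
  pal0 <- tiny_palette(overlap = 0)
  expect_length(intersect(pal0$reps$mucosa$keys, pal0$reps$residue$keys), 0)
  expect_null(pal0$shared)
  pal3 <- tiny_palette(overlap = 0.3)
  expect_gt(nrow(pal3$shared$rgb), 0)
})

test_that("patch libraries have the requested size and class colours", {
  pal <- tiny_palette()
  set.seed(2)
  lib <- generate_patch_library("residue", 5, pal, size_range = c(8, 12))
  expect_length(lib, 5L)
  for (p in lib) {
    expect_true(all(dim(p)[1:2] >= 8 & dim(p)[1:2] <= 12))
    lab <- rgb_to_lab8(p[, , 1], p[, , 2], p[, , 3])
    keys <- lab[, 1] * 65536L + lab[, 2] * 256L + lab[, 3]
    expect_true(all(keys %in% pal$reps$residue$keys))
  }
  expect_error(generate_patch_library("residue", 0, pal), "at least one")
  expect_error(generate_patch_library("unclassified", 3, pal), "unclassified")
  dir <- withr::local_tempdir()
  generate_patch_library("lumen", 3, pal, size_range = c(8, 10), dir = dir)
  expect_length(list.files(dir, pattern = "lumen_\\d+\\.tiff"), 3L)
})

test_that("cube classification recovers fresh same-palette pixels", {
  pal <- tiny_palette()
  cubes <- tiny_cubes(pal)
  set.seed(3)
  g <- generate_frame(scene_spec(height = 48, width = 48, seed = 9), pal)
  m <- classify_frame(g$frame, cubes)
  expect_gte(mean(m == g$labels), 0.98)
})

test_that("recovery accuracy grows with library size", {
  pal <- tiny_palette()
  set.seed(4)
  g <- generate_frame(scene_spec(height = 40, width = 40, seed = 13), pal)
  accs <- vapply(c(2L, 30L), function(n) {
    cubes <- tiny_cubes(pal, n = c(mucosa = n, residue = n, lumen = n),
                        seed = 5)
    mean(classify_frame(g$frame, cubes) == g$labels)
  }, numeric(1))
  expect_gt(accs[2], accs[1])
  expect_gte(accs[2], 0.98)
})

test_that("pseudo-videos plant boundaries, fractions and validity correctly", {
  pal <- tiny_palette()
  vid <- generate_video(segment_frames = c(25L, 25L, 25L),
                        palette = pal, height = 16L, width = 16L, seed = 6)
  expect_length(vid$frames, 75L)
  # boundaries round-trip through mm:ss timestamps at 25 fps
  expect_equal(vid$boundaries$cut_1_2, timestamp_to_frame(0, 1))
  expect_equal(vid$boundaries$cut_2_3, timestamp_to_frame(0, 2))
  # ground-truth report agrees with direct counting
  art <- vapply(vid$truth_labels, function(m) {
    100 * mean(m == region_classes()[["artifact"]])
  }, numeric(1))
  expect_equal(vid$truth_report$overall$valid_frames, sum(art < 34))
  expect_equal(vid$truth_report$overall$total_frames, 75L)
  # determinism
  vid2 <- generate_video(segment_frames = c(25L, 25L, 25L),
                         palette = pal, height = 16L, width = 16L, seed = 6)
  expect_identical(vid$frames, vid2$frames)
  expect_error(generate_video(segment_frames = c(5L, 5L)), "three")
})

test_that("good-prep profiles dominate poor-prep profiles in ground truth", {
  pal <- tiny_palette()
  good <- generate_video(segment_frames = c(10L, 10L, 10L),
                         profiles = rep(list(quality_profile("good")), 3),
                         palette = pal, height = 16L, width = 16L, seed = 7)
  poor <- generate_video(segment_frames = c(10L, 10L, 10L),
                         profiles = rep(list(quality_profile("poor")), 3),
                         palette = pal, height = 16L, width = 16L, seed = 7)
  g <- good$truth_report$overall
  p <- poor$truth_report$overall
  expect_gt(g$valid_frames, p$valid_frames)
  expect_gt(g$pct[["mucosa"]], p$pct[["mucosa"]])
  expect_lt(g$pct[["residue"]], p$pct[["residue"]])
})
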