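test_that("frame_stats counts percentages and applies the strict validity rule", {
  m <- label_map(matrix(1L, 576, 720))
  fs <- frame_stats(m)
  expect_equal(fs$pct[["mucosa"]], 100)
  expect_true(fs$valid)

  # 100-pixel map with exactly 34 artifact pixels: 34 is not < 34
  lab <- matrix(1L, 10, 10); lab[1:34] <- 3L
  expect_false(frame_stats(label_map(lab))$valid)
  lab[34] <- 1L # 33 artifact pixels
  expect_true(frame_stats(label_map(lab))$valid)

  lab2 <- matrix(rep(c(1L, 2L, 3L, 4L), times = c(40, 30, 20, 10)), 10, 10)
  fs2 <- frame_stats(label_map(lab2))
  expect_equal(unname(fs2$pct[1:4]), c(40, 30, 20, 10))
  expect_equal(sum(fs2$pct), 100)
})

test_that("validity is monotone in the threshold", {
  set.seed(1)
  maps <- replicate(10, rand_label_map(10, 10), simplify = FALSE)
  v0 <- vapply(maps, function(m) frame_stats(m, threshold = 0)$valid,
               logical(1))
  v101 <- vapply(maps, function(m) frame_stats(m, threshold = 101)$valid,
                 logical(1))
  expect_false(any(v0))
  expect_true(all(v101))
})

# Brute-force two-pass oracle for aggregation over synthetic maps.
oracle_report <- function(maps, cut12, cut23, threshold = 34) {
  seg <- ifelse(seq_along(maps) < cut12, 1L,
                ifelse(seq_along(maps) < cut23, 2L, 3L))
  pool <- function(idx) {
    tot <- 0; cnt <- rep(0, 5); nvalid <- 0
    mu75 <- 0; re50 <- 0
    for (i in idx) {
      m <- maps[[i]]
      px <- vapply(1:5, function(k) sum(m == k), numeric(1))
      pct <- 100 * px / length(m)
      if (pct[3] < threshold) { cnt <- cnt + px; tot <- tot + length(m)
        nvalid <- nvalid + 1 }
      if (pct[1] > 75) mu75 <- mu75 + 1
      if (pct[2] > 50) re50 <- re50 + 1
    }
    list(total = length(idx), valid = nvalid,
         pct = if (tot > 0) 100 * cnt / tot else rep(NA_real_, 5),
         mu75 = mu75, re50 = re50)
  }
  list(overall = pool(seq_along(maps)),
       segments = lapply(1:3, function(s) pool(which(seg == s))))
}

test_that("aggregate_video matches a brute-force two-pass counter", {
  set.seed(2)
  pal <- tiny_palette()
  maps <- c(
    lapply(1:14, function(i) {
      f <- runif(4); f <- f / sum(f)
      generate_frame(scene_spec(height = 16, width = 16,
                                fractions = c(mucosa = f[1], residue = f[2],
                                              artifact = f[3],
                                              lumen = f[4])), pal)$labels
    }),
    replicate(6, rand_label_map(16, 16), simplify = FALSE)
  )
  set.seed(3)
  maps <- sample(maps)
  stats <- lapply(maps, frame_stats)
  rep <- aggregate_video(stats, segment_boundaries(6, 13))
  want <- oracle_report(maps, 6, 13)
  expect_equal(rep$overall$total_frames, want$overall$total)
  expect_equal(rep$overall$valid_frames, want$overall$valid)
  expect_equal(unname(rep$overall$pct), want$overall$pct)
  expect_equal(rep$overall$n_frames_mucosa_over_75, want$overall$mu75)
  expect_equal(rep$overall$n_frames_residue_over_50, want$overall$re50)
  for (s in 1:3) {
    expect_equal(rep$segments[[s]]$total_frames, want$segments[[s]]$total)
    expect_equal(rep$segments[[s]]$valid_frames, want$segments[[s]]$valid)
    expect_equal(unname(rep$segments[[s]]$pct), want$segments[[s]]$pct)
  }
  # segments partition the video
  expect_equal(sum(vapply(rep$segments, `[[`, numeric(1), "total_frames")),
               rep$overall$total_frames)
})

test_that("single- and two-frame aggregations behave as expected", {
  m100 <- label_map(matrix(1L, 4, 4))
  m0 <- label_map(matrix(4L, 4, 4))
  one <- aggregate_video(lapply(list(m100, m100, m100), frame_stats),
                         segment_boundaries(2, 3))
  expect_equal(one$segments[[1]]$pct[["mucosa"]], 100)
  two <- aggregate_video(lapply(list(m100, m0, m100, m0), frame_stats),
                         segment_boundaries(3, 4))
  expect_equal(two$segments[[1]]$pct[["mucosa"]], 50)
  expect_error(aggregate_video(list(), segment_boundaries(2, 3)), "no frame")
  expect_error(aggregate_video(lapply(list(m100, m0), frame_stats),
                               segment_boundaries(2, 3)), "exceed")
  expect_error(segment_boundaries(5, 4), "cut_1_2 < cut_2_3")
})

test_that("pooled model-map percentages sum to 100", {
  set.seed(4)
  maps <- replicate(8, rand_label_map(10, 10, classes = 1:4),
                    simplify = FALSE)
  rep <- aggregate_video(lapply(maps, frame_stats), segment_boundaries(3, 6))
  expect_equal(sum(rep$overall$pct), 100)
})

test_that("exported reports round-trip through CSV and JSON", {
  set.seed(5)
  maps <- replicate(9, rand_label_map(12, 12), simplify = FALSE)
  rep <- aggregate_video(lapply(maps, frame_stats), segment_boundaries(4, 7))
  stem <- file.path(withr::local_tempdir(), "report")
  paths <- export_report(rep, stem)
  csv <- read.csv(paste0(stem, ".csv"))
  expect_equal(nrow(csv), 20L) # 4 scopes x 5 classes
  ov <- csv[csv$scope == "overall", ]
  expect_equal(ov$pct, unname(rep$overall$pct))
  expect_equal(unique(ov$valid_frames), rep$overall$valid_frames)
  js <- jsonlite::read_json(paste0(stem, ".json"))
  expect_equal(names(js$scopes),
               c("overall", "segment_1", "segment_2", "segment_3"))
  for (sc in js$scopes) {
    expect_named(sc, c("total_frames", "valid_frames", "pct",
                       "n_frames_mucosa_over_75",
                       "n_frames_residue_over_50"))
    expect_named(sc$pct, c("mucosa", "residue", "artifact", "lumen"))
  }
  expect_equal(js$scopes$overall$total_frames, 9L)
})
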