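#' Per-frame pixel statistics and validity
#'
#' Computes the percentage of the frame's pixels in each region class and
#' flags the frame valid when the artifact percentage is strictly below the
#' validity threshold. Frames dominated by artifacts (reflections,
#' over/underexposure, overlays) would otherwise distort residue and mucosa
#' readings, so they are excluded from pooled statistics.
#'
#' @param m A [label_map()].
#' @param threshold Artifact-percentage validity threshold. The calibrated
#'   default is 34 (of the scenarios 25 / 40 / 34, the last balances
#'   retained against excluded frames).
#' @return An object of class `frame_stats`: list with `counts` (pixels per
#'   class), `pct` (percentages, sum 100 including any unclassified),
#'   `n_pixels` and `valid`.
#' @export
frame_stats <- function(m, threshold = 34) {
  m <- label_map(unclass(m))
  counts <- tabulate(m, nbins = 5L)
  names(counts) <- region_names()
  n <- length(m)
  pct <- 100 * counts / n
  structure(list(counts = counts, pct = pct, n_pixels = n,
                 valid = pct[["artifact"]] < threshold,
                 threshold = threshold),
            class = "frame_stats")
}

#' Segment boundaries of a colonoscopy video
#'
#' Frame indices at which the colon-segment transitions occur (observed by
#' clinicians as mm:ss timestamps and converted with
#' [timestamp_to_frame()]). Frames before `cut_1_2` belong to segment 1,
#' frames in `[cut_1_2, cut_2_3)` to segment 2, and frames from `cut_2_3`
#' on to segment 3 (half-open convention).
#'
#' @param cut_1_2,cut_2_3 1-based frame indices, `1 < cut_1_2 < cut_2_3`.
#' @return An object of class `segment_boundaries`.
#' @export
segment_boundaries <- function(cut_1_2, cut_2_3) {
  cut_1_2 <- as.integer(cut_1_2); cut_2_3 <- as.integer(cut_2_3)
  if (!(1L < cut_1_2 && cut_1_2 < cut_2_3)) {
    stop("require 1 < cut_1_2 < cut_2_3")
  }
  structure(list(cut_1_2 = cut_1_2, cut_2_3 = cut_2_3),
            class = "segment_boundaries")
}

segment_of_frame <- function(idx, bounds) {
  findInterval(idx, c(bounds$cut_1_2, bounds$cut_2_3)) + 1L
}

pool_stats <- function(stats, mucosa_over = 75, residue_over = 50) {
  total <- length(stats)
  valid <- vapply(stats, `[[`, logical(1), "valid")
  pooled_counts <- rep(0, 5L)
  pooled_n <- 0
  for (s in stats[valid]) {
    pooled_counts <- pooled_counts + s$counts
    pooled_n <- pooled_n + s$n_pixels
  }
  pct <- if (pooled_n > 0) 100 * pooled_counts / pooled_n else
    rep(NA_real_, 5L)
  names(pct) <- region_names()
  mu <- vapply(stats, function(s) s$pct[["mucosa"]], numeric(1))
  re <- vapply(stats, function(s) s$pct[["residue"]], numeric(1))
  list(total_frames = total, valid_frames = sum(valid), pct = pct,
       n_frames_mucosa_over_75 = sum(mu > mucosa_over),
       n_frames_residue_over_50 = sum(re > residue_over))
}

#' Aggregate frame statistics into a per-segment video report
#'
#' For the whole video and each of the three colon segments: total and
#' valid frame counts; pooled class percentages (class pixel totals over
#' valid frames divided by pixel totals over valid frames); and the counts
#' of frames with more than 75% mucosa (well-performed examination
#' indicator) and more than 50% residues (inadequate-preparation
#' indicator). The exceedance counts use all frames' per-frame
#' percentages, valid or not; both inequalities are strict.
#'
#' @param stats Ordered list of [frame_stats()], one per frame.
#' @param bounds A [segment_boundaries()] within the frame range.
#' @return An object of class `video_report`: list with `overall`, a
#'   `segments` list of three per-segment reports, and
#'   `validity_threshold`.
#' @export
aggregate_video <- function(stats, bounds) {
  if (length(stats) == 0L) stop("no frame statistics to aggregate")
  stopifnot(inherits(bounds, "segment_boundaries"))
  if (bounds$cut_2_3 > length(stats)) {
    stop("segment boundaries exceed the number of frames")
  }
  seg <- segment_of_frame(seq_along(stats), bounds)
  structure(
    list(overall = pool_stats(stats),
         segments = lapply(1:3, function(s) pool_stats(stats[seg == s])),
         validity_threshold = stats[[1]]$threshold),
    class = "video_report")
}

#' @export
print.video_report <- function(x, ...) {
  sc <- function(r, nm) {
    cat(sprintf(
      "%s: %d frames (%d valid) | mucosa %.0f%% residue %.0f%% artifact %.0f%% lumen %.0f%% | >75%% mucosa: %d, >50%% residue: %d\n",
      nm, r$total_frames, r$valid_frames, r$pct[["mucosa"]],
      r$pct[["residue"]], r$pct[["artifact"]], r$pct[["lumen"]],
      r$n_frames_mucosa_over_75, r$n_frames_residue_over_50))
  }
  cat(sprintf("<video_report, validity threshold %g%% artifacts>\n",
              x$validity_threshold))
  sc(x$overall, "overall")
  for (s in 1:3) sc(x$segments[[s]], sprintf("segment %d", s))
  invisible(x)
}

report_to_df <- function(r) {
  scopes <- c(list(overall = r$overall),
              stats::setNames(r$segments, paste0("segment_", 1:3)))
  do.call(rbind, lapply(names(scopes), function(nm) {
    s <- scopes[[nm]]
    data.frame(scope = nm, class = region_names(),
               pct = unname(s$pct), total_frames = s$total_frames,
               valid_frames = s$valid_frames,
               n_frames_mucosa_over_75 = s$n_frames_mucosa_over_75,
               n_frames_residue_over_50 = s$n_frames_residue_over_50)
  }))
}

#' Export a video report as CSV and JSON
#'
#' Writes `<path>.csv` (one row per scope x class) and `<path>.json` (the
#' per-scope summaries: total/valid frames, the four class percentages and
#' the two exceedance counts).
#'
#' @param r A [aggregate_video()] report.
#' @param path Output stem (extensions are appended).
#' @return Character vector of the two paths, invisibly.
#' @export
export_report <- function(r, path) {
  stopifnot(inherits(r, "video_report"))
  csv <- paste0(path, ".csv"); json <- paste0(path, ".json")
  utils::write.csv(report_to_df(r), csv, row.names = FALSE)
  scopes <- c(list(overall = r$overall),
              stats::setNames(r$segments, paste0("segment_", 1:3)))
  payload <- list(validity_threshold = r$validity_threshold,
                  scopes = lapply(scopes, function(s) {
                    list(total_frames = s$total_frames,
                         valid_frames = s$valid_frames,
                         pct = as.list(s$pct[1:4]),
                         n_frames_mucosa_over_75 = s$n_frames_mucosa_over_75,
                         n_frames_residue_over_50 = s$n_frames_residue_over_50)
                  }))
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, json))
}
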