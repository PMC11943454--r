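#' Threshold-based 1-3 segment quality score
#'
#' Converts a segment's pooled mucosa and residue percentages into a
#' BBPS-like quality score: 3 when mucosa visualization reaches 70% or
#' more with residues at 10% or less; 1 when mucosa is below 50% with
#' residues above 15%; 2 for everything between. The score is
#' non-decreasing in mucosa and non-increasing in residue.
#'
#' @param mucosa_pct,residue_pct Percentages in `[0, 100]` (vectorised).
#' @param thresholds Named list overriding the score thresholds
#'   (`mucosa_high = 70`, `residue_low = 10`, `mucosa_low = 50`,
#'   `residue_high = 15`).
#' @return Integer score(s) in `{1, 2, 3}`.
#' @export
segment_score <- function(mucosa_pct, residue_pct,
                          thresholds = list(mucosa_high = 70,
                                            residue_low = 10,
                                            mucosa_low = 50,
                                            residue_high = 15)) {
  if (any(mucosa_pct < 0 | mucosa_pct > 100) ||
      any(residue_pct < 0 | residue_pct > 100)) {
    stop("percentages must lie in [0, 100]")
  }
  th <- thresholds
  out <- rep.int(2L, length(mucosa_pct))
  out[mucosa_pct >= th$mucosa_high & residue_pct <= th$residue_low] <- 3L
  out[mucosa_pct < th$mucosa_low & residue_pct > th$residue_high] <- 1L
  out
}

#' Tie-corrected Spearman rank correlation
#'
#' The Pearson correlation of mid-ranks, which is the standard tie
#' correction (scores and integer percentages are heavily tied).
#'
#' @param x,y Numeric series of equal length (>= 2), neither constant.
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    stop("need two equal-length series with >= 2 observations")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation is undefined for a constant series")
  }
  stats::cor(x, y, method = "spearman")
}

#' Cohen's kappa for two categorical series
#'
#' `(p_o - p_e) / (1 - p_e)`, where `p_o` is the observed agreement
#' fraction and `p_e` the chance agreement from the product of the
#' marginal distributions over the union of observed categories.
#'
#' @param x,y Categorical series of equal length.
#' @return Kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(x, y) {
  if (length(x) != length(y) || length(x) < 1L) {
    stop("need two equal-length nonempty series")
  }
  lev <- sort(unique(c(x, y)))
  tab <- table(factor(x, lev), factor(y, lev))
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (p_e >= 1) stop("kappa is undefined when chance agreement is 1")
  (p_o - p_e) / (1 - p_e)
}

#' Per-segment test-colonoscopy dataset
#'
#' The packaged 21-segment dataset of the seven test colonoscopies
#' (T1-T7, three colon segments each): the two raters' BBPS scores, the
#' pixel-statistics score, and the pooled mucosa / residue / artifact /
#' lumen pixel percentages over valid frames (< 34% artifacts). The
#' `rule_consistent` column flags the four printed scores that no reading
#' of the score thresholds reproduces from the printed percentages; they
#' are shipped as printed, not refitted.
#'
#' @return A 21-row data frame.
#' @export
test_colonoscopy_segments <- function() {
  path <- system.file("extdata", "test_colonoscopy_segments.csv", package = "coloqc",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$rule_consistent <- as.logical(df$rule_consistent)
  df
}

#' Agreement between expert BBPS and pixel-statistics measures
#'
#' Computes, over the per-segment records, the tie-corrected Spearman
#' correlation of the expert BBPS scores against the pixel score and the
#' mucosa, residue and artifact pixel percentages, plus Cohen's kappa
#' against the pixel score. Agreement is evaluated at segment level (the
#' granularity at which paired data exist).
#'
#' @param records Data frame in the layout of [test_colonoscopy_segments()].
#' @param bbps_source Which expert series to use: `"rater1"` (default),
#'   `"rater2"`, or `"mean"` of the two.
#' @return Data frame with columns `statistic`, `value` (full precision)
#'   and `rounded` (two decimals, for comparison with reported values).
#' @export
agreement_report <- function(records = test_colonoscopy_segments(),
                             bbps_source = c("rater1", "rater2", "mean")) {
  bbps_source <- match.arg(bbps_source)
  need <- c("bbps_rater1", "bbps_rater2", "pixel_score", "mucosa_pct",
            "residue_pct", "artifact_pct")
  if (!all(need %in% names(records)) || anyNA(records[need])) {
    stop("records are missing required columns or values")
  }
  bbps <- switch(bbps_source,
                 rater1 = records$bbps_rater1,
                 rater2 = records$bbps_rater2,
                 mean = (records$bbps_rater1 + records$bbps_rater2) / 2)
  vals <- c(
    spearman_bbps_vs_pixel_score = spearman_rho(bbps, records$pixel_score),
    spearman_bbps_vs_mucosa_pct = spearman_rho(bbps, records$mucosa_pct),
    spearman_bbps_vs_residue_pct = spearman_rho(bbps, records$residue_pct),
    spearman_bbps_vs_artifact_pct = spearman_rho(bbps, records$artifact_pct),
    kappa_bbps_vs_pixel_score = cohens_kappa(bbps, records$pixel_score)
  )
  data.frame(statistic = names(vals), value = unname(vals),
             rounded = round(unname(vals), 2), n = nrow(records),
             bbps_source = bbps_source, row.names = NULL)
}
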