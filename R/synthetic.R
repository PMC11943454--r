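#' Generative colour palettes for synthetic colonoscopy regions
#'
#' Each region is modelled as a finite repertoire of distinct colour
#' nuances — the premise of the occupancy-cube method: a region spans only
#' a limited set of the 16.7 million addressable nuances. Repertoires are
#' drawn once, at palette construction, from truncated Gaussians over
#' boxes in coded-CIELAB space that mimic the field's colour structure:
#' mucosa in reds to browns, residues in yellows to browns, lumen very
#' dark, artifacts very bright (plus an optional saturated
#' orange/green/blue subtype emulating overlay text). Every candidate is
#' re-coded after RGB quantisation, so sampled lumen pixels satisfy the
#' dark rule (coded L < 50) and bright-artifact pixels the luminance rule
#' (coded L >= 253) exactly, by construction. Nuances carry unequal
#' sampling weights, making frequent nuances more characteristic — the
#' property the cube tie-break exploits.
#'
#' `overlap` (in `[0, 1]`) does two things: it slides the mucosa and
#' residue boxes toward each other along the a (green-red) and
#' b (blue-yellow) axes, and it injects a shared pool of nuances (sampled
#' from the box intersection) into both repertoires, carrying a pixel mass
#' of `0.25 * overlap` in each class. Shared nuances are genuinely
#' ambiguous from colour alone, exercising the cube tie-break and the
#' segmentation network's contextual advantage.
#'
#' @param overlap Mucosa/residue hue overlap in `[0, 1]`; 0 gives disjoint
#'   palettes.
#' @param n_nuances Target repertoire size per class (the dark lumen box
#'   supports fewer distinct nuances and may saturate below this).
#' @param saturated_artifacts Also sample saturated (non-bright) artifact
#'   colours. Off by default: those nuances do not satisfy the luminance
#'   rule and are only classifiable by the network.
#' @param seed Seed fixing the repertoires (restores the caller's RNG
#'   state afterwards).
#' @return An object of class `region_palette`.
#' @export
region_palette <- function(overlap = 0, n_nuances = 3000L,
                           saturated_artifacts = FALSE, seed = 1L) {
  stopifnot(overlap >= 0, overlap <= 1)
  rules <- classifier_rules()
  boxes <- list(
    mucosa = rbind(L = c(90, 200),
                   a = c(148 - 25 * overlap, 185),
                   b = c(130, 162 + 20 * overlap)),
    residue = rbind(L = c(100, 210),
                    a = c(115, 140 + 25 * overlap),
                    b = c(168 - 20 * overlap, 205)),
    lumen = rbind(L = c(8, 46), a = c(120, 136), b = c(120, 136))
  )
  pal <- with_preserved_seed(seed, {
    reps <- list(
      mucosa = draw_nuances(boxes$mucosa, n_nuances, "mid", rules),
      residue = draw_nuances(boxes$residue, n_nuances, "mid", rules),
      lumen = draw_nuances(boxes$lumen, n_nuances, "dark", rules)
    )
    shared <- NULL
    if (overlap > 0) {
      inter <- rbind(
        L = c(max(boxes$mucosa[1, 1], boxes$residue[1, 1]),
              min(boxes$mucosa[1, 2], boxes$residue[1, 2])),
        a = c(max(boxes$mucosa[2, 1], boxes$residue[2, 1]),
              min(boxes$mucosa[2, 2], boxes$residue[2, 2])),
        b = c(max(boxes$mucosa[3, 1], boxes$residue[3, 1]),
              min(boxes$mucosa[3, 2], boxes$residue[3, 2])))
      n_sh <- max(1L, round(0.3 * overlap * n_nuances))
      shared <- draw_nuances(inter, n_sh, "mid", rules)
    }
    weights <- lapply(reps, function(r) {
      w <- rexp(nrow(r$rgb))
      w / sum(w)
    })
    list(reps = reps, shared = shared, weights = weights)
  })
  structure(list(boxes = boxes, overlap = overlap,
                 n_nuances = n_nuances, reps = pal$reps,
                 shared = pal$shared, weights = pal$weights,
                 shared_mass = 0.25 * overlap,
                 saturated_artifacts = isTRUE(saturated_artifacts),
                 seed = seed),
            class = "region_palette")
}

with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Decode a coded-Lab matrix (possibly fractional) to continuous Lab.
lab8_decode <- function(lab8) {
  cbind(lab8[, 1] * 100 / 255, lab8[, 2] - 128, lab8[, 3] - 128)
}

rtrunc_norm <- function(n, lo, hi) {
  mu <- (lo + hi) / 2
  s <- max((hi - lo) / 6, 1e-6)
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2L * n, mu, s)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

# Draw up to n distinct nuances (RGB bytes) from a coded-Lab box,
# validated after RGB quantisation against the luminance band:
# "dark" = lumen rule, "mid" = neither luminance rule fires.
draw_nuances <- function(box, n, band, rules) {
  rgb_keep <- matrix(0L, 0L, 3L)
  seen <- integer(0)
  attempts <- 0L
  while (nrow(rgb_keep) < n && attempts < 60L) {
    attempts <- attempts + 1L
    m <- max(4L * (n - nrow(rgb_keep)), 256L)
    cand8 <- cbind(rtrunc_norm(m, box[1, 1], box[1, 2]),
                   rtrunc_norm(m, box[2, 1], box[2, 2]),
                   rtrunc_norm(m, box[3, 1], box[3, 2]))
    rgb <- farver::convert_colour(lab8_decode(cand8), "lab", "rgb")
    ok <- !is.na(rowSums(rgb)) & rowSums(rgb >= 0 & rgb <= 255) == 3L
    rgb <- round(rgb[ok, , drop = FALSE])
    if (!nrow(rgb)) next
    back <- rgb_to_lab8(rgb[, 1], rgb[, 2], rgb[, 3])
    keep <- back[, 1] >= box[1, 1] & back[, 1] <= box[1, 2] &
      back[, 2] >= box[2, 1] & back[, 2] <= box[2, 2] &
      back[, 3] >= box[3, 1] & back[, 3] <= box[3, 2]
    keep <- keep & if (band == "dark") {
      back[, 1] < rules$lumen_l_max
    } else {
      back[, 1] >= rules$lumen_l_max & back[, 1] < rules$artifact_l_min
    }
    rgb <- rgb[keep, , drop = FALSE]
    back <- back[keep, , drop = FALSE]
    key <- lab8_key(back)
    new <- !(key %in% seen) & !duplicated(key)
    seen <- c(seen, key[new])
    rgb_keep <- rbind(rgb_keep, matrix(as.integer(rgb[new, , drop = FALSE]),
                                       ncol = 3L))
  }
  if (nrow(rgb_keep) > n) rgb_keep <- rgb_keep[seq_len(n), , drop = FALSE]
  if (nrow(rgb_keep) == 0L) stop("nuance box is empty")
  list(rgb = rgb_keep, keys = seen[seq_len(nrow(rgb_keep))])
}

# Draw n RGB byte colours for one region class from a palette.
sample_region_colors <- function(palette, class, n,
                                 rules = classifier_rules()) {
  stopifnot(inherits(palette, "region_palette"), n >= 1)
  if (class == "artifact") return(sample_artifact_colors(palette, n, rules))
  rep <- palette$reps[[class]]
  if (is.null(rep)) stop("no palette for class ", class)
  rgb <- rep$rgb
  w <- palette$weights[[class]]
  use_shared <- logical(n)
  if (!is.null(palette$shared) && class %in% c("mucosa", "residue") &&
      palette$shared_mass > 0) {
    use_shared <- runif(n) < palette$shared_mass
  }
  out <- matrix(0L, n, 3L)
  n_own <- sum(!use_shared)
  if (n_own > 0) {
    idx <- sample.int(nrow(rgb), n_own, replace = TRUE, prob = w)
    out[!use_shared, ] <- rgb[idx, , drop = FALSE]
  }
  if (any(use_shared)) {
    sh <- palette$shared$rgb
    idx <- sample.int(nrow(sh), sum(use_shared), replace = TRUE)
    out[use_shared, ] <- sh[idx, , drop = FALSE]
  }
  out
}

sample_artifact_colors <- function(palette, n, rules) {
  out <- matrix(0L, 0L, 3L)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 64L)
    rgb <- matrix(sample(250:255, 3L * m, replace = TRUE), ncol = 3L)
    keep <- rgb_to_lab8(rgb[, 1], rgb[, 2], rgb[, 3])[, 1] >=
      rules$artifact_l_min
    out <- rbind(out, rgb[keep, , drop = FALSE])
  }
  out <- out[seq_len(n), , drop = FALSE]
  if (palette$saturated_artifacts) {
    base <- rbind(c(255, 140, 0), c(0, 220, 30), c(20, 60, 255))
    pick <- base[sample.int(3L, n, replace = TRUE), , drop = FALSE]
    jit <- matrix(sample(-20:20, 3L * n, replace = TRUE), ncol = 3L)
    sat <- pmin(pmax(pick + jit, 0L), 255L)
    use_sat <- runif(n) < 0.5
    out[use_sat, ] <- sat[use_sat, ]
  }
  matrix(as.integer(out), ncol = 3L)
}

#' Scene specification for one synthetic frame
#'
#' @param height,width Frame size in pixels.
#' @param fractions Named target area fractions for `mucosa`, `residue`,
#'   `artifact`, `lumen`; must be nonnegative and sum to 1.
#' @param smoothness Gaussian smoothing radius (pixels) of the latent
#'   field; larger values give fewer, larger blobs.
#' @param seed Optional seed fixing the scene exactly.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(height = 64L, width = 64L,
                       fractions = c(mucosa = 0.7, residue = 0.1,
                                     artifact = 0.1, lumen = 0.1),
                       smoothness = 6, seed = NULL) {
  need <- c("mucosa", "residue", "artifact", "lumen")
  if (!all(need %in% names(fractions)) || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-6) {
    stop("infeasible area fractions: need named nonnegative fractions for ",
         paste(need, collapse = ", "), " summing to 1")
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 fractions = fractions[need], smoothness = smoothness,
                 seed = seed),
            class = "scene_spec")
}

blur_matrix <- function(n, sd) {
  if (sd <= 0) return(diag(n))
  K <- outer(seq_len(n), seq_len(n),
             function(i, j) exp(-(i - j)^2 / (2 * sd^2)))
  K / rowSums(K)
}

#' Generate one synthetic colonoscopy-like frame with ground truth
#'
#' A Gaussian-smoothed noise field is thresholded at the empirical
#' quantiles of the requested area fractions, giving organic connected
#' blobs with exact areas. Level bands map to classes in physical order:
#' the field's minima become lumen (dark cavities), its peaks artifacts
#' (bright reflections), with mucosa and residue in between. Every pixel's
#' colour is drawn from its region's palette sampler.
#'
#' @param spec A [scene_spec()].
#' @param palette A [region_palette()].
#' @return List with `frame` (RGB byte array) and `labels` (ground-truth
#'   [label_map()]).
#' @export
generate_frame <- function(spec, palette = region_palette()) {
  stopifnot(inherits(spec, "scene_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  h <- spec$height; w <- spec$width; n <- h * w
  field <- blur_matrix(h, spec$smoothness) %*%
    matrix(rnorm(n), h, w) %*% t(blur_matrix(w, spec$smoothness))
  # band order along the field: lumen (low) .. artifact (peaks)
  band_classes <- c("lumen", "mucosa", "residue", "artifact")
  f <- spec$fractions[band_classes]
  counts <- round(f * n)
  counts[length(counts)] <- n - sum(counts[-length(counts)])
  ord <- order(field)
  codes <- region_classes()
  lab <- integer(n)
  at <- 1L
  for (k in seq_along(band_classes)) {
    if (counts[k] > 0) {
      lab[ord[at:(at + counts[k] - 1L)]] <- codes[[band_classes[k]]]
      at <- at + counts[k]
    }
  }
  labels <- label_map(matrix(lab, h, w))
  frame <- array(0L, c(h, w, 3L))
  for (cls in band_classes) {
    idx <- which(lab == codes[[cls]])
    if (!length(idx)) next
    cols <- sample_region_colors(palette, cls, length(idx))
    for (ch in 1:3) frame[idx + (ch - 1L) * n] <- cols[, ch]
  }
  list(frame = frame, labels = labels)
}

#' Generate a synthetic patch library for one region class
#'
#' Small rectangular patches (default 30-80 px squares, the scale of real
#' patch thumbnails) whose pixels are drawn i.i.d. from the class palette.
#' Reference library sizes in this workflow are 209 (mucosa), 84
#' (residues) and 154 (lumen) patches.
#'
#' @param class One of `"mucosa"`, `"residue"`, `"lumen"`, `"artifact"`.
#' @param n Number of patches (>= 1).
#' @param palette A [region_palette()].
#' @param size_range Min/max patch side length in pixels.
#' @param seed Optional seed.
#' @param dir Optional directory; when given, patches are also written as
#'   TIFF files (`<class>_NNN.tiff`).
#' @return List of RGB byte arrays.
#' @export
generate_patch_library <- function(class, n, palette = region_palette(),
                                   size_range = c(30, 80), seed = NULL,
                                   dir = NULL) {
  if (class == "unclassified") stop("no palette exists for 'unclassified'")
  if (n < 1) stop("need at least one patch")
  if (!is.null(seed)) set.seed(seed)
  patches <- vector("list", n)
  for (i in seq_len(n)) {
    h <- sample(size_range[1]:size_range[2], 1L)
    w <- sample(size_range[1]:size_range[2], 1L)
    cols <- sample_region_colors(palette, class, h * w)
    p <- array(0L, c(h, w, 3L))
    for (ch in 1:3) p[, , ch] <- matrix(cols[, ch], h, w)
    patches[[i]] <- p
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      write_frame(patches[[i]],
                  file.path(dir, sprintf("%s_%03d.tiff", class, i)))
    }
  }
  patches
}

#' Preset per-segment quality profiles
#'
#' `"good"` emulates a well-prepared colonoscopy (high mucosa, little
#' residue, few artifact-dominated frames); `"poor"` an inadequately
#' prepared one (low mucosa, heavy residues, frequent artifact bursts that
#' push frames over the 34% validity threshold).
#'
#' @param name `"good"` or `"poor"`.
#' @return List with `fractions` (mean area fractions) and `jitter`
#'   (per-frame Gaussian sd of each fraction).
#' @export
quality_profile <- function(name = c("good", "poor")) {
  name <- match.arg(name)
  if (name == "good") {
    list(fractions = c(mucosa = 0.80, residue = 0.03, artifact = 0.07,
                       lumen = 0.10),
         jitter = c(mucosa = 0.06, residue = 0.02, artifact = 0.05,
                    lumen = 0.03))
  } else {
    list(fractions = c(mucosa = 0.33, residue = 0.25, artifact = 0.28,
                       lumen = 0.14),
         jitter = c(mucosa = 0.06, residue = 0.05, artifact = 0.12,
                    lumen = 0.04))
  }
}

#' Generate a synthetic pseudo-video with planted segment structure
#'
#' Produces an ordered frame sequence with three colon segments, each
#' following its own quality profile: per-frame area fractions are the
#' profile means plus Gaussian jitter (clipped and renormalised), so
#' artifact-heavy profiles plant frames that fail the validity threshold.
#' Returns the ground-truth label maps and the ground-truth video report
#' computed from them by direct counting.
#'
#' @param segment_frames Integer vector of three per-segment frame counts.
#' @param profiles List of three profiles (see [quality_profile()]).
#' @param palette A [region_palette()].
#' @param height,width Frame size.
#' @param smoothness Blob smoothness (see [scene_spec()]).
#' @param seed Seed fixing the whole video.
#' @param validity_threshold Artifact threshold for the ground-truth
#'   report.
#' @return List with `frames`, `truth_labels`, `boundaries`
#'   ([segment_boundaries()]), `truth_report` ([aggregate_video()] of the
#'   ground truth) and `fps` (25).
#' @export
generate_video <- function(segment_frames = c(10L, 10L, 10L),
                           profiles = list(quality_profile("poor"),
                                           quality_profile("poor"),
                                           quality_profile("good")),
                           palette = region_palette(),
                           height = 64L, width = 64L, smoothness = 6,
                           seed = 1L, validity_threshold = 34) {
  if (length(segment_frames) != 3L || any(segment_frames < 1L)) {
    stop("need three positive per-segment frame counts")
  }
  if (length(profiles) != 3L) stop("need three segment profiles")
  set.seed(seed)
  n <- sum(segment_frames)
  seg_of <- rep(1:3, times = segment_frames)
  frames <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    pr <- profiles[[seg_of[i]]]
    f <- pr$fractions + rnorm(4L) * pr$jitter
    f <- pmax(f, 0.002)
    f <- f / sum(f)
    sc <- scene_spec(height, width, fractions = f, smoothness = smoothness)
    g <- generate_frame(sc, palette)
    frames[[i]] <- g$frame
    truth[[i]] <- g$labels
  }
  bounds <- segment_boundaries(segment_frames[1] + 1L,
                               segment_frames[1] + segment_frames[2] + 1L)
  truth_stats <- lapply(truth, frame_stats, threshold = validity_threshold)
  list(frames = frames, truth_labels = truth, boundaries = bounds,
       truth_report = aggregate_video(truth_stats, bounds), fps = 25)
}
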