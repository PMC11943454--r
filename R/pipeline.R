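#' Pipeline configuration
#'
#' Collects every tunable of the pipeline in one object. The defaults are
#' the calibrated operating point: artifact luminance rule at coded
#' L >= 253, lumen rule at coded L < 50, 34% artifact validity threshold,
#' score thresholds 70/10 and 50/15, 25 fps, and the network schedule of
#' 50 epochs at 0.001, 50 at 0.0007 and 50 at 0.00049 with mini-batches of
#' 48 frames. `synth` holds the synthetic-video parameters used when the
#' pipeline runs on generated data.
#'
#' @param workdir Directory for all pipeline artifacts.
#' @param rules A [classifier_rules()].
#' @param segnet A [segnet_config()].
#' @param validity_threshold Artifact validity threshold (percent).
#' @param score_thresholds Score thresholds (see [segment_score()]).
#' @param fps Video frame rate.
#' @param seed Master seed; every stochastic stage derives from it.
#' @param bbps_source Expert series for the agreement stage.
#' @param synth List of [generate_video()] arguments for the synth stage.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(workdir = tempfile("coloqc_"),
                            rules = classifier_rules(),
                            segnet = segnet_config(),
                            validity_threshold = 34,
                            score_thresholds = list(mucosa_high = 70,
                                                    residue_low = 10,
                                                    mucosa_low = 50,
                                                    residue_high = 15),
                            fps = 25, seed = 1L,
                            bbps_source = "rater1",
                            synth = list(segment_frames = c(10L, 10L, 10L),
                                         overlap = 0,
                                         height = 64L, width = 64L,
                                         n_patches = c(mucosa = 209L,
                                                       residue = 84L,
                                                       lumen = 154L))) {
  structure(list(workdir = workdir, rules = rules, segnet = segnet,
                 validity_threshold = validity_threshold,
                 score_thresholds = score_thresholds, fps = fps,
                 seed = as.integer(seed), bbps_source = bbps_source,
                 synth = synth),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param cfg A [pipeline_config()].
#' @param path YAML file path.
#' @return `read_pipeline_config`: the configuration.
#'   `write_pipeline_config`: `path`, invisibly.
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(rapply(unclass(cfg), unclass, how = "replace"), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  for (nm in intersect(names(raw), names(cfg))) cfg[[nm]] <- raw[[nm]]
  cfg$rules <- do.call(classifier_rules, as.list(cfg$rules))
  sn <- as.list(cfg$segnet)
  sn <- sn[setdiff(names(sn), "n_classes")]
  if (!is.null(sn$schedule)) sn$schedule <- lapply(sn$schedule, unlist)
  cfg$segnet <- do.call(segnet_config, sn)
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(rapply(unclass(cfg), unclass, how = "replace"), tmp,
                       auto_unbox = TRUE, digits = 12, force = TRUE)
  unname(tools::md5sum(tmp))
}

pipeline_paths <- function(cfg) {
  w <- cfg$workdir
  list(frames = file.path(w, "frames"),
       patches = file.path(w, "patches"),
       cubes = file.path(w, "cubes"),
       annotations = file.path(w, "annotations"),
       labels = file.path(w, "labels"),
       truth = file.path(w, "truth"),
       predictions = file.path(w, "predictions"),
       model = file.path(w, "model.rds"),
       boundaries = file.path(w, "boundaries.json"),
       report = file.path(w, "report"),
       scores = file.path(w, "scores.json"),
       agreement = file.path(w, "agreement.csv"),
       manifest = file.path(w, "manifest.json"))
}

require_artifact <- function(path, producer) {
  if (!file.exists(path)) {
    stop(sprintf("missing artifact '%s': run the '%s' stage first",
                 path, producer), call. = FALSE)
  }
  path
}

#' Run the pipeline end to end
#'
#' Executes the requested stages in order inside `cfg$workdir`, each stage
#' reading the artifacts of its producers and logging what it wrote. The
#' stages mirror the data flow from video to quality score: `synth`
#' (generate a pseudo-video; skipped when real frames are supplied),
#' `build-features` (patch libraries to colour cubes), `annotate` (cube
#' classification to colour TIFFs + training PNGs), `train`, `segment`,
#' `stats` (per-frame and per-segment statistics), `score` (1-3 segment
#' scores) and `agreement` (packaged per-segment dataset vs expert BBPS).
#' A manifest records the configuration hash, so identical configurations
#' give identical manifests.
#'
#' @param cfg A [pipeline_config()].
#' @param stages Character vector of stage names, in execution order.
#' @param quiet Suppress per-stage log lines.
#' @return The manifest (list), invisibly.
#' @export
run_pipeline <- function(cfg = pipeline_config(),
                         stages = c("synth", "build-features", "annotate",
                                    "train", "segment", "stats", "score",
                                    "agreement"),
                         quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  p <- pipeline_paths(cfg)
  dir.create(cfg$workdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  palette <- region_palette(overlap = cfg$synth$overlap)
  outputs <- list()
  for (stage in stages) {
    say("[%s] starting", stage)
    outputs[[stage]] <- switch(
      stage,
      "synth" = {
        vid <- generate_video(
          segment_frames = cfg$synth$segment_frames,
          palette = palette, height = cfg$synth$height,
          width = cfg$synth$width, seed = cfg$seed,
          validity_threshold = cfg$validity_threshold)
        refs <- extract_frames(vid$frames, p$frames, video_id = 1L)
        dir.create(p$truth, showWarnings = FALSE)
        for (i in seq_along(vid$truth_labels)) {
          write_training_label(vid$truth_labels[[i]], file.path(
            p$truth, sub("\\.tiff$", ".png", basename(refs$path[i]))))
        }
        jsonlite::write_json(list(cut_1_2 = vid$boundaries$cut_1_2,
                                  cut_2_3 = vid$boundaries$cut_2_3),
                             p$boundaries, auto_unbox = TRUE)
        say("[synth] wrote %d frames to %s", nrow(refs), p$frames)
        list(n_frames = nrow(refs))
      },
      "build-features" = {
        dir.create(p$cubes, showWarnings = FALSE)
        set.seed(cfg$seed + 1L)
        for (cls in names(cfg$synth$n_patches)) {
          lib <- generate_patch_library(cls, cfg$synth$n_patches[[cls]],
                                        palette)
          cube <- build_cube(lib, cls)
          write_cube(cube, file.path(p$cubes, paste0(cls, ".cube.gz")))
          say("[build-features] %s: %d nuances", cls, length(cube$keys))
        }
        list(classes = names(cfg$synth$n_patches))
      },
      "annotate" = {
        require_artifact(p$frames, "synth")
        require_artifact(p$cubes, "build-features")
        cubes <- load_cube_dir(p$cubes)
        dir.create(p$annotations, showWarnings = FALSE)
        dir.create(p$labels, showWarnings = FALSE)
        files <- list.files(p$frames, pattern = "\\.tiff$",
                            full.names = TRUE)
        for (f in files) {
          m <- classify_frame(f, cubes, cfg$rules)
          write_color_annotation(m, file.path(p$annotations, basename(f)),
                                 frame = f)
          write_training_label(m, file.path(
            p$labels, sub("\\.tiff$", ".png", basename(f))))
        }
        say("[annotate] annotated %d frames", length(files))
        list(n_frames = length(files))
      },
      "train" = {
        require_artifact(p$frames, "synth")
        require_artifact(p$labels, "annotate")
        frames <- list.files(p$frames, pattern = "\\.tiff$",
                             full.names = TRUE)
        labels <- file.path(p$labels,
                            sub("\\.tiff$", ".png", basename(frames)))
        model <- train_segnet(build_segnet(cfg$segnet), frames, labels)
        save_segnet(model, p$model)
        say("[train] final mini-batch accuracy %.4f, loss %.4f",
            model$final_accuracy, model$final_loss)
        list(final_accuracy = model$final_accuracy,
             final_loss = model$final_loss)
      },
      "segment" = {
        require_artifact(p$frames, "synth")
        require_artifact(p$model, "train")
        model <- load_segnet(p$model)
        dir.create(p$predictions, showWarnings = FALSE)
        files <- list.files(p$frames, pattern = "\\.tiff$",
                            full.names = TRUE)
        for (f in files) {
          write_training_label(predict(model, f), file.path(
            p$predictions, sub("\\.tiff$", ".png", basename(f))))
        }
        say("[segment] segmented %d frames", length(files))
        list(n_frames = length(files))
      },
      "stats" = {
        require_artifact(p$predictions, "segment")
        require_artifact(p$boundaries, "synth")
        bj <- jsonlite::read_json(p$boundaries)
        bounds <- segment_boundaries(bj$cut_1_2, bj$cut_2_3)
        files <- list.files(p$predictions, pattern = "\\.png$",
                            full.names = TRUE)
        stats <- lapply(files, function(f) {
          frame_stats(read_label(f), threshold = cfg$validity_threshold)
        })
        report <- aggregate_video(stats, bounds)
        export_report(report, p$report)
        say("[stats] report written to %s.{csv,json}", p$report)
        report_to_df(report)
      },
      "score" = {
        require_artifact(paste0(p$report, ".json"), "stats")
        rep <- jsonlite::read_json(paste0(p$report, ".json"))
        segs <- rep$scopes[paste0("segment_", 1:3)]
        scores <- vapply(segs, function(s) {
          segment_score(s$pct$mucosa, s$pct$residue,
                        thresholds = cfg$score_thresholds)
        }, integer(1))
        jsonlite::write_json(as.list(scores), p$scores, auto_unbox = TRUE)
        say("[score] segment scores: %s", paste(scores, collapse = " "))
        scores
      },
      "agreement" = {
        agr <- agreement_report(bbps_source = cfg$bbps_source)
        utils::write.csv(agr, p$agreement, row.names = FALSE)
        say("[agreement] %s", paste(sprintf("%s=%.2f", agr$statistic,
                                            agr$value), collapse = ", "))
        agr
      },
      stop("unknown stage: ", stage)
    )
  }
  manifest <- list(config_hash = config_hash(cfg),
                   stages = stages,
                   outputs = rapply(outputs, unclass, how = "replace"))
  jsonlite::write_json(manifest, p$manifest, auto_unbox = TRUE, digits = 12,
                       force = TRUE)
  invisible(manifest)
}

#' Load every cube file in a directory
#'
#' @param dir Directory of `<class>.cube[.gz]` files written by
#'   [write_cube()].
#' @return Named list of `color_cube`s keyed by class name.
#' @export
load_cube_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.cube(\\.gz)?$", full.names = TRUE)
  if (!length(files)) stop("no cube files in ", dir)
  cubes <- lapply(files, read_cube)
  stats::setNames(cubes, vapply(cubes, `[[`, "", "class"))
}
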