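#' Configuration for the segmentation network
#'
#' The network takes an RGB frame, halves its spatial dimensions twice
#' through stride-2 convolutions (channel-doubling 3x3 kernels), mirrors
#' the reduction with two x2 upsampling + convolution blocks, and projects
#' each pixel to 4 class scores with a 1x1 convolution. Inputs are
#' zero-centered by subtracting the per-channel mean of the training
#' frames. Training uses SGD with momentum and a staged learning-rate
#' schedule; the canonical schedule is 50 epochs at 0.001, 50 at 0.0007
#' and 50 at 0.00049 with mini-batches of 48 frames on 576 x 720 inputs.
#'
#' @param input_height,input_width Frame dimensions; must be divisible by 4
#'   so two halvings invert exactly (canonical 576 x 720).
#' @param base_channels Channel width of the first encoder block (the
#'   second block uses twice as many).
#' @param schedule List of `c(epochs, learning_rate)` stages.
#' @param batch_size Frames per SGD step.
#' @param momentum SGD momentum coefficient.
#' @param shuffle Reshuffle the frame order every epoch.
#' @param seed Seed fixing weight initialisation and shuffling.
#' @return An object of class `segnet_config`.
#' @export
segnet_config <- function(input_height = 576L, input_width = 720L,
                          base_channels = 32L,
                          schedule = list(c(50, 0.001), c(50, 7e-4),
                                          c(50, 4.9e-4)),
                          batch_size = 48L, momentum = 0.9,
                          shuffle = TRUE, seed = 1L) {
  if (input_height %% 4L != 0L || input_width %% 4L != 0L) {
    stop("input dimensions must be divisible by 4 ",
         "(two stride-2 reductions must invert exactly)")
  }
  stopifnot(base_channels >= 1L, batch_size >= 1L, length(schedule) >= 1L)
  for (st in schedule) {
    if (length(st) != 2L || st[1] < 1 || st[2] <= 0) {
      stop("each schedule stage must be c(epochs >= 1, learning_rate > 0)")
    }
  }
  structure(list(input_height = as.integer(input_height),
                 input_width = as.integer(input_width),
                 base_channels = as.integer(base_channels),
                 n_classes = 4L, schedule = schedule,
                 batch_size = as.integer(batch_size), momentum = momentum,
                 shuffle = isTRUE(shuffle), seed = as.integer(seed)),
            class = "segnet_config")
}

# Layer shapes: list of (out_channels, in_channels, kernel_pixels)
segnet_layer_dims <- function(cfg) {
  C <- cfg$base_channels
  list(c(C, 3L, 9L), c(2L * C, C, 9L), c(C, 2L * C, 9L), c(C, C, 9L),
       c(4L, C, 1L))
}

#' Number of trainable parameters
#'
#' @param x A `segnet_config` or `segnet_model`.
#' @return Integer count of weights plus biases.
#' @export
segnet_n_params <- function(x) {
  cfg <- if (inherits(x, "segnet_model")) x$cfg else x
  sum(vapply(segnet_layer_dims(cfg),
             function(d) d[1] * d[2] * d[3] + d[1], numeric(1)))
}

#' Build an (untrained) segmentation network
#'
#' Initialises weights with He-scaled Gaussians under the configuration
#' seed, so a build is reproducible.
#'
#' @param cfg A [segnet_config()].
#' @return An object of class `segnet_model` (untrained: channel means are
#'   unset until [train_segnet()] runs).
#' @export
build_segnet <- function(cfg = segnet_config()) {
  stopifnot(inherits(cfg, "segnet_config"))
  dims <- segnet_layer_dims(cfg)
  weights <- vector("list", 10L)
  names(weights) <- c(paste0("W", 1:5), paste0("b", 1:5))
  set.seed(cfg$seed)
  for (l in seq_along(dims)) {
    d <- dims[[l]]
    fan_in <- d[2] * d[3]
    weights[[l]] <- matrix(rnorm(d[1] * fan_in, sd = sqrt(2 / fan_in)),
                           nrow = d[1])
    weights[[5L + l]] <- numeric(d[1])
  }
  structure(list(cfg = cfg, weights = weights, channel_means = c(0, 0, 0),
                 trained = FALSE, history = NULL),
            class = "segnet_model")
}

#' @export
print.segnet_model <- function(x, ...) {
  cat(sprintf("<segnet_model %dx%d, base %d channels, %d parameters, %s>\n",
              x$cfg$input_height, x$cfg$input_width, x$cfg$base_channels,
              segnet_n_params(x), if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# Decode one training input. Frames: path or array -> centered double cube.
prep_frame <- function(frame, cfg) {
  img <- as_byte_image(frame)
  if (dim(img)[1] != cfg$input_height || dim(img)[2] != cfg$input_width) {
    stop(sprintf("frame is %dx%d but the model expects %dx%d",
                 dim(img)[1], dim(img)[2],
                 cfg$input_height, cfg$input_width))
  }
  array(as.double(img), dim(img))
}

# Decode a training label (PNG path, label_map, or integer matrix) into the
# class-index matrix the loss consumes: 1..4, 0 = ignore.
prep_label <- function(label, cfg) {
  if (is.character(label)) label <- read_label(label)
  if (!is.matrix(label)) stop("labels must be matrices or PNG paths")
  y <- unclass(label)
  storage.mode(y) <- "integer"
  if (anyNA(y) || any(y < 1L) || any(y > 5L)) {
    stop("label values outside the region code table; aborting before ",
         "training")
  }
  y[y == region_classes()[["unclassified"]]] <- 0L
  if (nrow(y) != cfg$input_height || ncol(y) != cfg$input_width) {
    stop("label dimensions do not match the model input size")
  }
  y
}

#' Train the segmentation network
#'
#' Minimises pixel-wise softmax cross-entropy over the four region classes
#' with SGD (momentum per the configuration). Unannotated pixels (gray 0 in
#' the training PNGs / `unclassified` in label maps) are excluded from the
#' loss, which lets the network extend the sparse "clouds" of rule-annotated
#' pixels into compact regions. Frames are zero-centered with their
#' per-channel training mean, and the presentation order is reshuffled each
#' epoch. With a fixed configuration seed the run is reproducible.
#'
#' @param model A [build_segnet()] model (retraining restarts from its
#'   current weights).
#' @param frames List of RGB frames (arrays or TIFF paths).
#' @param labels List of matching labels ([label_map()]s, class matrices,
#'   or grayscale PNG paths), in the same order.
#' @return The trained `segnet_model`, with a `history` data frame of
#'   per-mini-batch loss and accuracy and `final_accuracy` / `final_loss`
#'   fields (metrics of the last mini-batch, in `[0,1]` / nonnegative).
#' @export
train_segnet <- function(model, frames, labels) {
  stopifnot(inherits(model, "segnet_model"))
  cfg <- model$cfg
  if (length(frames) < 1L || length(frames) != length(labels)) {
    stop("need >= 1 frame/label pair, in matching order")
  }
  X <- lapply(frames, prep_frame, cfg = cfg)
  Y <- lapply(labels, prep_label, cfg = cfg)
  ch_mean <- c(
    mean(vapply(X, function(a) mean(a[, , 1]), numeric(1))),
    mean(vapply(X, function(a) mean(a[, , 2]), numeric(1))),
    mean(vapply(X, function(a) mean(a[, , 3]), numeric(1)))
  )
  for (i in seq_along(X)) {
    for (ch in 1:3) X[[i]][, , ch] <- X[[i]][, , ch] - ch_mean[ch]
  }
  n <- length(X)
  epochs <- vapply(cfg$schedule, `[`, numeric(1), 1L)
  lrs <- vapply(cfg$schedule, `[`, numeric(1), 2L)
  total_epochs <- sum(epochs)
  set.seed(cfg$seed)
  perms <- matrix(0L, nrow = total_epochs, ncol = n)
  for (e in seq_len(total_epochs)) {
    perms[e, ] <- if (cfg$shuffle) sample.int(n) else seq_len(n)
  }
  fit <- .segnet_train_cpp(X, Y, model$weights, as.integer(epochs), lrs,
                           cfg$batch_size, cfg$momentum, perms)
  model$weights <- fit$weights
  model$channel_means <- ch_mean
  model$trained <- TRUE
  model$history <- data.frame(stage = fit$stage,
                              batch = seq_along(fit$loss),
                              loss = fit$loss, accuracy = fit$accuracy)
  model$final_loss <- fit$loss[length(fit$loss)]
  model$final_accuracy <- fit$accuracy[length(fit$accuracy)]
  model
}

#' Segment a frame with a trained network
#'
#' Arg-max over the four per-pixel class scores. Every pixel receives one
#' of the four region labels; unlike the rule-based classifier, the
#' network never outputs `unclassified`.
#'
#' @param object A `segnet_model`.
#' @param frame RGB frame matching the model input size (array or TIFF
#'   path).
#' @param ... Unused.
#' @return A [label_map()] containing only codes 1-4.
#' @export
predict.segnet_model <- function(object, frame, ...) {
  x <- prep_frame(frame, object$cfg)
  for (ch in 1:3) x[, , ch] <- x[, , ch] - object$channel_means[ch]
  label_map(.segnet_predict_cpp(x, object$weights))
}

#' Pixel accuracy of predictions against a reference labeling
#'
#' Fraction of pixels where `pred` matches `ref`, restricted to pixels
#' where `ref` is one of the four regions (unclassified reference pixels
#' carry no ground truth and are skipped).
#'
#' @param pred,ref Label maps of equal size.
#' @return Fraction in `[0, 1]`.
#' @export
pixel_accuracy <- function(pred, ref) {
  stopifnot(all(dim(pred) == dim(ref)))
  keep <- ref != region_classes()[["unclassified"]]
  if (!any(keep)) stop("reference labeling has no annotated pixels")
  mean(pred[keep] == ref[keep])
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the configuration, weights and zero-center
#' normalization statistics, so a reloaded model predicts identically.
#'
#' @param model A `segnet_model`.
#' @param path Checkpoint file path (RDS).
#' @return `load_segnet`: the model. `save_segnet`: `path`, invisibly.
#' @export
save_segnet <- function(model, path) {
  stopifnot(inherits(model, "segnet_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_segnet
#' @export
load_segnet <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "segnet_model"))
  model
}
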