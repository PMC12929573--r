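#' Architecture summary of the four-block CNN
#'
#' Four blocks of \[3x3 conv (stride 1, same padding) -> batch norm -> ReLU
#' -> 2x2 max-pool stride 2\] with channel widths 32/64/128/256, a flatten,
#' and a fully connected layer to a single logit.  For 256 x 256 input the
#' spatial chain is 256 -> 128 -> 64 -> 32 -> 16 and the flatten width is
#' 65,536.
#'
#' @param input_size Input spatial size (square), divisible by 16.
#' @param in_channels Input channels (RGB = 3).
#' @param widths Channel widths of the four blocks.
#' @return A list of class `cnn_spec` with per-block shapes and the flatten
#'   width.
#' @export
cnn_spec <- function(input_size = 256L, in_channels = 3L,
                     widths = c(32L, 64L, 128L, 256L)) {
  if (input_size %% 16 != 0)
    stop("shape error: input size must be divisible by 16")
  sizes <- input_size / c(1, 2, 4, 8)
  pooled <- input_size / c(2, 4, 8, 16)
  structure(list(input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels),
                 widths = as.integer(widths),
                 conv_sizes = as.integer(sizes),
                 pooled_sizes = as.integer(pooled),
                 flatten = as.integer(pooled[4]^2 * widths[4])),
            class = "cnn_spec")
}

#' @export
print.cnn_spec <- function(x, ...) {
  cat("<cnn_spec>\n")
  for (l in 1:4)
    cat(sprintf("  block %d: conv 3x3 -> %3d ch @ %3d^2, pool -> %3d^2\n",
                l, x$widths[l], x$conv_sizes[l], x$pooled_sizes[l]))
  cat(sprintf("  flatten %d -> dense 1\n", x$flatten))
  invisible(x)
}

#' Build the CNN with freshly initialized weights
#'
#' He-style initialization for convolution and dense weights, unit gamma /
#' zero beta batch-norm parameters, all drawn under `seed`.
#'
#' @param input_size Input spatial size, divisible by 16.
#' @param seed Initialization seed.
#' @return An object of class `doc_cnn` (untrained).
#' @export
build_cnn <- function(input_size = 256L, seed = 1L) {
  spec <- cnn_spec(input_size)
  with_seed(seed, {
    cin <- spec$in_channels
    conv_w <- list(); conv_b <- list()
    gam <- list(); bet <- list(); rme <- list(); rva <- list()
    for (l in 1:4) {
      cout <- spec$widths[l]
      fan_in <- 9 * cin
      conv_w[[l]] <- matrix(rnorm(fan_in * cout, 0, sqrt(2 / fan_in)),
                            nrow = fan_in, ncol = cout)
      conv_b[[l]] <- rep(0, cout)
      gam[[l]] <- rep(1, cout); bet[[l]] <- rep(0, cout)
      rme[[l]] <- rep(0, cout); rva[[l]] <- rep(1, cout)
      cin <- cout
    }
    weights <- list(conv_w = conv_w, conv_b = conv_b,
                    bn_gamma = gam, bn_beta = bet,
                    bn_mean = rme, bn_var = rva,
                    dense_w = rnorm(spec$flatten, 0, sqrt(1 / spec$flatten)),
                    dense_b = 0)
    structure(list(spec = spec, weights = weights, trained = FALSE,
                   loss_history = NULL, config = NULL),
              class = "doc_cnn")
  })
}

#' @export
print.doc_cnn <- function(x, ...) {
  cnt <- count_parameters(x)
  cat(sprintf("<doc_cnn> input %d^2x%d, %s, %s trainable parameters\n",
              x$spec$input_size, x$spec$in_channels,
              if (x$trained) "trained" else "untrained",
              format(attr(cnt, "total"), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters per layer
#'
#' Convolution and dense weights plus biases, following the convention that
#' excludes batch-norm affine terms from the per-layer counts (for each
#' convolution `3*3*c_in*c_out + c_out`; for the dense layer `n_in + 1`).
#' Batch-norm scale/shift parameters are reported separately.
#'
#' @param model A `doc_cnn` or `cnn_spec`.
#' @return data.frame with columns `layer` and `parameters`; attributes
#'   `total` (conv + dense) and `total_with_bn` (including batch-norm
#'   affine parameters).
#' @export
count_parameters <- function(model) {
  spec <- if (inherits(model, "doc_cnn")) model$spec else model
  cin <- spec$in_channels
  layers <- character(0); counts <- integer(0)
  bn_total <- 0L
  for (l in 1:4) {
    cout <- spec$widths[l]
    layers <- c(layers, sprintf("Conv%d", l))
    counts <- c(counts, 9L * cin * cout + cout)
    bn_total <- bn_total + 2L * cout
    cin <- cout
  }
  layers <- c(layers, "Dense")
  counts <- c(counts, spec$flatten + 1L)
  out <- data.frame(layer = layers, parameters = counts,
                    stringsAsFactors = FALSE)
  attr(out, "total") <- sum(counts)
  attr(out, "total_with_bn") <- sum(counts) + bn_total
  attr(out, "bn_parameters") <- bn_total
  out
}

#' Training configuration for the CNN
#'
#' The `"full"` profile is the complete published protocol: 256 x 256 input, RMSProp with
#' learning rate 0.01, alpha 0.99, epsilon 1e-8, weight decay 0, momentum 0,
#' batch size 1, 500 epochs.  The `"desk"` profile is a reduced protocol for
#' single-CPU runs: 64 x 64 input (block-averaged from the 256 crop), batch
#' size 8, learning rate 1e-3, 15 epochs (the training loss plateaus well
#' before that on the synthetic cohorts this profile targets).
#'
#' @param profile `"desk"` or `"full"`.
#' @param ... Named overrides of any field.
#' @return A list of class `cnn_train_config`.
#' @export
train_config <- function(profile = c("desk", "full"), ...) {
  profile <- match.arg(profile)
  cfg <- list(profile = profile, optimizer = "rmsprop",
              lr = 0.01, alpha = 0.99, eps = 1e-8, weight_decay = 0,
              momentum = 0, batch_size = 1L, epochs = 500L,
              input_size = 256L, bn_momentum = 0.1, seed = 1L)
  if (profile == "desk") {
    cfg$lr <- 1e-3; cfg$batch_size <- 8L; cfg$epochs <- 15L
    cfg$input_size <- 64L
  }
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  if (cfg$lr <= 0) stop("learning rate must be positive")
  if (cfg$epochs < 1) stop("epochs must be >= 1")
  structure(cfg, class = "cnn_train_config")
}

check_images <- function(images, input_size) {
  ok <- vapply(images, function(im)
    length(dim(im)) == 3 && all(dim(im) == c(input_size, input_size, 3)),
    logical(1))
  if (!all(ok))
    stop(sprintf("all images must be %d x %d x 3 arrays", input_size,
                 input_size))
}

#' Train the CNN
#'
#' Sigmoid + binary cross-entropy on the single logit, RMSProp updates,
#' fully seeded (weight initialization and example ordering).  Batch-norm
#' uses batch statistics when the batch has at least two examples and
#' running statistics otherwise (batch size 1 gives degenerate per-batch
#' variance).
#'
#' @param images List of `input_size x input_size x 3` arrays in \[0, 1\].
#' @param labels 0/1 vector (1 = positive class), both classes present.
#' @param cfg A [train_config()].
#' @param model Optional pre-built `doc_cnn`; built from `cfg` when absent.
#' @return A trained `doc_cnn` with `loss_history` (mean per-example loss by
#'   epoch).
#' @export
train_cnn <- function(images, labels, cfg = train_config("desk"),
                      model = NULL) {
  if (length(images) < 2) stop("need at least 2 images")
  labels <- as.numeric(labels)
  if (length(labels) != length(images))
    stop("labels must match images")
  if (length(unique(labels)) < 2)
    stop("training error: both classes must be present")
  if (is.null(model)) model <- build_cnn(cfg$input_size, seed = cfg$seed)
  check_images(images, model$spec$input_size)
  n <- length(images)
  order_mat <- with_seed(derive_seed(cfg$seed, "order"), {
    do.call(rbind, lapply(seq_len(cfg$epochs), function(e) sample.int(n)))
  })
  fit <- cnn_train_cpp(images, labels, model$weights, order_mat,
                       cfg$lr, cfg$alpha, cfg$eps,
                       as.integer(cfg$batch_size), cfg$bn_momentum)
  model$weights <- fit$weights
  model$loss_history <- as.numeric(fit$loss_history)
  model$trained <- TRUE
  model$config <- cfg
  model
}

#' Predicted class probabilities for images
#'
#' Forward pass in evaluation mode (running batch-norm statistics) followed
#' by the logistic link.
#'
#' @param object A `doc_cnn`.
#' @param images List of input arrays.
#' @param ... Unused.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
predict.doc_cnn <- function(object, images, ...) {
  check_images(images, object$spec$input_size)
  plogis_ <- function(z) 1 / (1 + exp(-z))
  plogis_(as.numeric(cnn_forward_cpp(images, object$weights)))
}

#' Aggregate image probabilities into a patient-level prediction
#'
#' Default aggregation is the mean of the per-image sigmoid outputs; the
#' majority-vote option labels positive when more than half the images
#' exceed the threshold.  Ties (aggregate exactly at threshold) resolve to
#' negative: the positive call requires a strict `>`.
#'
#' @param model A trained `doc_cnn`.
#' @param images The patient's images (>= 1).
#' @param threshold Decision threshold.
#' @param aggregation `"mean"` or `"majority"`.
#' @param patient_id Identifier carried into the result.
#' @return A list of class `patient_prediction`: per-image probabilities,
#'   aggregated probability, predicted label (logical `positive`),
#'   threshold.
#' @export
predict_patient <- function(model, images, threshold = 0.5,
                            aggregation = c("mean", "majority"),
                            patient_id = NA_character_) {
  aggregation <- match.arg(aggregation)
  if (length(images) < 1) stop("need at least one image per patient")
  probs <- predict(model, images)
  aggregate_image_probs(probs, threshold, aggregation,
                        patient_id = patient_id)
}

#' Aggregate per-image probabilities
#'
#' The aggregation rule used by [predict_patient()], exposed for direct use
#' on probabilities from any source.  `"mean"` averages the probabilities;
#' `"majority"` takes the fraction of images above the threshold.  The
#' positive call requires the aggregate to strictly exceed the threshold,
#' so exact ties resolve to negative.
#'
#' @param probs Per-image probabilities.
#' @param threshold Decision threshold.
#' @param aggregation `"mean"` or `"majority"`.
#' @param patient_id Identifier carried into the result.
#' @return A `patient_prediction` list.
#' @export
aggregate_image_probs <- function(probs, threshold = 0.5,
                                  aggregation = c("mean", "majority"),
                                  patient_id = NA_character_) {
  aggregation <- match.arg(aggregation)
  agg <- if (aggregation == "mean") mean(probs) else mean(probs > threshold)
  structure(list(patient_id = patient_id, image_probs = probs,
                 probability = agg, positive = agg > threshold,
                 threshold = threshold, aggregation = aggregation),
            class = "patient_prediction")
}
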