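# R-side surface of the convolutional detector: configuration, seeded
# weight initialisation, the epoch loop with best-validation-epoch
# checkpointing, and prediction/thresholding.

#' Detector configuration
#'
#' The network is a trunk of `n_conv_layers` convolutional stages (3 x 3
#' kernels, stride 1, same padding, `features_per_layer` output channels,
#' each followed by batch normalisation and a rectifier), global average
#' pooling and a single logistic output unit. Defaults reproduce the
#' reference training recipe: Adam with initial learning rate 5e-5,
#' cross-entropy loss, 100 epochs. Desk-scale runs override `epochs`,
#' `batch_size` and `learning_rate` (see the methods vignette).
#'
#' @param n_conv_layers trunk depth.
#' @param features_per_layer channels per conv stage.
#' @param kernel kernel side (3).
#' @param learning_rate Adam initial learning rate.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param threshold classification threshold Th in (0, 1).
#' @param beta1,beta2,adam_eps Adam moment parameters.
#' @param bn_momentum running-statistics update rate.
#' @param head `"gap"` (global average pooling + logistic unit) or
#'   `"dense"` (logistic unit over all trunk activations). The reference
#'   description specifies only the convolutional trunk; `"gap"` is the
#'   parameter-frugal completion, `"dense"` preserves the spatial layout
#'   of the multistatic matrix into the decision.
#' @param seed weight-initialisation / shuffling seed.
#' @return an `mwt_detector_config` list.
#' @export
detector_config <- function(n_conv_layers = 10L, features_per_layer = 32L,
                            kernel = 3L, learning_rate = 5e-5, epochs = 100L,
                            batch_size = 128L, threshold = 0.5,
                            beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                            bn_momentum = 0.1, head = c("gap", "dense"),
                            seed = 1L) {
  head <- match.arg(head)
  if (threshold <= 0 || threshold >= 1)
    abort("`threshold` must lie strictly inside (0, 1).", class = "mwtomo_bad_config")
  if (n_conv_layers < 1 || features_per_layer < 1 || kernel != 3L)
    abort("invalid architecture configuration.", class = "mwtomo_bad_config")
  structure(list(n_conv_layers = as.integer(n_conv_layers),
                 features_per_layer = as.integer(features_per_layer),
                 kernel = as.integer(kernel), learning_rate = learning_rate,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 threshold = threshold, beta1 = beta1, beta2 = beta2,
                 adam_eps = adam_eps, bn_momentum = bn_momentum,
                 head = head, seed = as.integer(seed)),
            class = "mwt_detector_config")
}

#' Build an (untrained) detector
#'
#' Initialises all weights reproducibly from `config$seed`: He-scaled
#' normal draws for convolution kernels, unit batch-norm scales, zero
#' shifts and a zero logistic head (so the untrained network scores every
#' input exactly 0.5 and the first-epoch loss of a balanced set starts at
#' chance level, log 2).
#'
#' @param config an [detector_config()].
#' @param input_channels input tensor channels (2: amplitude, phase).
#' @param img_side input side length (number of antennas).
#' @return an `mwt_detector` object (untrained).
#' @export
build_detector <- function(config = detector_config(), input_channels = 2L,
                           img_side = 30L) {
  L <- config$n_conv_layers; Cf <- config$features_per_layer
  with_seed(config$seed, {
    conv_W <- conv_b <- bn_gamma <- bn_beta <- bn_mean <- bn_var <- vector("list", L)
    cin <- input_channels
    for (l in seq_len(L)) {
      fan_in <- 9L * cin
      conv_W[[l]] <- matrix(rnorm(Cf * fan_in, 0, sqrt(2 / fan_in)), Cf, fan_in)
      conv_b[[l]] <- numeric(Cf)
      bn_gamma[[l]] <- rep(1, Cf); bn_beta[[l]] <- numeric(Cf)
      bn_mean[[l]] <- numeric(Cf); bn_var[[l]] <- rep(1, Cf)
      cin <- Cf
    }
    params <- list(conv_W = conv_W, conv_b = conv_b, bn_gamma = bn_gamma,
                   bn_beta = bn_beta, bn_mean = bn_mean, bn_var = bn_var,
                   head_w = numeric(if (identical(config$head, "dense"))
                     Cf * as.integer(img_side)^2 else Cf),
                   head_b = 0,
                   n_layers = L, n_features = Cf, img_side = as.integer(img_side))
    structure(list(params = params, config = config, stats = NULL,
                   history = NULL, trained = FALSE),
              class = "mwt_detector")
  })
}

#' Trainable-parameter counts of a detector
#'
#' @param model an `mwt_detector`.
#' @return named list: `conv_trunk` (convolution weights + biases),
#'   `batch_norm`, `head`, `total`.
#' @export
n_parameters <- function(model) {
  p <- model$params
  conv <- sum(vapply(p$conv_W, length, 0L)) + sum(vapply(p$conv_b, length, 0L))
  bn <- 2L * p$n_features * p$n_layers
  head <- length(p$head_w) + 1L
  list(conv_trunk = conv, batch_norm = bn, head = head, total = conv + bn + head)
}

zero_adam <- function(params) {
  zl <- function(x) lapply(x, function(m) array(0, dim = dim(m) %||% length(m)))
  list(mW = zl(params$conv_W), vW = zl(params$conv_W),
       mb = zl(params$conv_b), vb = zl(params$conv_b),
       mg = zl(params$bn_gamma), vg = zl(params$bn_gamma),
       mbeta = zl(params$bn_beta), vbeta = zl(params$bn_beta),
       mhw = numeric(length(params$head_w)), vhw = numeric(length(params$head_w)),
       mhb = 0, vhb = 0, t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train the detector
#'
#' Minimises binary cross-entropy with Adam over minibatches, logging
#' per-epoch training and validation loss and retaining the weights of the
#' best-validation-loss epoch. Fully reproducible from `config$seed`.
#'
#' @param model an `mwt_detector` from [build_detector()].
#' @param x_train,x_val arrays `(2, n_pixels, n)` from [encode_batch] /
#'   `encode_training_data`, or lists of scattering matrices together with
#'   `stats`.
#' @param y_train,y_val binary labels (1 = pathological).
#' @param stats the frozen [encoding_stats()] used to encode the inputs
#'   (stored in the model for inference).
#' @param augment present each training matrix under a random element of
#'   the acquisition ring's rotation/reflection group every epoch (see
#'   [permute_antennas()]); requires `x_train` as a list of scattering
#'   matrices and diagonal-pooled `stats`. No new simulation is involved —
#'   the group action is an exact symmetry of the acquisition.
#' @param checkpoint_file optional `.rds` path; training state is saved
#'   after every epoch and an interrupted run resumes exactly (identical
#'   random stream) from the last completed epoch.
#' @param verbose print per-epoch losses.
#' @return the trained `mwt_detector` (history tibble in `$history`).
#' @export
train_detector <- function(model, x_train, y_train, x_val, y_val, stats,
                           augment = FALSE, checkpoint_file = NULL,
                           verbose = FALSE) {
  cfg <- model$config
  if (length(unique(y_train)) < 2L)
    abort("training data must contain both classes.", class = "mwtomo_bad_input")
  if (length(y_train) == 0L || length(y_val) == 0L)
    abort("empty training or validation set.", class = "mwtomo_bad_input")
  if (augment && !is.list(x_train))
    abort("symmetry augmentation needs raw scattering matrices, not encoded arrays.",
          class = "mwtomo_bad_input")
  s_train <- NULL
  if (is.list(x_train)) {
    if (augment) s_train <- x_train
    x_train <- encode_batch(x_train, stats)
  }
  if (is.list(x_val)) x_val <- encode_batch(x_val, stats)
  n_ant <- as.integer(sqrt(dim(x_train)[2]))

  params <- model$params
  adam <- zero_adam(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  hist <- vector("list", cfg$epochs)
  start_ep <- 1L

  # protect the caller's random stream
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  caller_rng <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", caller_rng, envir = globalenv()), add = TRUE)

  if (!is.null(checkpoint_file) && file.exists(checkpoint_file)) {
    ck <- readRDS(checkpoint_file)
    params <- ck$params; adam <- ck$adam; best <- ck$best
    hist[seq_len(ck$epoch)] <- ck$hist
    start_ep <- ck$epoch + 1L
    assign(".Random.seed", ck$rng, envir = globalenv())
  } else {
    set.seed(cfg$seed)
  }

  for (ep in seq(from = start_ep, length.out = max(0L, cfg$epochs - start_ep + 1L))) {
    if (augment) {
      shifts <- sample.int(n_ant, length(s_train), replace = TRUE) - 1L
      flips <- runif(length(s_train)) < 0.5
      x_train <- encode_batch(
        lapply(seq_along(s_train), function(i)
          permute_antennas(s_train[[i]], shifts[i], flips[i])), stats)
    }
    ord <- sample.int(length(y_train))
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    names(batches) <- NULL
    res <- cnn_train_epoch(params, adam, x_train, as.numeric(y_train), batches,
                           cfg$learning_rate, cfg$beta1, cfg$beta2,
                           cfg$adam_eps, cfg$bn_momentum)
    params <- res$params; adam <- res$adam
    vl <- cnn_loss(params, x_val, as.numeric(y_val))
    hist[[ep]] <- tibble::tibble(epoch = ep, train_loss = res$train_loss,
                                 val_loss = vl)
    if (vl < best$loss) best <- list(loss = vl, params = rapply(
      params, identity, how = "replace"), epoch = ep)
    if (verbose) cat(sprintf("epoch %3d  train %.4f  val %.4f\n",
                             ep, res$train_loss, vl))
    if (!is.null(checkpoint_file))
      saveRDS(list(params = params, adam = adam, best = best,
                   hist = hist[seq_len(ep)], epoch = ep,
                   rng = get(".Random.seed", envir = globalenv())),
              checkpoint_file)
  }
  model$params <- best$params
  model$best_epoch <- best$epoch
  model$stats <- stats
  model$history <- dplyr::bind_rows(hist)
  model$trained <- TRUE
  model
}

#' Score scattering matrices with a trained detector
#'
#' @param object a trained `mwt_detector`.
#' @param newdata a list of `mwt_scattering` (or complex matrices), a single
#'   matrix, or a pre-encoded `(2, n_pixels, n)` array.
#' @param threshold decision threshold Th (default from the config).
#' @param ... unused.
#' @return tibble with `score` (probability of pathology) and `label`
#'   (`"suspicious"` iff `score >= threshold`, else `"healthy"`).
#' @export
predict.mwt_detector <- function(object, newdata, threshold = NULL, ...) {
  if (!object$trained && is.null(object$stats))
    abort("model has no frozen encoding stats; train it first or set `$stats`.",
          class = "mwtomo_missing_stats")
  th <- threshold %||% object$config$threshold
  if (th <= 0 || th >= 1)
    abort("`threshold` must lie strictly inside (0, 1).", class = "mwtomo_bad_config")
  if (is.matrix(newdata) || inherits(newdata, "mwt_scattering")) newdata <- list(newdata)
  X <- if (is.array(newdata) && length(dim(newdata)) == 3L) newdata
       else encode_batch(newdata, object$stats)
  if (dim(X)[2] != object$params$img_side^2)
    abort("input size does not match the model's acquisition geometry.",
          class = "mwtomo_bad_input")
  score <- as.numeric(cnn_predict(object$params, X, batch_size = 32L))
  tibble::tibble(score = score,
                 label = ifelse(score >= th, "suspicious", "healthy"))
}

#' @export
print.mwt_detector <- function(x, ...) {
  np <- n_parameters(x)
  cat(sprintf("<mwt_detector> %d conv layers x %d features (%s; %d trainable parameters)\n",
              x$params$n_layers, x$params$n_features,
              if (x$trained) sprintf("trained, best epoch %d", x$best_epoch) else "untrained",
              np$total))
  invisible(x)
}

#' @export
tidy.mwt_detector <- function(x, ...) {
  if (is.null(x$history)) abort("model has no training history.", class = "mwtomo_bad_input")
  x$history
}

#' @export
glance.mwt_detector <- function(x, ...) {
  np <- n_parameters(x)
  tibble::tibble(n_layers = x$params$n_layers, n_features = x$params$n_features,
                 parameters = np$total, trained = x$trained,
                 best_epoch = x$best_epoch %||% NA_integer_,
                 best_val_loss = if (x$trained) min(x$history$val_loss) else NA_real_)
}
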