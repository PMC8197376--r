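# Compact CNN classifier: conv3x3(32)-pool, conv3x3(64)-pool,
# conv3x3(128)-pool, dense(512, ReLU), softmax(K); valid convolutions,
# Adam on cross-entropy. The numerical core lives in src/cnn.cpp; this
# file provides the modelling interface (fit object + methods).

#' Build an untrained CNN
#'
#' Constructs the fixed three-block architecture with seeded
#' (Glorot-uniform) parameter initialization. The network accepts
#' single-channel spectrogram inputs of any size large enough to survive
#' three valid 3x3 convolutions with 2x2 max pooling; the default training
#' input is the mel matrix resized to 32 x 64.
#'
#' @param input_shape integer `c(height, width)` of the input maps.
#' @param n_classes number of softmax outputs; the two study tasks use 4
#'   (merged) or 5 (fine). Other values require `allow_any_k = TRUE`.
#' @param channels input channels (1 for the normalized mel matrix).
#' @param seed integer seed for weight initialization.
#' @param allow_any_k permit `n_classes` outside `{4, 5}`.
#' @return an object of class `anuran_cnn` (untrained).
#' @examples
#' m <- build_cnn(c(32, 64), n_classes = 5, seed = 1)
#' m
#' @export
build_cnn <- function(input_shape = c(32L, 64L), n_classes = 5L,
                      channels = 1L, seed = 1L, allow_any_k = FALSE) {
  input_shape <- as.integer(input_shape)
  stopifnot(length(input_shape) == 2L)
  if (!n_classes %in% c(4L, 5L) && !isTRUE(allow_any_k))
    stop("n_classes must be 4 or 5 for the study tasks ",
         "(set allow_any_k = TRUE to override)")
  weights <- cnn_init_cpp(input_shape[1], input_shape[2], as.integer(channels),
                          as.integer(n_classes), as.integer(seed))
  structure(list(weights = weights, input_shape = input_shape,
                 channels = as.integer(channels),
                 n_classes = as.integer(n_classes), classes = NULL,
                 seed = as.integer(seed), trained = FALSE, history = NULL,
                 train_config = NULL,
                 architecture = list(conv_filters = c(32L, 64L, 128L),
                                     kernel = c(3L, 3L), pool = c(2L, 2L),
                                     dense_units = 512L, padding = "valid")),
            class = "anuran_cnn")
}

# coerce features (h x w x N array, or feature matrix) to the (C*H*W, N)
# column layout the C++ core expects
as_feature_matrix <- function(x, model) {
  h <- model$input_shape[1]; w <- model$input_shape[2]; c <- model$channels
  if (is.array(x) && length(dim(x)) == 3L) {
    if (!all(dim(x)[1:2] == c(h, w)))
      stop("feature array is ", dim(x)[1], "x", dim(x)[2],
           " but the model expects ", h, "x", w)
    x <- matrix(x, h * w * c, dim(x)[3])
  } else if (is.matrix(x)) {
    if (nrow(x) != h * w * c)
      stop("feature matrix has ", nrow(x), " rows; expected ", h * w * c)
  } else stop("x must be an (h, w, N) array or an (h*w*c, N) matrix")
  x
}

#' Train a CNN
#'
#' Runs `epochs` full passes over the training set in shuffled mini-batches
#' of `batch_size`, updating with Adam (`beta1 = 0.9`, `beta2 = 0.999`) on
#' the categorical cross-entropy. Per-epoch training loss and accuracy are
#' recorded in the returned model's `$history`. Deterministic for fixed
#' seeds (single-threaded numerics).
#'
#' @param model an `anuran_cnn` from [build_cnn()].
#' @param x features: an `(h, w, N)` array (see [prepare_features()]).
#' @param y character/factor labels of length `N`; the distinct values
#'   must number exactly `model$n_classes`.
#' @param epochs training epochs; defaults to 6 for the 5-class task and 8
#'   for the 4-class task.
#' @param batch_size mini-batch size.
#' @param learning_rate initial Adam learning rate.
#' @param seed integer seed for batch shuffling.
#' @param class_order optional explicit class ordering.
#' @param verbose print per-epoch progress.
#' @return the trained `anuran_cnn`.
#' @export
train_cnn <- function(model, x, y, epochs = NULL, batch_size = 32L,
                      learning_rate = 0.001, seed = 1L, class_order = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(model, "anuran_cnn"))
  y <- as.character(y)
  if (length(y) == 0L) stop("empty training set")
  classes <- class_order %||% {
    u <- unique(y)
    if (all(u %in% call_classes())) call_classes()[call_classes() %in% u]
    else if (all(u %in% merged_classes())) merged_classes()[merged_classes() %in% u]
    else sort(u)
  }
  if (!setequal(unique(y), classes) || length(classes) != model$n_classes)
    stop("label set {", paste(sort(unique(y)), collapse = ", "),
         "} inconsistent with a ", model$n_classes, "-way model")
  if (is.null(epochs)) epochs <- if (model$n_classes == 4L) 8L else 6L
  X <- as_feature_matrix(x, model)
  if (ncol(X) != length(y)) stop("feature/label count mismatch")
  yi <- match(y, classes) - 1L
  fit <- cnn_train_cpp(model$weights, X, yi, model$input_shape[1],
                       model$input_shape[2], model$channels, model$n_classes,
                       as.integer(epochs), as.integer(batch_size),
                       learning_rate, as.integer(seed), 0.9, 0.999, 1e-8,
                       isTRUE(verbose))
  model$weights <- fit$weights
  model$classes <- classes
  model$trained <- TRUE
  model$history <- data.frame(epoch = seq_len(epochs),
                              loss = as.numeric(fit$loss),
                              accuracy = as.numeric(fit$accuracy))
  model$train_config <- list(epochs = as.integer(epochs),
                             batch_size = as.integer(batch_size),
                             learning_rate = learning_rate,
                             optimizer = "adam", seed = as.integer(seed))
  model
}

#' Fit the anuran call classifier
#'
#' One-shot interface: builds the fixed three-block CNN and trains it on
#' labelled spectrogram features. For the merged four-class task pass
#' labels through [merge_class()] first.
#'
#' @inheritParams train_cnn
#' @param x `(h, w, N)` feature array, e.g. from [prepare_features()].
#' @param n_classes number of classes; defaults to the number of distinct
#'   labels.
#' @param seed one seed driving both initialization and shuffling.
#' @param ... passed on to [train_cnn()].
#' @return a fitted `anuran_cnn`.
#' @examples
#' \donttest{
#' m <- generate_dataset(rep(5, 5), seed = 1)
#' a <- augment_dataset(m)
#' sp <- split_dataset(a)
#' tr <- prepare_features(sp$train)
#' fit <- anuran_cnn(tr$x, tr$y, epochs = 2, seed = 1)
#' fit
#' }
#' @export
anuran_cnn <- function(x, y, n_classes = length(unique(as.character(y))),
                       input_shape = dim(x)[1:2], epochs = NULL,
                       batch_size = 32L, learning_rate = 0.001, seed = 1L,
                       ...) {
  model <- build_cnn(input_shape = input_shape, n_classes = n_classes,
                     seed = seed,
                     allow_any_k = !n_classes %in% c(4L, 5L))
  train_cnn(model, x, y, epochs = epochs, batch_size = batch_size,
            learning_rate = learning_rate, seed = seed, ...)
}

#' @export
print.anuran_cnn <- function(x, ...) {
  cat(sprintf("<anuran_cnn> %s, input %dx%dx%d -> %d classes, %s parameters\n",
              if (x$trained) "trained" else "untrained",
              x$input_shape[1], x$input_shape[2], x$channels, x$n_classes,
              format(n_params(x), big.mark = ",")))
  if (x$trained) {
    h <- x$history
    cat(sprintf("  %d epochs (batch %d, lr %g, adam); final loss %.4f, acc %.4f\n",
                nrow(h), x$train_config$batch_size,
                x$train_config$learning_rate, h$loss[nrow(h)],
                h$accuracy[nrow(h)]))
  }
  invisible(x)
}

#' @export
summary.anuran_cnn <- function(object, ...) {
  print(object)
  d <- layer_dims(object$input_shape[1], object$input_shape[2],
                  object$channels, object$n_classes)
  cat("  layers (valid conv 3x3 + ReLU, max pool 2x2):\n")
  for (nm in names(d$shapes))
    cat(sprintf("    %-10s %s\n", nm, paste(d$shapes[[nm]], collapse = " x ")))
  if (object$trained) {
    cat("  training history:\n")
    print(object$history, row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.anuran_cnn <- function(object, ...) object$weights

#' @export
plot.anuran_cnn <- function(x, ...) {
  if (!x$trained) stop("nothing to plot: model is untrained")
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(h$epoch, h$loss, type = "b", xlab = "epoch", ylab = "cross-entropy",
       main = "training loss", ...)
  plot(h$epoch, h$accuracy, type = "b", xlab = "epoch", ylab = "accuracy",
       ylim = c(0, 1), main = "training accuracy", ...)
  invisible(x)
}

#' @export
predict.anuran_cnn <- function(object, x, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- as_feature_matrix(x, object)
  probs <- t(cnn_forward_cpp(object$weights, X, object$input_shape[1],
                             object$input_shape[2], object$channels,
                             object$n_classes))
  classes <- object$classes %||% paste0("class_", seq_len(object$n_classes))
  colnames(probs) <- classes
  if (type == "prob") return(probs)
  classes[max.col(probs, ties.method = "first")]
}

# per-layer output shapes and the total parameter count implied by the
# architecture (valid 3x3 convs, 2x2 pools, dense 512, softmax K)
layer_dims <- function(h, w, c, K) {
  shapes <- list(input = c(h, w, c))
  f <- c(32L, 64L, 128L)
  for (i in 1:3) {
    h <- h - 2L; w <- w - 2L
    shapes[[paste0("conv", i)]] <- c(h, w, f[i])
    h <- h %/% 2L; w <- w %/% 2L
    shapes[[paste0("pool", i)]] <- c(h, w, f[i])
  }
  flat <- h * w * 128L
  shapes$flatten <- flat
  shapes$dense <- 512L
  shapes$softmax <- K
  in_ch <- c(c, 32L, 64L)
  n_par <- sum(f * (9L * in_ch) + f) + (flat * 512L + 512L) + (512L * K + K)
  list(shapes = shapes, n_params = n_par)
}

#' Number of trainable parameters
#'
#' @param model an `anuran_cnn`.
#' @return integer parameter count (weights + biases over all layers).
#' @export
n_params <- function(model) {
  sum(vapply(model$weights, length, numeric(1)))
}

#' Export and reload a trained model
#'
#' `export_model()` serializes the fitted model to disk and reports the
#' artifact's byte size (the quantity that drives [model_deploy_time()]
#' when the network must be pushed to remote nodes over the radio link);
#' `load_model()` restores it.
#'
#' @param model a trained `anuran_cnn`.
#' @param path file path for the artifact.
#' @return `export_model()` returns a list with `path` and `bytes`;
#'   `load_model()` returns the `anuran_cnn`.
#' @export
export_model <- function(model, path) {
  stopifnot(inherits(model, "anuran_cnn"))
  saveRDS(model, path)
  list(path = path, bytes = as.numeric(file.size(path)))
}

#' @rdname export_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "anuran_cnn")) stop("not an anuran_cnn artifact")
  model
}

#' Compute network-ready features for a manifest
#'
#' Materializes each clip (originals once per origin, variants derived
#' from them), runs the mel front end, min-max normalizes, and resizes
#' each matrix to the network input shape. Returns features in manifest
#' row order.
#'
#' @param manifest an `anuran_manifest` (originals and/or variants).
#' @param mel_cfg a [mel_config()].
#' @param input_shape target `c(height, width)` of each feature map.
#' @param verbose print progress every 25 origins.
#' @return a list with `x` (`h x w x N` array), `y` (labels), `origin`,
#'   and `variant` (both per clip).
#' @export
prepare_features <- function(manifest, mel_cfg = mel_config(),
                             input_shape = c(32L, 64L), verbose = FALSE) {
  n <- nrow(manifest)
  x <- array(0, c(input_shape[1], input_shape[2], n))
  groups <- split(seq_len(n), manifest$origin_id)
  done <- 0L
  for (idx in groups) {
    base <- manifest[idx[1], , drop = FALSE]
    base$variant_tag <- "original"
    orig <- realize_clip(base, 1L)
    for (i in idx) {
      clip <- apply_variant(orig, manifest$variant_tag[i],
                            manifest$variant_param[i],
                            manifest$variant_seed[i])
      sp <- compute_melspec(clip, mel_cfg)
      x[, , i] <- resize_matrix(normalize_spec(sp), input_shape[1],
                                input_shape[2])
    }
    done <- done + 1L
    if (verbose && done %% 25L == 0L)
      message("prepared ", done, "/", length(groups), " origins")
  }
  list(x = x, y = manifest$label, origin = manifest$origin_id,
       variant = manifest$variant_tag)
}

#' Origin-grouped train/test split
#'
#' Per class, the originals are ordered lexicographically by `origin_id`
#' and every `every`-th one is selected for the test set together with all
#' of its augmentation variants, so no origin contributes to both sides
#' (augmented copies of a test recording never leak into training). With
#' the elevenfold augmentation this yields a test fraction near 20%.
#'
#' @param manifest an augmented `anuran_manifest` in which every origin
#'   has exactly 11 members (original + 10 variants).
#' @param every take every `every`-th origin per class (default 5, i.e. a
#'   1-in-5 test selection).
#' @param require_augmented enforce the 11-members-per-origin precondition.
#' @return a list with `train` and `test` manifests.
#' @examples
#' a <- augment_dataset(generate_dataset(rep(5, 5), seed = 1))
#' sp <- split_dataset(a)
#' nrow(sp$test)  # 5 origins x 1 selected x 11 variants
#' @export
split_dataset <- function(manifest, every = 5L, require_augmented = TRUE) {
  stopifnot(nrow(manifest) > 0L)
  per_origin <- table(manifest$origin_id)
  if (require_augmented && any(per_origin != 11L))
    stop("every origin must have exactly 11 members (original + 10 variants); ",
         "offending origins: ",
         paste(utils::head(names(per_origin)[per_origin != 11L], 3),
               collapse = ", "))
  origins <- unique(manifest[, c("origin_id", "label")])
  test_origins <- unlist(lapply(split(origins$origin_id, origins$label),
                                function(ids) {
                                  ids <- sort(ids)
                                  ids[seq_along(ids) %% every == 0L]
                                }), use.names = FALSE)
  in_test <- manifest$origin_id %in% test_origins
  list(train = manifest[!in_test, , drop = FALSE],
       test = manifest[in_test, , drop = FALSE])
}
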