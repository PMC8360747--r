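# Model construction, training, evaluation, and the wavelet x segment-length
# grid comparison. The network itself lives in src/cnn.cpp.

#' CNN architecture description
#'
#' The fixed layer stack of the classifier: 64 3x3 kernels (stride 1, same
#' padding, ReLU) -> 2x2 max pool (stride 2) -> 128 5x5 kernels (stride 1,
#' same padding, ReLU) -> 2x2 max pool -> dense 256 ReLU -> dense 128 ReLU
#' -> 1 sigmoid output, on 224 x 224 x 3 inputs. The description is fixed;
#' [build_model()] validates rather than parameterises it.
#'
#' @return A `cnn_config` list.
#' @export
cnn_config <- function() {
  structure(list(
    input = c(224L, 224L, 3L),
    conv1 = list(filters = 64L, kernel = 3L, stride = 1L, padding = "same",
                 activation = "relu"),
    pool1 = list(size = 2L, stride = 2L),
    conv2 = list(filters = 128L, kernel = 5L, stride = 1L, padding = "same",
                 activation = "relu"),
    pool2 = list(size = 2L, stride = 2L),
    dense1 = 256L, dense2 = 128L,
    output = list(units = 1L, activation = "sigmoid")),
    class = "cnn_config")
}

#' Training hyperparameters
#'
#' Conventional defaults for a from-scratch run at this scale: Adam,
#' learning rate 1e-4, batch size 32, 30 epochs, binary cross-entropy loss.
#'
#' @param optimizer Only `"adam"` is implemented.
#' @param lr Learning rate.
#' @param batch_size Mini-batch size (>= 1).
#' @param epochs Number of epochs (>= 1).
#' @param beta1,beta2,eps Adam moment decay rates and stabiliser.
#' @param seed Integer seed for weight initialisation and batch shuffling.
#' @param verbose Print per-epoch progress.
#' @return A `train_config` list.
#' @export
train_config <- function(optimizer = "adam", lr = 1e-4, batch_size = 32L,
                         epochs = 30L, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8, seed = 1L, verbose = FALSE) {
  optimizer <- match.arg(optimizer)
  if (epochs < 1 || batch_size < 1) stop("epochs and batch_size must be >= 1")
  structure(list(optimizer = optimizer, lr = lr,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), beta1 = beta1, beta2 = beta2,
                 eps = eps, seed = as.integer(seed), verbose = verbose),
            class = "train_config")
}

#' Build the classifier
#'
#' Initialises the network (He-normal weights) from `seed`. Training is
#' deterministic for a given seed under single-threaded BLAS, which the
#' package pins on load (see [set_blas_threads()]).
#'
#' @param config A [cnn_config()]; anything whose input shape is not
#'   224 x 224 x 3 is rejected.
#' @param seed Integer seed for weight initialisation.
#' @return A `scalobp_cnn` model handle.
#' @export
build_model <- function(config = cnn_config(), seed = 1L) {
  if (!inherits(config, "cnn_config") ||
      !identical(as.integer(config$input), c(224L, 224L, 3L)))
    stop("malformed config: input shape must be 224 x 224 x 3")
  structure(list(ptr = .cnn_create_cpp(as.numeric(seed)), config = config,
                 seed = as.integer(seed)),
            class = "scalobp_cnn")
}

#' @export
print.scalobp_cnn <- function(x, ...) {
  counts <- .cnn_param_counts_cpp(x$ptr)
  cat("<scalobp_cnn> conv(64@3x3)-pool-conv(128@5x5)-pool-256-128-1\n")
  cat(sprintf("  %s trainable parameters (seed %d)\n",
              format(sum(counts), big.mark = ","), x$seed))
  invisible(x)
}

#' Per-layer feature-map shapes and parameter counts
#'
#' @param model A `scalobp_cnn`.
#' @return List with `shapes` (named list of integer dims) and `params`
#'   (named vector of trainable parameter counts per layer).
#' @export
model_summary <- function(model) {
  stopifnot(inherits(model, "scalobp_cnn"))
  list(shapes = .cnn_feature_shapes_cpp(model$ptr),
       params = .cnn_param_counts_cpp(model$ptr))
}

#' Checksum of all trainable weights
#'
#' Sum of every weight in the network; equal checksums after identical
#' seeded runs are the determinism contract used in tests.
#'
#' @param model A `scalobp_cnn`.
#' @return Numeric scalar.
#' @export
weights_checksum <- function(model) {
  stopifnot(inherits(model, "scalobp_cnn"))
  .cnn_checksum_cpp(model$ptr)
}

# Collect the manifest's images as one raw byte buffer (n * 224*224*3),
# preferring the in-memory copies attached by build_dataset.
manifest_images_raw <- function(manifest) {
  imgs <- attr(manifest, "images")
  n <- nrow(manifest)
  per <- 224L * 224L * 3L
  out <- raw(as.numeric(n) * per)
  for (i in seq_len(n)) {
    px <- if (!is.null(imgs)) imgs[[i]]$pixels else load_image(manifest$image[i])$pixels
    out[((i - 1) * per + 1):(i * per)] <- as.raw(px)
  }
  out
}

#' Train the classifier on a dataset manifest
#'
#' Minimises mean binary cross-entropy with Adam over the manifest's
#' training split; the validation split is scored after every epoch.
#'
#' @param model A `scalobp_cnn` (trained in place; also returned).
#' @param manifest A manifest from [build_dataset()].
#' @param cfg A [train_config()].
#' @return The model, with the per-epoch history data frame (`epoch`,
#'   `train_loss`, `train_acc`, `val_loss`, `val_acc`) attached as
#'   `model$history`.
#' @export
train_cnn <- function(model, manifest, cfg = train_config()) {
  stopifnot(inherits(model, "scalobp_cnn"))
  tr <- which(manifest$split == "train")
  va <- which(manifest$split == "val")
  if (length(unique(manifest$binary[tr])) < 2)
    stop("training split must contain both classes")
  images <- manifest_images_raw(manifest)
  hist <- .cnn_train_cpp(model$ptr, images, as.integer(manifest$binary),
                         as.integer(tr - 1L), as.integer(va - 1L),
                         cfg$epochs, cfg$batch_size, cfg$lr, cfg$beta1,
                         cfg$beta2, cfg$eps, isTRUE(cfg$verbose))
  model$history <- data.frame(epoch = seq_len(nrow(hist)), hist)
  model
}

#' Classifier scores for manifest rows
#'
#' @param model A trained `scalobp_cnn`.
#' @param manifest A manifest from [build_dataset()].
#' @param rows Row indices to score (default: all).
#' @return Numeric scores in `[0, 1]`, one per row.
#' @export
predict_scores <- function(model, manifest, rows = seq_len(nrow(manifest))) {
  stopifnot(inherits(model, "scalobp_cnn"))
  sub <- manifest[rows, , drop = FALSE]
  attr(sub, "images") <- attr(manifest, "images")[rows]
  .cnn_predict_cpp(model$ptr, manifest_images_raw(sub), nrow(sub))
}

#' ROC curve and trapezoidal AUC from scores
#'
#' Sweeps the decision threshold over the sorted scores; the returned curve
#' starts at (0, 0) and ends at (1, 1).
#'
#' @param scores Numeric classifier scores.
#' @param labels Binary labels (0/1).
#' @return List with `roc` (data frame of `fpr`, `tpr`) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- sum(labels == 1); neg <- sum(labels == 0)
  if (pos == 0 || neg == 0) stop("need both classes for a ROC curve")
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[ord] == 1)
  fp <- cumsum(labels[ord] == 0)
  # collapse ties: keep the last point of each distinct score
  last <- c(diff(scores[ord]) != 0, TRUE)
  roc <- data.frame(fpr = c(0, fp[last] / neg, 1),
                    tpr = c(0, tp[last] / pos, 1))
  roc <- unique(roc)
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' Evaluate a trained model on one manifest split
#'
#' Accuracy at the 0.5 threshold plus the threshold-free ROC/AUC.
#'
#' @param model A trained `scalobp_cnn`.
#' @param manifest A manifest from [build_dataset()].
#' @param split `"val"` (default) or `"train"`.
#' @return An `eval_report`: `accuracy`, `roc`, `auc`, `scores`, `labels`,
#'   and the training `history` if the model carries one.
#' @export
evaluate_model <- function(model, manifest, split = "val") {
  rows <- which(manifest$split == split)
  if (!length(rows)) stop(sprintf("empty '%s' split", split))
  scores <- predict_scores(model, manifest, rows)
  labels <- manifest$binary[rows]
  rc <- if (length(unique(labels)) == 2) roc_curve(scores, labels)
        else {
          warning("only one class in the '", split,
                  "' split; ROC/AUC unavailable", call. = FALSE)
          list(roc = NULL, auc = NA_real_)
        }
  structure(list(accuracy = mean((scores >= 0.5) == (labels == 1)),
                 roc = rc$roc, auc = rc$auc, scores = scores,
                 labels = labels, history = model$history),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.3f, AUC %.3f (n = %d)\n",
              x$accuracy, x$auc, length(x$labels)))
  invisible(x)
}

#' Wavelet x segment-length grid comparison
#'
#' Runs one identically configured build/train/evaluate cycle per
#' (wavelet, segment length) cell — the cells differ in nothing else — and
#' collects validation accuracies. A failing cell is recorded and the grid
#' continues.
#'
#' @param records List of `waveform_record` objects (shared by all cells).
#' @param wavelets Character vector of wavelet names, possibly including
#'   `"none"` for the raw-segment baseline.
#' @param lengths Integer vector of segment lengths.
#' @param cfg A [train_config()] shared by all cells.
#' @param train_frac,seed Split parameters shared by all cells.
#' @param out_dir Root output directory for the per-cell datasets.
#' @param write_images Passed to [build_dataset()].
#' @return A `grid_result` data frame: `wavelet`, `segment_length`,
#'   `accuracy`, `auc`, `n_train`, `n_val`, `error`.
#' @export
grid_search <- function(records, wavelets, lengths, cfg = train_config(),
                        train_frac = 0.9, seed = 1L,
                        out_dir = tempfile("scalobp_grid_"),
                        write_images = FALSE) {
  if (!length(wavelets) || !length(lengths))
    stop("need at least one wavelet and one segment length")
  cells <- expand.grid(wavelet = wavelets, segment_length = lengths,
                       stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    wname <- cells$wavelet[i]; L <- cells$segment_length[i]
    out <- data.frame(wavelet = wname, segment_length = L,
                      accuracy = NA_real_, auc = NA_real_,
                      n_train = NA_integer_, n_val = NA_integer_,
                      error = NA_character_)
    tryCatch({
      wv <- if (wname == "none") "none" else wavelet_spec(wname)
      man <- build_dataset(records, wv, L, train_frac = train_frac,
                           seed = seed, out_dir = out_dir,
                           write_images = write_images)
      model <- build_model(seed = cfg$seed)
      model <- train_cnn(model, man, cfg)
      ev <- evaluate_model(model, man)
      out$accuracy <- ev$accuracy
      out$auc <- ev$auc
      out$n_train <- sum(man$split == "train")
      out$n_val <- sum(man$split == "val")
      rm(model, man)
    }, error = function(e) out$error <<- conditionMessage(e))
    gc(verbose = FALSE)   # free the ~GB-scale model before the next cell
    out
  })
  structure(do.call(rbind, res), class = c("grid_result", "data.frame"),
            config = cfg, seed = seed)
}

#' @export
print.grid_result <- function(x, ...) {
  cat("<grid_result> validation accuracy by wavelet x segment length\n")
  print.data.frame(as.data.frame(x), row.names = FALSE, digits = 3)
  invisible(x)
}
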