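# Training: acquisition-level splitting, artificial class balancing (train
# set only; evaluation stays in the real, imbalanced configuration),
# mean categorical cross-entropy minimized with Adam under a triangular
# cyclical learning rate, best-validation-epoch selection.

#' Training configuration
#'
#' @param stage cascade stage: 1 (reliable vs unreliable) or 2
#'   (flipping vs tank-treading).
#' @param balancing `"none"`, `"downsample_majority"`, `"upsample_minority"`
#'   or `"combined"` (down-sample the majority and up-sample the minority to
#'   stated targets); applied to the training data only.
#' @param down_to,up_to balancing targets (counts); defaults: down to the
#'   minority count, up to the majority count.
#' @param batch_size minibatch size.
#' @param epochs number of training epochs.
#' @param lr_range `c(low, high)` bounds of the triangular cyclical learning
#'   rate; one cycle spans each epoch.
#' @param seed integer seed covering balancing, shuffling and weight
#'   initialization.
#' @return an object of class `train_config`.
#' @export
train_config <- function(stage = 1,
                         balancing = c("none", "downsample_majority",
                                       "upsample_minority", "combined"),
                         down_to = NULL, up_to = NULL, batch_size = 64,
                         epochs = 20, lr_range = c(1e-4, 1e-3), seed = 1) {
  balancing <- match.arg(balancing)
  stopifnot(batch_size >= 1, epochs >= 1,
            length(lr_range) == 2, all(lr_range > 0),
            lr_range[1] <= lr_range[2])
  structure(list(stage = stage, balancing = balancing, down_to = down_to,
                 up_to = up_to, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr_range = lr_range,
                 seed = as.integer(seed)), class = "train_config")
}

#' Assign whole acquisitions to train / validation / test
#'
#' Acquisitions (recording sessions) are the unit of splitting, so sequences
#' from one acquisition never leak across splits.
#'
#' @param dataset an [rbc_dataset].
#' @param n_train,n_val,n_test number of acquisitions per split; their sum
#'   must not exceed the number of distinct acquisitions.
#' @param seed integer seed for the acquisition permutation.
#' @return the dataset with its `split` map set.
#' @export
split_by_acquisition <- function(dataset, n_train, n_val, n_test, seed = 1) {
  stopifnot(inherits(dataset, "rbc_dataset"))
  acqs <- unique(dataset$manifest$acquisition_id)
  if (n_train + n_val + n_test > length(acqs))
    stop("not enough acquisitions: have ", length(acqs), ", need ",
         n_train + n_val + n_test)
  set.seed(seed)
  perm <- sample(acqs)
  split <- setNames(rep(c("train", "validation", "test"),
                        c(n_train, n_val, n_test)),
                    perm[seq_len(n_train + n_val + n_test)])
  dataset$split <- split
  dataset
}

#' Artificially balance the two classes of a training set
#'
#' Down-sampling keeps a seeded random subset of the majority class;
#' up-sampling duplicates minority samples (the distinct-sequence set is
#' unchanged: originals plus sampled copies). `"combined"` does both, to the
#' two stated targets — e.g. the stage-1 setting down-samples the unreliable
#' class from 70000 to 5000 and up-samples the reliable class from 3800 to
#' 5000. Balancing must only ever be applied to training data.
#'
#' @param dataset an [rbc_dataset] (the training subset).
#' @param strategy `"downsample_majority"`, `"upsample_minority"` or
#'   `"combined"`.
#' @param stage cascade stage defining the binary classes.
#' @param down_to,up_to target counts; defaults: minority count / majority
#'   count (after down-sampling).
#' @param seed integer seed.
#' @return the balanced [rbc_dataset].
#' @export
balance_classes <- function(dataset,
                            strategy = c("downsample_majority",
                                         "upsample_minority", "combined"),
                            stage = 1, down_to = NULL, up_to = NULL, seed = 1) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(dataset, "rbc_dataset"))
  lab <- collapse_labels(dataset$manifest$label, stage)
  counts <- table(lab)
  if (length(counts) < 2 || any(counts == 0))
    stop("both classes must be present to balance")
  ord <- order(counts, decreasing = TRUE)
  maj <- names(counts)[ord[1]]; mino <- names(counts)[ord[2]]
  idx_maj <- which(lab == maj); idx_min <- which(lab == mino)
  set.seed(seed)
  if (strategy %in% c("downsample_majority", "combined")) {
    target <- down_to %||% length(idx_min)
    if (target < length(idx_maj))
      idx_maj <- sort(sample(idx_maj, target))
  }
  if (strategy %in% c("upsample_minority", "combined")) {
    target <- up_to %||% length(idx_maj)
    extra <- target - length(idx_min)
    if (extra > 0)
      idx_min <- c(idx_min, sample(idx_min, extra, replace = TRUE))
  }
  dataset_subset(dataset, c(idx_maj, idx_min))
}

#' Class counts after balancing, without materializing sequences
#'
#' The count arithmetic [balance_classes] follows: the majority class is cut
#' to `down_to` (if smaller than its count) and the minority class raised to
#' `up_to` (if larger than its count).
#'
#' @param n_majority,n_minority class counts before balancing.
#' @param down_to,up_to targets; `NULL` means minority count / majority count.
#' @return named integer vector `c(majority, minority)` after balancing.
#' @export
balanced_counts <- function(n_majority, n_minority, down_to = NULL,
                            up_to = NULL) {
  n_maj <- min(n_majority, down_to %||% n_minority)
  n_min <- if (is.null(up_to)) n_minority else max(n_minority, up_to)
  as.integer(c(n_maj, n_min))
}

#' Mean categorical cross-entropy
#'
#' The minimized form: mean over the batch of `-log p(true class)`, with the
#' true distribution one-hot. Probabilities are clamped below by `eps` so a
#' zero probability at the true class yields a large finite loss.
#'
#' @param probs `N x 2` matrix of class probabilities (columns named by
#'   class) or a named probability vector for a single sample.
#' @param true_labels character vector of true class names.
#' @param eps clamp for `log`.
#' @return non-negative scalar loss.
#' @export
cross_entropy_loss <- function(probs, true_labels, eps = 1e-12) {
  if (is.null(dim(probs))) probs <- matrix(probs, 1, dimnames = list(NULL, names(probs)))
  if (nrow(probs) == 0) stop("empty batch")
  if (nrow(probs) != length(true_labels)) stop("batch sizes differ")
  j <- match(true_labels, colnames(probs))
  if (anyNA(j)) stop("true labels outside the probability columns")
  p <- probs[cbind(seq_len(nrow(probs)), j)]
  mean(-log(pmax(p, eps)))
}

# Triangular cyclical learning rate: one cycle per epoch, rising to the top
# bound mid-epoch and back.
cyclical_lr <- function(batch, n_batches, lr_range) {
  pos <- (batch - 0.5) / n_batches
  lr_range[1] + (lr_range[2] - lr_range[1]) * (1 - abs(2 * pos - 1))
}

#' Train a classifier
#'
#' Builds the model from its spec (seeded), optionally balances the training
#' classes, and minimizes the mean categorical cross-entropy with Adam under
#' a triangular cyclical learning rate. After each epoch the model is
#' evaluated on the validation set; the epoch with the best validation loss
#' is returned as the final model.
#'
#' @param spec a [model_spec].
#' @param cfg a [train_config].
#' @param train,val [rbc_dataset]s, preprocessed compatibly with the spec
#'   (approach A: exactly `K` frames per sequence).
#' @return an object of class `rbc_train_result`: fields `model`,
#'   `train_loss`, `val_loss` (per-epoch curves), `best_epoch`, `seed`.
#' @export
train_model <- function(spec, cfg, train, val) {
  stopifnot(inherits(spec, "model_spec"), inherits(cfg, "train_config"),
            length(train) > 0, length(val) > 0)
  if (cfg$balancing != "none")
    train <- balance_classes(train, cfg$balancing, stage = cfg$stage,
                             down_to = cfg$down_to, up_to = cfg$up_to,
                             seed = cfg$seed)
  classes <- spec$classes
  y_train <- match(collapse_labels(train$manifest$label, cfg$stage), classes)
  y_val <- match(collapse_labels(val$manifest$label, cfg$stage), classes)
  if (anyNA(y_train) || anyNA(y_val)) stop("labels outside the spec's classes")

  model <- if (spec$approach == "A") build_model_a(spec) else build_model_b(spec)
  layers <- model_layers(model)
  is_a <- spec$approach == "A"
  Xtrain <- if (is_a) stack_sequences(train$sequences, spec$K) else NULL
  seq_arrays <- if (!is_a)
    lapply(train$sequences, sequence_array, frame_size = model$fx$frame_size)
    else NULL

  n <- length(train)
  set.seed(cfg$seed + 1L)
  train_loss <- val_loss <- numeric(cfg$epochs)
  best <- list(loss = Inf, epoch = NA_integer_, params = NULL)
  step <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(n)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    losses <- numeric(length(batches))
    for (b in seq_along(batches)) {
      idx <- batches[[b]]
      lr <- cyclical_lr(b, length(batches), cfg$lr_range)
      nn_zero_grads(layers)
      if (is_a) {
        x <- Xtrain[, , , idx, drop = FALSE]
        logits <- forward_logits(model, x, train = TRUE)
        probs <- softmax_cols(logits)
        onehot <- matrix(0, 2, length(idx))
        onehot[cbind(y_train[idx], seq_along(idx))] <- 1
        losses[b] <- mean(-log(pmax(probs[cbind(y_train[idx], seq_along(idx))],
                                    1e-12)))
        backward_from_logits(model, (probs - onehot) / length(idx))
      } else {
        lsum <- 0
        for (i in idx) {
          logits <- forward_logits(model, seq_arrays[[i]], train = TRUE)
          p <- softmax_cols(logits)
          lsum <- lsum - log(max(p[y_train[i], 1], 1e-12))
          d <- p
          d[y_train[i], 1] <- d[y_train[i], 1] - 1
          backward_from_logits(model, d / length(idx))
        }
        losses[b] <- lsum / length(idx)
      }
      if (!is.finite(losses[b]))
        stop("training diverged (non-finite loss) at epoch ", epoch)
      step <- step + 1L
      nn_adam_step(layers, lr, step)
    }
    train_loss[epoch] <- mean(losses)
    val_loss[epoch] <- dataset_loss(model, val, y_val)
    if (!is.finite(val_loss[epoch]))
      stop("training diverged (non-finite validation loss) at epoch ", epoch)
    if (val_loss[epoch] < best$loss)
      best <- list(loss = val_loss[epoch], epoch = epoch,
                   params = nn_get_params(layers))
  }
  nn_set_params(layers, best$params)
  structure(list(model = model, spec = spec, config = cfg,
                 train_loss = train_loss, val_loss = val_loss,
                 best_epoch = best$epoch, seed = cfg$seed),
            class = "rbc_train_result")
}

# Mean cross-entropy of a model over a dataset (forward only).
dataset_loss <- function(model, ds, y, batch_size = 64) {
  n <- length(ds)
  tot <- 0
  if (inherits(model, "rbc_model_a")) {
    for (b in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
      x <- stack_sequences(ds$sequences[b], model$spec$K)
      p <- softmax_cols(forward_logits(model, x))
      tot <- tot + sum(-log(pmax(p[cbind(y[b], seq_along(b))], 1e-12)))
    }
  } else {
    for (i in seq_len(n)) {
      p <- softmax_cols(forward_logits(model,
        sequence_array(ds$sequences[[i]], model$fx$frame_size)))
      tot <- tot + (-log(max(p[y[i], 1], 1e-12)))
    }
  }
  tot / n
}

#' @export
print.rbc_train_result <- function(x, ...) {
  cat(sprintf(
    "<training run: approach %s, stage %d, %d epochs, best epoch %d (val loss %.4f)>\n",
    x$spec$approach, x$config$stage, x$config$epochs, x$best_epoch,
    x$val_loss[x$best_epoch]))
  invisible(x)
}

#' Evaluate a trained model on a dataset
#'
#' Runs the model over the dataset and assembles the stage's evaluation
#' report (confusion matrix, accuracy/precision/recall/F1 and, for stage 2,
#' the per-acquisition marker table).
#'
#' @param model a trained `rbc_model`.
#' @param ds an [rbc_dataset] preprocessed compatibly with the model.
#' @param stage cascade stage (default: the model's).
#' @return an `rbc_eval_report`.
#' @export
evaluate_model <- function(model, ds, stage = model$spec$stage) {
  true <- collapse_labels(ds$manifest$label, stage)
  pred <- predict_labels(model, ds)
  evaluate_run(true, pred, ds$manifest$acquisition_id, stage = stage)
}
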