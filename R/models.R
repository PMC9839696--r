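# The two classifier families.
#
# Approach A: a fixed-size CNN where the channel dimension embeds time (the
# first channel is the first frame and so on) — a ResNet-18-style backbone:
# 7x7 stride-2 stem, 3x3 max pool, four stages of two residual basic blocks
# ([64, 128, 256, 512] filters, 3x3 kernels, stride-2 stage entry), global
# average pooling and a 2-way classification layer with softmax. No
# normalization layers (the architecture is implemented as specified:
# convolutions, ReLU and skip connections only).
#
# Approach B: a per-frame convolutional feature extractor with shared
# weights — conv(8, 3x3, s1, p1), conv(32, 2x2, s1, p1), conv(64, 2x2, s1,
# p1), max pool 3x3, conv(128, 3x3, s1, p1), each ReLU-activated — whose
# flattened output feeds a GRU with 64 units; the final hidden state (the
# context vector) passes through dense layers of 64 and 2 neurons.

#' Model specification
#'
#' @param approach `"A"` (fixed-size CNN, time as channels) or `"B"`
#'   (convolutional recurrent network).
#' @param K sequence-length bound: exact input length for approach A,
#'   maximum length for approach B.
#' @param stage cascade stage (1 or 2); sets the output class names.
#' @param classes optional length-2 character vector of class names
#'   (overrides `stage`); the network's two outputs in order.
#' @param gru_units GRU hidden size (approach B).
#' @param seed integer seed for weight initialization.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(approach = c("A", "B"), K = 20, stage = 1,
                       classes = NULL, gru_units = 64, seed = 1) {
  approach <- match.arg(approach)
  stopifnot(K >= 1)
  classes <- classes %||% stage_classes(stage)
  stopifnot(length(classes) == 2)
  structure(list(approach = approach, K = as.integer(K), stage = stage,
                 classes = classes, n_classes = 2L,
                 gru_units = as.integer(gru_units), seed = as.integer(seed)),
            class = "model_spec")
}

conv_out <- function(n, k, s, p) (n + 2 * p - k) %/% s + 1

#' Build the fixed-size CNN classifier (approach A)
#'
#' The first convolution accepts exactly `K` input channels; 31x31 frames
#' are assumed. Initialization is seeded He-normal (trained from scratch).
#'
#' @param spec a [model_spec] with `approach = "A"`.
#' @return an object of class `rbc_model` (and `rbc_model_a`).
#' @export
build_model_a <- function(spec) {
  stopifnot(inherits(spec, "model_spec"), spec$approach == "A")
  if (spec$K <= 0) stop("K must be positive")
  set.seed(spec$seed)
  stage <- function(in_ch, out_ch)
    list(nn_residual(in_ch, out_ch, stride = 2), nn_residual(out_ch, out_ch, 1))
  net <- nn_sequential(c(
    list(nn_conv(spec$K, 64, 7, stride = 2, pad = 3), nn_relu(),
         nn_maxpool(3, stride = 2, pad = 1)),
    stage(64, 64), stage(64, 128), stage(128, 256), stage(256, 512),
    list(nn_gap(), nn_dense(512, 2))))
  structure(list(spec = spec, net = net),
            class = c("rbc_model_a", "rbc_model"))
}

#' Build the per-frame feature extractor of approach B
#'
#' Weights are shared across frames: the extractor maps each 31x31 frame to
#' one fixed-length feature vector (the flattened final feature map).
#'
#' @param spec a [model_spec] with `approach = "B"`.
#' @param frame_size input frame side length.
#' @return an object of class `rbc_feature_extractor`, with fields `net` and
#'   `d_out` (the feature-vector length).
#' @export
build_feature_extractor <- function(spec, frame_size = 31) {
  stopifnot(inherits(spec, "model_spec"), spec$approach == "B")
  net <- nn_sequential(list(
    nn_conv(1, 8, 3, 1, 1), nn_relu(),
    nn_conv(8, 32, 2, 1, 1), nn_relu(),
    nn_conv(32, 64, 2, 1, 1), nn_relu(),
    nn_maxpool(3),
    nn_conv(64, 128, 3, 1, 1), nn_relu()))
  s <- frame_size
  s <- conv_out(s, 3, 1, 1)
  s <- conv_out(s, 2, 1, 1)
  s <- conv_out(s, 2, 1, 1)
  s <- conv_out(s, 3, 3, 0)
  s_final <- conv_out(s, 3, 1, 1)
  structure(list(net = net, frame_size = frame_size, s_out = s_final,
                 d_out = s_final * s_final * 128L),
            class = "rbc_feature_extractor")
}

#' Per-frame feature vectors for a sequence
#'
#' @param fx an `rbc_feature_extractor`.
#' @param seq an [rbc_sequence] of frames matching the extractor's size.
#' @return a `T x d_out` matrix, one row per frame.
#' @export
extract_features <- function(fx, seq) {
  stopifnot(inherits(fx, "rbc_feature_extractor"))
  x <- sequence_array(seq, fx$frame_size)
  y <- nn_forward(fx$net, x)
  t(matrix(y, fx$d_out, dim(x)[4]))
}

#' Build the convolutional recurrent classifier (approach B)
#'
#' Per-frame features feed a single-layer unidirectional GRU consuming the
#' sequence in temporal order; the final hidden state (context vector, size
#' `gru_units`) passes through dense layers of 64 and 2 neurons with
#' softmax. Accepts any sequence length >= 1.
#'
#' @inheritParams build_model_a
#' @param frame_size input frame side length.
#' @return an object of class `rbc_model` (and `rbc_model_b`).
#' @export
build_model_b <- function(spec, frame_size = 31) {
  stopifnot(inherits(spec, "model_spec"), spec$approach == "B")
  set.seed(spec$seed)
  fx <- build_feature_extractor(spec, frame_size)
  gru <- nn_gru(fx$d_out, spec$gru_units)
  head <- nn_sequential(list(nn_dense(spec$gru_units, 64), nn_relu(),
                             nn_dense(64, 2)))
  structure(list(spec = spec, fx = fx, gru = gru, head = head),
            class = c("rbc_model_b", "rbc_model"))
}

# Stack a sequence's frames into an (H, W, 1, T) array.
sequence_array <- function(seq, frame_size = NULL) {
  d <- dim(seq$frames[[1]])
  if (!is.null(frame_size) && !all(d == frame_size))
    stop("frames must be ", frame_size, "x", frame_size)
  array(unlist(seq$frames), dim = c(d[1], d[2], 1L, length(seq$frames)))
}

# Stack K-frame sequences into an (H, W, K, N) batch.
stack_sequences <- function(seqs, K) {
  d <- dim(seqs[[1]]$frames[[1]])
  lens <- vapply(seqs, function(s) length(s$frames), integer(1))
  if (!all(lens == K))
    stop("approach A requires exactly K = ", K, " frames per sequence")
  array(unlist(lapply(seqs, function(s) unlist(s$frames))),
        dim = c(d[1], d[2], K, length(seqs)))
}

model_layers <- function(model) {
  if (inherits(model, "rbc_model_a")) nn_collect(model$net)
  else c(nn_collect(model$fx$net), nn_collect(model$gru), nn_collect(model$head))
}

# Forward pass to logits. A: (31,31,K,N) batch -> (2 x N). B: one sequence
# array (31,31,1,T) -> (2 x 1).
forward_logits <- function(model, x, train = FALSE) {
  if (inherits(model, "rbc_model_a")) return(nn_forward(model$net, x, train))
  TT <- dim(x)[4]
  if (TT < 1) stop("empty sequence")
  y <- nn_forward(model$fx$net, x, train)
  feats <- matrix(y, model$fx$d_out, TT)
  h <- nn_forward(model$gru, feats, train)
  nn_forward(model$head, matrix(h, ncol = 1), train)
}

backward_from_logits <- function(model, dlogits) {
  if (inherits(model, "rbc_model_a")) {
    nn_backward(model$net, dlogits, need_dx = FALSE)
  } else {
    dh <- nn_backward(model$head, dlogits, TRUE)
    dfeats <- nn_backward(model$gru, dh, TRUE)
    darr <- array(dfeats, dim = c(model$fx$s_out, model$fx$s_out, 128,
                                  ncol(dfeats)))
    nn_backward(model$fx$net, darr, need_dx = FALSE)
  }
  invisible(NULL)
}

#' Class probabilities for one sequence
#'
#' Deterministic forward pass ending in softmax; names follow the model's
#' class vector, argmax (first index on ties) is the predicted class.
#' Approach A requires exactly `K` frames; approach B accepts any length.
#'
#' @param model a trained `rbc_model`.
#' @param seq a preprocessed [rbc_sequence].
#' @return named numeric vector of 2 probabilities summing to 1.
#' @export
predict_proba <- function(model, seq) UseMethod("predict_proba")

#' @export
predict_proba.rbc_model_a <- function(model, seq) {
  if (length(seq$frames) != model$spec$K)
    stop("approach A requires exactly K = ", model$spec$K, " frames")
  x <- stack_sequences(list(seq), model$spec$K)
  p <- softmax_cols(forward_logits(model, x))
  setNames(as.vector(p), model$spec$classes)
}

#' @export
predict_proba.rbc_model_b <- function(model, seq) {
  if (length(seq$frames) < 1) stop("empty sequence")
  x <- sequence_array(seq, model$fx$frame_size)
  p <- softmax_cols(forward_logits(model, x))
  setNames(as.vector(p), model$spec$classes)
}

#' Predicted stage labels for many sequences
#'
#' @param model a trained `rbc_model`.
#' @param sequences list of preprocessed [rbc_sequence]s, or an [rbc_dataset].
#' @param batch_size forward batch size for approach A.
#' @return character vector of predicted class names.
#' @export
predict_labels <- function(model, sequences, batch_size = 64) {
  if (inherits(sequences, "rbc_dataset")) sequences <- sequences$sequences
  if (inherits(model, "rbc_model_a")) {
    n <- length(sequences)
    out <- character(n)
    for (b in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
      x <- stack_sequences(sequences[b], model$spec$K)
      p <- softmax_cols(forward_logits(model, x))
      out[b] <- model$spec$classes[max.col(t(p), ties.method = "first")]
    }
    out
  } else {
    vapply(sequences, function(s) names(which.max(predict_proba(model, s))),
           character(1))
  }
}

#' Layer-by-layer architecture summary
#'
#' Introspects a built model and reports every convolution, pooling, dense
#' and recurrent layer with its kernel count/size, stride and padding —
#' useful for auditing the architecture against its definition.
#'
#' @param model an `rbc_model`.
#' @return data.frame with columns `type`, `filters`, `kernel`, `stride`,
#'   `pad`.
#' @export
model_summary <- function(model) {
  rows <- list()
  walk <- function(l) {
    if (inherits(l, "nn_sequential")) { lapply(l$layers, walk); return(invisible()) }
    if (inherits(l, "nn_residual")) {
      walk(l$conv1); walk(l$conv2)
      if (!is.null(l$proj)) walk(l$proj)
      return(invisible())
    }
    row <- switch(class(l)[1],
      nn_conv = data.frame(type = "conv", filters = l$out_ch, kernel = l$k,
                           stride = l$stride, pad = l$pad),
      nn_maxpool = data.frame(type = "maxpool", filters = NA, kernel = l$k,
                              stride = l$stride, pad = l$pad),
      nn_gap = data.frame(type = "avgpool", filters = NA, kernel = NA,
                          stride = NA, pad = NA),
      nn_dense = data.frame(type = "dense", filters = l$n_out, kernel = NA,
                            stride = NA, pad = NA),
      nn_gru = data.frame(type = "gru", filters = l$units, kernel = NA,
                          stride = NA, pad = NA),
      NULL)
    if (!is.null(row)) rows[[length(rows) + 1]] <<- row
    invisible()
  }
  if (inherits(model, "rbc_model_a")) walk(model$net)
  else { walk(model$fx$net); walk(model$gru); walk(model$head) }
  do.call(rbind, rows)
}

#' Number of trainable parameters
#' @param model an `rbc_model`.
#' @export
n_parameters <- function(model)
  sum(vapply(model_layers(model), function(l)
    sum(vapply(l$param_names, function(p) length(l[[p]]), numeric(1))), numeric(1)))

#' Save a model checkpoint
#'
#' A self-describing container: weights, the full [model_spec] and
#' optionally the [preprocess_config] the model expects. Round-trips
#' bit-exactly through [load_checkpoint].
#'
#' @param model an `rbc_model`.
#' @param path destination file.
#' @param preprocess optional [preprocess_config] stored alongside.
#' @export
save_checkpoint <- function(model, path, preprocess = NULL) {
  saveRDS(list(spec = model$spec, preprocess = preprocess,
               params = nn_get_params(model_layers(model))), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path file written by [save_checkpoint].
#' @return list with `model` and `preprocess`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- if (ck$spec$approach == "A") build_model_a(ck$spec)
           else build_model_b(ck$spec)
  nn_set_params(model_layers(model), ck$params)
  list(model = model, preprocess = ck$preprocess)
}
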