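# Sequence-length bounding.
#
# Sequences run from 6 to >100 frames; the classifiers bound length by an
# upper limit K (a hyperparameter, typically 10-50): either uniform frame
# removal or an iterative similarity-based removal that keeps the most
# dissimilar consecutive frames, ranked by the structural similarity index.

#' Preprocessing configuration
#'
#' @param K maximum sequence length after downsampling (>= 2). The fixed-size
#'   CNN consumes exactly `K` frames (shorter sequences are padded); the
#'   recurrent model treats `K` as a maximum only.
#' @param sampling `"uniform"` or `"similarity"`.
#' @param pad_to_K pad shorter sequences with all-black frames up to `K`
#'   (`TRUE` for the fixed-size CNN, `FALSE` for the recurrent model).
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(K = 20, sampling = c("uniform", "similarity"),
                              pad_to_K = TRUE) {
  stopifnot(K >= 2)
  sampling <- match.arg(sampling)
  structure(list(K = as.integer(K), sampling = sampling, pad_to_K = pad_to_K),
            class = "preprocess_config")
}

# Moving-sum box filter over valid windows, as banded-matrix products
# (one BLAS call per side); the banded matrices are cached per geometry.
box_mat_cache <- new.env(parent = emptyenv())
box_mat <- function(n, win) {
  key <- paste(n, win)
  m <- box_mat_cache[[key]]
  if (is.null(m)) {
    rows <- n - win + 1
    m <- matrix(0, rows, n)
    for (i in seq_len(rows)) m[i, i:(i + win - 1)] <- 1
    box_mat_cache[[key]] <- m
  }
  m
}
box_sum <- function(x, win)
  box_mat(nrow(x), win) %*% x %*% t(box_mat(ncol(x), win))

#' Structural similarity index between two frames
#'
#' Windowed SSIM in its standard luminance-contrast-structure form with
#' stabilization constants `C1 = (K1 * L)^2`, `C2 = (K2 * L)^2`, computed
#' over a sliding square window (uniform weights, sample variances) and
#' averaged over all valid window positions. Equal to 1 for identical
#' frames; symmetric in its arguments.
#'
#' @param a,b numeric matrices of identical dimensions.
#' @param win window side length; clipped to the smaller image dimension.
#' @param K1,K2 stabilization coefficients.
#' @param data_range dynamic range `L` of the data (1 for `[0, 1]` frames).
#' @return a scalar in `[-1, 1]`.
#' @export
ssim <- function(a, b, win = 7, K1 = 0.01, K2 = 0.03, data_range = 1) {
  if (!identical(dim(a), dim(b))) stop("frames must share dimensions")
  win <- min(win, nrow(a), ncol(a))
  n <- win * win
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  sa <- box_sum(a, win); sb <- box_sum(b, win)
  mua <- sa / n; mub <- sb / n
  # sample (n-1)-normalized variances and covariance per window
  va <- (box_sum(a * a, win) - n * mua^2) / (n - 1)
  vb <- (box_sum(b * b, win) - n * mub^2) / (n - 1)
  cab <- (box_sum(a * b, win) - n * mua * mub) / (n - 1)
  s <- ((2 * mua * mub + C1) * (2 * cab + C2)) /
       ((mua^2 + mub^2 + C1) * (va + vb + C2))
  mean(s)
}

#' Uniform sequence downsampling
#'
#' Keeps frames at indices `round(i * (len - 1) / (K - 1))` for
#' `i = 0 .. K-1` (half-up rounding; the first and last frames are always
#' kept, order preserved). Sequences of length `<= K` pass unchanged.
#'
#' @param seq an [rbc_sequence].
#' @param K maximum length (>= 2).
#' @return the downsampled [rbc_sequence].
#' @export
uniform_downsample <- function(seq, K) {
  stopifnot(inherits(seq, "rbc_sequence"), K >= 2)
  len <- length(seq$frames)
  if (len <= K) return(seq)
  idx <- floor((seq_len(K) - 1) * (len - 1) / (K - 1) + 0.5) + 1L
  seq$frames <- seq$frames[idx]
  seq
}

#' Similarity-based sequence downsampling
#'
#' Iteratively removes the most redundant frame until length `K`: at each
#' step the SSIM of every consecutive frame pair is considered, the second
#' (later) member of the most similar pair is dropped (earliest pair wins on
#' ties), and only the two pairs adjacent to the removal are re-scored. The
#' retained frames are the most mutually dissimilar ones, preserving the
#' shape dynamics that discriminate the motion regimes.
#'
#' @inheritParams uniform_downsample
#' @param ... passed on to [ssim].
#' @return the downsampled [rbc_sequence].
#' @export
similarity_downsample <- function(seq, K, ...) {
  stopifnot(inherits(seq, "rbc_sequence"), K >= 2)
  len <- length(seq$frames)
  if (len <= K) return(seq)
  frames <- seq$frames
  sims <- vapply(seq_len(len - 1),
                 function(i) ssim(frames[[i]], frames[[i + 1]], ...), numeric(1))
  while (length(frames) > K) {
    j <- which.max(sims)           # earliest maximally similar pair
    frames <- frames[-(j + 1)]     # drop the later member
    sims <- sims[-j]
    if (j <= length(sims))         # new pair (j, j+1) created by the removal
      sims[j] <- ssim(frames[[j]], frames[[j + 1]], ...)
  }
  seq$frames <- frames
  seq
}

#' Pad a sequence with black frames to exactly K
#'
#' Appends all-zero frames at the end; the original frames are preserved
#' bit-identically and in place. Used by the fixed-size CNN whose input
#' length is exactly `K`.
#'
#' @inheritParams uniform_downsample
#' @return an [rbc_sequence] of exactly `K` frames.
#' @export
pad_sequence <- function(seq, K) {
  stopifnot(inherits(seq, "rbc_sequence"))
  len <- length(seq$frames)
  if (len > K) stop("sequence longer than K; downsample before padding")
  if (len < K) {
    d <- dim(seq$frames[[1]])
    black <- matrix(0, d[1], d[2])
    seq$frames <- c(seq$frames, rep(list(black), K - len))
  }
  seq
}

#' Preprocess every sequence of a dataset
#'
#' Applies the configured downsampling to each sequence and, if
#' `cfg$pad_to_K`, pads all of them to exactly `K` frames. Labels,
#' identifiers and row order are preserved.
#'
#' @param dataset an [rbc_dataset].
#' @param cfg a [preprocess_config].
#' @return the preprocessed [rbc_dataset].
#' @export
preprocess_batch <- function(dataset, cfg) {
  stopifnot(inherits(dataset, "rbc_dataset"), inherits(cfg, "preprocess_config"))
  down <- if (cfg$sampling == "uniform") uniform_downsample else similarity_downsample
  seqs <- lapply(dataset$sequences, function(s) {
    s <- down(s, cfg$K)
    if (cfg$pad_to_K) s <- pad_sequence(s, cfg$K)
    s
  })
  rbc_dataset(seqs, split = dataset$split)
}
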