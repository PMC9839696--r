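# Small in-code fixtures shared across test files.

# A sequence of small frames with distinct, recognisable content: frame i has
# constant value i / (n + 1). Useful for tracing frame identity through
# downsampling and padding.
graded_sequence <- function(n, size = 4, label = NULL) {
  frames <- lapply(seq_len(n), function(i) matrix(i / (n + 1), size, size))
  rbc_sequence(frames, label = label, sequence_id = paste0("graded", n))
}

# Deterministic textured frames so SSIM between pairs is non-trivial.
textured_frame <- function(seed, size = 4) {
  set.seed(seed)
  matrix(runif(size * size), size, size)
}

# Quiet generator settings: no noise, no orientation wobble, so rendered
# geometry is exactly reproducible.
quiet_params <- function(...)
  motion_params(noise_sd = 0, orientation_osc_amplitude_deg = 0, ...)

# Coefficient of variation of the apparent-width series of a sequence.
width_cv <- function(seq) {
  w <- vapply(seq$frames, measure_apparent_width, integer(1))
  stats::sd(w) / mean(w)
}

# Independent single-window SSIM evaluation, straight from the formula, for
# use as an oracle against the sliding-window implementation.
ssim_single_window <- function(a, b, K1 = 0.01, K2 = 0.03, L = 1) {
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  mua <- mean(a); mub <- mean(b)
  va <- stats::var(as.vector(a)); vb <- stats::var(as.vector(b))
  cab <- stats::cov(as.vector(a), as.vector(b))
  ((2 * mua * mub + C1) * (2 * cab + C2)) /
    ((mua^2 + mub^2 + C1) * (va + vb + C2))
}

# Brute-force replay of the greedy similarity-downsampling rule, recomputing
# every consecutive-pair SSIM at each iteration (the lazy re-scoring in the
# implementation must agree with this full recomputation).
similarity_downsample_bruteforce <- function(seq, K) {
  frames <- seq$frames
  while (length(frames) > K) {
    sims <- vapply(seq_len(length(frames) - 1), function(i)
      ssim(frames[[i]], frames[[i + 1]]), numeric(1))
    j <- which.max(sims)
    frames <- frames[-(j + 1)]
  }
  frames
}

# Brute-force normalized cross-correlation over all integer shifts, the
# oracle for the C++ shift search used in position refinement.
best_shift_bruteforce <- function(a, b, max_shift) {
  H <- nrow(a); W <- ncol(a)
  best <- c(0, 0); best_cc <- -Inf
  for (sy in -max_shift:max_shift) for (sx in -max_shift:max_shift) {
    h <- seq(max(1, 1 - sy), min(H, H - sy))
    w <- seq(max(1, 1 - sx), min(W, W - sx))
    if (length(h) < 3 || length(w) < 3) next
    va <- as.vector(a[h, w]); vb <- as.vector(b[h + sy, w + sx])
    if (stats::sd(va) < 1e-8 || stats::sd(vb) < 1e-8) next
    cc <- stats::cor(va, vb)
    if (cc > best_cc + 1e-12) { best_cc <- cc; best <- c(sx, sy) }
  }
  best
}

# Access to engine internals used by the architecture audits.
nn_forward <- rbcmotion:::nn_forward
nn_collect_first_conv <- function(m) rbcmotion:::nn_collect(m$net)[[1]]
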