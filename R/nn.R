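# Minimal neural-network engine.
#
# Layers are environments carrying parameters, Adam state and gradient
# buffers; forward passes cache what the backward pass needs. Image batches
# are (H, W, C, N) arrays; dense activations are (features x N) matrices.
# Convolutions and pooling run through single-precision C++ kernels
# (src/nn_kernels.cpp); everything is deterministic given the R RNG seed
# used at initialization.

new_layer <- function(cls, params = character(0), ...) {
  e <- new.env(parent = emptyenv())
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  e$param_names <- params
  for (p in params) {
    e[[paste0("g_", p)]] <- e[[p]] * 0
    e[[paste0("m_", p)]] <- e[[p]] * 0
    e[[paste0("v_", p)]] <- e[[p]] * 0
  }
  class(e) <- c(cls, "nn_layer")
  e
}

# Explicit dispatch on the layer's leading class: these generics are called
# from hot loops and the layer set is closed.
nn_forward <- function(l, x, train = FALSE)
  switch(class(l)[1],
         nn_conv = nn_forward.nn_conv(l, x, train),
         nn_relu = nn_forward.nn_relu(l, x, train),
         nn_maxpool = nn_forward.nn_maxpool(l, x, train),
         nn_gap = nn_forward.nn_gap(l, x, train),
         nn_dense = nn_forward.nn_dense(l, x, train),
         nn_residual = nn_forward.nn_residual(l, x, train),
         nn_sequential = nn_forward.nn_sequential(l, x, train),
         nn_gru = nn_forward.nn_gru(l, x, train),
         stop("unknown layer class"))

nn_backward <- function(l, dy, need_dx = TRUE)
  switch(class(l)[1],
         nn_conv = nn_backward.nn_conv(l, dy, need_dx),
         nn_relu = nn_backward.nn_relu(l, dy, need_dx),
         nn_maxpool = nn_backward.nn_maxpool(l, dy, need_dx),
         nn_gap = nn_backward.nn_gap(l, dy, need_dx),
         nn_dense = nn_backward.nn_dense(l, dy, need_dx),
         nn_residual = nn_backward.nn_residual(l, dy, need_dx),
         nn_sequential = nn_backward.nn_sequential(l, dy, need_dx),
         nn_gru = nn_backward.nn_gru(l, dy, need_dx),
         stop("unknown layer class"))

# Flat list of parameter-bearing layers (shared environments, not copies).
nn_collect <- function(l)
  switch(class(l)[1],
         nn_residual = nn_collect.nn_residual(l),
         nn_sequential = nn_collect.nn_sequential(l),
         if (length(l$param_names)) list(l) else list())

he_init <- function(nout, nin) matrix(rnorm(nout * nin, 0, sqrt(2 / nin)), nout, nin)

## -- convolution ------------------------------------------------------------

nn_conv <- function(in_ch, out_ch, k, stride = 1, pad = 0) {
  new_layer("nn_conv", params = c("W", "b"),
            W = he_init(out_ch, in_ch * k * k), b = numeric(out_ch),
            in_ch = in_ch, out_ch = out_ch, k = k, stride = stride, pad = pad)
}

nn_forward.nn_conv <- function(l, x, train = FALSE) {
  if (train) l$x <- x
  cpp_conv_fwd(x, l$W, l$b, l$k, l$k, l$stride, l$pad)
}

nn_backward.nn_conv <- function(l, dy, need_dx = TRUE) {
  r <- cpp_conv_bwd(l$x, l$W, dy, l$k, l$k, l$stride, l$pad, need_dx)
  l$g_W <- l$g_W + r$dw
  l$g_b <- l$g_b + r$db
  if (need_dx) r$dx else NULL
}

## -- relu / pooling ---------------------------------------------------------

nn_relu <- function() new_layer("nn_relu")

nn_forward.nn_relu <- function(l, x, train = FALSE) {
  if (train) l$x <- x
  cpp_relu_fwd(x)
}
nn_backward.nn_relu <- function(l, dy, need_dx = TRUE) cpp_relu_bwd(dy, l$x)

nn_maxpool <- function(k, stride = k, pad = 0)
  new_layer("nn_maxpool", k = k, stride = stride, pad = pad)

nn_forward.nn_maxpool <- function(l, x, train = FALSE) {
  r <- cpp_maxpool_fwd(x, l$k, l$stride, l$pad)
  if (train) { l$idx <- r$idx; l$xdim <- dim(x) }
  r$y
}
nn_backward.nn_maxpool <- function(l, dy, need_dx = TRUE)
  cpp_maxpool_bwd(dy, l$idx, l$xdim)

# Global average pooling: (H, W, C, N) -> (C x N)
nn_gap <- function() new_layer("nn_gap")

nn_forward.nn_gap <- function(l, x, train = FALSE) {
  d <- dim(x)
  if (train) l$xdim <- d
  matrix(.colMeans(matrix(x, d[1] * d[2], d[3] * d[4]), d[1] * d[2], d[3] * d[4]),
         d[3], d[4])
}
nn_backward.nn_gap <- function(l, dy, need_dx = TRUE) {
  d <- l$xdim
  hw <- d[1] * d[2]
  array(rep(as.vector(dy) / hw, each = hw), dim = d)
}

## -- dense ------------------------------------------------------------------

nn_dense <- function(n_in, n_out)
  new_layer("nn_dense", params = c("W", "b"),
            W = he_init(n_out, n_in), b = numeric(n_out),
            n_in = n_in, n_out = n_out)

nn_forward.nn_dense <- function(l, x, train = FALSE) {
  if (train) l$x <- x
  l$W %*% x + l$b
}
nn_backward.nn_dense <- function(l, dy, need_dx = TRUE) {
  l$g_W <- l$g_W + dy %*% t(l$x)
  l$g_b <- l$g_b + rowSums(dy)
  if (need_dx) t(l$W) %*% dy else NULL
}

## -- residual basic block (two 3x3 convs + identity/projection skip) --------

nn_residual <- function(in_ch, out_ch, stride = 1) {
  l <- new_layer("nn_residual",
                 conv1 = nn_conv(in_ch, out_ch, 3, stride, 1),
                 conv2 = nn_conv(out_ch, out_ch, 3, 1, 1),
                 proj = if (stride != 1 || in_ch != out_ch)
                   nn_conv(in_ch, out_ch, 1, stride, 0) else NULL,
                 in_ch = in_ch, out_ch = out_ch, stride = stride)
  l
}

nn_collect.nn_residual <- function(l)
  c(nn_collect(l$conv1), nn_collect(l$conv2),
    if (!is.null(l$proj)) nn_collect(l$proj) else list())

nn_forward.nn_residual <- function(l, x, train = FALSE) {
  h1 <- nn_forward(l$conv1, x, train)
  if (train) l$h1 <- h1
  h <- nn_forward(l$conv2, cpp_relu_fwd(h1), train)
  sk <- if (is.null(l$proj)) x else nn_forward(l$proj, x, train)
  s <- h + sk
  if (train) l$s <- s
  cpp_relu_fwd(s)
}

nn_backward.nn_residual <- function(l, dy, need_dx = TRUE) {
  ds <- cpp_relu_bwd(dy, l$s)
  da1 <- cpp_relu_bwd(nn_backward(l$conv2, ds, TRUE), l$h1)
  dx1 <- nn_backward(l$conv1, da1, need_dx)
  dsk <- if (is.null(l$proj)) ds else nn_backward(l$proj, ds, need_dx)
  if (need_dx) dx1 + dsk else NULL
}

## -- sequential container ---------------------------------------------------

nn_sequential <- function(layers) new_layer("nn_sequential", layers = layers)

nn_collect.nn_sequential <- function(l)
  do.call(c, lapply(l$layers, nn_collect))

nn_forward.nn_sequential <- function(l, x, train = FALSE) {
  for (layer in l$layers) x <- nn_forward(layer, x, train)
  x
}
nn_backward.nn_sequential <- function(l, dy, need_dx = TRUE) {
  n <- length(l$layers)
  for (i in rev(seq_len(n)))
    dy <- nn_backward(l$layers[[i]], dy, need_dx || i > 1)
  if (need_dx) dy else NULL
}

## -- gated recurrent unit ---------------------------------------------------

# PyTorch-convention GRU cell over a (T x d) feature-sequence matrix:
#   r = sigmoid(Wx_r x + bx_r + Uh_r h + bh_r)
#   z = sigmoid(Wx_z x + bx_z + Uh_z h + bh_z)
#   n = tanh(Wx_n x + bx_n + r * (Uh_n h + bh_n))
#   h = (1 - z) * n + z * h
# The final hidden state is the context vector summarizing the sequence.
nn_gru <- function(d_in, units) {
  s <- 1 / sqrt(units)
  u3 <- 3 * units
  new_layer("nn_gru", params = c("Wx", "Uh", "bx", "bh"),
            Wx = matrix(runif(u3 * d_in, -s, s), u3, d_in),
            Uh = matrix(runif(u3 * units, -s, s), u3, units),
            bx = runif(u3, -s, s), bh = runif(u3, -s, s),
            d_in = d_in, units = units)
}

# The GRU consumes frame features column-wise: x is a (d_in x T) matrix, one
# column per frame, so the feature extractor's output feeds in without
# transposition.
nn_forward.nn_gru <- function(l, x, train = FALSE) {
  u <- l$units; TT <- ncol(x)
  ir <- 1:u; iz <- (u + 1):(2 * u); inn <- (2 * u + 1):(3 * u)
  Gx <- cpp_sgemm(l$Wx, x) + l$bx
  h <- numeric(u)
  R <- Z <- Nn <- U3 <- Hp <- matrix(0, u, TT)
  for (t in seq_len(TT)) {
    g <- Gx[, t]
    uh <- as.vector(l$Uh %*% h) + l$bh
    r <- plogis(g[ir] + uh[ir])
    z <- plogis(g[iz] + uh[iz])
    nn <- tanh(g[inn] + r * uh[inn])
    Hp[, t] <- h
    h <- (1 - z) * nn + z * h
    R[, t] <- r; Z[, t] <- z; Nn[, t] <- nn; U3[, t] <- uh[inn]
  }
  if (train) { l$x <- x; l$R <- R; l$Z <- Z; l$Nn <- Nn; l$U3 <- U3; l$Hp <- Hp }
  h
}

nn_backward.nn_gru <- function(l, dy, need_dx = TRUE) {
  u <- l$units; TT <- ncol(l$x)
  DG <- matrix(0, 3 * u, TT)
  DU <- matrix(0, 3 * u, TT)
  dh <- as.vector(dy)
  for (t in rev(seq_len(TT))) {
    r <- l$R[, t]; z <- l$Z[, t]; nn <- l$Nn[, t]
    u3 <- l$U3[, t]; hp <- l$Hp[, t]
    dz <- dh * (hp - nn)
    daz <- dz * z * (1 - z)
    dan <- dh * (1 - z) * (1 - nn^2)
    dar <- dan * u3 * r * (1 - r)
    DG[, t] <- c(dar, daz, dan)
    DU[, t] <- c(dar, daz, dan * r)
    dh <- dh * z + as.vector(crossprod(l$Uh, DU[, t]))
  }
  l$g_Wx <- l$g_Wx + cpp_sgemm(DG, l$x, tb = TRUE)
  l$g_Uh <- l$g_Uh + tcrossprod(DU, l$Hp)  # DU %*% t(Hp)
  l$g_bx <- l$g_bx + rowSums(DG)
  l$g_bh <- l$g_bh + rowSums(DU)
  if (need_dx) cpp_sgemm(l$Wx, DG, ta = TRUE) else NULL
}

## -- optimizer --------------------------------------------------------------

nn_zero_grads <- function(layers) {
  for (l in layers) for (p in l$param_names) l[[paste0("g_", p)]][] <- 0
  invisible(NULL)
}

# One Adam update over all layers; parameters and moments update in place.
nn_adam_step <- function(layers, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  for (l in layers) for (p in l$param_names)
    cpp_adam_step(l[[p]], l[[paste0("g_", p)]], l[[paste0("m_", p)]],
                  l[[paste0("v_", p)]], lr, b1, b2, eps, t)
  invisible(NULL)
}

nn_get_params <- function(layers)
  lapply(layers, function(l)
    setNames(lapply(l$param_names, function(p) l[[p]] + 0), l$param_names))

nn_set_params <- function(layers, params) {
  stopifnot(length(layers) == length(params))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    stopifnot(identical(names(params[[i]]), l$param_names))
    for (p in l$param_names) {
      stopifnot(length(params[[i]][[p]]) == length(l[[p]]))
      l[[p]] <- params[[i]][[p]] + 0
    }
  }
  invisible(NULL)
}

softmax_cols <- function(logits) {
  e <- exp(sweep(logits, 2, apply(logits, 2, max)))
  sweep(e, 2, colSums(e), "/")
}
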