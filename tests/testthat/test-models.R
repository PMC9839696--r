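# Architecture audits keep the built networks honest against their stated
# layer tables; small fixed-seed sequences exercise the forward contracts.

test_that("approach A's backbone matches the stated architecture", {
  m <- build_model_a(model_spec("A", K = 20, stage = 2, seed = 1))
  s <- model_summary(m)
  convs <- s[s$type == "conv", ]
  # stem: 64 kernels 7x7 s2 p3
  expect_equal(unlist(convs[1, c("filters", "kernel", "stride", "pad")]),
               c(filters = 64, kernel = 7, stride = 2, pad = 3))
  # first convolution accepts exactly K input channels
  first_conv <- nn_collect_first_conv(m)
  expect_equal(ncol(first_conv$W), 20 * 7 * 7)
  # four stages of two basic blocks: 3x3 convs at 64/128/256/512 filters
  body <- convs[-1, ]
  main <- body[body$kernel == 3, ]
  expect_equal(main$filters, rep(c(64, 128, 256, 512), each = 4))
  expect_true(all(main$pad == 1))
  # stage entries are stride-2, all other 3x3 convs stride-1
  expect_equal(main$stride, rep(c(2, 1, 1, 1), 4))
  # projection shortcuts are 1x1 at channel changes
  proj <- body[body$kernel == 1, ]
  expect_equal(proj$filters, c(64, 128, 256, 512))
  # pooling stem, global average pool and 2-way head
  expect_equal(s$kernel[s$type == "maxpool"], 3)
  expect_equal(sum(s$type == "avgpool"), 1)
  expect_equal(s$filters[s$type == "dense"], 2)
})

test_that("the feature extractor matches its layer table and derived dimension", {
  spec <- model_spec("B", K = 50, stage = 1, seed = 1)
  fx <- build_feature_extractor(spec)
  s <- model_summary(build_model_b(spec))
  convs <- s[s$type == "conv", ]
  expect_equal(convs$filters, c(8, 32, 64, 128))
  expect_equal(convs$kernel, c(3, 2, 2, 3))
  expect_true(all(convs$stride == 1) && all(convs$pad == 1))
  # independently trace the spatial size through the stated layers
  trace <- function(n, k, s, p) (n + 2 * p - k) %/% s + 1
  d <- 31
  d <- trace(d, 3, 1, 1)   # 31
  d <- trace(d, 2, 1, 1)   # 32
  d <- trace(d, 2, 1, 1)   # 33
  d <- trace(d, 3, 3, 0)   # 11 (pool stride = pool size)
  d <- trace(d, 3, 1, 1)   # 11
  expect_equal(fx$d_out, d * d * 128)

  # one fixed-length vector per frame, identical frames -> identical vectors
  p <- quiet_params()
  seq2 <- generate_sequence("tank_treading", 2, p, seed = 3)
  F2 <- extract_features(fx, seq2)
  expect_equal(dim(F2), c(2, fx$d_out))
  expect_equal(F2[1, ], F2[2, ])  # constant projection, zero noise
})

test_that("softmax probabilities are valid for both approaches", {
  specA <- model_spec("A", K = 6, stage = 1, seed = 2)
  mA <- build_model_a(specA)
  specB <- model_spec("B", K = 20, stage = 2, seed = 2)
  mB <- build_model_b(specB)
  for (seed in 1:3) {
    s6 <- generate_sequence("flipping", 6, motion_params(), seed = seed)
    pA <- predict_proba(mA, s6)
    pB <- predict_proba(mB, s6)
    for (p in list(pA, pB)) {
      expect_equal(sum(p), 1, tolerance = 1e-6)
      expect_true(all(p >= 0))
    }
    expect_named(pA, c("unreliable", "reliable"))
    expect_named(pB, c("tank_treading", "flipping"))
    # repeated calls are identical (no stochastic layers at inference)
    expect_identical(pA, predict_proba(mA, s6))
  }
})

test_that("initialization is seed-deterministic", {
  w1 <- nn_collect_first_conv(build_model_a(model_spec("A", K = 4, seed = 7)))$W
  w2 <- nn_collect_first_conv(build_model_a(model_spec("A", K = 4, seed = 7)))$W
  w3 <- nn_collect_first_conv(build_model_a(model_spec("A", K = 4, seed = 8)))$W
  expect_identical(w1, w2)
  expect_false(identical(w1, w3))
})

test_that("approach B accepts arbitrary lengths and is order-sensitive", {
  m <- build_model_b(model_spec("B", K = 50, stage = 2, seed = 4))
  s6 <- generate_sequence("flipping", 6, motion_params(), seed = 1)
  s50 <- generate_sequence("flipping", 50, motion_params(), seed = 1)
  expect_length(predict_proba(m, s6), 2)
  expect_length(predict_proba(m, s50), 2)
  # the context vector is the GRU's final hidden state, size 64
  h <- nn_forward(m$gru, matrix(rnorm(m$fx$d_out * 3), m$fx$d_out, 3))
  expect_length(h, 64)
  # a two-frame pair with distinct frames: reversing changes the output
  pair <- generate_sequence("flipping", 2, quiet_params(flip_period_frames = 4),
                            seed = 2)
  rev_pair <- rbc_sequence(rev(pair$frames), sequence_id = "rev")
  expect_false(isTRUE(all.equal(predict_proba(m, pair),
                                predict_proba(m, rev_pair),
                                check.attributes = FALSE)))
})

test_that("approach A rejects wrong input lengths; B rejects empty input", {
  mA <- build_model_a(model_spec("A", K = 10, seed = 1))
  s6 <- generate_sequence("flipping", 6, motion_params(), seed = 1)
  expect_error(predict_proba(mA, s6), "K = 10")
  expect_error(build_model_a(model_spec("B", K = 10)), "A")
})

test_that("checkpoints round-trip bit-exactly", {
  for (spec in list(model_spec("A", K = 6, stage = 1, seed = 5),
                    model_spec("B", K = 20, stage = 2, seed = 5))) {
    m <- if (spec$approach == "A") build_model_a(spec) else build_model_b(spec)
    s <- generate_sequence("flipping", 6, motion_params(), seed = 9)
    before <- predict_proba(m, s)
    f <- tempfile(fileext = ".rds")
    save_checkpoint(m, f, preprocess = preprocess_config(K = 6))
    ck <- load_checkpoint(f)
    expect_identical(predict_proba(ck$model, s), before)
    expect_equal(ck$preprocess$K, 6L)
  }
})

test_that("approach A parameter count is input-independent; B cost grows with length", {
  nA1 <- n_parameters(build_model_a(model_spec("A", K = 10, seed = 1)))
  nA2 <- n_parameters(build_model_a(model_spec("A", K = 50, seed = 1)))
  # only the K-channel stem differs
  expect_equal(nA2 - nA1, 64 * 7 * 7 * 40)
  m <- build_model_b(model_spec("B", K = 50, seed = 1))
  t_short <- system.time(for (i in 1:3) predict_proba(
    m, generate_sequence("flipping", 5, motion_params(), seed = 1)))["elapsed"]
  t_long <- system.time(for (i in 1:3) predict_proba(
    m, generate_sequence("flipping", 60, motion_params(), seed = 1)))["elapsed"]
  expect_gt(t_long, t_short)
})
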