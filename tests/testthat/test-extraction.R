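# Extraction pipeline: each stage is checked against the generator's ground
# truth, which shares no code with the detector or tracker.

lane_movie <- function(n_cells = 3, seed = 8, noise_sd = 0.01, width = 240) {
  generate_movie(n_cells, field_size = c(100, width),
                 params = motion_params(noise_sd = 0),
                 y_sampler = function(n) seq(22, 78, length.out = n),
                 noise_sd = noise_sd, stagger_frames = 40, seed = seed)
}

test_that("the background of a constant movie is exact and short movies use all frames", {
  frames <- rep(list(matrix(0.4, 20, 30)), 50)
  m <- rbc_movie(frames, fps = 60)
  cfg <- extraction_config(n_background_frames = 100)
  expect_equal(compute_background(m, cfg), matrix(0.4, 20, 30))
  expect_error(compute_background(rbc_movie(frames[1], fps = 60),
                                  extraction_config(n_background_frames = 1)),
               NA)
})

test_that("the median background recovers the illumination field under moving cells", {
  m <- lane_movie(4, noise_sd = 0.01)
  clean <- generate_movie(0, field_size = c(100, 240), n_frames = 3,
                          noise_sd = 0, seed = 1)$frames[[1]]
  bg <- compute_background(m, extraction_config(n_background_frames = 60))
  expect_lt(max(abs(bg - clean)), 0.03)
})

test_that("detection finds each synthetic cell within a pixel, and nothing in background", {
  m <- lane_movie(2, seed = 12)
  cfg <- extraction_config()
  bg <- compute_background(m, cfg)
  f <- 35
  gt <- do.call(rbind, lapply(m$tracks, function(tr) tr[tr$frame == f, c("x", "y")]))
  d <- detect_objects(m$frames[[f]], bg, cfg)
  expect_equal(nrow(d), nrow(gt))
  for (i in seq_len(nrow(gt))) {
    err <- min(sqrt((d$x - gt$x[i])^2 + (d$y - gt$y[i])^2))
    expect_lt(err, 1)
  }
  # a pure-background frame yields no detections
  empty <- generate_movie(0, field_size = c(100, 240), n_frames = 5,
                          noise_sd = 0.01, seed = 3)
  d0 <- detect_objects(empty$frames[[2]], compute_background(empty, cfg), cfg)
  expect_equal(nrow(d0), 0)
  expect_error(detect_objects(m$frames[[1]], matrix(0, 5, 5), cfg), "dimensions")
})

test_that("right-to-left motion is never linked into a track", {
  # synthetic detection tables: one object moving left 5 px/frame
  dets <- lapply(1:6, function(f)
    data.frame(x = 100 - 5 * f, y = 20, x0 = 95 - 5 * f, x1 = 105 - 5 * f,
               y0 = 15, y1 = 25, area = 50))
  tracks <- link_tracks(dets, extraction_config())
  expect_true(all(vapply(tracks, nrow, integer(1)) == 1))
})

test_that("tracks partition detections and stay x-monotone", {
  m <- lane_movie(3)
  cfg <- extraction_config()
  bg <- compute_background(m, cfg)
  dets <- lapply(m$frames, detect_objects, background = bg, cfg = cfg)
  tracks <- link_tracks(dets, cfg)
  for (tr in tracks) expect_true(all(diff(tr$x) > 0))
  # partition: per frame, track rows use distinct detections
  for (f in seq_along(dets)) {
    used <- do.call(rbind, lapply(tracks, function(tr) tr[tr$frame == f, c("x", "y")]))
    if (!is.null(used) && nrow(used) > 1)
      expect_equal(nrow(used), nrow(unique(used)))
  }
})

test_that("overtaking cells in distinct lanes keep distinct identities", {
  m <- generate_movie(2, field_size = c(100, 240),
                      params = motion_params(noise_sd = 0),
                      speed_sampler = function(n) c(2, 5),
                      y_sampler = function(n) c(35, 65),
                      label_sampler = function(n) rep("tank_treading", n),
                      noise_sd = 0.01, stagger_frames = 5, seed = 4)
  seqs <- extract_sequences(m, extraction_config())
  expect_equal(length(seqs), 2)
  tracks <- attr(seqs, "tracks")
  ys <- vapply(tracks, function(tr) mean(tr$y), numeric(1))
  expect_equal(sort(round(ys)), c(35, 65), tolerance = 0.05)
})

test_that("cross-correlation refinement recovers exact integer shifts", {
  set.seed(7)
  big <- matrix(runif(60 * 60), 60, 60)
  a <- big[21:35, 21:35]
  for (shift in list(c(0, 0), c(3, -2), c(-4, 5))) {
    b <- big[21:35 + shift[2], 21:35 + shift[1]]
    got <- rbcmotion:::cpp_best_shift(a, b, 7)
    # the displacement recovered is the content motion from a to b
    expect_equal(got[1:2], -shift)
    expect_equal(best_shift_bruteforce(a, b, 7), -shift)
  }
  # identical crops: autocorrelation peaks at the origin
  expect_equal(rbcmotion:::cpp_best_shift(a, a, 7)[1:2], c(0, 0))
})

test_that("refined positions track a noisy translating cell within a pixel", {
  # tank-treading: constant projection, so frame-to-frame change is a pure
  # translation (the setting in which correlation positioning is exact)
  m <- generate_movie(1, field_size = c(100, 240),
                      params = motion_params(noise_sd = 0),
                      y_sampler = function(n) 50,
                      label_sampler = function(n) rep("tank_treading", n),
                      noise_sd = 0.02, stagger_frames = 5, seed = 21)
  cfg <- extraction_config()
  bg <- compute_background(m, cfg)
  dets <- lapply(m$frames, detect_objects, background = bg, cfg = cfg)
  tracks <- link_tracks(dets, cfg)
  tracks <- tracks[vapply(tracks, nrow, integer(1)) >= cfg$min_track_length]
  expect_equal(length(tracks), 1)
  ref <- refine_positions(tracks[[1]], m, cfg)
  gt <- m$tracks[[1]]
  common <- intersect(ref$frame, gt$frame)
  err <- abs(ref$x[match(common, ref$frame)] - gt$x[match(common, gt$frame)])
  # integer shifts anchored at rounded detections: ~1 px quantization,
  # no drift over the track
  expect_lt(mean(err), 1)
  expect_lt(max(err), 3)
})

test_that("short tracks are discarded and crops are normalized 31x31", {
  # a movie shorter than min_track_length leaves nothing
  m_short <- generate_movie(1, field_size = c(100, 240),
                            params = motion_params(noise_sd = 0),
                            speed_sampler = function(n) rep(4, n),
                            n_frames = 5, stagger_frames = 1, seed = 2)
  expect_length(extract_sequences(m_short, extraction_config()), 0)

  m <- lane_movie(3, seed = 8)
  seqs <- extract_sequences(m, extraction_config())
  expect_equal(length(seqs), 3)
  for (s in seqs) {
    expect_gte(length(s$frames), 6)
    expect_true(all(vapply(s$frames, function(f) all(dim(f) == c(31, 31)),
                           logical(1))))
    px <- unlist(s$frames)
    expect_gte(min(px), 0); expect_lte(max(px), 1)
    # per-sequence (not per-frame) rescaling: the full range is spanned
    expect_equal(min(px), 0); expect_equal(max(px), 1)
  }
})

test_that("extracted sequence spans match ground truth within one frame", {
  m <- lane_movie(3, seed = 8)
  seqs <- extract_sequences(m, extraction_config())
  tracks <- attr(seqs, "tracks")
  gt_spans <- t(vapply(m$tracks, function(tr) range(tr$frame), numeric(2)))
  got_spans <- t(vapply(tracks, function(tr) range(tr$frame), numeric(2)))
  gt_spans <- gt_spans[order(gt_spans[, 1]), , drop = FALSE]
  got_spans <- got_spans[order(got_spans[, 1]), , drop = FALSE]
  expect_true(all(abs(gt_spans - got_spans) <= 1))
})
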