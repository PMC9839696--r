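# Trajectory extraction: full-field movie -> per-cell 31x31 sequences.
#
# Median background over stratified-random frames, background subtraction,
# local-variance detection with an automatic (Otsu) threshold, greedy
# left-to-right tracking under a steady-speed assumption, cross-correlation
# positioning, and fixed-size cropping with per-sequence intensity rescaling.

#' Extraction configuration
#'
#' @param n_background_frames number of frames entering the median background
#'   (stratified random: one seeded-random frame per equal movie bin; all
#'   frames if the movie is shorter).
#' @param variance_kernel_px local-variance filter window (odd).
#' @param detection_threshold `"auto"` (Otsu on the variance image) or an
#'   absolute numeric threshold.
#' @param min_snr with `"auto"` thresholding, the threshold is floored at
#'   `min_snr` times the median of the variance image (which cells, being
#'   sparse, leave at the noise level); this keeps pure-noise frames empty.
#' @param min_area_px connected components smaller than this are discarded.
#' @param min_track_length tracks shorter than this are discarded (sequences
#'   of fewer frames indicate a detection problem).
#' @param crop_size_px side of the square per-cell crop (odd).
#' @param max_speed_deviation steady-speed gate: a link is accepted when its
#'   x-step deviates from the track's running mean by at most this fraction
#'   (an absolute slack of 2 px covers pixel quantization).
#' @param max_initial_step_px largest x-step allowed for a track's first link,
#'   before a running speed exists.
#' @param y_gate_px largest |y| displacement allowed between linked
#'   detections (motion is linear along x).
#' @param exclude_border drop detections whose bounding box touches the field
#'   border (partially visible cells).
#' @param drop_overlap_frames drop detections whose bounding boxes overlap
#'   another detection in the same frame (momentary cell overlap during
#'   overtaking); affected frames simply do not enter any track.
#' @param seed integer seed (background frame sampling).
#' @return an object of class `extraction_config`.
#' @export
extraction_config <- function(n_background_frames = 100, variance_kernel_px = 5,
                              detection_threshold = "auto", min_snr = 8,
                              min_area_px = 20,
                              min_track_length = 6, crop_size_px = 31,
                              max_speed_deviation = 0.25,
                              max_initial_step_px = 15, y_gate_px = 6,
                              exclude_border = TRUE, drop_overlap_frames = TRUE,
                              seed = 1) {
  stopifnot(n_background_frames >= 1, min_track_length >= 1,
            crop_size_px >= 3, crop_size_px %% 2 == 1,
            variance_kernel_px %% 2 == 1)
  structure(as.list(environment()), class = "extraction_config")
}

#' Median background of a movie
#'
#' Pixel-wise median over `n_background_frames` frames chosen by stratified
#' sampling: the movie is divided into that many equal bins and one
#' seeded-random frame is taken per bin. Movies with fewer frames use all of
#' them. With cells sparse in the field, the median suppresses every moving
#' object.
#'
#' @param movie an [rbc_movie].
#' @param cfg an [extraction_config].
#' @return a background frame (matrix).
#' @export
compute_background <- function(movie, cfg = extraction_config()) {
  stopifnot(inherits(movie, "rbc_movie"))
  nf <- length(movie$frames)
  if (nf == 0) stop("empty movie")
  nb <- min(cfg$n_background_frames, nf)
  if (nf <= cfg$n_background_frames) {
    idx <- seq_len(nf)
  } else {
    set.seed(cfg$seed)
    edges <- floor(seq(0, nf, length.out = nb + 1))
    idx <- vapply(seq_len(nb), function(i)
      if (edges[i] + 1 >= edges[i + 1]) edges[i + 1]
      else sample(seq(edges[i] + 1, edges[i + 1]), 1), numeric(1))
  }
  d <- dim(movie$frames[[1]])
  M <- vapply(movie$frames[idx], as.vector, numeric(d[1] * d[2]))
  matrix(apply(M, 1, median), d[1], d[2])
}

# Local variance in a k x k window (replicated boundary).
local_variance <- function(x, k) {
  box <- matrix(1 / (k * k), k, k)
  m <- EBImage::filter2(x, box, boundary = "replicate")
  m2 <- EBImage::filter2(x * x, box, boundary = "replicate")
  pmax(m2 - m * m, 0)
}

#' Detect objects in one frame
#'
#' The background is subtracted, a local-variance filter applied, the result
#' thresholded (Otsu by default) and connected components extracted;
#' components below the minimum area — and, optionally, components touching
#' the border — are discarded.
#'
#' @param frame,background matrices of identical dimensions.
#' @param cfg an [extraction_config].
#' @return data.frame with one row per detection: centroid `x`, `y`
#'   (column / row pixel coordinates), bounding box `x0`, `x1`, `y0`, `y1`,
#'   `area`.
#' @export
detect_objects <- function(frame, background, cfg = extraction_config()) {
  if (!identical(dim(frame), dim(background)))
    stop("frame and background must share dimensions")
  D <- abs(frame - background)
  V <- local_variance(D, cfg$variance_kernel_px)
  vmax <- max(V)
  empty <- data.frame(x = numeric(0), y = numeric(0), x0 = numeric(0),
                      x1 = numeric(0), y0 = numeric(0), y1 = numeric(0),
                      area = numeric(0))
  if (vmax <= 0) return(empty)
  thr <- if (identical(cfg$detection_threshold, "auto"))
    max(EBImage::otsu(V / vmax, range = c(0, 1)) * vmax,
        cfg$min_snr * median(V)) else cfg$detection_threshold
  mask <- V > thr
  # close + fill: the variance response is strongest at object edges, so a
  # single cell can leave disconnected lobes (e.g. the two rims of an
  # edge-on flipping cell); closing merges them before labelling
  mask <- EBImage::closing(mask, EBImage::makeBrush(cfg$variance_kernel_px,
                                                    "box"))
  mask <- EBImage::fillHull(mask)
  lab <- EBImage::bwlabel(mask)
  nl <- max(lab)
  if (nl == 0) return(empty)
  H <- nrow(frame); W <- ncol(frame)
  rows <- lapply(seq_len(nl), function(i) {
    px <- which(lab == i, arr.ind = TRUE)
    if (nrow(px) < cfg$min_area_px) return(NULL)
    y0 <- min(px[, 1]); y1 <- max(px[, 1])
    x0 <- min(px[, 2]); x1 <- max(px[, 2])
    if (cfg$exclude_border && (x0 <= 1 || x1 >= W || y0 <= 1 || y1 >= H))
      return(NULL)
    data.frame(x = mean(px[, 2]), y = mean(px[, 1]),
               x0 = x0, x1 = x1, y0 = y0, y1 = y1, area = nrow(px))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$x), , drop = FALSE]
}

boxes_overlap <- function(a, b)
  a["x0"] <= b["x1"] && b["x0"] <= a["x1"] && a["y0"] <= b["y1"] && b["y0"] <= a["y1"]

drop_overlapping <- function(dets) {
  n <- nrow(dets)
  if (n < 2) return(dets)
  bad <- rep(FALSE, n)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (boxes_overlap(unlist(dets[i, ]), unlist(dets[j, ])))
      bad[i] <- bad[j] <- TRUE
  }
  dets[!bad, , drop = FALSE]
}

#' Link per-frame detections into tracks
#'
#' Greedy frame-to-frame association under the acquisition convention:
#' objects only move from left to right along x with a steady speed. A
#' candidate link must move forward (`dx > 0`), stay within the y gate, and
#' — once a track has a running mean x-step — deviate from it by at most
#' `max_speed_deviation` (the first link is exempt, bounded by
#' `max_initial_step_px`). Unmatched detections start new tracks; no
#' detection is shared between tracks.
#'
#' @param detections list (one per frame) of detection data.frames from
#'   [detect_objects].
#' @param cfg an [extraction_config].
#' @return list of track data.frames (columns `frame`, `x`, `y`, `x0`, `x1`,
#'   `y0`, `y1`).
#' @export
link_tracks <- function(detections, cfg = extraction_config()) {
  stopifnot(length(detections) >= 1)
  tracks <- list()
  active <- integer(0)  # indices into tracks
  for (f in seq_along(detections)) {
    dets <- detections[[f]]
    if (cfg$drop_overlap_frames && nrow(dets) > 1) dets <- drop_overlapping(dets)
    used <- rep(FALSE, nrow(dets))
    still_active <- integer(0)
    # process active tracks rightmost-first
    ord <- active[order(-vapply(active, function(i) tail(tracks[[i]]$x, 1),
                                numeric(1)))]
    for (ti in ord) {
      tr <- tracks[[ti]]
      lastx <- tail(tr$x, 1); lasty <- tail(tr$y, 1)
      dx <- dets$x - lastx
      ok <- !used & dx > 0 & abs(dets$y - lasty) <= cfg$y_gate_px
      if (nrow(tr) >= 2) {
        mdx <- mean(diff(tr$x))
        tol <- max(cfg$max_speed_deviation * mdx, 2)
        ok <- ok & abs(dx - mdx) <= tol
        pick <- which(ok)[order(abs(dx[ok] - mdx))][1]
      } else {
        ok <- ok & dx <= cfg$max_initial_step_px
        pick <- which(ok)[order(dx[ok])][1]
      }
      if (!is.na(pick)) {
        tracks[[ti]] <- rbind(tr, cbind(frame = f, dets[pick, ]))
        used[pick] <- TRUE
        still_active <- c(still_active, ti)
      }
    }
    for (d in which(!used)) {
      tracks[[length(tracks) + 1]] <- cbind(frame = f, dets[d, ])
      still_active <- c(still_active, length(tracks))
    }
    active <- still_active
  }
  lapply(tracks, function(t) { rownames(t) <- NULL; t })
}

clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)

crop_at <- function(frame, cx, cy, size) {
  half <- (size - 1) / 2
  H <- nrow(frame); W <- ncol(frame)
  cx <- clamp(round(cx), half + 1, W - half)
  cy <- clamp(round(cy), half + 1, H - half)
  frame[(cy - half):(cy + half), (cx - half):(cx + half)]
}

#' Refine track positions by cross-correlation of sequential frames
#'
#' Starting from the first detection, each subsequent position is the
#' previous one displaced by the argmax of the normalized cross-correlation
#' between background-subtracted crops of consecutive frames taken at the
#' previous position, with the shift limited to half the crop size (without
#' background removal the static illumination field would pin the
#' correlation peak at zero shift). Positions whose crop would leave the
#' frame are clamped to the border and flagged.
#'
#' @param track a track data.frame from [link_tracks] (length >= 2).
#' @param movie the source [rbc_movie].
#' @param cfg an [extraction_config].
#' @param background optional precomputed background; computed from the
#'   movie otherwise.
#' @return the track with refined `x`, `y` and a logical `clamped` column.
#' @export
refine_positions <- function(track, movie, cfg = extraction_config(),
                             background = NULL) {
  stopifnot(nrow(track) >= 2)
  background <- background %||% compute_background(movie, cfg)
  half <- (cfg$crop_size_px - 1) / 2
  H <- nrow(movie$frames[[1]]); W <- ncol(movie$frames[[1]])
  track$clamped <- FALSE
  det <- track[, c("x", "y")]  # detected centroids: the crop anchors
  for (i in seq(2, nrow(track))) {
    # both crops sit at the previous *detected* centroid, so every step is
    # anchored to an absolute position and shift errors cannot accumulate
    cx <- det$x[i - 1]; cy <- det$y[i - 1]
    a <- crop_at(movie$frames[[track$frame[i - 1]]] - background, cx, cy,
                 cfg$crop_size_px)
    b <- crop_at(movie$frames[[track$frame[i]]] - background, cx, cy,
                 cfg$crop_size_px)
    sh <- cpp_best_shift(a, b, half)
    nx <- clamp(round(cx), half + 1, W - half) + sh[1]
    ny <- clamp(round(cy), half + 1, H - half) + sh[2]
    cl <- nx < half + 1 || nx > W - half || ny < half + 1 || ny > H - half
    track$x[i] <- clamp(nx, half + 1, W - half)
    track$y[i] <- clamp(ny, half + 1, H - half)
    track$clamped[i] <- cl
  }
  track
}

#' Extract per-cell sequences from a movie
#'
#' Runs the full pipeline: median background, per-frame detection, greedy
#' left-to-right linking, discarding of tracks shorter than
#' `min_track_length`, cross-correlation position refinement, and per-frame
#' cropping to `crop_size_px` (detections larger than the crop are resized
#' bilinearly). Intensities are min-max rescaled to `[0, 1]` once per
#' sequence — not per frame, which would erase the brightness dynamics of
#' flipping cells.
#'
#' @param movie an [rbc_movie].
#' @param cfg an [extraction_config].
#' @param acquisition_id id stamped on the extracted sequences.
#' @return list of [rbc_sequence]s; the refined tracks are attached as
#'   attribute `"tracks"`.
#' @export
extract_sequences <- function(movie, cfg = extraction_config(),
                              acquisition_id = "acq1") {
  stopifnot(inherits(movie, "rbc_movie"))
  bg <- compute_background(movie, cfg)
  dets <- lapply(movie$frames, detect_objects, background = bg, cfg = cfg)
  tracks <- link_tracks(dets, cfg)
  tracks <- tracks[vapply(tracks, nrow, integer(1)) >= cfg$min_track_length]
  tracks <- lapply(tracks, refine_positions, movie = movie, cfg = cfg,
                   background = bg)
  seqs <- vector("list", length(tracks))
  for (i in seq_along(tracks)) {
    tr <- tracks[[i]]
    frames <- lapply(seq_len(nrow(tr)), function(j) {
      bw <- max(tr$x1[j] - tr$x0[j], tr$y1[j] - tr$y0[j]) + 1
      if (bw > cfg$crop_size_px) {
        big <- crop_at(movie$frames[[tr$frame[j]]], tr$x[j], tr$y[j],
                       2 * floor(bw / 2) + 1)
        as.matrix(EBImage::resize(big, w = cfg$crop_size_px,
                                  h = cfg$crop_size_px))
      } else {
        crop_at(movie$frames[[tr$frame[j]]], tr$x[j], tr$y[j], cfg$crop_size_px)
      }
    })
    mn <- min(unlist(frames)); mx <- max(unlist(frames))
    if (mx > mn) frames <- lapply(frames, function(f) (f - mn) / (mx - mn))
    seqs[[i]] <- rbc_sequence(frames, acquisition_id = acquisition_id,
                              sequence_id = sprintf("track%03d", i))
  }
  structure(seqs, tracks = tracks)
}
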