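# Synthetic videomicroscopy generator.
#
# Emulates the statistical structure of RBC acquisitions in shear flow near a
# wall, seen in top view: tank-treading cells keep a near-constant elliptical
# projection (orientation oscillating around a mean), flipping cells show a
# rod<->disc oscillation of the apparent minor axis, and unreliable sequences
# carry one of three artifact modes (defocus blur, a second overlapping cell,
# a partially cropped cell). Cells are drawn as anti-aliased filled ellipses
# with a soft Gaussian-profile edge on a darker background: downstream stages
# only need the shape-over-time structure, not bright-field pixel statistics.

#' Motion and appearance parameters for the synthetic generator
#'
#' @param cell_radius_px semi-major axis of the cell projection, pixels (> 0).
#' @param aspect_ratio minor/major axis ratio of the resting projection, in (0, 1].
#' @param flip_period_frames tumbling period in frames (> 2); flipping only.
#' @param orientation_osc_amplitude_deg amplitude of the orientation
#'   oscillation around the mean, degrees; tank-treading only.
#' @param orientation_osc_period_frames period of that oscillation, frames.
#' @param aspect_ratio_min floor on the apparent aspect ratio of a flipping
#'   cell (a disc seen edge-on still has thickness).
#' @param noise_sd additive Gaussian pixel noise standard deviation.
#' @param artifact_mode one of `"none"`, `"defocus_blur"`,
#'   `"overlap_second_cell"`, `"partial_cell"`. Anything other than `"none"`
#'   implies the `unreliable` label.
#' @param defocus_sigma Gaussian blur sigma (pixels) for the defocus artifact.
#' @param background_level,contrast background intensity and cell-to-background
#'   contrast, both in `[0, 1]` units.
#' @param edge_softness_px width of the soft cell edge, pixels.
#' @param phase initial motion phase, radians (drawn at random by
#'   [generate_sequence]).
#' @param seed optional integer seed consumed by generators when no explicit
#'   seed is passed.
#' @return an object of class `motion_params`.
#' @export
motion_params <- function(cell_radius_px = 6, aspect_ratio = 0.75,
                          flip_period_frames = 12,
                          orientation_osc_amplitude_deg = 5,
                          orientation_osc_period_frames = 20,
                          aspect_ratio_min = 0.15,
                          noise_sd = 0.02, artifact_mode = "none",
                          defocus_sigma = 3, background_level = 0.35,
                          contrast = 0.4, edge_softness_px = 0.8,
                          phase = 0, seed = NULL) {
  stopifnot(cell_radius_px > 0, aspect_ratio > 0, aspect_ratio <= 1,
            flip_period_frames > 2, orientation_osc_amplitude_deg >= 0,
            noise_sd >= 0, aspect_ratio_min > 0)
  artifact_mode <- match.arg(artifact_mode,
    c("none", "defocus_blur", "overlap_second_cell", "partial_cell"))
  structure(as.list(environment()), class = "motion_params")
}

# Additively draw a soft-edged ellipse: rho is the normalized elliptical
# radius, the edge profile a logistic ramp of width edge_softness_px.
draw_ellipse <- function(img, cx, cy, a, b, theta, contrast, softness) {
  h <- nrow(img); w <- ncol(img)
  X <- matrix(rep(seq_len(w), each = h), h, w)  # column = x (flow axis)
  Y <- matrix(rep(seq_len(h), w), h, w)         # row = y
  ct <- cos(theta); st <- sin(theta)
  xr <- (X - cx) * ct + (Y - cy) * st
  yr <- -(X - cx) * st + (Y - cy) * ct
  rho <- sqrt((xr / a)^2 + (yr / b)^2)
  img + contrast * plogis((1 - rho) * min(a, b) / softness)
}

# Apparent semi-axes and orientation at frame t for a given motion regime.
cell_pose <- function(label, p, t) {
  if (label == "flipping") {
    # |cos| brings the disc edge-on once per flip_period_frames, so the
    # apparent-width time series has period exactly flip_period_frames
    ax <- p$cell_radius_px *
      max(p$aspect_ratio_min, abs(cos(pi * t / p$flip_period_frames + p$phase)))
    list(a = ax, b = p$cell_radius_px, theta = 0)
  } else {
    amp <- p$orientation_osc_amplitude_deg * pi / 180
    theta <- amp * sin(2 * pi * t / p$orientation_osc_period_frames + p$phase)
    list(a = p$cell_radius_px, b = p$cell_radius_px * p$aspect_ratio, theta = theta)
  }
}

#' Render one synthetic cell frame
#'
#' Draws the projection of a cell at frame index `t` of its motion cycle on a
#' uniform background. Tank-treading cells keep constant axes with an
#' orientation oscillating around the flow direction; flipping cells have an
#' apparent minor axis `radius * max(aspect_ratio_min, |cos(pi*t/P)|)` with
#' `P = flip_period_frames` (a tumbling disc seen in top view, edge-on once
#' per period). For the `unreliable` label the
#' configured artifact is applied: Gaussian defocus blur, a second cell
#' entering the crop over time, or a cell clipped by the crop border.
#' Additive Gaussian noise of sd `noise_sd` is drawn from the current RNG
#' stream and the result is clipped to `[0, 1]`.
#'
#' @param label one of [MOTION_LABELS].
#' @param params a [motion_params] object.
#' @param t frame index (0-based) within the motion cycle.
#' @param size frame side length in pixels.
#' @return a `size x size` numeric matrix in `[0, 1]`.
#' @export
render_cell_frame <- function(label, params, t, size = 31) {
  label <- match.arg(label, MOTION_LABELS)
  p <- params
  stopifnot(t >= 0)
  c0 <- (size + 1) / 2
  img <- matrix(p$background_level, size, size)
  if (label != "unreliable") {
    pose <- cell_pose(label, p, t)
    img <- draw_ellipse(img, c0, c0, pose$a, pose$b, pose$theta,
                        p$contrast, p$edge_softness_px)
  } else {
    base <- cell_pose("tank_treading", p, t)
    switch(p$artifact_mode,
      defocus_blur = {
        img <- draw_ellipse(img, c0, c0, base$a, base$b, base$theta,
                            p$contrast, p$edge_softness_px)
        img <- EBImage::gblur(img, sigma = p$defocus_sigma, boundary = "replicate")
      },
      overlap_second_cell = {
        img <- draw_ellipse(img, c0, c0, base$a, base$b, base$theta,
                            p$contrast, p$edge_softness_px)
        # second cell drifts through the crop over the sequence
        cx2 <- -p$cell_radius_px + 1.5 * t + p$phase / (2 * pi) * size
        img <- draw_ellipse(img, cx2, c0 + p$cell_radius_px * 0.7,
                            base$a, base$b, 0, p$contrast, p$edge_softness_px)
      },
      partial_cell = {
        # cell center sits near the crop border; most of the body is clipped
        img <- draw_ellipse(img, size - 1, c0, base$a, base$b, base$theta,
                            p$contrast, p$edge_softness_px)
      },
      none = stop("artifact_mode 'none' is inconsistent with the unreliable label"),
      stop("unknown artifact_mode: ", p$artifact_mode)
    )
  }
  if (p$noise_sd > 0) img <- img + matrix(rnorm(size * size, 0, p$noise_sd), size, size)
  pmin(pmax(img, 0), 1)
}

#' Generate one labeled synthetic sequence
#'
#' Renders `length` frames at consecutive frame indices with a random initial
#' motion phase drawn from the seeded generator.
#'
#' @inheritParams render_cell_frame
#' @param length number of frames (>= 1).
#' @param seed integer seed; defaults to `params$seed`.
#' @param size frame side length in pixels.
#' @param sequence_id,acquisition_id identifiers attached to the sequence.
#' @return an [rbc_sequence] with the label attached.
#' @export
generate_sequence <- function(label, length, params = motion_params(),
                              seed = params$seed, size = 31,
                              sequence_id = "seq1", acquisition_id = "acq1") {
  stopifnot(length >= 1)
  label <- match.arg(label, MOTION_LABELS)
  if (!is.null(seed)) set.seed(seed)
  params$phase <- runif(1, 0, 2 * pi)
  if (label == "unreliable" && params$artifact_mode == "none")
    params$artifact_mode <- sample(c("defocus_blur", "overlap_second_cell",
                                     "partial_cell"), 1,
                                   prob = c(0.4, 0.3, 0.3))
  frames <- lapply(seq_len(length) - 1L,
                   function(t) render_cell_frame(label, params, t, size))
  rbc_sequence(frames, label = label, acquisition_id = acquisition_id,
               sequence_id = sequence_id)
}

# Log-uniform sequence-length sampler: mean length below 40, rare long
# sequences. Reliable classes span [6, 100]; unreliable ones may reach 120.
sample_lengths <- function(n, lo = 6, hi = 100) {
  if (n == 0) return(integer(0))
  pmin(hi, pmax(lo, round(exp(runif(n, log(lo), log(hi))))))
}

#' Generate a labeled synthetic dataset
#'
#' Draws per-class sequence counts with the length distribution and artifact
#' mixture of the clinical-like regime: log-uniform lengths on `[6, 100]`
#' (unreliable sequences up to 120), artifact mixture 40% defocus / 30%
#' overlap / 30% partial, acquisition ids assigned round-robin.
#'
#' @param n_tank,n_flip,n_unreliable per-class sequence counts (>= 0, not all 0).
#' @param params baseline [motion_params]; per-sequence radius, aspect ratio
#'   and flip period are jittered around it.
#' @param n_acquisitions number of synthetic acquisitions to spread ids over.
#' @param seed integer seed controlling every random draw.
#' @param length_sampler optional function(n) returning reliable-class lengths
#'   (>= 6); defaults to the log-uniform sampler.
#' @param size frame side length in pixels.
#' @return an [rbc_dataset] with exactly the requested class histogram.
#' @export
generate_dataset <- function(n_tank, n_flip, n_unreliable,
                             params = motion_params(), n_acquisitions = 4,
                             seed = 1, length_sampler = NULL, size = 31) {
  stopifnot(n_tank >= 0, n_flip >= 0, n_unreliable >= 0)
  n <- n_tank + n_flip + n_unreliable
  if (n == 0) stop("at least one sequence must be requested")
  set.seed(seed)
  labels <- rep(c("tank_treading", "flipping", "unreliable"),
                c(n_tank, n_flip, n_unreliable))
  lengths <- integer(n)
  rel <- labels != "unreliable"
  sampler <- length_sampler %||% sample_lengths
  lengths[rel] <- sampler(sum(rel))
  lengths[!rel] <- sample_lengths(sum(!rel), hi = 120)
  stopifnot(all(lengths >= 6))
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  acq <- paste0("acq", (seq_len(n) - 1L) %% n_acquisitions + 1L)
  radius <- runif(n, 0.85, 1.15) * params$cell_radius_px
  aspect <- pmin(1, runif(n, 0.9, 1.1) * params$aspect_ratio)
  period <- runif(n, 0.75, 1.35) * params$flip_period_frames
  seqs <- vector("list", n)
  for (i in seq_len(n)) {
    p <- params
    p$cell_radius_px <- radius[i]
    p$aspect_ratio <- aspect[i]
    p$flip_period_frames <- period[i]
    seqs[[i]] <- generate_sequence(labels[i], lengths[i], p, seed = seeds[i],
                                   size = size,
                                   sequence_id = sprintf("seq%05d", i),
                                   acquisition_id = acq[i])
  }
  rbc_dataset(seqs)
}

#' Generate a full-field acquisition movie with ground truth
#'
#' Cells enter at the left edge and cross the field left to right, each with
#' a constant per-cell speed (cells at different distances from the wall move
#' at different speeds, so overtaking is possible). The background is a
#' smooth illumination field plus per-frame pixel noise. Ground-truth tracks
#' record, for every frame in which a cell's full extent lies inside the
#' field, its centroid and bounding box.
#'
#' @param n_cells number of cells (>= 0).
#' @param field_size `c(height, width)` of the field, pixels.
#' @param speed_sampler function(n) returning positive per-cell speeds in
#'   px/frame; default uniform on `[2, 5]`.
#' @param y_sampler function(n) returning per-cell row positions; default
#'   uniform over the field with a margin. Distinct lanes guarantee cells
#'   never overlap.
#' @param label_sampler function(n) returning motion labels; default
#'   tank-treading/flipping mix (70/30).
#' @param params baseline [motion_params] for cell appearance.
#' @param n_frames number of movie frames; by default just enough for every
#'   cell to cross.
#' @param fps frame rate, frames per second.
#' @param noise_sd background pixel noise sd.
#' @param stagger_frames entry times are spread uniformly over this many frames.
#' @param seed integer seed.
#' @return an [rbc_movie] carrying ground-truth tracks and labels.
#' @export
generate_movie <- function(n_cells, field_size = c(120, 300),
                           speed_sampler = NULL, label_sampler = NULL,
                           y_sampler = NULL, params = motion_params(),
                           n_frames = NULL, fps = 60, noise_sd = 0.01,
                           stagger_frames = 30, seed = 1) {
  stopifnot(n_cells >= 0, length(field_size) == 2)
  H <- field_size[1]; W <- field_size[2]
  r <- params$cell_radius_px
  if (2 * r + 2 >= min(H, W)) stop("cell larger than the field")
  set.seed(seed)
  speeds <- if (n_cells > 0)
    (speed_sampler %||% function(n) runif(n, 2, 5))(n_cells) else numeric(0)
  stopifnot(all(speeds > 0))
  labels <- if (n_cells > 0)
    (label_sampler %||% function(n)
      sample(c("tank_treading", "flipping"), n, TRUE, prob = c(0.7, 0.3)))(n_cells)
    else character(0)
  entry <- if (n_cells > 0) sort(runif(n_cells, 0, stagger_frames)) else numeric(0)
  ys <- if (n_cells > 0) {
    (y_sampler %||% function(n) runif(n, 2 * r + 2, H - 2 * r - 2))(n_cells)
  } else numeric(0)
  phases <- if (n_cells > 0) runif(n_cells, 0, 2 * pi) else numeric(0)
  if (is.null(n_frames)) {
    n_frames <- if (n_cells > 0)
      ceiling(max(entry + (W + 4 * r) / speeds)) + 2L else 30L
  }
  # smooth illumination: gentle horizontal gradient plus a wide vignette
  xg <- matrix(rep(seq_len(W) / W, each = H), H, W)
  yg <- matrix(rep(seq_len(H) / H, W), H, W)
  bg <- params$background_level + 0.06 * xg - 0.04 * (yg - 0.5)^2

  cell_ids <- if (n_cells > 0) sprintf("cell%02d", seq_len(n_cells)) else character(0)
  tracks <- setNames(vector("list", n_cells), cell_ids)
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    t <- f - 1L
    img <- bg
    for (i in seq_len(n_cells)) {
      x <- -2 * r + speeds[i] * (t - entry[i])
      if (x < -2 * r || x > W + 2 * r) next
      p <- params; p$phase <- phases[i]
      pose <- cell_pose(labels[i], p, t)
      img <- draw_ellipse(img, x, ys[i], pose$a, pose$b, pose$theta,
                          p$contrast, p$edge_softness_px)
      ext <- max(pose$a * abs(cos(pose$theta)), pose$b) + 1
      box <- c(x0 = x - ext, x1 = x + ext, y0 = ys[i] - pose$b - 1,
               y1 = ys[i] + pose$b + 1)
      if (box["x0"] >= 1 && box["x1"] <= W && box["y0"] >= 1 && box["y1"] <= H) {
        tracks[[i]] <- rbind(tracks[[i]],
          data.frame(frame = f, x = x, y = ys[i], x0 = box[["x0"]],
                     x1 = box[["x1"]], y0 = box[["y0"]], y1 = box[["y1"]]))
      }
    }
    if (noise_sd > 0) img <- img + matrix(rnorm(H * W, 0, noise_sd), H, W)
    frames[[f]] <- pmin(pmax(img, 0), 1)
  }
  keep <- !vapply(tracks, is.null, logical(1))
  rbc_movie(frames, fps = fps, tracks = tracks[keep],
            labels = setNames(labels, cell_ids)[keep])
}

#' Apparent cell width along the flow axis
#'
#' Thresholds a frame at the midpoint of its intensity range and returns the
#' x-extent (number of columns spanned) of above-threshold pixels. The
#' time series of this width separates the motion regimes: near-constant for
#' tank-treading, strongly oscillating for flipping.
#'
#' @param frame a grayscale matrix.
#' @param threshold optional absolute threshold; default midpoint of range.
#' @return the width in pixels (0 if nothing is above threshold).
#' @export
measure_apparent_width <- function(frame, threshold = NULL) {
  thr <- threshold %||% ((max(frame) + min(frame)) / 2)
  cols <- which(apply(frame > thr, 2, any))
  if (!length(cols)) return(0L)
  as.integer(max(cols) - min(cols) + 1L)
}
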