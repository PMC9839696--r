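#' @useDynLib rbcmotion, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif median plogis setNames
#' @importFrom utils head tail read.csv write.csv
NULL

#' Motion classes
#'
#' The three labels a per-cell sequence can carry: `tank_treading` (highly
#' deformable cell, near-constant projection), `flipping` (poorly deformable
#' cell tumbling like a coin, periodically varying projection) and
#' `unreliable` (sequence unusable for motion determination: defocus,
#' overlapping cells, partial cell).
#'
#' @export
MOTION_LABELS <- c("tank_treading", "flipping", "unreliable")

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_frame <- function(px) {
  stopifnot(is.matrix(px), nrow(px) >= 1, ncol(px) >= 1)
  if (!all(is.finite(px)) || min(px) < 0 || max(px) > 1)
    stop("frame pixels must be finite and within [0, 1]")
  invisible(px)
}

#' Per-cell frame sequence
#'
#' The atom both classifiers consume: an ordered list of equally sized
#' grayscale frames (matrices with values in `[0, 1]`) for one cell
#' trajectory, with an optional motion label and acquisition id.
#'
#' @param frames list of numeric matrices, all the same size, values in `[0, 1]`.
#' @param label optional motion label, one of [MOTION_LABELS].
#' @param acquisition_id optional acquisition identifier.
#' @param sequence_id sequence identifier.
#' @return an object of class `rbc_sequence`.
#' @export
rbc_sequence <- function(frames, label = NULL, acquisition_id = NA_character_,
                         sequence_id = NA_character_) {
  stopifnot(is.list(frames), length(frames) >= 1)
  d <- dim(frames[[1]])
  for (f in frames) {
    assert_frame(f)
    if (!identical(dim(f), d)) stop("all frames in a sequence must share dimensions")
  }
  if (!is.null(label)) label <- match.arg(label, MOTION_LABELS)
  structure(list(frames = frames, label = label,
                 acquisition_id = acquisition_id, sequence_id = sequence_id),
            class = "rbc_sequence")
}

#' @export
length.rbc_sequence <- function(x) length(x$frames)

#' @export
print.rbc_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<rbc_sequence %s: %d frames of %dx%d, label=%s, acquisition=%s>\n",
              x$sequence_id, length(x$frames), d[1], d[2],
              x$label %||% "<none>", x$acquisition_id))
  invisible(x)
}

#' Labeled sequence dataset
#'
#' A collection of [rbc_sequence] objects with a manifest
#' (`sequence_id`, `acquisition_id`, `label`, `n_frames`) and an optional
#' acquisition-level split assignment. The manifest rows parallel the
#' sequence list.
#'
#' @param sequences list of [rbc_sequence] objects.
#' @param split optional named character vector mapping acquisition id to
#'   one of `"train"`, `"validation"`, `"test"`.
#' @return an object of class `rbc_dataset`.
#' @export
rbc_dataset <- function(sequences, split = NULL) {
  stopifnot(is.list(sequences), length(sequences) >= 1)
  manifest <- data.frame(
    sequence_id = vapply(sequences, function(s) s$sequence_id, character(1)),
    acquisition_id = vapply(sequences, function(s) s$acquisition_id, character(1)),
    label = vapply(sequences, function(s) s$label %||% NA_character_, character(1)),
    n_frames = vapply(sequences, function(s) length(s$frames), integer(1)),
    stringsAsFactors = FALSE)
  structure(list(sequences = sequences, manifest = manifest, split = split),
            class = "rbc_dataset")
}

#' @export
length.rbc_dataset <- function(x) length(x$sequences)

#' @export
print.rbc_dataset <- function(x, ...) {
  cat(sprintf("<rbc_dataset: %d sequences, %d acquisitions>\n",
              length(x$sequences), length(unique(x$manifest$acquisition_id))))
  print(table(x$manifest$label))
  invisible(x)
}

#' Subset a dataset by sequence index
#'
#' @param ds an [rbc_dataset].
#' @param idx integer or logical index over sequences.
#' @return the subset, as an `rbc_dataset` keeping the split map.
#' @export
dataset_subset <- function(ds, idx) {
  stopifnot(inherits(ds, "rbc_dataset"))
  out <- rbc_dataset(ds$sequences[idx], split = ds$split)
  out
}

#' Sequences belonging to one split
#'
#' @param ds an [rbc_dataset] whose `split` maps acquisition ids to splits.
#' @param which one of `"train"`, `"validation"`, `"test"`.
#' @export
dataset_split <- function(ds, which = c("train", "validation", "test")) {
  which <- match.arg(which)
  if (is.null(ds$split)) stop("dataset has no split assignment; see split_by_acquisition()")
  acqs <- names(ds$split)[ds$split == which]
  dataset_subset(ds, ds$manifest$acquisition_id %in% acqs)
}

#' Full-field acquisition movie
#'
#' @param frames ordered list of full-field frames (matrices in `[0, 1]`).
#' @param fps acquisition frame rate (frames per second), positive.
#' @param tracks optional list of ground-truth tracks (synthetic movies): each
#'   a data.frame with columns `frame`, `x`, `y`, `x0`, `x1`, `y0`, `y1` and a
#'   `cell_id` attribute; x is the column (flow) axis, y the row axis.
#' @param labels optional named character vector, cell id to motion label.
#' @return an object of class `rbc_movie`.
#' @export
rbc_movie <- function(frames, fps = 60, tracks = NULL, labels = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1, fps > 0)
  d <- dim(frames[[1]])
  for (f in frames) {
    assert_frame(f)
    if (!identical(dim(f), d)) stop("all movie frames must share dimensions")
  }
  structure(list(frames = frames, fps = fps, tracks = tracks, labels = labels),
            class = "rbc_movie")
}

#' @export
print.rbc_movie <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<rbc_movie: %d frames of %dx%d @ %g fps, %d ground-truth tracks>\n",
              length(x$frames), d[1], d[2], x$fps, length(x$tracks %||% list())))
  invisible(x)
}
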