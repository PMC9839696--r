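# Disk layout: one multi-page TIFF per sequence plus a manifest CSV
# (sequence_id, acquisition_id, label, n_frames, path); movies as a single
# multi-page TIFF with ground-truth tracks and labels CSVs alongside.

#' Write a dataset as per-sequence TIFF stacks with a manifest CSV
#'
#' @param dataset an [rbc_dataset].
#' @param dir output directory (created if needed).
#' @param bits TIFF bit depth (8 or 16).
#' @return the manifest path, invisibly.
#' @export
write_sequences <- function(dataset, dir, bits = 16) {
  stopifnot(inherits(dataset, "rbc_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- dataset$manifest
  man$path <- file.path(dir, paste0(man$sequence_id, ".tif"))
  for (i in seq_along(dataset$sequences))
    tiff::writeTIFF(dataset$sequences[[i]]$frames, man$path[i],
                    bits.per.sample = bits, compression = "none")
  manifest_path <- file.path(dir, "manifest.csv")
  write.csv(man, manifest_path, row.names = FALSE)
  invisible(manifest_path)
}

#' Read a dataset written by [write_sequences]
#'
#' @param manifest_path path to the manifest CSV; TIFF paths inside are
#'   resolved relative to its directory when not found as-is.
#' @return an [rbc_dataset].
#' @export
read_sequences <- function(manifest_path) {
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  seqs <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, basename(p))
    frames <- tiff::readTIFF(p, all = TRUE)
    lab <- man$label[i]
    rbc_sequence(frames, label = if (is.na(lab)) NULL else lab,
                 acquisition_id = as.character(man$acquisition_id[i]),
                 sequence_id = as.character(man$sequence_id[i]))
  })
  rbc_dataset(seqs)
}

#' Write a movie as a multi-page TIFF with ground-truth CSVs
#'
#' Writes `<stem>.tif` plus, when ground truth is present,
#' `<stem>_tracks.csv` (`cell_id`, `frame`, `x`, `y`, box columns) and
#' `<stem>_labels.csv` (`cell_id`, `label`).
#'
#' @param movie an [rbc_movie].
#' @param path output TIFF path.
#' @param bits TIFF bit depth.
#' @export
write_movie <- function(movie, path, bits = 16) {
  stopifnot(inherits(movie, "rbc_movie"))
  tiff::writeTIFF(movie$frames, path, bits.per.sample = bits,
                  compression = "none")
  stem <- sub("\\.tiff?$", "", path)
  if (!is.null(movie$tracks)) {
    tr <- do.call(rbind, lapply(names(movie$tracks), function(id)
      cbind(cell_id = id, movie$tracks[[id]])))
    write.csv(tr, paste0(stem, "_tracks.csv"), row.names = FALSE)
  }
  if (!is.null(movie$labels))
    write.csv(data.frame(cell_id = names(movie$labels), label = movie$labels),
              paste0(stem, "_labels.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a movie TIFF (or a directory of per-frame TIFFs)
#'
#' A directory is read in lexicographic file order. Ground-truth CSVs
#' written by [write_movie] are picked up when present.
#'
#' @param path multi-page TIFF file or directory of single-frame TIFFs.
#' @param fps frame rate to stamp on the movie.
#' @return an [rbc_movie].
#' @export
read_movie <- function(path, fps = 60) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE))
    if (!length(files)) stop("no TIFF files in ", path)
    frames <- lapply(files, function(f) tiff::readTIFF(f))
    return(rbc_movie(frames, fps = fps))
  }
  frames <- tiff::readTIFF(path, all = TRUE)
  stem <- sub("\\.tiff?$", "", path)
  tracks <- NULL; labels <- NULL
  tp <- paste0(stem, "_tracks.csv")
  if (file.exists(tp)) {
    tr <- read.csv(tp, stringsAsFactors = FALSE)
    tracks <- split(tr[setdiff(names(tr), "cell_id")], tr$cell_id)
  }
  lp <- paste0(stem, "_labels.csv")
  if (file.exists(lp)) {
    ld <- read.csv(lp, stringsAsFactors = FALSE)
    labels <- setNames(ld$label, ld$cell_id)
  }
  rbc_movie(frames, fps = fps, tracks = tracks, labels = labels)
}
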