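#' Labeled image sequence
#'
#' Container for a time-ordered sequence of instance-segmentation label
#' images (integer grids, 0 = background) plus an optional lineage table.
#' Frames are 0-based in time; pixel coordinates are 0-based with axis
#' order (y, x) in 2D and (z, y, x) in 3D.
#'
#' @param frames list of integer matrices (2D) or 3D arrays, all the same
#'   shape; element `i` is frame `i - 1`.
#' @param lineage optional data.frame with columns `label`, `begin`, `end`,
#'   `parent` (0 = no parent), one row per track.
#' @return object of class `labeled_sequence` with fields `frames`,
#'   `lineage`, `dim` (spatial extent) and `ndim`.
#' @export
labeled_sequence <- function(frames, lineage = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1)
  d <- dim(frames[[1]])
  if (is.null(d)) stop("frames must be matrices or arrays")
  for (f in frames) {
    if (!identical(dim(f), d)) stop("all frames must share one shape")
    if (!(is.integer(f) || all(f == floor(f))))
      stop("label images must hold integer labels")
  }
  frames <- lapply(frames, function(f) { storage.mode(f) <- "integer"; f })
  if (is.null(lineage)) {
    lineage <- data.frame(label = integer(), begin = integer(),
                          end = integer(), parent = integer())
  } else {
    lineage <- as.data.frame(lineage)[, c("label", "begin", "end", "parent")]
    if (any(lineage$begin > lineage$end))
      stop("lineage: begin must not exceed end")
    pos <- lineage$parent != 0
    if (any(pos & !(lineage$parent %in% lineage$label)))
      stop("lineage: parent refers to unknown track")
    if (any(pos)) {
      pend <- lineage$end[match(lineage$parent[pos], lineage$label)]
      if (any(pend >= lineage$begin[pos]))
        stop("lineage: parent must end before daughter begins")
    }
  }
  structure(list(frames = frames, lineage = lineage,
                 dim = d, ndim = length(d)),
            class = "labeled_sequence")
}

#' @export
print.labeled_sequence <- function(x, ...) {
  nobj <- sum(vapply(x$frames, function(f) length(unique(f[f > 0])), 1L))
  cat(sprintf("<labeled_sequence> %d frame(s), %s px, %d masks, %d lineage record(s)\n",
              length(x$frames), paste(x$dim, collapse = "x"),
              nobj, nrow(x$lineage)))
  invisible(x)
}

n_masks <- function(seq) {
  sum(vapply(seq$frames, function(f) length(unique(f[f > 0L])), 1L))
}

#' Read a Cell Tracking Challenge style sequence from disk
#'
#' Expects one TIFF label image per frame, named with zero-padded frame
#' indices (e.g. `mask000.tif`, `man_track012.tif`), and optionally a
#' 4-column whitespace lineage file (`res_track.txt` / `man_track.txt`)
#' with rows `label begin end parent`.
#'
#' @param directory path containing the per-frame TIFFs.
#' @param kind `"segmentation"` (lineage optional) or `"ground_truth"`
#'   (lineage required).
#' @return a [labeled_sequence].
#' @export
read_ctc_sequence <- function(directory,
                              kind = c("segmentation", "ground_truth")) {
  kind <- match.arg(kind)
  files <- list.files(directory, pattern = "[0-9]+\\.tiff?$")
  if (!length(files)) stop("no TIFF label images found in ", directory)
  nums <- as.integer(sub("^.*?([0-9]+)\\.tiff?$", "\\1", files))
  o <- order(nums)
  files <- files[o]; nums <- nums[o]
  expect <- seq(min(nums), max(nums))
  if (!identical(nums, expect)) {
    gap <- setdiff(expect, nums)[1]
    stop("missing frame ", gap)
  }
  frames <- lapply(file.path(directory, files), read_label_tiff)
  lin_file <- list.files(directory, pattern = "_track\\.txt$",
                         full.names = TRUE)
  lineage <- NULL
  if (length(lin_file)) {
    tb <- read.table(lin_file[1], header = FALSE)
    names(tb) <- c("label", "begin", "end", "parent")
    lineage <- tb
  } else if (kind == "ground_truth") {
    stop("ground truth sequence requires a lineage file")
  }
  labeled_sequence(frames, lineage)
}

read_label_tiff <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE, all = TRUE)
  if (is.list(img)) {
    if (length(img) == 1L) img <- img[[1]]
    else {  # multi-page: stack to (z, y, x)
      img <- aperm(simplify2array(img), c(3, 1, 2))
    }
  }
  if (!(is.integer(img) || all(img == floor(img))))
    stop("non-integer pixel type in ", path)
  storage.mode(img) <- "integer"
  img
}

write_label_tiff <- function(img, path) {
  mx <- max(img, 1L)
  if (mx > 65535L) stop("labels exceed 16-bit range")
  if (length(dim(img)) == 3L) {
    pages <- lapply(seq_len(dim(img)[1]),
                    function(z) img[z, , ] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else {
    tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L)
  }
}

#' Write a labeled sequence in CTC layout
#'
#' @param seq a [labeled_sequence].
#' @param directory output directory (created if missing).
#' @param prefix file-name prefix for the label TIFFs (default `"mask"`).
#' @param lineage_file lineage file name, written only when lineage rows
#'   exist (default `"res_track.txt"`).
#' @return `directory`, invisibly.
#' @export
write_ctc_sequence <- function(seq, directory, prefix = "mask",
                               lineage_file = "res_track.txt") {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  nT <- length(seq$frames)
  wd <- max(3L, nchar(as.character(nT - 1L)))
  for (t in seq_len(nT) - 1L) {
    fn <- sprintf("%s%0*d.tif", prefix, wd, t)
    write_label_tiff(seq$frames[[t + 1L]], file.path(directory, fn))
  }
  if (nrow(seq$lineage)) {
    write.table(seq$lineage, file.path(directory, lineage_file),
                row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(directory)
}

#' Convert a tracking graph to a labeled sequence
#'
#' Tracks are relabeled to consecutive positive integers (ordered by first
#' frame, then by old id) and painted into per-frame label images; the
#' lineage table records `label begin end parent`.
#'
#' @param graph a `tracking_graph`.
#' @param n_frames total number of frames (defaults to the graph span).
#' @return a [labeled_sequence].
#' @export
as_labeled_sequence <- function(graph, n_frames = NULL) {
  tr <- graph$tracks
  if (is.null(n_frames)) n_frames <- graph$n_frames
  dims <- graph$dim
  if (!length(tr)) {
    frames <- replicate(max(1L, n_frames),
                        array(0L, dim = dims), simplify = FALSE)
    return(labeled_sequence(frames))
  }
  ord <- order(vapply(tr, function(x) min(x$frames), 1L),
               vapply(tr, function(x) x$id, 1L))
  tr <- tr[ord]
  newid <- setNames(seq_along(tr), vapply(tr, function(x) x$id, 1L))
  frames <- replicate(n_frames, array(0L, dim = dims), simplify = FALSE)
  lineage <- data.frame(label = integer(), begin = integer(),
                        end = integer(), parent = integer())
  for (k in seq_along(tr)) {
    x <- tr[[k]]
    for (j in seq_along(x$frames)) {
      t <- x$frames[j]
      pix <- x$masks[[j]]
      if (!length(pix)) next
      img <- frames[[t + 1L]]
      if (any(img[pix] != 0L))
        stop("overlapping pixel claims between tracks in frame ", t)
      img[pix] <- k
      frames[[t + 1L]] <- img
    }
    parent <- 0L
    if (length(x$preds) == 1L) {
      p <- as.character(x$preds)
      if (!is.na(newid[p])) parent <- unname(newid[p])
    }
    lineage <- rbind(lineage,
                     data.frame(label = k, begin = min(x$frames),
                                end = max(x$frames), parent = parent))
  }
  labeled_sequence(frames, lineage)
}

#' Write tracking output in CTC result layout
#'
#' Writes one 16-bit label TIFF per frame plus `res_track.txt` with one
#' line `label begin end parent` per track (parent 0 if none). Requires
#' every track to have at most one predecessor.
#'
#' @param graph a `tracking_graph`.
#' @param directory output directory.
#' @return `directory`, invisibly.
#' @export
write_tracking_result <- function(graph, directory) {
  npred <- vapply(graph$tracks, function(x) length(x$preds), 1L)
  if (any(npred > 1L))
    stop("tracks with more than one predecessor; run untangling first")
  seq <- as_labeled_sequence(graph)
  write_ctc_sequence(seq, directory, prefix = "mask",
                     lineage_file = "res_track.txt")
}

#' Extract per-object position features from a label image
#'
#' For every distinct nonzero label the centroid (mean pixel coordinate),
#' the axis-aligned bounding box, its diagonal length, the pixel set and a
#' set of representative interior mask points are computed. The mask
#' points are the pixels whose Euclidean distance-transform value reaches
#' at least half the mask's maximum depth, subsampled by uniform stride to
#' at most `max_points` points.
#'
#' @param label_image integer matrix or 3D array, 0 = background.
#' @param time frame index (0-based) stored with each object.
#' @param max_points cap on the interior mask-point set size.
#' @return list of `segmented_object`s, each with fields `label`, `time`,
#'   `centroid`, `bbox_min`, `bbox_max`, `bbox_diag`, `npix`, `pix`
#'   (linear indices) and `Q` (matrix of 0-based point coordinates).
#' @export
extract_features <- function(label_image, time = 0L, max_points = 50L) {
  dims <- dim(label_image)
  fg <- which(label_image > 0L)
  if (!length(fg)) return(list())
  labs <- label_image[fg]
  by_lab <- split(fg, labs)
  objs <- lapply(names(by_lab), function(lb) {
    pix <- by_lab[[lb]]
    coords <- pix_coords(pix, dims)
    ctr <- colMeans(coords)
    lo <- apply(coords, 2, min); hi <- apply(coords, 2, max)
    # interior points via distance transform on the bbox crop
    cdims <- hi - lo + 1L
    cd <- sweep(coords, 2, lo)
    cpix <- coords_to_pix(cd, cdims)
    arr <- array(FALSE, dim = cdims); arr[cpix] <- TRUE
    dt <- distance_transform(arr)
    depth <- dt[cpix]
    keep <- which(depth >= 0.5 * max(depth))
    if (length(keep) > max_points) {
      keep <- keep[unique(round(seq(1, length(keep),
                                    length.out = max_points)))]
    }
    structure(list(label = as.integer(lb), time = as.integer(time),
                   centroid = ctr, bbox_min = lo, bbox_max = hi,
                   bbox_diag = sqrt(sum((hi - lo)^2)),
                   npix = length(pix), pix = pix,
                   Q = coords[keep, , drop = FALSE]),
              class = "segmented_object")
  })
  names(objs) <- names(by_lab)
  objs
}

#' Extract features for every frame of a sequence
#'
#' @param seq a [labeled_sequence].
#' @param max_points per-object cap for interior mask points.
#' @return list of class `sequence_features`: `objects[[t+1]]` is the
#'   feature list of frame `t`; `dim` the spatial extent.
#' @export
sequence_features <- function(seq, max_points = 50L) {
  objects <- lapply(seq_along(seq$frames) - 1L, function(t)
    extract_features(seq$frames[[t + 1L]], t, max_points))
  structure(list(objects = objects, dim = seq$dim, ndim = seq$ndim),
            class = "sequence_features")
}

# point-in-box test, 0-based coords
in_bbox <- function(p, lo, hi) all(p >= lo - 1e-9) && all(p <= hi + 1e-9)
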