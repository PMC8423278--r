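#' Track a segmented sequence end to end
#'
#' Runs the full pipeline: candidate discovery (ROI propagation with
#' phase-correlation displacement estimates), coupled minimum-cost flow
#' matching over overlapping windows, lineage untangling, and
#' false-negative gap interpolation. The two post-processing stages can be
#' disabled to reproduce ablation protocols: without untangling,
#' predecessor information of multi-predecessor tracks and successor
#' information of tracks with more than two successors is dropped; without
#' FN correction, each gapped track is cut into contiguous segments and
#' the segments after a gap become new tracks without predecessor.
#'
#' @param seg a [labeled_sequence] (raw instance segmentation) or a
#'   directory in CTC layout.
#' @param raw optional list of raw intensity frames (or a directory of
#'   TIFFs) used for displacement estimation.
#' @param config a [matching_config].
#' @param untangle apply the untangling stage (default `TRUE`).
#' @param fn_correction apply FN gap interpolation (default `TRUE`).
#' @return list with `graph` (the final `tracking_graph`), `result`
#'   (a [labeled_sequence]) and `manifest` (config, timings, logs).
#' @export
track_sequence <- function(seg, raw = NULL, config = matching_config(),
                           untangle = TRUE, fn_correction = TRUE) {
  t_start <- proc.time()[["elapsed"]]
  if (is.character(seg)) seg <- read_ctc_sequence(seg, "segmentation")
  if (is.character(raw)) {
    files <- list.files(raw, pattern = "[0-9]+\\.tiff?$", full.names = TRUE)
    raw <- lapply(files[order(files)], function(f) {
      img <- tiff::readTIFF(f, as.is = TRUE, all = TRUE)
      if (is.list(img)) {
        img <- if (length(img) == 1L) img[[1]] else
          aperm(simplify2array(img), c(3, 1, 2))
      }
      img
    })
  }
  timings <- c()
  tick <- local({
    last <- t_start
    function(name) {
      now <- proc.time()[["elapsed"]]
      timings[name] <<- now - last
      last <<- now
    }
  })

  features <- sequence_features(seg)
  n_objects <- sum(lengths(features$objects))
  tick("features")

  if (n_objects == 0L) {
    warning("empty segmentation: returning an empty result")
    graph <- structure(list(tracks = list(), dim = seg$dim,
                            n_frames = length(seg$frames)),
                       class = "tracking_graph")
    result <- as_labeled_sequence(graph, n_frames = length(seg$frames))
    manifest <- list(config = unclass(config), n_objects = 0,
                     timings = as.list(timings), warnings = "empty input")
    return(list(graph = graph, result = result, manifest = manifest))
  }

  graph <- match_sequence(features, raw, config)
  sols <- graph$solutions
  graph$solutions <- NULL
  tick("matching")

  if (untangle) {
    graph <- untangle_tracks(graph)
  } else {
    # ablation: drop offending link information
    for (i in seq_along(graph$tracks)) {
      if (length(graph$tracks[[i]]$preds) > 1L) {
        for (p in graph$tracks[[i]]$preds) {
          ip <- which(vapply(graph$tracks, function(x) x$id, 1L) == p)
          graph$tracks[[ip]]$succs <-
            setdiff(graph$tracks[[ip]]$succs, graph$tracks[[i]]$id)
        }
        graph$tracks[[i]]$preds <- integer()
      }
    }
    for (i in seq_along(graph$tracks)) {
      if (length(graph$tracks[[i]]$succs) > 2L) {
        for (v in graph$tracks[[i]]$succs) {
          iv <- which(vapply(graph$tracks, function(x) x$id, 1L) == v)
          graph$tracks[[iv]]$preds <-
            setdiff(graph$tracks[[iv]]$preds, graph$tracks[[i]]$id)
        }
        graph$tracks[[i]]$succs <- integer()
      }
    }
  }
  tick("untangling")

  if (fn_correction) {
    graph <- correct_false_negatives(graph)
  } else {
    # ablation: cut gapped tracks into segments; post-gap segments get no
    # predecessor
    tr <- graph$tracks
    next_id <- if (length(tr)) max(vapply(tr, function(x) x$id, 1L)) + 1L else 1L
    out <- list()
    for (x in tr) {
      o <- order(x$frames)
      fr <- x$frames[o]
      segs <- split(seq_along(fr), cumsum(c(1, diff(fr) != 1)))
      if (length(segs) == 1L) { out[[length(out) + 1L]] <- x; next }
      for (si in seq_along(segs)) {
        sel <- segs[[si]]
        nt <- list(id = if (si == 1L) x$id else next_id,
                   frames = fr[sel], labels = x$labels[o][sel],
                   masks = x$masks[o][sel],
                   preds = if (si == 1L) x$preds else integer(),
                   succs = if (si == length(segs)) x$succs else integer())
        if (si > 1L) next_id <- next_id + 1L
        out[[length(out) + 1L]] <- nt
      }
    }
    graph$tracks <- out
  }
  tick("fn_correction")

  result <- as_labeled_sequence(graph, n_frames = length(seg$frames))
  tick("write")

  manifest <- list(
    config = unclass(config),
    untangle = untangle, fn_correction = fn_correction,
    n_objects = n_objects,
    n_tracks = length(graph$tracks),
    n_windows = length(graph$windows),
    stitch_conflicts = graph$stitch_conflicts,
    matching_objectives = vapply(sols, function(s)
      if (is.null(s)) NA_real_ else s$objective, 1),
    untangling_log = graph$untangling_log,
    fn_insertions = length(graph$fn_log),
    timings = as.list(timings))
  list(graph = graph, result = result, manifest = manifest)
}

#' Track a CTC directory and write the result
#'
#' Thin wrapper over [track_sequence] that reads a segmentation directory,
#' tracks it, writes the CTC result layout and a JSON run manifest.
#'
#' @param seg_dir directory with per-frame label TIFFs.
#' @param out_dir output directory.
#' @param raw_dir optional directory with raw TIFFs.
#' @param ... passed to [track_sequence].
#' @return the manifest, invisibly.
#' @export
track_directory <- function(seg_dir, out_dir, raw_dir = NULL, ...) {
  res <- track_sequence(seg_dir, raw = raw_dir, ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_ctc_sequence(res$result, out_dir)
  jsonlite::write_json(res$manifest,
                       file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(res$manifest)
}

#' Structural validity checks for a tracking graph
#'
#' Asserts the invariants every finished run must satisfy: at most one
#' predecessor and at most two successors per track, and (optionally
#' against a reference segmentation) pixel conservation.
#'
#' @param graph a `tracking_graph`.
#' @return `TRUE` (invisibly) or an error describing the violation.
#' @export
check_tracking_validity <- function(graph) {
  for (x in graph$tracks) {
    if (length(x$preds) > 1L)
      stop("track ", x$id, " has ", length(x$preds), " predecessors")
    if (length(x$succs) > 2L)
      stop("track ", x$id, " has ", length(x$succs), " successors")
    if (any(duplicated(x$frames)))
      stop("track ", x$id, " has duplicated frames")
  }
  invisible(TRUE)
}
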