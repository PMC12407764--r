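#' Write a recording to a plain-text container
#'
#' The container is a directory of diff-friendly text files: a JSON
#' manifest (format version, shapes, frame duration, provenance), a sparse
#' spike-count table (`counts.csv`: cell, frame, count), cell positions and
#' the trial table. Arrays round-trip exactly through
#' [read_recording()].
#'
#' @param rec A [recording()].
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  nz <- which(rec$spikes > 0, arr.ind = TRUE)
  counts <- data.frame(cell = nz[, 1], frame = nz[, 2],
                       count = rec$spikes[nz])
  counts <- counts[order(counts$cell, counts$frame), ]
  utils::write.csv(counts, file.path(path, "counts.csv"), row.names = FALSE)
  utils::write.csv(data.frame(cell = seq_len(nrow(rec$positions)),
                              x_um = rec$positions[, 1],
                              y_um = rec$positions[, 2]),
                   file.path(path, "positions.csv"), row.names = FALSE)
  if (!is.null(rec$trials))
    utils::write.csv(rec$trials, file.path(path, "trials.csv"),
                     row.names = FALSE)
  meta <- rec$meta
  meta$ground_truth <- NULL  # planted truth travels separately if at all
  manifest <- list(format = "critperturb-recording", version = "1",
                   n_cells = nrow(rec$spikes), n_frames = ncol(rec$spikes),
                   frame_ms = rec$frame_ms, tc = rec$tc,
                   n_trials = if (is.null(rec$trials)) 0L else nrow(rec$trials),
                   meta = meta)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

io_error <- function(msg) stop(errorCondition(msg,
                                              class = c("critperturb_io_error",
                                                        "error", "condition")))

#' Read a recording from its plain-text container
#'
#' Validates the arrays against the manifest: shapes, non-negative counts,
#' finite positions. A missing trial table yields a spontaneous-only
#' recording; structural problems raise typed `critperturb_io_error`
#' conditions.
#'
#' @param path Container directory written by [write_recording()].
#' @return A [recording()].
#' @export
read_recording <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) io_error("missing manifest.json: not a recording container")
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(manifest$format, "critperturb-recording"))
    io_error("unrecognised container format")
  if (!identical(as.character(manifest$version), "1"))
    io_error(sprintf("unsupported container version '%s'", manifest$version))
  for (f in c("counts.csv", "positions.csv"))
    if (!file.exists(file.path(path, f)))
      io_error(sprintf("missing group '%s'", f))
  counts <- utils::read.csv(file.path(path, "counts.csv"))
  pos <- utils::read.csv(file.path(path, "positions.csv"))
  n_cells <- manifest$n_cells; n_frames <- manifest$n_frames
  if (nrow(pos) != n_cells) io_error("positions shape mismatch with manifest")
  if (nrow(counts) > 0 &&
      (max(counts$cell) > n_cells || max(counts$frame) > n_frames ||
       any(counts$count < 0)))
    io_error("counts out of declared bounds")
  spikes <- matrix(0L, n_cells, n_frames)
  if (nrow(counts) > 0)
    spikes[cbind(counts$cell, counts$frame)] <- as.integer(counts$count)
  trials <- NULL
  tf <- file.path(path, "trials.csv")
  if (file.exists(tf) && manifest$n_trials > 0) {
    trials <- utils::read.csv(tf)
    if (nrow(trials) != manifest$n_trials)
      io_error("trial table length mismatch with manifest")
  }
  recording(spikes = spikes,
            positions = cbind(pos$x_um, pos$y_um),
            tc = as.integer(unlist(manifest$tc)),
            trials = trials, frame_ms = manifest$frame_ms,
            meta = as.list(manifest$meta))
}

#' Write analysis result tables to CSV/JSON files
#'
#' Data frames become CSV files with deterministic column order and fixed
#' float precision; everything else is serialised to JSON. Re-running with
#' identical inputs produces byte-identical files.
#'
#' @param tables Named list of data.frames and/or lists.
#' @param path Output directory.
#' @return Character vector of written file paths, invisibly.
#' @export
write_results <- function(tables, path) {
  stopifnot(is.list(tables), !is.null(names(tables)),
            all(nzchar(names(tables))))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (nm in names(tables)) {
    x <- tables[[nm]]
    if (is.data.frame(x)) {
      num <- vapply(x, is.double, logical(1))
      x[num] <- lapply(x[num], function(v) signif(v, 10))
      f <- file.path(path, paste0(nm, ".csv"))
      utils::write.csv(x, f, row.names = FALSE)
    } else {
      f <- file.path(path, paste0(nm, ".json"))
      jsonlite::write_json(x, f, auto_unbox = TRUE, digits = 10,
                           pretty = TRUE, force = TRUE)
    }
    written <- c(written, f)
  }
  invisible(written)
}
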