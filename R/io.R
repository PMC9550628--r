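# File formats and logging: multi-page TIFF timelapses (with a JSON sidecar
# for pixel size and frame period), JSON-lines event logs, YAML run configs,
# and event evidence bundles.

#' Read and write widefield timelapses as multi-page TIFF
#'
#' Images are stored as uncompressed little-endian 16-bit grayscale
#' multi-page TIFF; counts are integers in 0..65535, so a write/read cycle
#' is bit-identical. Pixel size and frame period travel in a JSON sidecar
#' (`<path>.meta.json`); if the sidecar is absent on read, the arguments (or
#' defaults) are used.
#'
#' @param path TIFF file path.
#' @param pixel_size_nm,frame_period_ms Metadata used if no sidecar exists.
#' @return `read_timelapse()` returns a [wf_timelapse()].
#' @export
read_timelapse <- function(path, pixel_size_nm = 100, frame_period_ms = 50) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  for (p in pages) {
    if (length(dim(p)) != 2L) {
      .err("timelapse TIFF must be single-channel grayscale", "etsted_format_error")
    }
  }
  shapes <- unique(lapply(pages, dim))
  if (length(shapes) != 1L) {
    .err("TIFF pages have mismatched shapes", "etsted_format_error")
  }
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    pixel_size_nm <- meta$pixel_size_nm %||% pixel_size_nm
    frame_period_ms <- meta$frame_period_ms %||% frame_period_ms
  }
  wf_timelapse(lapply(pages, function(p) { storage.mode(p) <- "double"; p }),
               pixel_size_nm, frame_period_ms)
}

#' @rdname read_timelapse
#' @param timelapse A [wf_timelapse()] or 3-D array of counts in 0..65535.
#' @param sidecar Write the metadata sidecar?
#' @export
write_timelapse <- function(timelapse, path, sidecar = TRUE) {
  d <- dim(timelapse)
  stopifnot(length(d) == 3L)
  if (any(timelapse < 0) || any(timelapse > 65535)) {
    .err("counts must lie in 0..65535 for 16-bit TIFF", "etsted_format_error")
  }
  pages <- lapply(seq_len(d[3L]), function(k) {
    m <- timelapse[, , k, drop = TRUE] / 65535
    storage.mode(m) <- "double"
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  if (sidecar) {
    jsonlite::write_json(list(pixel_size_nm = pixel_size_nm(timelapse),
                              frame_period_ms = frame_period_ms(timelapse),
                              n_frames = d[3L]),
                         paste0(path, ".meta.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

.log_schema <- "etsted/event_log/1"

#' Write and reload the experiment event log
#'
#' The log is JSON-lines: the first record carries the run-level parameter
#' dump (schema-versioned), then one self-contained record per event with
#' frame index, both coordinate spaces, salience and trigger status. Every
#' line parses independently, so a truncated log is still readable record by
#' record. Wall-clock per-stage timings are measurement metadata and go to a
#' separate sidecar (`<path>.timings.jsonl`) so the event log itself is
#' bit-reproducible for a fixed seed.
#'
#' @param record An `experiment_record` from [run_experiment()].
#' @param path Log file path.
#' @param timings_sidecar Also write the timing sidecar?
#' @return `write_log()` returns `path` invisibly; `read_event_log()` a list
#'   with `meta` and `events` (tibble).
#' @export
write_log <- function(record, path, timings_sidecar = TRUE) {
  stopifnot(inherits(record, "experiment_record"))
  cfg <- record$config
  meta <- list(schema = .log_schema, type = "run_meta",
               pipeline = cfg$pipeline, mode = cfg$mode,
               buffer_frames = cfg$buffer_frames,
               scan_size_um = cfg$scan_size_um,
               scan_pixel_nm = cfg$scan_pixel_nm,
               scan_frames = cfg$scan_frames, seed = cfg$seed,
               n_frames_processed = record$n_frames_processed,
               n_events = nrow(record$events),
               n_triggers = record$n_triggers)
  lines <- jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)
  ev <- record$events
  if (nrow(ev)) {
    scan_xy <- lapply(record$bundles, `[[`, "scan_coordinate")
    trig_frames <- vapply(record$bundles, function(b) b$event$frame, 0)
    for (i in seq_len(nrow(ev))) {
      bi <- if (isTRUE(ev$triggered[i])) match(ev$frame[i], trig_frames) else NA
      rec <- list(schema = .log_schema, type = "event",
                  frame = ev$frame[i], pipeline = ev$pipeline[i],
                  x_wf = ev$x[i], y_wf = ev$y[i],
                  salience = ev$salience[i],
                  triggered = isTRUE(ev$triggered[i]),
                  x_scan = if (!is.na(bi)) scan_xy[[bi]][["x"]] else NULL,
                  y_scan = if (!is.na(bi)) scan_xy[[bi]][["y"]] else NULL)
      lines <- c(lines, jsonlite::toJSON(rec[!vapply(rec, is.null, TRUE)],
                                         auto_unbox = TRUE, digits = NA))
    }
  }
  writeLines(lines, path)
  if (timings_sidecar && nrow(record$timings)) {
    tl <- vapply(seq_len(nrow(record$timings)), function(i)
      as.character(jsonlite::toJSON(as.list(record$timings[i, ]),
                                    auto_unbox = TRUE)), character(1L))
    writeLines(tl, paste0(path, ".timings.jsonl"))
  }
  invisible(path)
}

#' @rdname write_log
#' @export
read_event_log <- function(path) {
  lines <- readLines(path)
  recs <- lapply(lines, function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
  meta <- recs[[1L]]
  if (!identical(meta$schema, .log_schema)) {
    .err("not an event log", "etsted_format_error")
  }
  evs <- recs[vapply(recs, function(r) identical(r$type, "event"), TRUE)]
  events <- if (length(evs)) bind_rows(lapply(evs, function(r) {
    tibble(frame = r$frame, x = r$x_wf, y = r$y_wf, salience = r$salience,
           pipeline = r$pipeline, triggered = r$triggered,
           x_scan = r$x_scan %||% NA_real_, y_scan = r$y_scan %||% NA_real_)
  })) else tibble(frame = integer(), x = numeric(), y = numeric(),
                  salience = numeric(), pipeline = character(),
                  triggered = logical(), x_scan = numeric(), y_scan = numeric())
  list(meta = meta, events = events)
}

#' Write one event evidence bundle
#'
#' Saves the pre-event widefield buffer and the triggered scan stack as
#' TIFFs named by run id and event index, plus a JSON-lines entry appended
#' to the bundle log. Existing files are only overwritten with
#' `overwrite = TRUE` (the policy is recorded in the log line).
#'
#' @param bundle One element of `experiment_record$bundles`.
#' @param dir Output directory (created if needed).
#' @param run_id Run identifier used in filenames.
#' @param index Event index used in filenames.
#' @param overwrite Allow overwriting existing bundle files?
#' @return Named character vector of written paths.
#' @export
write_event_bundle <- function(bundle, dir, run_id = "run", index = 1L,
                               overwrite = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wf_path <- file.path(dir, sprintf("%s_event%03d_widefield.tif", run_id, index))
  scan_path <- file.path(dir, sprintf("%s_event%03d_scan.tif", run_id, index))
  log_path <- file.path(dir, sprintf("%s_events.jsonl", run_id))
  for (p in c(wf_path, scan_path)) {
    if (file.exists(p) && !overwrite) {
      .err(sprintf("refusing to overwrite '%s' (set overwrite = TRUE)", p),
           "etsted_io_error")
    }
  }
  write_timelapse(bundle$widefield_buffer, wf_path)
  paths <- c(widefield = wf_path, log = log_path)
  if (!is.null(bundle$scan_stack)) {
    scan <- bundle$scan_stack
    write_timelapse(wf_timelapse(scan), scan_path)
    paths <- c(paths, scan = scan_path)
  }
  line <- jsonlite::toJSON(list(schema = .log_schema, type = "bundle",
                                run_id = run_id, index = index,
                                frame = bundle$event$frame,
                                x_wf = bundle$event$x, y_wf = bundle$event$y,
                                x_scan = bundle$scan_coordinate[["x"]],
                                y_scan = bundle$scan_coordinate[["y"]],
                                salience = bundle$event$salience,
                                overwrite = overwrite,
                                widefield = basename(wf_path),
                                scan = if (is.null(bundle$scan_stack)) NULL else
                                  basename(scan_path)),
                           auto_unbox = TRUE, digits = NA)
  cat(paste0(line, "\n"), file = log_path, append = TRUE)
  paths
}

#' Read and write run configuration files
#'
#' Run configs are YAML and round-trip losslessly; every CLI run writes its
#' resolved config next to its outputs so a run can be reproduced
#' bit-identically from the output directory alone.
#'
#' @param config A named list (e.g. an [acquisition_config()], class
#'   dropped).
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}
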