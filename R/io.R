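#' Write trials to the rootwave container format
#'
#' Serializes a list of trials into one hierarchical container file
#' (an RDS-serialized nested list; schema below). Samples round-trip
#' bit-exactly through [read_trials()]. An existing file is never
#' overwritten unless `overwrite = TRUE`; a partially written file is
#' removed on error.
#'
#' Container schema (version 1): a list with elements `format`
#' (`"rootwave-container"`), `version`, and `trials` — each trial a list
#' with `samples` (channels x time numeric matrix, volts), `fs`,
#' `channels` (list of label/segment/side/dominance), `light`
#' (onset_s/offset_s/mode/pulse_rate_Hz/pulse_width_ms), and the three id
#' strings.
#'
#' @param trials List of [trial()] objects (may be empty).
#' @param path Output file path.
#' @param overwrite Replace an existing file.
#' @return Invisibly, `path`.
#' @export
write_trials <- function(trials, path, overwrite = FALSE) {
  if (!all(vapply(trials, inherits, logical(1), "trial"))) {
    stop("trials must be a list of trial objects")
  }
  if (file.exists(path) && !overwrite) {
    stop("refusing to overwrite existing file '", path,
         "' (pass overwrite = TRUE)")
  }
  payload <- list(
    format = "rootwave-container", version = 1L,
    trials = lapply(trials, function(tr) {
      list(samples = tr$samples, fs = tr$fs,
           channels = lapply(tr$channels, unclass),
           light = unclass(tr$light),
           trial_id = tr$trial_id, experiment_id = tr$experiment_id,
           group_id = tr$group_id)
    }))
  ok <- FALSE
  on.exit(if (!ok && file.exists(path)) unlink(path))
  tryCatch(saveRDS(payload, path),
           error = function(e) stop("failed to write '", path, "': ",
                                    conditionMessage(e)))
  ok <- TRUE
  invisible(path)
}

required_field <- function(x, field, where) {
  parts <- strsplit(field, ".", fixed = TRUE)[[1]]
  for (p in parts) {
    if (is.null(x) || !p %in% names(x)) {
      stop("container schema error in ", where, ": missing field '",
           field, "'")
    }
    x <- x[[p]]
  }
  x
}

#' Read trials from the rootwave container format
#'
#' Inverse of [write_trials()]. Metadata is schema-validated; a missing
#' field raises an error naming it (e.g. `light.onset_s`).
#'
#' @param path Container file written by [write_trials()].
#' @return List of [trial()] objects (possibly empty).
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  payload <- tryCatch(readRDS(path),
                      error = function(e) stop("cannot read '", path, "': ",
                                               conditionMessage(e)))
  if (!identical(payload$format, "rootwave-container")) {
    stop("'", path, "' is not a rootwave container")
  }
  lapply(payload$trials, function(rec) {
    where <- paste0("trial ", rec$trial_id %||% "?")
    samples <- required_field(rec, "samples", where)
    fs <- required_field(rec, "fs", where)
    chans <- required_field(rec, "channels", where)
    for (f in c("light.onset_s", "light.offset_s", "light.mode")) {
      required_field(rec, f, where)
    }
    li <- rec$light
    channels <- lapply(chans, function(ch) {
      for (f in c("label", "segment", "side", "dominance")) {
        required_field(ch, f, paste0(where, " channel"))
      }
      channel_meta(ch$label, ch$segment, ch$side, ch$dominance,
                   override = TRUE)
    })
    trial(samples, fs, channels,
          light_epoch(li$onset_s, li$offset_s, li$mode,
                      li$pulse_rate_Hz, li$pulse_width_ms),
          trial_id = required_field(rec, "trial_id", where),
          experiment_id = required_field(rec, "experiment_id", where),
          group_id = required_field(rec, "group_id", where),
          check_fs = TRUE)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a trial to plain columnar text
#'
#' Writes an RFC-4180 CSV with a `time_s` column and one column per
#' channel (header row = channel labels), plus a JSON sidecar
#' (`<path>.meta.json`) holding fs, light epoch, channel metadata and ids,
#' so that [import_trial_csv()] can reconstruct the trial.
#'
#' @param tr A [trial()].
#' @param path CSV output path.
#' @param overwrite Replace existing files.
#' @return Invisibly, `path`.
#' @export
export_trial_csv <- function(tr, path, overwrite = FALSE) {
  stopifnot(inherits(tr, "trial"))
  meta_path <- paste0(path, ".meta.json")
  if (!overwrite && (file.exists(path) || file.exists(meta_path))) {
    stop("refusing to overwrite existing export '", path, "'")
  }
  dt <- data.table::as.data.table(t(tr$samples))
  data.table::setnames(dt, channel_labels(tr))
  dt <- cbind(data.table::data.table(time_s = (seq_len(ncol(tr$samples)) - 1) / tr$fs), dt)
  data.table::fwrite(dt, path)
  meta <- list(fs = tr$fs, light = unclass(tr$light),
               channels = lapply(tr$channels, unclass),
               trial_id = tr$trial_id, experiment_id = tr$experiment_id,
               group_id = tr$group_id)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Import a trial from the CSV export
#'
#' @param path CSV written by [export_trial_csv()] (the
#'   `<path>.meta.json` sidecar must sit next to it).
#' @return A [trial()].
#' @export
import_trial_csv <- function(path) {
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path)) {
    stop("container schema error: missing metadata sidecar '", meta_path, "'")
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = FALSE)
  dt <- data.table::fread(path)
  labs <- vapply(meta$channels, `[[`, character(1), "label")
  samples <- t(as.matrix(dt[, labs, with = FALSE]))
  rownames(samples) <- NULL
  channels <- lapply(meta$channels, function(ch) {
    channel_meta(ch$label, ch$segment, ch$side, ch$dominance, override = TRUE)
  })
  li <- meta$light
  for (f in c("onset_s", "offset_s", "pulse_rate_Hz", "pulse_width_ms")) {
    if (!is.null(li[[f]])) li[[f]] <- as.numeric(li[[f]])
  }
  trial(samples, as.numeric(meta$fs), channels,
        light_epoch(li$onset_s, li$offset_s, li$mode,
                    li$pulse_rate_Hz, li$pulse_width_ms),
        trial_id = meta$trial_id, experiment_id = meta$experiment_id,
        group_id = meta$group_id, check_fs = FALSE)
}
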