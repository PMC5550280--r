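#' Channel metadata for a ventral-root recording channel
#'
#' Describes one suction-electrode channel: which lumbar segment the root
#' exits from, which side of the cord, and whether its motor pool is
#' flexor- or extensor-dominated. By convention L1/L2 roots are
#' flexor-dominated and L5/L6 extensor-dominated; constructing a channel
#' that contradicts the convention requires `override = TRUE`.
#'
#' @param label Channel label, e.g. `"rL2"` (right L2 root).
#' @param segment Lumbar segment, one of `"L1".."L6"`.
#' @param side `"left"` or `"right"`.
#' @param dominance `"flexor"` or `"extensor"`. Defaults to the segment
#'   convention (L1/L2 flexor, L5/L6 extensor).
#' @param override Allow a dominance label inconsistent with the segment
#'   convention (L3/L4 channels always need an explicit dominance).
#' @return A `channel_meta` object.
#' @export
channel_meta <- function(label, segment, side,
                         dominance = NULL, override = FALSE) {
  segment <- match.arg(segment, paste0("L", 1:6))
  side <- match.arg(side, c("left", "right"))
  conventional <- switch(segment,
    L1 = "flexor", L2 = "flexor", L5 = "extensor", L6 = "extensor",
    NULL)
  if (is.null(dominance)) {
    if (is.null(conventional)) {
      stop("channel ", label, ": dominance must be given for segment ", segment)
    }
    dominance <- conventional
  }
  dominance <- match.arg(dominance, c("flexor", "extensor"))
  if (!override && !is.null(conventional) && dominance != conventional) {
    stop("channel ", label, ": dominance '", dominance,
         "' contradicts the ", segment,
         " convention; pass override = TRUE if intended")
  }
  structure(
    list(label = as.character(label), segment = segment, side = side,
         dominance = dominance),
    class = "channel_meta")
}

#' Light-epoch descriptor
#'
#' Records when the optogenetic light was on, in absolute trial time
#' (seconds from recording start; half-open interval `[onset, offset)`),
#' and whether illumination was continuous or a pulse train.
#'
#' @param onset_s,offset_s Light on/off times in seconds. The standard
#'   protocol is `[60, 120)` within a 180-s trial.
#' @param mode `"continuous"` or `"pulse_train"`.
#' @param pulse_rate_Hz,pulse_width_ms Pulse-train parameters (required for
#'   `mode = "pulse_train"`; the standard train is 1-ms pulses at 100 Hz).
#' @return A `light_epoch` object.
#' @export
light_epoch <- function(onset_s = 60, offset_s = 120,
                        mode = c("continuous", "pulse_train"),
                        pulse_rate_Hz = NULL, pulse_width_ms = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(onset_s), is.numeric(offset_s),
            is.finite(onset_s), is.finite(offset_s))
  if (offset_s <= onset_s) stop("light epoch: offset_s must exceed onset_s")
  if (mode == "pulse_train") {
    if (is.null(pulse_rate_Hz) || is.null(pulse_width_ms)) {
      stop("pulse_train light epoch requires pulse_rate_Hz and pulse_width_ms")
    }
    stopifnot(pulse_rate_Hz > 0, pulse_width_ms > 0)
  }
  structure(
    list(onset_s = onset_s, offset_s = offset_s, mode = mode,
         pulse_rate_Hz = pulse_rate_Hz, pulse_width_ms = pulse_width_ms),
    class = "light_epoch")
}

#' One three-minute multichannel ventral-root trial
#'
#' Container for a single trial: a channels x time matrix of raw voltages,
#' the sampling rate, per-channel metadata and the light epoch. The
#' standard protocol is 60 s pre-light, 60 s light, 60 s post-light,
#' digitized at 5 or 10 kHz; other sampling rates are accepted with a
#' warning (set `check_fs = FALSE` to silence it, e.g. for synthesized
#' trials whose rate is a generator parameter).
#'
#' @param samples Numeric matrix, channels in rows, time in columns (volts).
#' @param fs Sampling rate, samples/s.
#' @param channels List of [channel_meta()] objects, one per row.
#' @param light A [light_epoch()].
#' @param trial_id,experiment_id,group_id Identifier strings.
#' @param check_fs Warn when `fs` is not one of the standard acquisition
#'   rates (5000, 10000).
#' @return A `trial` object.
#' @export
trial <- function(samples, fs, channels, light,
                  trial_id = "t1", experiment_id = "e1", group_id = "g1",
                  check_fs = TRUE) {
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop("samples must be a numeric channels x time matrix")
  }
  if (length(channels) != nrow(samples)) {
    stop("channels metadata length (", length(channels),
         ") does not match sample rows (", nrow(samples), ")")
  }
  if (!all(vapply(channels, inherits, logical(1), "channel_meta"))) {
    stop("channels must be a list of channel_meta objects")
  }
  if (!inherits(light, "light_epoch")) stop("light must be a light_epoch")
  stopifnot(is.numeric(fs), length(fs) == 1, fs > 0)
  if (check_fs && !fs %in% c(5000, 10000)) {
    warning("fs = ", fs, " Hz is not a standard acquisition rate (5 or 10 kHz)",
            call. = FALSE)
  }
  dur <- ncol(samples) / fs
  if (light$offset_s > dur) {
    stop("light epoch extends beyond the recording (", round(dur, 3), " s)")
  }
  structure(
    list(samples = samples, fs = fs, channels = channels, light = light,
         trial_id = as.character(trial_id),
         experiment_id = as.character(experiment_id),
         group_id = as.character(group_id)),
    class = "trial")
}

#' @export
print.trial <- function(x, ...) {
  cat(sprintf("<trial %s/%s/%s: %d ch x %.1f s @ %g Hz; light [%g,%g) %s>\n",
              x$group_id, x$experiment_id, x$trial_id,
              nrow(x$samples), ncol(x$samples) / x$fs, x$fs,
              x$light$onset_s, x$light$offset_s, x$light$mode))
  invisible(x)
}

trial_duration_s <- function(tr) ncol(tr$samples) / tr$fs

channel_labels <- function(tr) vapply(tr$channels, `[[`, character(1), "label")

#' A set of trials from one animal/preparation
#'
#' Groups 3-5 trials sharing channel layout and light protocol.
#'
#' @param trials List of [trial()] objects.
#' @param experiment_id,group_id Identifiers (group = cohort/genotype label).
#' @return An `experiment` object.
#' @export
experiment <- function(trials, experiment_id = trials[[1]]$experiment_id,
                       group_id = trials[[1]]$group_id) {
  stopifnot(length(trials) >= 1)
  if (!all(vapply(trials, inherits, logical(1), "trial"))) {
    stop("trials must be a list of trial objects")
  }
  labs <- channel_labels(trials[[1]])
  for (tr in trials[-1]) {
    if (!identical(channel_labels(tr), labs)) {
      stop("all trials in an experiment must share channel labels")
    }
    if (!identical(tr$light[c("onset_s", "offset_s", "mode")],
                   trials[[1]]$light[c("onset_s", "offset_s", "mode")])) {
      stop("all trials in an experiment must share the light protocol")
    }
  }
  structure(list(trials = trials, experiment_id = experiment_id,
                 group_id = group_id),
            class = "experiment")
}
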