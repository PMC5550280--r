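## End-to-end pipeline: preprocess -> wavelet -> normalize -> aggregate
## -> bootstrap compare, driven by a single config object.

#' Pipeline configuration
#'
#' One auditable object holding every stage parameter. The defaults are
#' the analysis constants: filter cutoffs 200 / 10 / 5 Hz (integration)
#' and 0.01-5 Hz (slow potential); 5-s alignment trim to a 170-s record;
#' 3200-point wavelet time base; Morlet centre parameter 6 on 64
#' log-spaced frequencies over 0.1-2 Hz with a 5% ridge power threshold;
#' 10-s edge clip; 19-Hz intermediate resampling of integrated
#' neurograms; control window [10, 55) s, 10-s summary windows; minimum
#' 3 valid trials per experiment; bootstrap with 10,000 iterations and
#' significance tiers 0.05 / 0.01 / 0.001 / 0.0001.
#'
#' @param ... Overrides of any default field.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    lp1_Hz = 200, hp_Hz = 10, lp2_Hz = 5,
    slow_band_Hz = c(0.01, 5),
    trim_s = 5, duration_s = 170,
    n_time = 3200,
    omega0 = 6, n_freq = 64, freq_range_Hz = c(0.1, 2),
    ridge_band_Hz = c(0.1, 2), ridge_threshold_frac = 0.05,
    clip_s = 10,
    firing_resample_Hz = 19,
    control_window_s = c(10, 55),
    light_window_s = c(55, 115),
    summary_width_s = 10,
    min_valid_trials = 3,
    step_artifact_window_s = 0.2,
    boot_iterations = 10000, boot_null = "shift",
    sig_tiers = c(0.05, 0.01, 0.001, 0.0001))
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  with(cfg, {
    if (boot_iterations < 1) stop("config: boot_iterations must be >= 1")
    if (n_time < 2) stop("config: n_time must be >= 2")
    if (min_valid_trials < 1) stop("config: min_valid_trials must be >= 1")
    if (clip_s < 0 || clip_s * 2 >= duration_s) {
      stop("config: clip_s must be non-negative and below half the record")
    }
    if (lp2_Hz >= hp_Hz || hp_Hz >= lp1_Hz) {
      stop("config: filter cascade cutoffs must satisfy lp2 < hp < lp1")
    }
  })
  invisible(cfg)
}

#' Serialize a pipeline config to JSON
#'
#' @param cfg A [pipeline_config()].
#' @param path Optional output file; otherwise the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to file).
#' @export
config_json <- function(cfg, path = NULL) {
  js <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Process one raw trial into normalized series
#'
#' Runs the single-trial stages: step/pulse artifact correction,
#' alignment trim, both filter chains per channel, wavelet spectrograms
#' of the slow potentials, pair phase and joint-ridge frequency for the
#' bilateral-flexor and ipsilateral flexor-extensor pairs, edge
#' clipping, the trial-validity rule, and baseline normalization of
#' frequency, phase and firing.
#'
#' @param tr A [trial()] (>= 180 s, light `[60, 120)`).
#' @param cfg A [pipeline_config()].
#' @param pulse_times Pulse onset times (s) for pulse-train trials.
#' @return List with `valid` (logical), `freq` / `phase` (per pair
#'   class) and `firing` (per channel label, plus per dominance class)
#'   normalized series, and the raw `pairs` indices.
#' @export
process_trial <- function(tr, cfg = pipeline_config(),
                          pulse_times = numeric(0)) {
  stopifnot(inherits(tr, "trial"))
  if (tr$light$mode == "continuous") {
    for (i in seq_len(nrow(tr$samples))) {
      tr$samples[i, ] <- correct_step_artifact(
        tr$samples[i, ], tr$fs, tr$light, cfg$step_artifact_window_s)
    }
  } else if (length(pulse_times) >= 1) {
    for (i in seq_len(nrow(tr$samples))) {
      tr$samples[i, ] <- subtract_pulse_artifacts(tr$samples[i, ], tr$fs,
                                                  pulse_times)
    }
  }
  tr <- align_trim(tr, cfg$trim_s)

  grid <- default_freq_grid(cfg$n_freq, cfg$freq_range_Hz)
  nchan <- nrow(tr$samples)
  specs <- vector("list", nchan)
  firing <- vector("list", nchan)
  for (i in seq_len(nchan)) {
    ig <- integrate_neurogram(tr$samples[i, ], tr$fs,
                              cutoffs = list(lp1 = cfg$lp1_Hz, hp = cfg$hp_Hz,
                                             lp2 = cfg$lp2_Hz))
    firing[[i]] <- normalize_firing(ig, cfg$control_window_s,
                                    cfg$firing_resample_Hz, cfg$n_time,
                                    cfg$duration_s)
    sl <- extract_slow_potential(tr$samples[i, ], tr$fs, cfg$slow_band_Hz)
    specs[[i]] <- cwt_spectrogram(sl, grid, n_time = cfg$n_time,
                                  duration_s = cfg$duration_s,
                                  omega0 = cfg$omega0)
  }
  names(firing) <- channel_labels(tr)

  pairs <- find_pairs(tr$channels)
  labs <- channel_labels(tr)
  phase <- list(); freq <- list(); valid <- TRUE
  for (pc in names(pairs)) {
    ix <- pairs[[pc]]
    ps <- pair_phase(specs[[ix[1]]], specs[[ix[2]]], cfg$ridge_band_Hz,
                     pair = labs[ix], pair_class = pc,
                     threshold_frac = cfg$ridge_threshold_frac)
    ps <- clip_edges(ps, cfg$clip_s)
    ok <- check_validity(ps, cfg$light_window_s, cfg$clip_s)
    valid <- valid && ok
    phase[[pc]] <- ps
    freq[[pc]] <- ps
  }

  norm <- list(valid = valid, pairs = pairs)
  if (valid) {
    norm$freq <- lapply(freq, normalize_frequency, cfg$control_window_s)
    norm$phase <- lapply(phase, normalize_phase, cfg$control_window_s)
    norm$firing <- firing
    dom <- vapply(tr$channels, `[[`, character(1), "dominance")
    norm$firing_class <- lapply(c(flexor = "flexor", extensor = "extensor"),
                                function(cl) {
      sel <- which(dom == cl)
      if (!length(sel)) return(NULL)
      avg <- firing[[sel[1]]]
      if (length(sel) > 1) {
        avg$values <- rowMeans(vapply(firing[sel], `[[`,
                                      numeric(cfg$n_time), "values"))
      }
      avg
    })
  }
  norm
}

series_keys <- function() {
  c("freq_pct.bilateral_flexor", "freq_pct.ipsilateral_flexor_extensor",
    "abs_phase_deg.bilateral_flexor",
    "abs_phase_deg.ipsilateral_flexor_extensor",
    "firing_pct.flexor", "firing_pct.extensor")
}

trial_series <- function(proc) {
  list(
    "freq_pct.bilateral_flexor" = proc$freq$bilateral_flexor,
    "freq_pct.ipsilateral_flexor_extensor" =
      proc$freq$ipsilateral_flexor_extensor,
    "abs_phase_deg.bilateral_flexor" = proc$phase$bilateral_flexor,
    "abs_phase_deg.ipsilateral_flexor_extensor" =
      proc$phase$ipsilateral_flexor_extensor,
    "firing_pct.flexor" = proc$firing_class$flexor,
    "firing_pct.extensor" = proc$firing_class$extensor)
}

#' Process all trials of one experiment and average the valid ones
#'
#' @param trials List of [trial()]s, or an [experiment()].
#' @param cfg A [pipeline_config()].
#' @return `NULL` when fewer than `cfg$min_valid_trials` trials are
#'   valid (a log message is emitted); otherwise a list of
#'   `experiment_average`s keyed by series (see `series_keys`), plus
#'   `n_valid_trials`.
#' @export
process_experiment <- function(trials, cfg = pipeline_config()) {
  if (inherits(trials, "experiment")) trials <- trials$trials
  procs <- lapply(trials, process_trial, cfg = cfg)
  valid <- vapply(procs, `[[`, logical(1), "valid")
  eid <- trials[[1]]$experiment_id
  if (sum(valid) < cfg$min_valid_trials) {
    message("experiment ", eid, " excluded: ", sum(valid),
            " valid trial(s) < required ", cfg$min_valid_trials)
    return(NULL)
  }
  out <- list()
  for (key in series_keys()) {
    sl <- lapply(procs[valid], function(p) trial_series(p)[[key]])
    out[[key]] <- average_experiment(sl, min_valid = cfg$min_valid_trials,
                                     experiment_id = eid)
  }
  out$n_valid_trials <- sum(valid)
  out
}

#' Run the full two-cohort pipeline
#'
#' Generates (or accepts) two cohorts, processes every trial (streaming:
#' raw signals are discarded as soon as each trial's series are
#' extracted), averages per experiment, stacks the experiment averages
#' into time x experiment matrices, runs the pointwise bootstrap t-test
#' per series, and tabulates the standard window summaries.
#'
#' @param groupA,groupB Either [synthetic_scenario()]s (trials are
#'   generated on the fly) or lists of [experiment()]s.
#' @param cfg A [pipeline_config()].
#' @param seed Seed for the bootstrap resampling.
#' @param compare Run the bootstrap comparisons (set `FALSE` to get
#'   averages/summaries only).
#' @return A result bundle: `matrices` (per series key), `comparisons`
#'   (per series key), `window_table` (long data.frame), `truth`
#'   (per-group ground-truth window summaries, synthetic input only),
#'   `n_experiments`, `log`, `config`, and `provenance` (package/R
#'   versions, seed, timestamp).
#' @export
run_pipeline <- function(groupA, groupB, cfg = pipeline_config(),
                         seed = 1L, compare = TRUE) {
  validate_config(cfg)
  bundle <- list(
    config = cfg,
    provenance = list(
      package = as.character(utils::packageVersion("rootwave")),
      r_version = R.version.string,
      seed = as.integer(seed),
      timestamp = format(Sys.time(), tz = "UTC")),
    log = character(0))
  keys <- series_keys()

  one_group <- function(g, gid) {
    averages <- list(); truths <- list()
    if (inherits(g, "synthetic_scenario")) {
      for (e in seq_len(g$n_experiments)) {
        gen <- lapply(seq_len(g$trials_per_experiment), function(k) {
          generate_trial(g, e, k, group_id = gid)
        })
        avg <- process_experiment(lapply(gen, `[[`, "trial"), cfg)
        if (!is.null(avg)) {
          averages[[length(averages) + 1]] <- avg
          truths[[length(truths) + 1]] <-
            lapply(gen, function(x) truth_window_summaries(
              x$truth, cfg$trim_s, cfg$control_window_s, cfg$light_window_s,
              cfg$summary_width_s))
        }
      }
    } else {
      for (ex in g) {
        avg <- process_experiment(ex, cfg)
        if (!is.null(avg)) averages[[length(averages) + 1]] <- avg
      }
    }
    list(averages = averages, truths = truths)
  }

  ga <- one_group(groupA, "A")
  gb <- one_group(groupB, "B")
  nA <- length(ga$averages); nB <- length(gb$averages)
  bundle$log <- c(bundle$log,
                  sprintf("group A: %d experiment(s) retained", nA),
                  sprintf("group B: %d experiment(s) retained", nB))
  if (nA == 0 || nB == 0) stop("a cohort retained no experiments")

  stack <- function(avgs, key) {
    vapply(avgs, function(a) a[[key]]$values, numeric(cfg$n_time))
  }
  bundle$matrices <- lapply(stats::setNames(keys, keys), function(key) {
    list(A = stack(ga$averages, key), B = stack(gb$averages, key))
  })
  bundle$time_axis_s <- ga$averages[[1]][[keys[1]]]$time_axis_s
  bundle$n_experiments <- c(A = nA, B = nB)

  if (compare) {
    if (nA < 2 || nB < 2) stop("bootstrap needs >= 2 experiments per group")
    bundle$comparisons <- lapply(stats::setNames(keys, keys), function(key) {
      bootstrap_ttest_series(bundle$matrices[[key]]$A,
                             bundle$matrices[[key]]$B,
                             n_iter = cfg$boot_iterations, seed = seed,
                             null = cfg$boot_null)
    })
  }

  rows <- list()
  for (key in keys) {
    for (grp in c("A", "B")) {
      avgs <- if (grp == "A") ga$averages else gb$averages
      for (a in avgs) {
        ws <- window_summary(a[[key]], cfg$light_window_s,
                             cfg$summary_width_s)
        rows[[length(rows) + 1]] <- data.frame(
          group = grp, experiment_id = a[[key]]$experiment_id,
          series = key, window = names(ws), value = unname(ws),
          stringsAsFactors = FALSE)
      }
    }
  }
  bundle$window_table <- do.call(rbind, rows)
  if (length(ga$truths) || length(gb$truths)) {
    bundle$truth <- list(A = ga$truths, B = gb$truths)
  }
  class(bundle) <- "pipeline_result"
  bundle
}

#' Group-mean window summary from a pipeline result
#'
#' @param bundle A [run_pipeline()] result.
#' @param series Series key (see the bundle's matrix names).
#' @param window One of `control`, `start_light`, `end_light`,
#'   `after_light`.
#' @param group `"A"` or `"B"`.
#' @return Mean over experiments of the per-experiment window means.
#' @export
group_window_mean <- function(bundle, series, window, group = "A") {
  wt <- bundle$window_table
  sel <- wt$series == series & wt$window == window & wt$group == group
  if (!any(sel)) stop("no rows for ", series, "/", window, "/", group)
  mean(wt$value[sel])
}

#' Mean ground-truth window summary across a synthetic cohort
#'
#' Averages, over the experiments and trials of one group of a
#' synthetic [run_pipeline()] bundle, the ground-truth value of a
#' window summary — the generative target the pipeline estimate is
#' compared against in parameter-recovery studies.
#'
#' @param bundle A [run_pipeline()] result built from scenarios.
#' @param what `"freq_pct"`, `"firing_pct.flexor"`,
#'   `"firing_pct.extensor"`, or `"abs_phase_deg.<pair class>"`.
#' @param window Window name.
#' @param group `"A"` or `"B"`.
#' @return Scalar ground-truth mean.
#' @export
truth_window_mean <- function(bundle, what, window, group = "A") {
  if (is.null(bundle$truth)) stop("bundle carries no ground truth")
  truths <- bundle$truth[[group]]
  per_exp <- vapply(truths, function(tl) {
    mean(vapply(tl, function(tw) {
      parts <- strsplit(what, ".", fixed = TRUE)[[1]]
      v <- tw[[parts[1]]]
      if (length(parts) > 1) v <- v[[parts[2]]]
      v[[window]]
    }, numeric(1)))
  }, numeric(1))
  mean(per_exp)
}
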