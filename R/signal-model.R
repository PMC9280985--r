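# Domain types and trial I/O.
#
# A Trial is one recording: a named set of uniformly sampled channels
# (EMG in volts, accelerometer axes in m/s^2, vertical ground reaction
# force in newtons) plus subject/condition metadata. Trials serialize as a
# TSV numeric matrix (one column per channel) with a JSON metadata sidecar
# `<stem>.meta.json`; calibration (gain, offset) is applied at read so all
# downstream stages see physical units. Event indices are 0-based sample
# indices; time in seconds = index / fs.

#' Muscle channel names
#'
#' The eight surface-EMG channels used throughout: seven cervical muscles
#' plus one jaw adductor, with the semispinalis capitis recorded on both
#' sides.
#' @export
MUSCLES <- c(
  "sternohyoid", "sternocleidomastoid", "masseter", "levator_scapulae",
  "upper_trapezius", "splenius_capitis", "semispinalis_r", "semispinalis_l"
)

#' Condition labels
#'
#' Running conditions (treadmill at constant speed, with/without added head
#' mass and horizontal pulls), countermovement-jump conditions (control,
#' added downward "gravity" force, added head mass, graded submaximal
#' effort), MVC reference trials, and rest.
#' @export
RUN_CONDITIONS <- c(
  "control", "head_mass", "forward_pull", "rearward_pull",
  "forward_pull_mass", "rearward_pull_mass"
)

#' @rdname RUN_CONDITIONS
#' @export
JUMP_CONDITIONS <- c("jump_control", "jump_gravity", "jump_mass", "jump_submax")

ALL_CONDITIONS <- c(RUN_CONDITIONS, JUMP_CONDITIONS,
                    "mvc_flexion", "mvc_extension", "rest")

# Channel roles that are not EMG.
ACCEL_CHANNELS <- c("foot", "neck_vertical", "neck_fore_aft")
FORCE_CHANNEL <- "force_z"

CHANNEL_UNITS <- c("V", "m/s^2", "N")

#' Construct a uniformly sampled channel
#'
#' @param samples numeric vector of physical values (V, m/s^2 or N).
#' @param fs sampling frequency in Hz (> 0).
#' @param units one of `"V"`, `"m/s^2"`, `"N"`.
#' @param gain,offset calibration applied when reading raw stored values:
#'   physical = (raw - offset) * gain. Stored so a written trial can be
#'   recovered exactly.
#' @return object of class `channel_trace`.
#' @export
channel_trace <- function(samples, fs, units = "V", gain = 1, offset = 0) {
  stopifnot_finite(samples, "channel samples")
  if (length(samples) < 1L) stop("channel must have length >= 1", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a positive number", call. = FALSE)
  units <- match.arg(units, CHANNEL_UNITS)
  structure(
    list(samples = as.numeric(samples), fs = fs, units = units,
         gain = gain, offset = offset),
    class = "channel_trace"
  )
}

#' @export
print.channel_trace <- function(x, ...) {
  cat(sprintf("<channel_trace> %d samples @ %g Hz [%s] (%.3g s)\n",
              length(x$samples), x$fs, x$units, length(x$samples) / x$fs))
  invisible(x)
}

#' @export
length.channel_trace <- function(x) length(x$samples)

#' Construct a trial
#'
#' Bundles the channels of a single recording with subject and condition
#' metadata, and validates the invariants: shared sampling rate, positive
#' body mass, and condition-specific required channels (running trials need
#' the foot and neck accelerometers, jump trials the vertical force).
#'
#' @param subject_id subject identifier (character).
#' @param condition one of the condition labels (see [RUN_CONDITIONS]).
#' @param channels named list of [channel_trace] objects. EMG channels are
#'   named by muscle (see [MUSCLES]); accelerometer channels `"foot"`,
#'   `"neck_vertical"`, `"neck_fore_aft"`; vertical force `"force_z"`.
#' @param body_mass subject body mass in kg.
#' @param head_added_mass mass added to the head harness in kg (default 0).
#' @param applied_force applied horizontal or vertical force in N: either a
#'   scalar or a numeric series logged over the trial (default 0).
#' @param effort nominal effort fraction in (0, 1] for graded submaximal
#'   jumps, `NA` otherwise.
#' @return object of class `nc_trial`.
#' @export
trial <- function(subject_id, condition, channels, body_mass,
                  head_added_mass = 0, applied_force = 0, effort = NA_real_) {
  condition <- match.arg(condition, ALL_CONDITIONS)
  if (!is.list(channels) || length(channels) == 0L ||
      is.null(names(channels)) || any(names(channels) == ""))
    stop("channels must be a non-empty named list", call. = FALSE)
  if (!all(vapply(channels, inherits, logical(1), "channel_trace")))
    stop("all channels must be channel_trace objects", call. = FALSE)
  fs <- vapply(channels, function(ch) ch$fs, numeric(1))
  if (length(unique(fs)) != 1L)
    stop("all channels in a trial must share the sampling rate", call. = FALSE)
  if (!is.numeric(body_mass) || body_mass <= 0)
    stop("body_mass must be > 0", call. = FALSE)
  if (condition %in% RUN_CONDITIONS) {
    need <- c("foot", "neck_vertical")
    miss <- setdiff(need, names(channels))
    if (length(miss))
      stop("running trial missing required channels: ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  if (condition %in% c("jump_control", "jump_gravity", "jump_mass", "jump_submax") &&
      !(FORCE_CHANNEL %in% names(channels)))
    stop("jump trial missing required channel: force_z", call. = FALSE)
  structure(
    list(subject_id = as.character(subject_id), condition = condition,
         channels = channels, body_mass = body_mass,
         head_added_mass = head_added_mass,
         applied_force = as.numeric(applied_force), effort = effort),
    class = "nc_trial"
  )
}

#' @export
print.nc_trial <- function(x, ...) {
  ch <- x$channels[[1L]]
  cat(sprintf("<trial> subject %s, condition %s: %d channels, %d samples @ %g Hz\n",
              x$subject_id, x$condition, length(x$channels),
              length(ch$samples), ch$fs))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

trial_fs <- function(trial) trial$channels[[1L]]$fs
trial_length <- function(trial) length(trial$channels[[1L]]$samples)

#' Construct an event set
#'
#' Analysis-window boundaries: either foot-strike sample indices for
#' running strides, or the onset/takeoff/landing triple of a jump. Indices
#' are 0-based and must be strictly increasing.
#'
#' @param kind `"foot_strikes"` or `"jump_phases"`.
#' @param times integer vector of 0-based sample indices (foot strikes).
#' @param onset,takeoff,landing 0-based indices of the jump phases.
#' @param n_samples trial length, used to validate indices if supplied.
#' @return object of class `event_set`.
#' @export
event_set <- function(kind = c("foot_strikes", "jump_phases"), times = NULL,
                      onset = NULL, takeoff = NULL, landing = NULL,
                      n_samples = NULL) {
  kind <- match.arg(kind)
  if (kind == "foot_strikes") {
    times <- as.integer(times)
    if (length(times) < 1L || any(times < 0L))
      stop("foot-strike events must be non-negative indices", call. = FALSE)
    if (is.unsorted(times, strictly = TRUE))
      stop("event times must be strictly increasing", call. = FALSE)
    if (!is.null(n_samples) && any(times >= n_samples))
      stop("event index beyond trial length", call. = FALSE)
    out <- list(kind = kind, times = times)
  } else {
    idx <- c(onset = onset, takeoff = takeoff, landing = landing)
    if (length(idx) != 3L || anyNA(idx))
      stop("jump phases need onset, takeoff, landing", call. = FALSE)
    if (!(onset < takeoff && takeoff < landing))
      stop("jump phases must satisfy onset < takeoff < landing", call. = FALSE)
    if (!is.null(n_samples) && landing >= n_samples)
      stop("event index beyond trial length", call. = FALSE)
    out <- list(kind = kind, onset = as.integer(onset),
                takeoff = as.integer(takeoff), landing = as.integer(landing))
  }
  structure(out, class = "event_set")
}

#' @export
print.event_set <- function(x, ...) {
  if (x$kind == "foot_strikes")
    cat(sprintf("<event_set> %d foot strikes\n", length(x$times)))
  else
    cat(sprintf("<event_set> jump phases: onset %d, takeoff %d, landing %d\n",
                x$onset, x$takeoff, x$landing))
  invisible(x)
}

#' Accept or reject a pull trial on its applied-force record
#'
#' Pull trials are rejected when the logged applied force ever leaves the
#' acceptance band (defaults 150-200 N). The force record may be a
#' continuously logged series or a single spot-checked scalar.
#'
#' @param trial an [trial] object.
#' @param min_n,max_n acceptance band in newtons.
#' @return `TRUE` to accept, `FALSE` to reject.
#' @export
validate_applied_force <- function(trial, min_n = 150, max_n = 200) {
  f <- trial$applied_force
  is_pull <- trial$condition %in% c("forward_pull", "rearward_pull",
                                    "forward_pull_mass", "rearward_pull_mass")
  if (is_pull && (length(f) == 0L || all(f == 0)))
    stop("pull-condition trial carries no applied-force record", call. = FALSE)
  stopifnot_finite(f, "applied force")
  !(any(f < min_n) || any(f > max_n))
}

#' Write a trial to a TSV + JSON sidecar bundle
#'
#' Stores the raw (de-calibrated) channel matrix as `<stem>.tsv` with a
#' header row of channel names, and the metadata (subject, condition,
#' sampling rate, per-channel units and calibration) as `<stem>.meta.json`.
#' [read_trial] on the result reproduces the trial to serialization
#' precision (15 significant digits).
#'
#' @param trial an [trial] object.
#' @param stem file path without extension.
#' @return the stem, invisibly.
#' @export
write_trial <- function(trial, stem) {
  raw <- lapply(trial$channels, function(ch) ch$samples / ch$gain + ch$offset)
  mat <- do.call(cbind, raw)
  colnames(mat) <- names(trial$channels)
  tsv <- paste0(stem, ".tsv")
  meta <- paste0(stem, ".meta.json")
  utils::write.table(format(mat, digits = 15, trim = TRUE, scientific = NA),
                     tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  chan_meta <- lapply(trial$channels, function(ch)
    list(fs = ch$fs, units = ch$units, gain = ch$gain, offset = ch$offset))
  jsonlite::write_json(
    list(subject_id = trial$subject_id, condition = trial$condition,
         fs = trial_fs(trial), body_mass = trial$body_mass,
         head_added_mass = trial$head_added_mass,
         applied_force = trial$applied_force, effort = trial$effort,
         channels = chan_meta),
    meta, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(stem)
}

#' Read a trial bundle
#'
#' Reads `<stem>.tsv` + `<stem>.meta.json`, applies per-channel calibration
#' (physical = (raw - offset) * gain), and validates all trial invariants.
#'
#' @param stem file path without extension (as written by [write_trial]).
#' @return an [trial] object.
#' @export
read_trial <- function(stem) {
  tsv <- paste0(stem, ".tsv")
  meta_path <- paste0(stem, ".meta.json")
  if (!file.exists(meta_path))
    stop("missing metadata sidecar: ", meta_path, call. = FALSE)
  if (!file.exists(tsv))
    stop("missing trial data file: ", tsv, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$fs) || !is.numeric(meta$fs) || meta$fs <= 0)
    stop("sidecar fs must be a positive number", call. = FALSE)
  mat <- utils::read.table(tsv, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "numeric")
  chans <- names(meta$channels)
  if (!setequal(chans, colnames(mat)))
    stop("sidecar channel map does not match TSV columns", call. = FALSE)
  channels <- lapply(chans, function(nm) {
    cm <- meta$channels[[nm]]
    channel_trace((mat[[nm]] - cm$offset) * cm$gain, fs = cm$fs,
                  units = cm$units, gain = cm$gain, offset = cm$offset)
  })
  names(channels) <- chans
  trial(meta$subject_id, meta$condition, channels, meta$body_mass,
        head_added_mass = meta$head_added_mass %||% 0,
        applied_force = meta$applied_force %||% 0,
        effort = meta$effort %||% NA_real_)
}

#' Write / read a study manifest
#'
#' A study manifest (YAML) lists the subjects, the per-subject trial file
#' stems keyed by condition, and the per-subject muscle availability mask
#' (electrodes discarded for a subject are dropped from every analysis,
#' reducing that muscle's N).
#'
#' @param manifest a list with elements `subjects` (character), `trials`
#'   (per subject, per condition: file stem or vector of stems), and
#'   `muscles` (per subject: character vector of usable muscle channels).
#' @param path YAML file path.
#' @return `read_manifest` returns the manifest list.
#' @export
write_manifest <- function(manifest, path) {
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' @rdname write_manifest
#' @param check if `TRUE`, verify every referenced trial bundle exists.
#' @export
read_manifest <- function(path, check = TRUE) {
  manifest <- yaml::read_yaml(path)
  if (check) {
    base <- dirname(path)
    for (sub in names(manifest$trials)) {
      for (stems in manifest$trials[[sub]]) {
        for (stem in stems) {
          p <- if (file.exists(paste0(stem, ".tsv"))) stem else file.path(base, stem)
          if (!file.exists(paste0(p, ".tsv")))
            stop("manifest references missing trial: ", stem, call. = FALSE)
        }
      }
    }
  }
  manifest
}
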