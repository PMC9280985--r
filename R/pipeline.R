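# Orchestration: run the full running / kinematics / jump analyses over a
# study (in-memory synthetic_study or a study directory written by
# write_study), producing per-subject tables, ensemble profiles, condition
# comparison tables and summary statistics as plain data frames, with a
# provenance block for reproducibility.

RUN_COMPARISONS <- list(
  head_mass          = "control",
  forward_pull       = "control",
  rearward_pull      = "control",
  forward_pull_mass  = "forward_pull",
  rearward_pull_mass = "rearward_pull"
)

as_study <- function(study) {
  if (inherits(study, "synthetic_study")) return(study)
  if (is.character(study) && length(study) == 1L) return(read_study(study))
  stop("study must be a synthetic_study or a study directory", call. = FALSE)
}

# Per-subject, per-muscle background level and MVC reference from the rest
# and MVC trials. Flexor muscles are referenced against the neck-flexion
# MVC trials, extensors against neck extension.
subject_references <- function(sub) {
  rest <- sub$trials$rest
  if (is.null(rest))
    stop("subject has no rest trial for background estimation", call. = FALSE)
  refs <- list()
  for (m in sub$muscles) {
    direction <- if (m %in% FLEXOR_MUSCLES) "mvc_flexion" else "mvc_extension"
    mvc_trials <- sub$trials[[direction]]
    if (is.null(mvc_trials))
      stop("subject has no ", direction, " trials", call. = FALSE)
    bg <- estimate_background(rectify(rest$channels[[m]]))
    mvc_traces <- lapply(mvc_trials, function(tr)
      subtract_background(rectify(tr$channels[[m]]), bg))
    refs[[m]] <- list(background = bg, reference = mvc_reference(mvc_traces))
  }
  refs
}

#' Run the running EMG analysis over a study
#'
#' Executes the full chain for every subject and running condition:
#' foot-strike detection, cycle segmentation (capped at `max_cycles`),
#' rectification, background subtraction, MVC normalization, per-cycle
#' integration and time-normalized binning; then per-subject
#' manipulation/baseline activation ratios with paired one-tailed Wilcoxon
#' tests and Holm correction (added-head-mass and pull conditions against
#' control; pull-plus-mass conditions against the matching pull trials),
#' and across-subject ensemble profiles with 95% CIs.
#'
#' @param study a `synthetic_study` or study directory path.
#' @param conditions running conditions to analyse (defaults to those
#'   present).
#' @param n_bins bins per stride profile (default 100).
#' @param max_cycles cycles retained per trial (default 20).
#' @param alpha familywise alpha.
#' @param direction one-tailed test direction (manipulation vs baseline).
#' @param stride_freq_hint expected stride frequency for strike detection.
#' @return list of class `result_bundle`: `integrals` (per subject x
#'   condition x muscle mean cycle integral, %MVC*s), `comparisons` (named
#'   list of [ratio_table]s), `profiles` (per condition, per muscle
#'   [ensemble_average]), `provenance`.
#' @export
run_running_analysis <- function(study, conditions = NULL, n_bins = 100L,
                                 max_cycles = 20L, alpha = 0.05,
                                 direction = "greater",
                                 stride_freq_hint = NULL) {
  study <- as_study(study)
  hint <- stride_freq_hint %||%
    (if (!is.null(study$config)) study$config$stride_frequency else 1.4)
  present <- names(study$subjects[[1L]]$trials)
  conditions <- conditions %||% intersect(RUN_CONDITIONS, present)
  missing_conds <- setdiff(conditions, present)
  if (length(missing_conds))
    stop("study lacks running conditions: ",
         paste(missing_conds, collapse = ", "), call. = FALSE)

  rows <- list()
  prof <- list()  # prof[[cond]][[muscle]] -> list of subject profiles
  for (id in names(study$subjects)) {
    sub <- study$subjects[[id]]
    refs <- subject_references(sub)
    for (cond in conditions) {
      tr <- sub$trials[[cond]]
      events <- detect_foot_strikes(tr$channels$foot, stride_freq_hint = hint)
      cycles <- segment_cycles(events, max_cycles = max_cycles)
      for (m in sub$muscles) {
        act <- normalize_emg(rectify(tr$channels[[m]]),
                             refs[[m]]$background, refs[[m]]$reference)
        integrals <- vapply(cycles, function(w) integrate_cycle(act, w),
                            numeric(1))
        cyc_prof <- t(vapply(cycles, function(w) bin_profile(act, w, n_bins),
                             numeric(n_bins)))
        rows[[length(rows) + 1L]] <- data.frame(
          subject = id, condition = cond, muscle = m,
          n_cycles = length(cycles), mean_cycle_integral = mean(integrals))
        prof[[cond]][[m]][[id]] <- colMeans(cyc_prof)
      }
    }
  }
  integrals <- do.call(rbind, rows)

  comparisons <- list()
  for (manip in intersect(names(RUN_COMPARISONS), conditions)) {
    base_cond <- RUN_COMPARISONS[[manip]]
    if (!base_cond %in% conditions) next
    baseline <- list(); manipulation <- list()
    for (m in MUSCLES) {
      b <- integrals[integrals$condition == base_cond & integrals$muscle == m, ]
      x <- integrals[integrals$condition == manip & integrals$muscle == m, ]
      common <- intersect(b$subject, x$subject)
      if (length(common) == 0L) next
      baseline[[m]] <- b$mean_cycle_integral[match(common, b$subject)]
      manipulation[[m]] <- x$mean_cycle_integral[match(common, x$subject)]
    }
    if (length(baseline))
      comparisons[[paste0(manip, "_vs_", base_cond)]] <-
        ratio_table(baseline, manipulation, direction = direction, alpha = alpha)
  }

  profiles <- lapply(prof, function(by_muscle)
    lapply(by_muscle, ensemble_average))

  structure(list(integrals = integrals, comparisons = comparisons,
                 profiles = profiles,
                 provenance = result_provenance(study)),
            class = "result_bundle")
}

#' Run the accelerometer kinematics analysis over a study
#'
#' For every subject and running condition: 10-ms smoothing, foot-strike
#' detection, stride-to-step splitting, flight-phase vertical baselining,
#' mode-dependent fore-aft offset removal (cycle mean for control and
#' added-head-mass, per-step peaks for forward pulls, per-step minima for
#' rearward pulls), and per-step statistics. The condition summary reports
#' the mean vertical acceleration over the whole step and the fore-aft
#' mean over the accelerating (second) half of the step for control-like
#' conditions or over the entire step for pull conditions.
#'
#' @inheritParams run_running_analysis
#' @return list of class `result_bundle` with `steps` (per-step table) and
#'   `summary` (per-condition group mean and SD).
#' @export
run_kinematics_analysis <- function(study, conditions = NULL,
                                    stride_freq_hint = NULL) {
  study <- as_study(study)
  hint <- stride_freq_hint %||%
    (if (!is.null(study$config)) study$config$stride_frequency else 1.4)
  present <- names(study$subjects[[1L]]$trials)
  conditions <- conditions %||% intersect(RUN_CONDITIONS, present)

  step_rows <- list()
  subj_rows <- list()
  for (id in names(study$subjects)) {
    sub <- study$subjects[[id]]
    for (cond in conditions) {
      tr <- sub$trials[[cond]]
      vert <- rolling_mean(tr$channels$neck_vertical, 10)
      fa <- rolling_mean(tr$channels$neck_fore_aft, 10)
      events <- detect_foot_strikes(tr$channels$foot, stride_freq_hint = hint)
      steps <- stride_to_steps(events)
      v_off <- vertical_baseline_flight(vert, events)
      mode <- switch(cond,
                     forward_pull = , forward_pull_mass = "step_peaks",
                     rearward_pull = , rearward_pull_mass = "step_minima",
                     "cycle_mean")
      h_off <- horizontal_offset(fa, steps, mode = mode)
      vert$samples <- vert$samples - v_off
      fa$samples <- fa$samples - h_off
      st <- step_stats(vert, fa, steps)
      st$subject <- id; st$condition <- cond
      step_rows[[length(step_rows) + 1L]] <- st
      fa_mean <- if (mode == "cycle_mean") mean(st$mean_fore_aft_second_half)
                 else mean(st$mean_fore_aft)
      subj_rows[[length(subj_rows) + 1L]] <- data.frame(
        subject = id, condition = cond,
        mean_vertical = mean(st$mean_vertical), mean_fore_aft = fa_mean)
    }
  }
  per_subject <- do.call(rbind, subj_rows)
  summary <- do.call(rbind, lapply(split(per_subject, per_subject$condition),
    function(d) data.frame(
      condition = d$condition[1L], n = nrow(d),
      vertical_mean = mean(d$mean_vertical),
      vertical_sd = stats::sd(d$mean_vertical),
      fore_aft_mean = mean(d$mean_fore_aft),
      fore_aft_sd = stats::sd(d$mean_fore_aft))))
  rownames(summary) <- NULL
  structure(list(steps = do.call(rbind, step_rows),
                 per_subject = per_subject, summary = summary,
                 provenance = result_provenance(study)),
            class = "result_bundle")
}

# Per-trial jump EMG metrics over the onset-to-landing window.
jump_emg_metrics <- function(act, phases, n_bins) {
  w <- c(phases$onset, phases$landing)
  y <- act$samples[(w[1L] + 1L):w[2L]]
  list(metrics = c(maximum = max(y), mean = mean(y),
                   integrated = trapz_uniform(y, 1 / act$fs)),
       profile = bin_profile(act, w, n_bins))
}

#' Run the countermovement-jump analysis over a study
#'
#' For every jump trial: quiet-standing baseline, phase detection,
#' impulse-momentum kinetics, and per-muscle maximum, mean and integrated
#' activation over the onset-to-landing window with a 200-bin profile.
#' Per-subject condition means feed ratio tables (manipulation over
#' control, per metric) with paired one-tailed Wilcoxon tests under Holm
#' correction, group impulse summaries with percent changes, and, when
#' graded submaximal jumps are present, a per-muscle exponential fit of
#' integrated activation against net impulse. Trials whose phases cannot
#' be detected are skipped and listed in `skipped`.
#'
#' @inheritParams run_running_analysis
#' @param n_bins bins per jump profile (default 200).
#' @param directions named one-tailed directions per manipulation
#'   (defaults: added gravity tests a decrease, added head mass an
#'   increase, per the postural-stabilization predictions).
#' @param normalize express activation in %MVC (requires MVC/rest trials).
#'   With `FALSE`, metrics stay in rectified volts; ratio tables are
#'   unchanged because the per-subject reference cancels in ratios.
#' @return list of class `result_bundle` with `kinetics` (per-trial),
#'   `impulse_summary`, `impulse_changes`, `emg_metrics` (per subject x
#'   condition x muscle), `comparisons` (per manipulation x metric ratio
#'   tables), `profiles`, `effort_fits`, `skipped`, `provenance`.
#' @export
run_jump_analysis <- function(study, conditions = NULL, n_bins = 200L,
                              alpha = 0.05,
                              directions = c(jump_gravity = "less",
                                             jump_mass = "greater"),
                              normalize = TRUE) {
  study <- as_study(study)
  present <- names(study$subjects[[1L]]$trials)
  max_conds <- intersect(c("jump_control", "jump_gravity", "jump_mass"),
                         conditions %||% present)
  has_submax <- "jump_submax" %in% (conditions %||% present)

  kin_rows <- list(); met_rows <- list(); skipped <- list()
  prof <- list()
  effort_x <- list(); effort_y <- list()
  for (id in names(study$subjects)) {
    sub <- study$subjects[[id]]
    refs <- if (normalize) subject_references(sub) else NULL
    all_conds <- c(max_conds, if (has_submax) "jump_submax")
    for (cond in all_conds) {
      trs <- sub$trials[[cond]]
      if (inherits(trs, "nc_trial")) trs <- list(trs)
      for (k in seq_along(trs)) {
        tr <- trs[[k]]
        res <- tryCatch({
          force <- tr$channels$force_z
          w_eff <- body_weight_baseline(force)
          phases <- detect_jump_phases(force, w_eff)
          kin <- com_kinematics(force, tr$body_mass + tr$head_added_mass,
                                w_eff, phases)
          list(kin = kin, phases = phases)
        }, error = function(e) e)
        if (inherits(res, "error")) {
          skipped[[length(skipped) + 1L]] <- data.frame(
            subject = id, condition = cond, trial = k,
            reason = conditionMessage(res))
          next
        }
        kin <- res$kin
        kin_rows[[length(kin_rows) + 1L]] <- data.frame(
          subject = id, condition = cond, trial = k,
          effort = tr$effort, body_weight = kin$body_weight,
          net_impulse = kin$net_impulse,
          takeoff_velocity = kin$takeoff_velocity,
          jump_height = kin$jump_height,
          jump_height_flight = kin$jump_height_flight)
        for (m in sub$muscles) {
          act <- if (normalize)
            normalize_emg(rectify(tr$channels[[m]]),
                          refs[[m]]$background, refs[[m]]$reference)
          else rectify(tr$channels[[m]])
          jm <- jump_emg_metrics(act, res$phases, n_bins)
          met_rows[[length(met_rows) + 1L]] <- data.frame(
            subject = id, condition = cond, trial = k, muscle = m,
            maximum = jm$metrics[["maximum"]], mean = jm$metrics[["mean"]],
            integrated = jm$metrics[["integrated"]])
          if (cond %in% max_conds)
            prof[[cond]][[m]][[id]] <- if (is.null(prof[[cond]][[m]][[id]]))
              jm$profile / length(trs) else
                prof[[cond]][[m]][[id]] + jm$profile / length(trs)
          if (cond %in% c("jump_submax", "jump_control")) {
            effort_x[[m]] <- c(effort_x[[m]], kin$net_impulse)
            effort_y[[m]] <- c(effort_y[[m]], jm$metrics[["integrated"]])
          }
        }
      }
    }
  }
  kinetics <- do.call(rbind, kin_rows)
  metrics <- do.call(rbind, met_rows)

  # per-subject condition means
  agg <- stats::aggregate(cbind(maximum, mean, integrated) ~
                            subject + condition + muscle,
                          data = metrics, FUN = mean)
  imp_subj <- stats::aggregate(net_impulse ~ subject + condition,
                               data = kinetics[kinetics$condition %in% max_conds, ],
                               FUN = mean)
  impulse_summary <- do.call(rbind, lapply(split(imp_subj, imp_subj$condition),
    function(d) data.frame(condition = d$condition[1L], n = nrow(d),
                           impulse_mean = mean(d$net_impulse),
                           impulse_sd = stats::sd(d$net_impulse))))
  rownames(impulse_summary) <- NULL

  impulse_changes <- list()
  ctrl <- imp_subj$net_impulse[imp_subj$condition == "jump_control"]
  for (cond in setdiff(max_conds, "jump_control")) {
    manip <- imp_subj$net_impulse[imp_subj$condition == cond]
    if (length(ctrl) && length(manip))
      impulse_changes[[cond]] <- impulse_change(ctrl, manip)
  }

  comparisons <- list()
  for (cond in setdiff(max_conds, "jump_control")) {
    dir_cond <- directions[[cond]] %||% "greater"
    for (metric in c("maximum", "mean", "integrated")) {
      baseline <- list(); manipulation <- list()
      for (m in MUSCLES) {
        b <- agg[agg$condition == "jump_control" & agg$muscle == m, ]
        x <- agg[agg$condition == cond & agg$muscle == m, ]
        common <- intersect(b$subject, x$subject)
        if (length(common) == 0L) next
        baseline[[m]] <- b[[metric]][match(common, b$subject)]
        manipulation[[m]] <- x[[metric]][match(common, x$subject)]
      }
      if (length(baseline))
        comparisons[[paste0(cond, "_", metric)]] <-
          ratio_table(baseline, manipulation, direction = dir_cond,
                      alpha = alpha)
    }
  }

  effort_fits <- NULL
  if (has_submax && length(effort_x)) {
    effort_fits <- lapply(names(effort_x), function(m)
      fit_exponential(effort_x[[m]], effort_y[[m]]))
    names(effort_fits) <- names(effort_x)
  }

  profiles <- lapply(prof, function(by_muscle)
    lapply(by_muscle, function(by_subject)
      ensemble_average(do.call(rbind, by_subject))))

  structure(list(kinetics = kinetics, emg_metrics = agg,
                 impulse_summary = impulse_summary,
                 impulse_changes = impulse_changes,
                 comparisons = comparisons, profiles = profiles,
                 effort_fits = effort_fits,
                 skipped = if (length(skipped)) do.call(rbind, skipped) else NULL,
                 provenance = result_provenance(study)),
            class = "result_bundle")
}

result_provenance <- function(study) {
  list(seed = if (!is.null(study$config)) study$config$seed else NA_integer_,
       n_subjects = length(study$subjects),
       package_version = as.character(utils::packageVersion("neckcore")))
}

#' @export
print.result_bundle <- function(x, ...) {
  cat("<result_bundle>", paste(setdiff(names(x), "provenance"), collapse = ", "),
      "\n")
  if (length(x$comparisons)) {
    cat("comparisons:\n")
    for (nm in names(x$comparisons)) {
      tab <- x$comparisons[[nm]]
      cat(sprintf("  %s: %d muscles, %d significant\n", nm, nrow(tab),
                  sum(tab$reject, na.rm = TRUE)))
    }
  }
  invisible(x)
}

#' Write a result bundle to TSV files
#'
#' Writes every tabular element (integrals, comparisons, kinetics,
#' summaries, profiles) as TSV under `dir`, plus a JSON provenance block.
#'
#' @param bundle a `result_bundle`.
#' @param dir output directory (created if needed).
#' @export
write_results <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name)
    utils::write.table(df, file.path(dir, paste0(name, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  for (nm in c("integrals", "kinetics", "emg_metrics", "impulse_summary",
               "steps", "per_subject", "summary")) {
    if (!is.null(bundle[[nm]])) wr(bundle[[nm]], nm)
  }
  for (nm in names(bundle$comparisons))
    wr(bundle$comparisons[[nm]], paste0("comparison_", nm))
  for (cond in names(bundle$profiles)) {
    for (m in names(bundle$profiles[[cond]])) {
      p <- bundle$profiles[[cond]][[m]]
      wr(data.frame(bin = seq_len(p$n_bins), mean = p$bin_means,
                    ci_low = p$ci_low, ci_high = p$ci_high),
         paste0("profile_", cond, "_", m))
    }
  }
  if (!is.null(bundle$effort_fits)) {
    ef <- do.call(rbind, lapply(names(bundle$effort_fits), function(m) {
      f <- bundle$effort_fits[[m]]
      data.frame(muscle = m, a = f$a, b = f$b, rss = f$rss, n = f$n,
                 converged = f$converged)
    }))
    wr(ef, "effort_fits")
  }
  jsonlite::write_json(bundle$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
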